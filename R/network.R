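#' Network and run configuration
#'
#' Collects every knob of a network realization and simulation run:
#' population sizes, the six connection-class probabilities and
#' conductances, synaptic delays, durations and the master seed. Defaults
#' reproduce the reference mixed network: N = 1000 neurons, 80%
#' excitatory / 20% inhibitory, within-population connection probabilities
#' p_e = 0.05 and p_i = 0.2, cross-population p_ei = p_ie = 0.05, autapse
#' fraction 0.25 in each population, delays d_exc = 1.5 ms and
#' d_inh = 0.8 ms, integration step dt = 0.01 ms, and a 20 s run analysed
#' over the window [10, 20] s. Conductances default to 0 nS (uncoupled)
#' and are the quantities scanned in the experiments.
#'
#' @param N number of neurons.
#' @param P_exc excitatory fraction; the inhibitory fraction is `1 - P_exc`.
#' @param p_e,p_i within-population connection probabilities
#'   (excitatory-to-excitatory, inhibitory-to-inhibitory).
#' @param p_ei,p_ie cross-population connection probabilities
#'   (excitatory-to-inhibitory, inhibitory-to-excitatory).
#' @param p_e_aut,p_i_aut autapse fractions of each population.
#' @param g_e,g_i,g_ei,g_ie,g_e_aut,g_i_aut class conductances, nS.
#' @param d_exc,d_inh synaptic delays for excitatory / inhibitory
#'   presynaptic neurons, ms; must be integer multiples of `dt`.
#' @param T_total simulated duration, ms.
#' @param t_ini,t_fin analysis window, ms.
#' @param dt integration step, ms.
#' @param record_dt sampling interval of the mean synaptic current, ms.
#' @param V_thres spike-detection cutoff, mV (see [neuron_params()]).
#' @param seed master RNG seed; independent streams for graph edges,
#'   autapse choice and initial conditions are derived from it.
#'
#' @return An object of class `network_config` (validated list).
#' @export
network_config <- function(N = 1000, P_exc = 0.8,
                           p_e = 0.05, p_i = 0.2, p_ei = 0.05, p_ie = 0.05,
                           p_e_aut = 0.25, p_i_aut = 0.25,
                           g_e = 0, g_i = 0, g_ei = 0, g_ie = 0,
                           g_e_aut = 0, g_i_aut = 0,
                           d_exc = 1.5, d_inh = 0.8,
                           T_total = 20000, t_ini = 10000, t_fin = 20000,
                           dt = 0.01, record_dt = 0.1,
                           V_thres = -40, seed = 1L) {
  probs <- c(p_e = p_e, p_i = p_i, p_ei = p_ei, p_ie = p_ie,
             p_e_aut = p_e_aut, p_i_aut = p_i_aut)
  if (N <= 0) stop("N must be positive")
  if (P_exc < 0 || P_exc > 1) stop("P_exc must lie in [0, 1]")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  g <- c(g_e = g_e, g_i = g_i, g_ei = g_ei, g_ie = g_ie,
         g_e_aut = g_e_aut, g_i_aut = g_i_aut)
  if (any(g < 0)) stop("conductances must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (!(t_ini < t_fin && t_fin <= T_total)) {
    stop("need t_ini < t_fin <= T_total")
  }
  for (d in c(d_exc, d_inh)) {
    if (d < 0 || abs(d / dt - round(d / dt)) > 1e-6) {
      stop("delays must be non-negative integer multiples of dt")
    }
  }
  if (record_dt < dt || abs(record_dt / dt - round(record_dt / dt)) > 1e-6) {
    stop("record_dt must be an integer multiple of dt")
  }
  structure(list(N = as.integer(N), P_exc = P_exc,
                 p_e = p_e, p_i = p_i, p_ei = p_ei, p_ie = p_ie,
                 p_e_aut = p_e_aut, p_i_aut = p_i_aut,
                 g_e = g_e, g_i = g_i, g_ei = g_ei, g_ie = g_ie,
                 g_e_aut = g_e_aut, g_i_aut = g_i_aut,
                 d_exc = d_exc, d_inh = d_inh,
                 T_total = T_total, t_ini = t_ini, t_fin = t_fin,
                 dt = dt, record_dt = record_dt,
                 V_thres = V_thres, seed = as.integer(seed)),
            class = "network_config")
}

#' Desk-scale single-population and mixed configurations
#'
#' Convenience constructors for the three network types studied:
#' excitatory-only, inhibitory-only, and the 80/20 mixed network. The
#' single-population variants zero the probabilities of the absent
#' population (cross-population probabilities are undefined there). Their
#' defaults are the desk-scale conditions used by the experiment drivers:
#' N = 200 neurons, 8 s runs analysed over [4, 8] s.
#'
#' @param N,T_total,t_ini,t_fin,seed see [network_config()].
#' @param ... further fields passed to [network_config()].
#' @return A `network_config` object.
#' @export
config_excitatory_only <- function(N = 200, T_total = 8000, t_ini = 4000,
                                   t_fin = 8000, seed = 1L, ...) {
  network_config(N = N, P_exc = 1, p_i = 0, p_ei = 0, p_ie = 0,
                 p_i_aut = 0, T_total = T_total, t_ini = t_ini,
                 t_fin = t_fin, seed = seed, ...)
}

#' @rdname config_excitatory_only
#' @export
config_inhibitory_only <- function(N = 200, T_total = 8000, t_ini = 4000,
                                   t_fin = 8000, seed = 1L, ...) {
  network_config(N = N, P_exc = 0, p_e = 0, p_ei = 0, p_ie = 0,
                 p_e_aut = 0, T_total = T_total, t_ini = t_ini,
                 t_fin = t_fin, seed = seed, ...)
}

#' @rdname config_excitatory_only
#' @export
config_mixed <- function(N = 200, T_total = 8000, t_ini = 4000,
                         t_fin = 8000, seed = 1L, ...) {
  network_config(N = N, T_total = T_total, t_ini = t_ini, t_fin = t_fin,
                 seed = seed, ...)
}

# derive reproducible sub-seeds (< 2^31) from the master seed so graph
# topology, autapse choice and initial conditions can be varied in isolation
stream_seed <- function(seed, stream) {
  offset <- switch(stream,
                   graph = 101L, autapse = 211L, ic = 307L, fixture = 401L,
                   stop("unknown RNG stream: ", stream))
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %%
               2147483629)
}

#' Split neurons into excitatory and inhibitory populations
#'
#' The first `round(P_exc * N)` neuron indices are labelled excitatory,
#' the remainder inhibitory, matching the convention that excitatory
#' neurons occupy the leading indices.
#'
#' @param N number of neurons.
#' @param P_exc excitatory fraction in `[0, 1]`.
#' @return A character vector of length `N` with values `"excitatory"` or
#'   `"inhibitory"`.
#' @export
build_populations <- function(N, P_exc) {
  if (N <= 0) stop("N must be positive")
  stopifnot(P_exc >= 0, P_exc <= 1)
  n_exc <- round(P_exc * N)
  rep(c("excitatory", "inhibitory"), times = c(n_exc, N - n_exc))
}

#' Sample a directed Erdos-Renyi edge set
#'
#' Each ordered pair `(pre k, post j)` is included independently with
#' probability `p`. Pairs with `k == j` are excluded unless `allow_self`
#' is set, so within-population sampling covers `n (n - 1)` ordered pairs.
#'
#' @param pre_ids,post_ids integer vectors of candidate pre- and
#'   postsynaptic neuron indices.
#' @param p connection probability in `[0, 1]`.
#' @param allow_self include self-pairs `k == j`?
#' @return A data frame with integer columns `pre` and `post`.
#' @export
sample_random_edges <- function(pre_ids, post_ids, p, allow_self = FALSE) {
  stopifnot(p >= 0, p <= 1)
  n_pre <- length(pre_ids)
  n_post <- length(post_ids)
  if (n_pre == 0L || n_post == 0L || p == 0) {
    return(data.frame(pre = integer(0), post = integer(0)))
  }
  hit <- which(stats::runif(n_pre * n_post) < p)
  pre <- pre_ids[((hit - 1L) %% n_pre) + 1L]
  post <- post_ids[((hit - 1L) %/% n_pre) + 1L]
  if (!allow_self) {
    keep <- pre != post
    pre <- pre[keep]
    post <- post[keep]
  }
  data.frame(pre = pre, post = post)
}

#' Choose autaptic neurons
#'
#' Flags exactly `round(p_aut * length(ids))` distinct neurons of a
#' population, drawn uniformly without replacement; each flagged neuron
#' carries one self-edge. The autapse probability is a fixed count
#' fraction, not a per-neuron Bernoulli draw.
#'
#' @param ids neuron indices of the population.
#' @param p_aut autapse fraction in `[0, 1]`.
#' @return Integer vector of autaptic neuron indices.
#' @export
assign_autapses <- function(ids, p_aut) {
  stopifnot(p_aut >= 0, p_aut <= 1)
  n_aut <- round(p_aut * length(ids))
  if (n_aut == 0L) return(integer(0))
  sort(ids[sample.int(length(ids), n_aut)])
}

#' Assemble the random network graph
#'
#' Builds the directed network of a configuration: population labels, the
#' four cross/within connection classes sampled as independent Bernoulli
#' edges, the two autapse classes as fixed-fraction self-edges, and
#' per-edge conductance weights taken from the class map
#' `{ee: g_e, ei: g_ei, ii: g_i, ie: g_ie, e_aut: g_e_aut, i_aut: g_i_aut}`.
#' When one population is absent the classes touching it are skipped
#' (their probabilities are undefined); configured positive probabilities
#' for such classes are ignored with a warning.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for the graph streams; defaults to `config$seed`.
#' @return An object of class `aeif_network`: a list with `N`, `labels`,
#'   `autaptic` (logical per neuron), and `edges` (data frame `pre`,
#'   `post`, `class`, `weight`).
#' @export
assemble_network <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "network_config"))
  labels <- build_populations(config$N, config$P_exc)
  exc <- which(labels == "excitatory")
  inh <- which(labels == "inhibitory")
  if (length(exc) == 0L && (config$p_e > 0 || config$p_ei > 0 ||
                            config$p_ie > 0 || config$p_e_aut > 0)) {
    warning("no excitatory neurons: ignoring p_e, p_ei, p_ie, p_e_aut",
            call. = FALSE)
  }
  if (length(inh) == 0L && (config$p_i > 0 || config$p_ei > 0 ||
                            config$p_ie > 0 || config$p_i_aut > 0)) {
    warning("no inhibitory neurons: ignoring p_i, p_ei, p_ie, p_i_aut",
            call. = FALSE)
  }

  set.seed(stream_seed(seed, "graph"))
  parts <- list()
  if (length(exc) > 1L) {
    e <- sample_random_edges(exc, exc, config$p_e)
    parts$ee <- cbind(e, class = rep_len("ee", nrow(e)))
  }
  if (length(inh) > 1L) {
    e <- sample_random_edges(inh, inh, config$p_i)
    parts$ii <- cbind(e, class = rep_len("ii", nrow(e)))
  }
  if (length(exc) > 0L && length(inh) > 0L) {
    e <- sample_random_edges(exc, inh, config$p_ei)
    parts$ei <- cbind(e, class = rep_len("ei", nrow(e)))
    e <- sample_random_edges(inh, exc, config$p_ie)
    parts$ie <- cbind(e, class = rep_len("ie", nrow(e)))
  }

  set.seed(stream_seed(seed, "autapse"))
  aut_e <- if (length(exc)) assign_autapses(exc, config$p_e_aut) else integer(0)
  aut_i <- if (length(inh)) assign_autapses(inh, config$p_i_aut) else integer(0)
  if (length(aut_e)) {
    parts$e_aut <- data.frame(pre = aut_e, post = aut_e,
                              class = "e_aut")
  }
  if (length(aut_i)) {
    parts$i_aut <- data.frame(pre = aut_i, post = aut_i,
                              class = "i_aut")
  }

  edges <- if (length(parts)) {
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  } else {
    data.frame(pre = integer(0), post = integer(0), class = character(0))
  }
  autaptic <- logical(config$N)
  autaptic[c(aut_e, aut_i)] <- TRUE
  graph <- structure(list(N = config$N, labels = labels,
                          autaptic = autaptic, edges = edges,
                          seed = seed),
                     class = "aeif_network")
  set_conductances(graph, config)
}

#' Refresh per-edge weights from a configuration
#'
#' Re-maps every edge weight from its class conductance. Used by the sweep
#' drivers to scan conductances on a fixed topology, isolating coupling
#' effects from graph resampling.
#'
#' @param graph an `aeif_network`.
#' @param config a [network_config()] supplying the six conductances.
#' @return The graph with an updated `weight` column.
#' @export
set_conductances <- function(graph, config) {
  stopifnot(inherits(graph, "aeif_network"))
  wmap <- c(ee = config$g_e, ii = config$g_i, ei = config$g_ei,
            ie = config$g_ie, e_aut = config$g_e_aut,
            i_aut = config$g_i_aut)
  graph$edges$weight <- unname(wmap[graph$edges$class])
  graph
}

#' @export
print.aeif_network <- function(x, ...) {
  n_exc <- sum(x$labels == "excitatory")
  cat(sprintf("AEIF network: %d neurons (%d excitatory, %d inhibitory)\n",
              x$N, n_exc, x$N - n_exc))
  cat(sprintf("  %d edges (%d autaptic neurons)\n",
              nrow(x$edges), sum(x$autaptic)))
  print(table(x$edges$class))
  invisible(x)
}

#' Binary adjacency matrices by presynaptic type
#'
#' Recovers the excitatory and inhibitory adjacency matrices: entry
#' `[j, k] = 1` iff an edge runs from presynaptic neuron `k` of the given
#' type to postsynaptic neuron `j`.
#'
#' @param graph an `aeif_network`.
#' @return A list with matrices `M_exc` and `M_inh` (N x N, 0/1).
#' @export
adjacency_matrices <- function(graph) {
  stopifnot(inherits(graph, "aeif_network"))
  M_exc <- matrix(0L, graph$N, graph$N)
  M_inh <- matrix(0L, graph$N, graph$N)
  e <- graph$edges
  is_exc <- e$class %in% c("ee", "ei", "e_aut")
  M_exc[cbind(e$post[is_exc], e$pre[is_exc])] <- 1L
  M_inh[cbind(e$post[!is_exc], e$pre[!is_exc])] <- 1L
  list(M_exc = M_exc, M_inh = M_inh)
}

#' Write / read a network edge list
#'
#' Plain-text graph exchange format: tab-separated columns `pre_id`,
#' `post_id`, `class`, `weight_nS` with a header line, preceded by comment
#' lines recording `N` and the excitatory count (labels follow from the
#' index convention); autapses appear as rows with `pre_id == post_id`.
#'
#' @param graph an `aeif_network`.
#' @param path file path.
#' @return `write_edges` returns `path` invisibly; `read_edges` returns an
#'   `aeif_network`.
#' @export
write_edges <- function(graph, path) {
  stopifnot(inherits(graph, "aeif_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N\t%d", graph$N),
               sprintf("# n_exc\t%d", sum(graph$labels == "excitatory")),
               "pre_id\tpost_id\tclass\tweight_nS"), con)
  e <- graph$edges
  if (nrow(e)) {
    writeLines(sprintf("%d\t%d\t%s\t%.10g", e$pre, e$post, e$class,
                       e$weight), con)
  }
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  hdr <- readLines(path, n = 2L)
  N <- as.integer(sub("# N\t", "", hdr[1L], fixed = TRUE))
  n_exc <- as.integer(sub("# n_exc\t", "", hdr[2L], fixed = TRUE))
  e <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = c("integer", "integer", "character",
                                        "numeric"))
  names(e) <- c("pre", "post", "class", "weight")
  autaptic <- logical(N)
  autaptic[e$pre[e$pre == e$post]] <- TRUE
  structure(list(N = N,
                 labels = rep(c("excitatory", "inhibitory"),
                              times = c(n_exc, N - n_exc)),
                 autaptic = autaptic, edges = e, seed = NA_integer_),
            class = "aeif_network")
}
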