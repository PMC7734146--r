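# the six scannable conductance fields of a network_config
CONDUCTANCE_FIELDS <- c("g_e", "g_i", "g_ei", "g_ie", "g_e_aut", "g_i_aut")

#' Marked parameter points of the excitatory-only plane
#'
#' Named presets for the four marked points of the excitatory
#' conductance plane whose raster plots illustrate the
#' synchronization transitions: circle (g_e = 0.05, g_e_aut = 10 nS,
#' desynchronized), triangle (0.05, 31; synchronized by the autaptic
#' feedback), square (0.1, 15) and hexagon (0.1, 22).
#'
#' @param name one of `"circle"`, `"triangle"`, `"square"`, `"hexagon"`.
#' @return A list with elements `g_e` and `g_e_aut` (nS).
#' @export
preset_point <- function(name = c("circle", "triangle", "square",
                                  "hexagon")) {
  name <- match.arg(name)
  switch(name,
         circle = list(g_e = 0.05, g_e_aut = 10),
         triangle = list(g_e = 0.05, g_e_aut = 31),
         square = list(g_e = 0.1, g_e_aut = 15),
         hexagon = list(g_e = 0.1, g_e_aut = 22))
}

run_point <- function(config, graph, params, seed) {
  sim <- run_simulation(config, graph = graph, params = params,
                        seed = seed)
  compute_metrics(sim$spikes, sim$current, config$t_ini, config$t_fin)
}

#' Two-dimensional conductance-plane sweep
#'
#' Runs the simulator over a grid of two conductance parameters and
#' collects the diagnostic table at every grid point, in long format
#' (one row per point, seed and metric). For each seed the network
#' topology is built once from the base configuration and reused across
#' the grid with re-mapped edge weights (`reuse_graph = TRUE`, the
#' default), so conductance effects are not confounded with topology
#' resampling; with `reuse_graph = FALSE` a fresh graph is drawn per
#' point. A failed run yields `NA` rows carrying the error message in the
#' `note` column instead of aborting the sweep.
#'
#' @param base a [network_config()]; its conductances give the values not
#'   scanned.
#' @param axis_x,axis_y lists `list(param = <name>, values = <numeric>)`;
#'   `param` must be one of the six conductance fields. `axis_y` may be
#'   `NULL` for a one-dimensional scan.
#' @param metrics which [compute_metrics()] columns to keep.
#' @param seeds integer vector of master seeds (replicates).
#' @param reuse_graph reuse one topology per seed across the grid?
#' @param params shared neuron constants.
#' @return Long-format data frame with columns `x_param`, `x`, `y_param`,
#'   `y`, `seed`, `metric`, `value`, `note`.
#' @export
sweep_2d <- function(base, axis_x, axis_y = NULL,
                     metrics = c("R_mean", "R_mean_non", "R_mean_aut",
                                 "CV_mean", "F_mean", "F_mean_aut",
                                 "F_mean_non", "F_mean_exc", "F_mean_inh",
                                 "I_s_mean"),
                     seeds = 1:3, reuse_graph = TRUE,
                     params = neuron_params()) {
  stopifnot(inherits(base, "network_config"))
  check_axis <- function(ax) {
    stopifnot(is.list(ax), ax$param %in% CONDUCTANCE_FIELDS,
              is.numeric(ax$values), length(ax$values) >= 1)
  }
  check_axis(axis_x)
  if (!is.null(axis_y)) check_axis(axis_y)
  y_values <- if (is.null(axis_y)) NA_real_ else axis_y$values
  y_param <- if (is.null(axis_y)) NA_character_ else axis_y$param

  rows <- list()
  for (seed in seeds) {
    graph0 <- if (reuse_graph) assemble_network(base, seed = seed)
    for (y in y_values) {
      for (x in axis_x$values) {
        cfg <- base
        cfg[[axis_x$param]] <- x
        if (!is.null(axis_y)) cfg[[y_param]] <- y
        graph <- if (reuse_graph) {
          set_conductances(graph0, cfg)
        } else {
          assemble_network(cfg, seed = seed)
        }
        met <- tryCatch(run_point(cfg, graph, params, seed),
                        error = function(e) conditionMessage(e))
        if (is.character(met)) {
          val <- rep(NA_real_, length(metrics))
          note <- met
        } else {
          val <- as.numeric(met[1, metrics])
          note <- ""
        }
        rows[[length(rows) + 1L]] <- data.frame(
          x_param = axis_x$param, x = x, y_param = y_param, y = y,
          seed = seed, metric = metrics, value = val, note = note,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-dimensional conductance line scan
#'
#' [sweep_2d()] with a single axis; by default reports the subgroup
#' firing rates (non-autaptic, autaptic, all) used for the
#' autapse-effect scans, plus the order-parameter averages.
#'
#' @inheritParams sweep_2d
#' @param axis list `list(param = <name>, values = <numeric>)`.
#' @return Long-format data frame as in [sweep_2d()] (without `y`
#'   columns).
#' @export
line_scan <- function(base, axis,
                      metrics = c("F_mean_non", "F_mean_aut", "F_mean",
                                  "R_mean", "R_mean_aut", "R_mean_non"),
                      seeds = 1:3, reuse_graph = TRUE,
                      params = neuron_params()) {
  out <- sweep_2d(base, axis_x = axis, axis_y = NULL, metrics = metrics,
                  seeds = seeds, reuse_graph = reuse_graph,
                  params = params)
  out$y_param <- NULL
  out$y <- NULL
  out
}

#' Export a raster table from a simulation
#'
#' Flattens spike trains into (display row, neuron id, spike time)
#' triples for raster plotting. With `ordering = "autaptic-last"` the
#' autaptic neurons are grouped contiguously on the top rows (the usual
#' presentation when highlighting the autaptic subgroup); with
#' `ordering = "index"` the display row equals the neuron id.
#'
#' @param sim an `aeif_sim` from [run_simulation()], or an
#'   [aeif_spikes()] object.
#' @param window time window `c(t0, t1)` in ms.
#' @param ordering `"index"` or `"autaptic-last"`.
#' @return Data frame with columns `row`, `neuron`, `time`.
#' @export
raster_export <- function(sim, window = NULL,
                          ordering = c("index", "autaptic-last")) {
  ordering <- match.arg(ordering)
  spikes <- if (inherits(sim, "aeif_sim")) sim$spikes else sim
  stopifnot(inherits(spikes, "aeif_spikes"))
  n <- length(spikes$times)
  row_of <- seq_len(n)
  if (ordering == "autaptic-last") {
    ord <- c(which(!spikes$autaptic), which(spikes$autaptic))
    row_of[ord] <- seq_len(n)
  }
  id <- rep(seq_len(n), times = vapply(spikes$times, length, integer(1)))
  t <- unlist(spikes$times, use.names = FALSE)
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    id <- id[keep]
    t <- t[keep]
  }
  o <- order(t, id)
  data.frame(row = row_of[id[o]], neuron = id[o], time = t[o])
}
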