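# synaptic reversal potentials, mV
V_REV_EXC <- 0
V_REV_INH <- -80

#' Delayed conductance-based synaptic currents
#'
#' Reference implementation of the chemical-synapse current: for each
#' postsynaptic neuron `j`,
#' `I_exc_j = (V_rev_exc - V_j) * sum_k w_kj * s_k(t - d_exc)` over
#' incoming edges with excitatory presynaptic neurons, and analogously
#' `I_inh_j` with `V_rev_inh` and the inhibitory delay. The per-edge
#' weight `w_kj` is the class conductance in nS; traces are
#' dimensionless, so currents come out in pA. Reversal potentials are
#' 0 mV (excitatory) and -80 mV (inhibitory).
#'
#' The compiled integrator re-implements this sum; this R version is the
#' module surface and the cross-check used by the tests.
#'
#' @param V membrane potentials, mV (length N).
#' @param trace_exc presynaptic traces evaluated at `t - d_exc`
#'   (length N).
#' @param trace_inh presynaptic traces evaluated at `t - d_inh`
#'   (length N).
#' @param graph an `aeif_network`.
#' @return List with vectors `I_exc` (>= 0 while V < 0) and `I_inh`, pA.
#' @export
synaptic_currents <- function(V, trace_exc, trace_inh, graph) {
  stopifnot(inherits(graph, "aeif_network"), length(V) == graph$N)
  if (any(trace_exc < 0) || any(trace_inh < 0)) {
    stop("synaptic traces must be non-negative")
  }
  e <- graph$edges
  is_exc <- e$class %in% c("ee", "ei", "e_aut")
  accumulate <- function(rows, trace) {
    A <- numeric(graph$N)
    if (any(rows)) {
      agg <- rowsum(e$weight[rows] * trace[e$pre[rows]], e$post[rows])
      A[as.integer(rownames(agg))] <- agg[, 1L]
    }
    A
  }
  A_exc <- accumulate(is_exc, trace_exc)
  A_inh <- accumulate(!is_exc, trace_inh)
  list(I_exc = (V_REV_EXC - V) * A_exc,
       I_inh = (V_REV_INH - V) * A_inh)
}

#' One RK4 step of the coupled AEIF equations (reference)
#'
#' Classical fourth-order Runge-Kutta step for all neurons, with the
#' delayed presynaptic trace sums `A_exc`, `A_inh` (sum of weight times
#' delayed trace per postsynaptic neuron) held constant across the four
#' substages — delayed values exist only on the dt grid, and the O(dt)
#' freezing error is negligible for dt = 0.01 ms against
#' tau_s = 2.728 ms. The driving-force factors `(V_rev - V)` do use the
#' substage V estimates. Threshold/reset is applied after the full step.
#'
#' This plain-R step mirrors the compiled integrator and is used by the
#' tests as an independent check of single steps and short trajectories.
#'
#' @param V,w,s state vectors.
#' @param params a [neuron_params()] (fields `a`, `b` may be per neuron).
#' @param A_exc,A_inh delayed trace sums per postsynaptic neuron.
#' @param dt step, ms.
#' @return List `V`, `w`, `s`, `spiked` after step + reset.
#' @export
aeif_rk4_step <- function(V, w, s, params, A_exc = 0, A_inh = 0, dt) {
  n <- length(V)
  A_exc <- rep_len(A_exc, n)
  A_inh <- rep_len(A_inh, n)
  f <- function(V, w, s) {
    I_syn <- (V_REV_EXC - V) * A_exc + (V_REV_INH - V) * A_inh
    aeif_derivatives(V, w, s, params, I_syn)
  }
  k1 <- f(V, w, s)
  k2 <- f(V + dt / 2 * k1$dV, w + dt / 2 * k1$dw, s + dt / 2 * k1$ds)
  k3 <- f(V + dt / 2 * k2$dV, w + dt / 2 * k2$dw, s + dt / 2 * k2$ds)
  k4 <- f(V + dt * k3$dV, w + dt * k3$dw, s + dt * k3$ds)
  V1 <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  w1 <- w + dt / 6 * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw)
  s1 <- s + dt / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
  apply_threshold_reset(V1, w1, s1, params)
}

# incoming-edge compressed sparse rows split by presynaptic type,
# 0-based for the compiled engine
graph_csr <- function(graph) {
  build <- function(e) {
    o <- order(e$post, e$pre)
    e <- e[o, , drop = FALSE]
    counts <- tabulate(e$post, nbins = graph$N)
    list(ptr = c(0L, cumsum(counts)), pre = as.integer(e$pre - 1L),
         w = as.numeric(e$weight))
  }
  e <- graph$edges
  is_exc <- e$class %in% c("ee", "ei", "e_aut")
  list(exc = build(e[is_exc, , drop = FALSE]),
       inh = build(e[!is_exc, , drop = FALSE]))
}

#' Run a network simulation
#'
#' Integrates the coupled AEIF network with RK4 at `config$dt` (default
#' 0.01 ms), delivering presynaptic conductance traces with the
#' type-specific delays (1.5 ms excitatory, 0.8 ms inhibitory by
#' default). Initial conditions follow the reference protocol: membrane
#' potentials uniform in [-70, -50] mV; adaptation currents uniform in
#' [0, 300] pA (excitatory) or [0, 80] pA (inhibitory); traces start at
#' zero, and the delay history before t = 0 is empty. Per-neuron
#' subthreshold adaptation is drawn uniformly in [1.9, 2.1] nS for
#' excitatory neurons (b = 70 pA) and is zero for inhibitory neurons
#' (b = 0 pA), unless `params` carries explicit per-neuron vectors.
#'
#' Spikes are detected after each full step (`V > V_thres`) and recorded
#' at the step-end time; a spike's trace increment first reaches its
#' targets one delay later (strictly causal). The mean network synaptic
#' current is sampled every `config$record_dt` ms.
#'
#' @param config a [network_config()].
#' @param graph an `aeif_network`; built from `config` when `NULL`.
#' @param params shared neuron constants, see [neuron_params()]. The
#'   `V_thres` field is taken from `config`.
#' @param seed master seed; defaults to `config$seed`.
#' @return An object of class `aeif_sim`: list with `spikes`
#'   ([aeif_spikes()]), `current` (data frame `time`, `I_chem`), `state`
#'   (final `V`, `w`, `s`), `a`, `b`, `config`, `seed`.
#' @export
run_simulation <- function(config, graph = NULL, params = neuron_params(),
                           seed = config$seed) {
  stopifnot(inherits(config, "network_config"))
  if (is.null(graph)) graph <- assemble_network(config, seed = seed)
  stopifnot(inherits(graph, "aeif_network"), graph$N == config$N)
  N <- config$N
  exc <- graph$labels == "excitatory"

  set.seed(stream_seed(seed, "ic"))
  V0 <- stats::runif(N, -70, -50)
  w0 <- ifelse(exc, stats::runif(N, 0, 300), stats::runif(N, 0, 80))
  a <- if (length(params$a) == N) params$a else {
    ifelse(exc, stats::runif(N, 1.9, 2.1), 0)
  }
  b <- if (length(params$b) == N) params$b else ifelse(exc, 70, 0)

  csr <- graph_csr(graph)
  n_steps <- round(config$T_total / config$dt)
  res <- aeif_run_cpp(V0, w0, numeric(N), a, b,
                      params$C_m, params$g_L, params$E_L, params$Delta_T,
                      params$V_T, params$tau_w, params$tau_s, params$V_r,
                      params$I_const, config$V_thres,
                      csr$exc$ptr, csr$exc$pre, csr$exc$w,
                      csr$inh$ptr, csr$inh$pre, csr$inh$w,
                      config$dt, as.integer(n_steps),
                      as.integer(round(config$d_exc / config$dt)),
                      as.integer(round(config$d_inh / config$dt)),
                      as.integer(round(config$record_dt / config$dt)),
                      V_REV_EXC, V_REV_INH)
  times <- split(res$spike_t, factor(res$spike_id, levels = seq_len(N)))
  spikes <- aeif_spikes(lapply(times, unname), labels = graph$labels,
                        autaptic = graph$autaptic)
  structure(list(spikes = spikes,
                 current = data.frame(time = res$rec_t,
                                      I_chem = res$rec_I),
                 state = list(V = res$V, w = res$w, s = res$s),
                 a = a, b = b, config = config, seed = seed),
            class = "aeif_sim")
}

#' @export
print.aeif_sim <- function(x, ...) {
  cat(sprintf("AEIF simulation: N = %d, %.4g ms at dt = %.4g ms (seed %d)\n",
              x$config$N, x$config$T_total, x$config$dt, x$seed))
  print(x$spikes)
  invisible(x)
}
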