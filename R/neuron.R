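#' Single-neuron parameters for the AEIF model
#'
#' Bundles the constants of the adaptive exponential integrate-and-fire
#' (AEIF) neuron. Defaults are the standard cortical parameter set used
#' throughout the package: a regular-spiking excitatory cell driven by a
#' constant 270 pA current. Inhibitory (fast-spiking) neurons use the same
#' membrane constants but no adaptation (`a = 0` nS, `b = 0` pA).
#'
#' `a` and `b` may be vectors (one entry per neuron) to express per-neuron
#' heterogeneity; all other fields are scalar.
#'
#' @param C_m membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L leak reversal potential, mV.
#' @param Delta_T slope factor of the exponential spike-initiation term, mV.
#' @param V_T exponential threshold potential, mV.
#' @param tau_w adaptation time constant, ms.
#' @param tau_s synaptic-trace time constant, ms.
#' @param V_r post-spike reset potential, mV.
#' @param I_const constant input current, pA.
#' @param V_thres spike-detection cutoff, mV. Crossings of this value
#'   trigger the reset rule. It must sit above `V_T` so the exponential
#'   upswing can develop; the default is `V_T + 5 * Delta_T`.
#' @param a subthreshold adaptation conductance, nS (scalar or per neuron).
#' @param b spike-triggered adaptation increment, pA (scalar or per neuron).
#'
#' @return An object of class `neuron_params` (a validated list).
#' @examples
#' p <- neuron_params()
#' p$tau_s
#' @export
neuron_params <- function(C_m = 200, g_L = 12, E_L = -70, Delta_T = 2,
                          V_T = -50, tau_w = 300, tau_s = 2.728,
                          V_r = -58, I_const = 270,
                          V_thres = V_T + 5 * Delta_T,
                          a = 2, b = 70) {
  stopifnot(C_m > 0, g_L > 0, Delta_T > 0, tau_w > 0, tau_s > 0)
  if (!(V_r < V_thres)) stop("V_r must lie below V_thres")
  if (!(V_T < V_thres)) stop("V_T must lie below V_thres")
  if (any(!is.finite(c(C_m, g_L, E_L, Delta_T, V_T, tau_w, tau_s, V_r,
                       I_const, V_thres, a, b)))) {
    stop("all neuron parameters must be finite")
  }
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T,
                 V_T = V_T, tau_w = tau_w, tau_s = tau_s, V_r = V_r,
                 I_const = I_const, V_thres = V_thres, a = a, b = b),
            class = "neuron_params")
}

# cap on the exponential argument; never reached for V <= V_thres with the
# default parameters, only guards the overshoot between crossing and reset
EXP_ARG_MAX <- 50

#' AEIF right-hand side
#'
#' Time derivatives of the membrane potential `V`, adaptation current `w`
#' and synaptic trace `s` of an AEIF neuron:
#' \deqn{C_m dV/dt = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'       - w + I_{const} + I_{syn}}
#' \deqn{\tau_w dw/dt = a (V - E_L) - w, \qquad \tau_s ds/dt = -s.}
#' All arguments are vectorized over neurons.
#'
#' @param V membrane potential, mV.
#' @param w adaptation current, pA.
#' @param s dimensionless synaptic trace (>= 0).
#' @param params a [neuron_params()] object.
#' @param I_syn synaptic input current, pA.
#'
#' @return A list with components `dV` (mV/ms), `dw` (pA/ms), `ds` (1/ms).
#' @examples
#' aeif_derivatives(-70, 0, 0, neuron_params())
#' @export
aeif_derivatives <- function(V, w, s, params, I_syn = 0) {
  stopifnot(inherits(params, "neuron_params"))
  if (any(!is.finite(V)) || any(!is.finite(w)) || any(!is.finite(s)) ||
      any(!is.finite(I_syn))) {
    stop("non-finite neuron state")
  }
  arg <- pmin((V - params$V_T) / params$Delta_T, EXP_ARG_MAX)
  dV <- (-params$g_L * (V - params$E_L) +
           params$g_L * params$Delta_T * exp(arg) -
           w + params$I_const + I_syn) / params$C_m
  dw <- (params$a * (V - params$E_L) - w) / params$tau_w
  ds <- -s / params$tau_s
  list(dV = dV, dw = dw, ds = ds)
}

#' Threshold detection and reset
#'
#' Applies the AEIF spike rule to (vectors of) neuron states: wherever
#' `V > V_thres` the neuron is marked as spiking and its state is updated
#' to `V -> V_r`, `w -> w + b`, `s -> s + 1`. The unit trace increment is
#' scaled by the class conductance (g_e, g_i, ...) per edge inside the
#' synaptic-current sum, so each of the six connection classes keeps its
#' own weight.
#'
#' @inheritParams aeif_derivatives
#' @return A list with updated `V`, `w`, `s` and a logical vector `spiked`.
#' @examples
#' apply_threshold_reset(-30, 100, 0.2, neuron_params())
#' @export
apply_threshold_reset <- function(V, w, s, params) {
  stopifnot(inherits(params, "neuron_params"))
  spiked <- V > params$V_thres
  V[spiked] <- params$V_r
  b <- rep_len(params$b, length(V))
  w[spiked] <- w[spiked] + b[spiked]
  s[spiked] <- s[spiked] + 1
  list(V = V, w = w, s = s, spiked = spiked)
}
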