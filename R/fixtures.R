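#' Synthetic spike trains for diagnostic testing
#'
#' Generates spike-train ensembles with known phase and variability
#' structure, so the synchronization and variability diagnostics can be
#' exercised without running the network simulator:
#' \describe{
#'   \item{periodic}{identical aligned trains of the given period; the
#'     order parameter of such an ensemble is exactly 1 and every CV is 0.}
#'   \item{antiphase-pairs}{odd-indexed neurons fire at `t0, t0 + period,
#'     ...`, even-indexed neurons half a period later; pairwise phases are
#'     opposite, driving the order parameter of a pair to 0.}
#'   \item{jittered}{the periodic train plus independent Gaussian jitter
#'     per spike (no cumulative drift), truncated at 49% of the period so
#'     interspike intervals stay positive; `jitter_sd = 0` recovers the
#'     periodic case exactly.}
#'   \item{poisson}{independent homogeneous Poisson trains of the given
#'     rate; interspike intervals are exponential, so CV is near 1.}
#' }
#'
#' @param kind one of `"periodic"`, `"jittered"`, `"antiphase-pairs"`,
#'   `"poisson"`.
#' @param n_neurons number of trains.
#' @param period spike period, ms (periodic/jittered/antiphase kinds).
#' @param rate firing rate, Hz (poisson kind); alternative to `period`.
#' @param jitter_sd jitter standard deviation, ms; must stay below
#'   `period / 2`.
#' @param duration train length, ms.
#' @param t0 time of the first spike, ms.
#' @param labels,autaptic optional per-neuron label / autapse-flag
#'   patterns, recycled to `n_neurons`.
#' @param seed RNG seed (jittered and poisson kinds).
#' @return An [aeif_spikes()] object.
#' @examples
#' make_synthetic_trains("antiphase-pairs", 2, period = 10, duration = 30)
#' @export
make_synthetic_trains <- function(kind = c("periodic", "jittered",
                                           "antiphase-pairs", "poisson"),
                                  n_neurons, period = NULL, rate = NULL,
                                  jitter_sd = 0, duration, t0 = 0,
                                  labels = NULL, autaptic = NULL,
                                  seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_neurons >= 1, duration > 0, jitter_sd >= 0)
  if (kind == "poisson") {
    if (is.null(rate)) {
      if (is.null(period)) stop("poisson trains need a rate")
      rate <- 1000 / period
    }
    stopifnot(rate > 0)
  } else {
    if (is.null(period) && !is.null(rate)) period <- 1000 / rate
    if (is.null(period) || period <= 0) stop("need a positive period")
    if (kind == "jittered" && jitter_sd >= period / 2) {
      stop("jitter_sd must be below period / 2")
    }
  }

  set.seed(stream_seed(seed, "fixture"))
  base <- if (kind != "poisson") seq(t0, duration, by = period)
  times <- switch(kind,
    periodic = rep(list(base), n_neurons),
    `antiphase-pairs` = lapply(seq_len(n_neurons), function(j) {
      off <- if (j %% 2 == 0) period / 2 else 0
      tt <- base + off
      tt[tt <= duration]
    }),
    jittered = lapply(seq_len(n_neurons), function(j) {
      lim <- 0.49 * period
      jit <- pmin(pmax(stats::rnorm(length(base), 0, jitter_sd), -lim), lim)
      base + jit
    }),
    poisson = lapply(seq_len(n_neurons), function(j) {
      # draw ~50% margin beyond the expected count, top up if short
      tt <- cumsum(stats::rexp(ceiling(rate * duration / 1000 * 1.5) + 20,
                               rate / 1000))
      while (length(tt) && tt[length(tt)] < duration) {
        tt <- c(tt, tt[length(tt)] +
                  cumsum(stats::rexp(50, rate / 1000)))
      }
      tt[tt <= duration]
    }))
  if (!is.null(labels)) labels <- rep_len(labels, n_neurons)
  if (!is.null(autaptic)) autaptic <- rep_len(autaptic, n_neurons)
  aeif_spikes(times, labels = labels, autaptic = autaptic)
}
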