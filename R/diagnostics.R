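#' Interpolated spike phase
#'
#' Piecewise-linear phase of a spike train: between consecutive spikes
#' `t_m` and `t_{m+1}` the phase grows linearly by 2*pi,
#' `psi(t) = 2 pi m + 2 pi (t - t_m) / (t_{m+1} - t_m)`,
#' with `m` counting from 0 at the first spike of the train. The phase is
#' defined only on `[t_1, t_last)`; outside that span (or with fewer than
#' two spikes) `NA` is returned.
#'
#' @param spike_times strictly increasing spike times, ms.
#' @param t evaluation times, ms (vectorized).
#' @return Phase in radians, `NA` where undefined.
#' @examples
#' interpolate_phase(c(0, 10), 5) # pi
#' @export
interpolate_phase <- function(spike_times, t) {
  if (length(spike_times) < 2L) return(rep(NA_real_, length(t)))
  m <- findInterval(t, spike_times)
  ok <- m >= 1L & t < spike_times[length(spike_times)]
  psi <- rep(NA_real_, length(t))
  mi <- m[ok]
  psi[ok] <- 2 * pi * (mi - 1) +
    2 * pi * (t[ok] - spike_times[mi]) /
    (spike_times[mi + 1L] - spike_times[mi])
  psi
}

#' Kuramoto order parameter over time
#'
#' `R(t) = | mean_j exp(i psi_j(t)) |` over the neurons of a subset whose
#' phase is defined at `t`. Values lie in `[0, 1]`: 1 for identical
#' phases, near 0 for incoherent ensembles. Phases use only spikes inside
#' `[t_ini, t_fin]` (phase index `m` restarts at the first in-window
#' spike), and a neuron contributes at `t` only while `t` lies strictly
#' inside its in-window spike span; grid points where no neuron qualifies
#' yield `NA`.
#'
#' @param spikes an [aeif_spikes()] object.
#' @param t_ini,t_fin analysis window, ms.
#' @param grid_dt phase-sampling interval, ms.
#' @param subset `"all"`, `"aut"` or `"non"` (autaptic / non-autaptic).
#' @return Data frame with columns `time`, `R`, `n_defined`.
#' @export
order_parameter_series <- function(spikes, t_ini, t_fin, grid_dt = 1,
                                   subset = c("all", "aut", "non")) {
  stopifnot(inherits(spikes, "aeif_spikes"), t_ini < t_fin, grid_dt > 0)
  subset <- match.arg(subset)
  idx <- subset_neurons(spikes, subset)
  grid <- seq(t_ini, t_fin, by = grid_dt)
  z <- complex(length.out = length(grid))
  n_def <- integer(length(grid))
  for (j in idx) {
    st <- spikes$times[[j]]
    st <- st[st >= t_ini & st <= t_fin]
    psi <- interpolate_phase(st, grid)
    ok <- !is.na(psi)
    z[ok] <- z[ok] + exp(1i * psi[ok])
    n_def <- n_def + ok
  }
  R <- ifelse(n_def > 0L, Mod(z) / n_def, NA_real_)
  data.frame(time = grid, R = R, n_defined = n_def)
}

#' Trapezoidal time average of a sampled series
#'
#' `(t_fin - t_ini)^-1 * integral of the series` over the window, with the
#' integral taken by the trapezoidal rule on the sample grid. `NA` samples
#' (e.g. grid points where an order parameter is undefined) are dropped
#' and the average is taken over the span the remaining samples cover.
#'
#' @param time sample times, ms.
#' @param value sampled values.
#' @param t_ini,t_fin averaging window, ms; defaults to the series span.
#' @return The time-averaged value (scalar).
#' @examples
#' time_average(0:10, (0:10) / 10) # 0.5
#' @export
time_average <- function(time, value, t_ini = min(time), t_fin = max(time)) {
  stopifnot(length(time) == length(value), t_ini < t_fin)
  if (t_ini < min(time) - 1e-9 || t_fin > max(time) + 1e-9) {
    stop("averaging window lies outside the sampled span")
  }
  keep <- time >= t_ini & time <= t_fin & !is.na(value)
  tt <- time[keep]
  vv <- value[keep]
  if (length(tt) < 2L) {
    if (length(tt) == 1L) return(vv)
    stop("no samples in the averaging window")
  }
  dt <- diff(tt)
  sum(dt * (vv[-1] + vv[-length(vv)]) / 2) / (tt[length(tt)] - tt[1L])
}

#' Interspike-interval coefficients of variation
#'
#' For each neuron, `CV_j = sd(ISI_j) / mean(ISI_j)` over the interspike
#' intervals of its spikes inside the window. The standard deviation is
#' the population form (divisor `n`) by default. Neurons with fewer than
#' two ISIs (fewer than three in-window spikes) are excluded from the
#' ensemble mean and counted in `n_excluded`.
#'
#' @inheritParams order_parameter_series
#' @param subset neuron subset, see [aeif_spikes()] subsets.
#' @param sd_type `"population"` (divisor n) or `"sample"` (divisor n-1).
#' @return List with `cv` (per neuron, `NA` where ineligible), `cv_mean`,
#'   and `n_excluded`.
#' @export
cv_stats <- function(spikes, t_ini = -Inf, t_fin = Inf,
                     subset = c("all", "aut", "non", "exc", "inh"),
                     sd_type = c("population", "sample")) {
  stopifnot(inherits(spikes, "aeif_spikes"))
  subset <- match.arg(subset)
  sd_type <- match.arg(sd_type)
  idx <- subset_neurons(spikes, subset)
  cv <- rep(NA_real_, length(spikes$times))
  for (j in idx) {
    st <- spikes$times[[j]]
    st <- st[st >= t_ini & st <= t_fin]
    isi <- diff(st)
    if (length(isi) < 2L) next
    mu <- mean(isi)
    v <- if (sd_type == "population") {
      sqrt(mean((isi - mu)^2))
    } else {
      stats::sd(isi)
    }
    cv[j] <- v / mu
  }
  eligible <- !is.na(cv[idx])
  if (!any(eligible)) {
    stop("no neuron with >= 2 interspike intervals in the window")
  }
  list(cv = cv, cv_mean = mean(cv[idx][eligible]),
       n_excluded = sum(!eligible))
}

#' Spike vs burst classification
#'
#' A network is classified as burst-firing when the ensemble-mean
#' coefficient of variation reaches 0.5 (inclusive), spike-firing below.
#'
#' @param cv_mean ensemble-mean CV (>= 0).
#' @return `"burst"` or `"spike"`.
#' @examples
#' classify_pattern(0.49) # "spike"
#' classify_pattern(0.5)  # "burst"
#' @export
classify_pattern <- function(cv_mean) {
  stopifnot(is.numeric(cv_mean), cv_mean >= 0)
  ifelse(cv_mean >= 0.5, "burst", "spike")
}

#' Mean firing rate of a neuron subset
#'
#' Number of subset spikes inside `[t_ini, t_fin]` divided by subset size
#' and window length, in Hz.
#'
#' @inheritParams cv_stats
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(spikes, t_ini, t_fin,
                        subset = c("all", "aut", "non", "exc", "inh")) {
  stopifnot(inherits(spikes, "aeif_spikes"), t_ini < t_fin)
  subset <- match.arg(subset)
  idx <- subset_neurons(spikes, subset)
  if (length(idx) == 0L) stop("empty neuron subset: ", subset)
  n_spk <- sum(vapply(spikes$times[idx], function(st) {
    sum(st >= t_ini & st <= t_fin)
  }, numeric(1)))
  n_spk / (length(idx) * (t_fin - t_ini) / 1000)
}

#' Full diagnostic table for one run
#'
#' Computes every summary statistic of the analysis over the window
#' `[t_ini, t_fin]`: time-averaged order parameter for all, autaptic and
#' non-autaptic neurons, the ensemble-mean ISI coefficient of variation
#' and the spike/burst label, subgroup firing rates, and the time-averaged
#' mean synaptic current (when a current series is supplied). Subgroup
#' columns are `NA` when the subgroup is empty.
#'
#' @param spikes an [aeif_spikes()] object.
#' @param current optional data frame `time`, `I_chem` from the simulator.
#' @param t_ini,t_fin analysis window, ms.
#' @param grid_dt order-parameter sampling interval, ms.
#' @return A one-row data frame with columns `R_mean`, `R_mean_non`,
#'   `R_mean_aut`, `CV_mean`, `pattern`, `F_mean`, `F_mean_aut`,
#'   `F_mean_non`, `F_mean_exc`, `F_mean_inh`, `I_s_mean`.
#' @export
compute_metrics <- function(spikes, current = NULL, t_ini, t_fin,
                            grid_dt = 1) {
  stopifnot(inherits(spikes, "aeif_spikes"))
  r_of <- function(sub) {
    if (length(subset_neurons(spikes, sub)) == 0L) return(NA_real_)
    ser <- order_parameter_series(spikes, t_ini, t_fin, grid_dt,
                                  subset = sub)
    if (all(is.na(ser$R))) return(NA_real_)
    time_average(ser$time, ser$R)
  }
  f_of <- function(sub) {
    if (length(subset_neurons(spikes, sub)) == 0L) return(NA_real_)
    firing_rate(spikes, t_ini, t_fin, subset = sub)
  }
  cv <- tryCatch(cv_stats(spikes, t_ini, t_fin)$cv_mean,
                 error = function(e) NA_real_)
  i_s <- if (is.null(current)) NA_real_ else {
    time_average(current$time, current$I_chem, t_ini, t_fin)
  }
  data.frame(R_mean = r_of("all"), R_mean_non = r_of("non"),
             R_mean_aut = r_of("aut"), CV_mean = cv,
             pattern = if (is.na(cv)) NA_character_ else
               classify_pattern(cv),
             F_mean = f_of("all"), F_mean_aut = f_of("aut"),
             F_mean_non = f_of("non"), F_mean_exc = f_of("exc"),
             F_mean_inh = f_of("inh"), I_s_mean = i_s,
             stringsAsFactors = FALSE)
}
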