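test_that("spike phase interpolates linearly between spikes", {
  expect_equal(interpolate_phase(c(0, 10), 5), pi)
  expect_equal(interpolate_phase(c(0, 10), 2.5), pi / 2)
  expect_equal(interpolate_phase(c(0, 10, 20), 10), 2 * pi)
  expect_equal(interpolate_phase(c(0, 10, 20), c(5, 15)),
               c(pi, 2 * pi + pi))
  # undefined outside the span or with < 2 spikes
  expect_true(is.na(interpolate_phase(c(0, 10), 10)))
  expect_true(is.na(interpolate_phase(c(0, 10), -1)))
  expect_true(all(is.na(interpolate_phase(5, c(5, 6)))))
})

test_that("order parameter is 1 for identical trains, 0 for anti-phase", {
  sp <- make_synthetic_trains("periodic", 50, period = 10, duration = 100)
  ser <- order_parameter_series(sp, 0, 100, grid_dt = 1)
  ok <- !is.na(ser$R)
  expect_gt(sum(ok), 50)
  expect_true(all(abs(ser$R[ok] - 1) < 1e-12))

  # two neurons, period 10 ms, half-period offset: opposite unit vectors
  sp <- aeif_spikes(list(c(0, 10, 20), c(5, 15)))
  ser <- order_parameter_series(sp, 0, 20, grid_dt = 2.5)
  r75 <- ser$R[ser$time == 7.5]
  expect_equal(ser$n_defined[ser$time == 7.5], 2L)
  expect_lt(r75, 1e-12)

  # uniformly spaced phases cancel by symmetry
  n <- 8
  sp <- aeif_spikes(lapply(0:(n - 1), function(k) {
    seq(k * 10 / n, 100, by = 10)
  }))
  ser <- order_parameter_series(sp, 0, 100, grid_dt = 1)
  mid <- ser$time > 20 & ser$time < 80 & ser$n_defined == n
  expect_true(all(ser$R[mid] < 1e-10))
})

test_that("order parameter is invariant under a common time shift", {
  sp <- make_synthetic_trains("jittered", 20, period = 12, jitter_sd = 2,
                              duration = 200, seed = 5)
  shift <- 30
  sp2 <- aeif_spikes(lapply(sp$times, `+`, shift))
  s1 <- order_parameter_series(sp, 0, 200, grid_dt = 1)
  s2 <- order_parameter_series(sp2, shift, 230, grid_dt = 1)
  expect_equal(s2$R, s1$R, tolerance = 1e-12)
})

test_that("time averaging uses the trapezoidal rule", {
  expect_equal(time_average(0:10, rep(3.5, 11)), 3.5)
  expect_equal(time_average(0:10, (0:10) / 10), 0.5)

  # refined Riemann-sum oracle on a smooth series
  f <- function(t) sin(t / 7) + 0.3 * cos(t / 3)
  t_coarse <- seq(0, 50, by = 0.5)
  t_fine <- seq(0, 50, by = 0.05)
  riemann <- mean(f((t_fine[-1] + t_fine[-length(t_fine)]) / 2))
  got <- time_average(t_coarse, f(t_coarse))
  expect_lt(abs(got - riemann) / abs(riemann), 1e-3)

  expect_error(time_average(0:10, 0:10, t_ini = -5, t_fin = 5), "outside")
  expect_error(time_average(0:10, 0:10, t_ini = 5, t_fin = 15), "outside")
})

test_that("CV statistics match direct formulas and the naive oracle", {
  # perfectly periodic: zero variability
  sp <- make_synthetic_trains("periodic", 3, period = 15, duration = 300)
  cv <- cv_stats(sp)
  expect_equal(cv$cv_mean, 0)

  # alternating 10/20 ms intervals: population sd 5, mean 15
  sp <- aeif_spikes(list(train_from_isi(c(10, 20, 10, 20))))
  cv <- cv_stats(sp)
  expect_equal(cv$cv_mean, 1 / 3, tolerance = 1e-12)

  # sample-sd variant uses divisor n - 1
  cv_s <- cv_stats(sp, sd_type = "sample")
  expect_equal(cv_s$cv_mean, sd(c(10, 20, 10, 20)) / 15, tolerance = 1e-12)

  # random fixtures against the two-pass oracle
  set.seed(42)
  for (rep in 1:5) {
    isi <- rexp(50, 1 / 20) + 1
    sp <- aeif_spikes(list(train_from_isi(isi)))
    expect_equal(cv_stats(sp)$cv_mean, naive_cv(isi),
                 tolerance = 1e-12)
  }

  # neurons with fewer than two ISIs are excluded but counted
  sp <- aeif_spikes(list(train_from_isi(c(10, 20, 10)), c(1, 2),
                         numeric(0)))
  cv <- cv_stats(sp)
  expect_identical(cv$n_excluded, 2L)
  expect_true(is.na(cv$cv[2]) && is.na(cv$cv[3]))
  expect_error(cv_stats(aeif_spikes(list(c(1, 2)))), "no neuron")
})

test_that("burst classification thresholds CV at 0.5, inclusive", {
  expect_identical(classify_pattern(0.49), "spike")
  expect_identical(classify_pattern(0.5), "burst")
  expect_identical(classify_pattern(0), "spike")
  expect_identical(classify_pattern(1.7), "burst")
  expect_error(classify_pattern(-0.1))
})

test_that("firing rates count subset spikes per neuron per second", {
  # every neuron fires 10 spikes in a 10 s window
  sp <- aeif_spikes(rep(list(seq(500, 9500, by = 1000)), 7))
  expect_equal(firing_rate(sp, 0, 10000), 1)
  expect_equal(firing_rate(sp, 20000, 30000), 0)

  # 80/20 mixture: excitatory at 8 Hz, inhibitory at 20 Hz
  times <- c(rep(list(seq(62.5, 999, by = 125)), 8),
             rep(list(seq(25, 999, by = 50)), 2))
  sp <- aeif_spikes(times, labels = rep(c("excitatory", "inhibitory"),
                                        c(8, 2)))
  expect_equal(firing_rate(sp, 0, 1000, subset = "exc"), 8)
  expect_equal(firing_rate(sp, 0, 1000, subset = "inh"), 20)
  expect_equal(firing_rate(sp, 0, 1000), 0.8 * 8 + 0.2 * 20)

  expect_error(firing_rate(sp, 0, 1000, subset = "aut"), "empty")
})

test_that("subset spike counts are additive", {
  sp <- make_synthetic_trains("poisson", 30, rate = 12, duration = 5000,
                              labels = rep(c("excitatory", "inhibitory"),
                                           c(24, 6)),
                              autaptic = rep(c(TRUE, FALSE, FALSE), 10),
                              seed = 9)
  count <- function(sub) {
    idx <- aeifnet:::subset_neurons(sp, sub)
    length(idx) * firing_rate(sp, 0, 5000, subset = sub)
  }
  expect_equal(count("all"), count("aut") + count("non"))
  expect_equal(count("all"), count("exc") + count("inh"))
  # rates are invariant under relabelling within a subset
  perm <- sample(which(sp$autaptic))
  sp2 <- sp
  sp2$times[which(sp$autaptic)] <- sp$times[perm]
  expect_equal(firing_rate(sp2, 0, 5000, subset = "aut"),
               firing_rate(sp, 0, 5000, subset = "aut"))
})

test_that("the metrics table assembles all diagnostics coherently", {
  sp <- make_synthetic_trains("jittered", 20, period = 50, jitter_sd = 4,
                              duration = 4000,
                              autaptic = rep(c(TRUE, FALSE), 10),
                              seed = 3)
  cur <- data.frame(time = seq(0, 4000, by = 10), I_chem = 2)
  m <- compute_metrics(sp, cur, t_ini = 500, t_fin = 3500)
  expect_true(m$R_mean >= 0 && m$R_mean <= 1)
  expect_true(m$R_mean_aut >= 0 && m$R_mean_aut <= 1)
  expect_gte(m$CV_mean, 0)
  expect_identical(m$pattern, classify_pattern(m$CV_mean))
  expect_equal(m$F_mean, 20, tolerance = 0.1)
  expect_equal(m$I_s_mean, 2)
  expect_true(is.na(m$F_mean_inh)) # no inhibitory neurons present
})
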