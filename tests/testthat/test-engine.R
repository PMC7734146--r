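test_that("synaptic currents follow the driving-force formula", {
  # one excitatory edge 1 -> 2, weight 0.5 nS, delayed trace 1
  g <- make_graph(2, edges = data.frame(pre = 1L, post = 2L, class = "ee",
                                        weight = 0.5))
  I <- synaptic_currents(V = c(-70, -70), trace_exc = c(1, 0),
                         trace_inh = c(0, 0), g)
  expect_equal(I$I_exc, c(0, (0 - (-70)) * 0.5 * 1))
  expect_equal(I$I_inh, c(0, 0))

  # one inhibitory edge, weight 2 nS: driving force below rest is -10 mV
  g <- make_graph(2, labels = rep("inhibitory", 2),
                  edges = data.frame(pre = 1L, post = 2L, class = "ii",
                                     weight = 2))
  I <- synaptic_currents(V = c(-70, -70), trace_exc = c(0, 0),
                         trace_inh = c(1, 0), g)
  expect_equal(I$I_inh, c(0, (-80 - (-70)) * 2 * 1))
  expect_equal(I$I_exc, c(0, 0))

  # no incoming edges
  g <- make_graph(3)
  I <- synaptic_currents(c(-60, -60, -60), rep(1, 3), rep(1, 3), g)
  expect_equal(I$I_exc, rep(0, 3))
  expect_equal(I$I_inh, rep(0, 3))

  expect_error(synaptic_currents(c(-60, -60, -60), c(-1, 0, 0),
                                 rep(0, 3), g), "non-negative")

  # autapse weight multiplies the neuron's own delayed trace
  g <- make_graph(1, edges = data.frame(pre = 1L, post = 1L,
                                        class = "e_aut", weight = 10),
                  autaptic = TRUE)
  I <- synaptic_currents(-50, trace_exc = 0.3, trace_inh = 0, g)
  expect_equal(I$I_exc, 50 * 10 * 0.3)
})

test_that("trace decay matches the closed form per RK4 step", {
  p <- neuron_params()
  dt <- 0.01
  st <- list(V = -65, w = 0, s = 1)
  for (i in 1:200) {
    st <- aeif_rk4_step(st$V, st$w, st$s, p, 0, 0, dt)
    expect_equal(st$s, exp(-i * dt / p$tau_s), tolerance = 1e-8)
  }
})

test_that("compiled engine matches the plain-R step composition", {
  cfg <- config_excitatory_only(N = 3, p_e = 0, p_e_aut = 0,
                                T_total = 50, t_ini = 10, t_fin = 50)
  sim <- run_simulation(cfg, seed = 4)
  p <- neuron_params(a = sim$a, b = sim$b)
  # replay the same initial conditions through the R reference step
  set.seed(aeifnet:::stream_seed(4, "ic"))
  V <- runif(3, -70, -50)
  w <- runif(3, 0, 300)
  s <- numeric(3)
  for (i in seq_len(round(50 / cfg$dt))) {
    st <- aeif_rk4_step(V, w, s, p, 0, 0, cfg$dt)
    V <- st$V; w <- st$w; s <- st$s
  }
  expect_equal(sim$state$V, V, tolerance = 1e-9)
  expect_equal(sim$state$w, w, tolerance = 1e-9)
})

test_that("uncoupled trajectory agrees with a 10x-refined oracle", {
  cfg <- config_excitatory_only(N = 1, p_e = 0, p_e_aut = 0,
                                T_total = 8, t_ini = 1, t_fin = 8)
  sim <- run_simulation(cfg, seed = 2)
  expect_length(sim$spikes$times[[1]], 0) # well before the first spike
  set.seed(aeifnet:::stream_seed(2, "ic"))
  V0 <- runif(1, -70, -50)
  w0 <- runif(1, 0, 300)
  p <- neuron_params(a = sim$a, b = sim$b)
  y <- single_neuron_rk4(V0, w0, 0, p, dt = 0.001, n_steps = 8000)
  expect_lt(abs(sim$state$V - y[1]), 8 * 1e-6) # < 1e-6 mV per ms
  expect_lt(abs(sim$state$w - y[2]), 1e-6)
})

test_that("simulation runs are deterministic and causally silent at rest", {
  cfg <- config_excitatory_only(N = 10, g_e = 0.2, g_e_aut = 5,
                                T_total = 300, t_ini = 100, t_fin = 300,
                                seed = 6)
  g <- assemble_network(cfg)
  s1 <- run_simulation(cfg, graph = g)
  s2 <- run_simulation(cfg, graph = g)
  expect_identical(s1$spikes$times, s2$spikes$times)
  expect_identical(s1$current, s2$current)

  # before any spike there is no synaptic current anywhere
  if (length(unlist(s1$spikes$times))) {
    first <- min(unlist(s1$spikes$times))
    expect_true(all(s1$current$I_chem[s1$current$time <= first] == 0))
  } else {
    expect_true(all(s1$current$I_chem == 0))
  }
})

test_that("zero conductances decouple the network exactly", {
  cfg_c <- config_excitatory_only(N = 5, g_e = 0, g_e_aut = 0,
                                  T_total = 1500, t_ini = 500,
                                  t_fin = 1500, seed = 8)
  g <- assemble_network(cfg_c) # edges present, weights zero
  expect_gt(nrow(g$edges), 0)
  sim_c <- run_simulation(cfg_c, graph = g)

  g_empty <- make_graph(5, labels = g$labels, autaptic = g$autaptic)
  sim_e <- run_simulation(cfg_c, graph = g_empty)
  expect_identical(sim_c$spikes$times, sim_e$spikes$times)
})

test_that("trace bookkeeping: final traces equal summed decayed spikes", {
  cfg <- config_excitatory_only(N = 4, p_e = 0, p_e_aut = 0,
                                T_total = 3000, t_ini = 1000,
                                t_fin = 3000, seed = 3)
  sim <- run_simulation(cfg)
  for (j in 1:4) {
    st <- sim$spikes$times[[j]]
    expected <- sum(exp(-(3000 - st) / 2.728))
    expect_equal(sim$state$s[j], expected, tolerance = 1e-6)
  }
})

test_that("excitatory-only coupled runs keep non-negative mean current", {
  cfg <- config_excitatory_only(N = 20, g_e = 0.3, g_e_aut = 10,
                                T_total = 2000, t_ini = 500, t_fin = 2000,
                                seed = 5)
  sim <- run_simulation(cfg)
  expect_gt(length(unlist(sim$spikes$times)), 0)
  expect_true(all(sim$current$I_chem >= 0))
  # spike times strictly increasing per neuron, within (0, T]
  for (st in sim$spikes$times) {
    if (length(st) > 1) expect_true(all(diff(st) > 0))
    if (length(st)) expect_true(all(st > 0 & st <= 2000))
  }
})

test_that("spike and current series round-trip through text files", {
  cfg <- config_excitatory_only(N = 6, g_e = 0.2, T_total = 2000,
                                t_ini = 500, t_fin = 2000, seed = 10)
  sim <- run_simulation(cfg)
  sp <- tempfile(fileext = ".tsv")
  cu <- tempfile(fileext = ".tsv")
  write_spikes(sim$spikes, sp, comment = "seed 10")
  write_current(sim$current, cu)
  sp2 <- read_spikes(sp)
  expect_equal(sp2$times, sim$spikes$times, tolerance = 1e-9)
  expect_identical(sp2$labels, sim$spikes$labels)
  expect_identical(sp2$autaptic, sim$spikes$autaptic)
  cu2 <- read_current(cu)
  expect_equal(cu2$I_chem, sim$current$I_chem, tolerance = 1e-9)
  unlink(c(sp, cu))
})
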