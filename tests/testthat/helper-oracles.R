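# independent oracles and tiny builders shared across tests

# hand-built network container (bypasses the sampler)
make_graph <- function(N, labels = rep("excitatory", N),
                       edges = data.frame(pre = integer(0),
                                          post = integer(0),
                                          class = character(0),
                                          weight = numeric(0)),
                       autaptic = logical(N)) {
  structure(list(N = N, labels = labels, autaptic = autaptic,
                 edges = edges, seed = NA_integer_),
            class = "aeif_network")
}

# two-pass CV oracle, kept deliberately naive
naive_cv <- function(isi, population = TRUE) {
  mu <- sum(isi) / length(isi)
  ss <- sum((isi - mu)^2)
  v <- if (population) ss / length(isi) else ss / (length(isi) - 1)
  sqrt(v) / mu
}

# plain-R RK4 trajectory of one uncoupled AEIF neuron, written out
# independently of the package step function
single_neuron_rk4 <- function(V, w, s, p, dt, n_steps) {
  rhs <- function(V, w, s) {
    c((-p$g_L * (V - p$E_L) +
         p$g_L * p$Delta_T * exp((V - p$V_T) / p$Delta_T) -
         w + p$I_const) / p$C_m,
      (p$a * (V - p$E_L) - w) / p$tau_w,
      -s / p$tau_s)
  }
  y <- c(V, w, s)
  for (i in seq_len(n_steps)) {
    k1 <- rhs(y[1], y[2], y[3])
    y2 <- y + dt / 2 * k1
    k2 <- rhs(y2[1], y2[2], y2[3])
    y3 <- y + dt / 2 * k2
    k3 <- rhs(y3[1], y3[2], y3[3])
    y4 <- y + dt * k3
    k4 <- rhs(y4[1], y4[2], y4[3])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# spike trains from an explicit ISI sequence
train_from_isi <- function(isi, t0 = 0) cumsum(c(t0, isi))
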