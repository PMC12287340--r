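test_that("spiking connectivity is mean-zeroed with the right density", {
  cfg <- spike_config(N = 1000, seed = 2)
  conn <- init_spike_connectivity(cfg)
  G <- as.matrix(conn$G)
  expect_lt(abs(sum(G)), 1e-8)
  expect_lt(abs(sum(conn$M)), 1e-8)
  expect_equal(mean(G != 0), 0.1, tolerance = 0.02)

  cfg0 <- spike_config(N = 50, g_g = 0, seed = 2)
  conn0 <- init_spike_connectivity(cfg0)
  expect_true(all(as.matrix(conn0$G) == 0))

  expect_error(spike_config(v_reset = 2), "v_reset")
})

test_that("a neuron at threshold bias approaches but never crosses", {
  cfg <- spike_config(N = 1, g_g = 0, g_m = 0, seed = 1)
  conn <- init_spike_connectivity(cfg)
  st <- spike_state(cfg$v_reset, cfg = cfg)   # start at reset, no spikes
  v_prev <- st$v
  for (k in 1:1000) {
    st <- step_lif(st, conn, cfg, dt = 0.5)
    expect_length(st$spikes, 0)
    expect_gte(st$v, v_prev)   # monotone approach from below
    v_prev <- st$v
  }
  expect_lt(st$v, cfg$v_th)
  expect_gt(st$v, cfg$v_th - 0.01)
})

test_that("synaptic trace is the Euler image of the delta-driven filter", {
  cfg <- spike_config(N = 1, g_g = 0, g_m = 0, I_bias = 0, seed = 1)
  conn <- init_spike_connectivity(cfg)
  dt <- 0.5
  st <- spike_state(v = 0, r = 1 / cfg$tau_s, cfg = cfg)  # just spiked
  rs <- numeric(100)
  for (k in 1:100) {
    st <- step_lif(st, conn, cfg, dt = dt)
    rs[k] <- st$r
  }
  expected <- (1 / cfg$tau_s) * (1 - dt / cfg$tau_s)^(1:100)
  expect_equal(rs, expected, tolerance = 1e-12)
  # close to the continuous-time exponential on this grid
  expect_equal(rs, (1 / cfg$tau_s) * exp(-(1:100) * dt / cfg$tau_s),
               tolerance = 0.01)
})

test_that("inter-spike interval matches the closed-form LIF solution", {
  I <- 2  # constant super-threshold drive
  cfg <- spike_config(N = 1, g_g = 0, g_m = 0, I_bias = I, seed = 1)
  conn <- init_spike_connectivity(cfg)
  dt <- 0.1
  st <- spike_state(v = cfg$v_reset, cfg = cfg)
  spikes <- numeric(0)
  for (k in 1:4000) {
    st <- step_lif(st, conn, cfg, dt = dt)
    if (length(st$spikes)) spikes <- c(spikes, st$t)
  }
  isi <- diff(spikes)
  t_star <- cfg$tau_m * log((I - cfg$v_reset) / (I - cfg$v_th))
  expect_true(all(abs(isi - (t_star + cfg$tau_ref)) <= dt + 1e-9))
})

test_that("refractory period is respected in a recurrent run", {
  cfg <- spike_config(N = 100, seed = 5)
  conn <- init_spike_connectivity(cfg)
  set.seed(6)
  sim <- simulate_spike(conn, 2000, dt = 0.5, record_r = FALSE)
  expect_gt(nrow(sim$spikes), 100)  # bias at threshold: network spikes
  by_neuron <- split(sim$spikes$time_ms, sim$spikes$neuron_id)
  gaps <- unlist(lapply(by_neuron, function(tt) diff(sort(tt))))
  expect_true(all(gaps >= cfg$tau_ref - 1e-9))
})

test_that("two-population symmetry and reduction to a single population", {
  cfg <- spike_config(N = 40, seed = 3)
  conn <- init_two_pop(N_E = 20, N_I = 20, cfg = cfg, seed = 9)
  # make the blocks and initial states symmetric across populations
  conn$G_IE <- conn$G_EE; conn$G_II <- conn$G_EI
  conn$M_EE[] <- 0; conn$M_EI[] <- 0; conn$M_IE[] <- 0; conn$M_II[] <- 0
  set.seed(11)
  sE <- spike_state(20, cfg = cfg)
  sI <- structure(sE, class = "spike_state")
  for (k in 1:200) {
    out <- step_lif_two_pop(sE, sI, conn, cfg, dt = 0.5)
    sE <- out$E; sI <- out$I
    expect_identical(sE$v, sI$v)
    expect_identical(sE$r, sI$r)
  }

  # silencing the inhibitory population reduces E to single-population
  conn2 <- init_two_pop(N_E = 30, N_I = 10, cfg = spike_config(N = 40,
                                                               seed = 4),
                        seed = 12)
  conn2$bias_I <- rep(-5, 10)  # I never spikes, r_I stays 0
  set.seed(13)
  sE <- spike_state(30, cfg = cfg)
  sI <- spike_state(rep(-5, 10), cfg = cfg)
  ref <- list(G = Matrix::Matrix(conn2$G_EE, sparse = TRUE),
              M = conn2$M_EE)
  stE <- sE
  for (k in 1:100) {
    out <- step_lif_two_pop(stE, sI, conn2, cfg, dt = 0.5)
    drive <- as.numeric((conn2$G_EE + conn2$M_EE) %*% stE$r) + conn2$bias_E
    # manual single-population update
    v <- stE$v; r <- stE$r; refr <- stE$refr
    refractory <- refr > 0
    v[refractory] <- cfg$v_reset
    refr[refractory] <- refr[refractory] - 0.5
    v[!refractory] <- v[!refractory] +
      (0.5 / cfg$tau_m) * (-v[!refractory] + drive[!refractory])
    r <- r * (1 - 0.5 / cfg$tau_s)
    fired <- which(refr <= 0 & v >= cfg$v_th)
    v[fired] <- cfg$v_reset; refr[fired] <- cfg$tau_ref
    r[fired] <- r[fired] + 1 / cfg$tau_s
    expect_equal(out$E$v, v, tolerance = 1e-12)
    sI <- out$I
    stE <- out$E
  }
})

test_that("Dale sign constraints survive plastic updates", {
  cfg <- spike_config(N = 100, seed = 7)
  conn <- init_two_pop(N_E = 80, N_I = 20, cfg = cfg, seed = 8)
  task <- make_periodic("sine", 200, 1)
  set.seed(9)
  out <- simulate_two_pop(conn, task, duration = 5000, dt = 0.5,
                          plastic = TRUE,
                          cfg = train_config(dt = 0.5, eta_m = 1e-3,
                                             eta_w = 1e-3))
  # 10^4 update steps later every plastic block is still non-negative
  expect_true(all(out$conn$M_EE >= 0))
  expect_true(all(out$conn$M_EI >= 0))
  expect_true(all(out$conn$M_IE >= 0))
  expect_true(all(out$conn$M_II >= 0))
  bad <- out$conn
  bad$M_EE[1, 1] <- -1
  expect_error(step_lif_two_pop(spike_state(80, cfg = cfg),
                                spike_state(20, cfg = cfg), bad, cfg),
               "non-negative")
})
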