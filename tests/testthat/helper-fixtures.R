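# Shared fixtures and independent oracles. Expensive trained networks are
# cached in an environment so several test files (and the acceptance
# suite) can reuse a single training run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_conn <- function(N = 5, K = 1, n_in = 0, seed = 1, g_g = 1.2,
                       g_m = 0.5) {
  init_connectivity(connectivity_spec(N = N, p_g = 0.5, g_g = g_g,
                                      p_m = 1, g_m = g_m, K = K,
                                      n_in = n_in, seed = seed))
}

# Instantaneous recurrent cost of the predictive-alignment rule,
# L = 1/2 ||Qz - Mr||^2 - alpha <Gr, Mr>, with r and z held fixed.
# Used as the finite-difference gradient oracle.
pa_cost <- function(M, conn, z, r, alpha) {
  e <- as.numeric(conn$Q %*% z) - as.numeric(M %*% r)
  0.5 * sum(e^2) -
    alpha * sum(as.numeric(conn$G %*% r) * as.numeric(M %*% r))
}

pa_grad_fd <- function(conn, z, r, alpha, eps = 1e-5) {
  M <- conn$M
  Gfd <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      Mp <- M; Mp[i, j] <- M[i, j] + eps
      Mm <- M; Mm[i, j] <- M[i, j] - eps
      Gfd[i, j] <- (pa_cost(Mp, conn, z, r, alpha) -
                      pa_cost(Mm, conn, z, r, alpha)) / (2 * eps)
    }
  }
  Gfd
}

# Plain-R reference integrator for the Lorenz system (RK4 with its own
# step), independent of the C++ generator.
lorenz_reference <- function(y0, n_units, h = 0.002, s = 10, rho = 28,
                             b = 8 / 3) {
  deriv <- function(u) {
    c(s * (u[2] - u[1]),
      rho * u[1] - u[2] - u[1] * u[3],
      u[1] * u[2] - b * u[3])
  }
  n <- as.integer(round(n_units / h))
  out <- matrix(NA_real_, 3, n + 1)
  y <- y0
  out[, 1] <- y
  for (k in seq_len(n)) {
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[, k + 1] <- y
  }
  out
}

# Mean nearest-neighbour distance from tent-map points a to points b.
tent_nn_dist <- function(a, b) {
  mean(vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((a$prev[i] - b$prev)^2 + (a$curr[i] - b$curr)^2))
  }, numeric(1)))
}

# Memory-bit scoring: for every pulse event whose hold window fits in the
# horizon, the readout sign at 250/350/450 ms after pulse onset (mid-hold,
# before the earliest possible next pulse) must match the pulse sign.
membit_score <- function(z, task, horizon, t0 = 0) {
  sched <- task$meta$schedule
  ok <- 0; n <- 0
  for (i in seq_len(nrow(sched))) {
    t_eval <- sched$t_on[i] + c(250, 350, 450) - t0
    if (max(t_eval) > horizon || min(t_eval) < 1) next
    zm <- mean(z[sched$bit[i], round(t_eval) + 1])
    n <- n + 1
    ok <- ok + (sign(zm) == sched$sign[i])
  }
  list(acc = ok / n, ok = ok, n = n)
}

# ---- cached trained networks (shared across test files) -------------------

# Reference sine task fit: N = 300, 90 s (criterion scale).
sine_fit <- function() {
  cached("sine_fit", function() {
    conn <- init_connectivity(connectivity_spec(N = 300, seed = 11))
    task <- make_periodic("sine", 60, 1.5)
    train(conn, task, train_config(T_train = 90000, seed = 12))
  })
}

# Paired alpha = 1 / alpha = 0 runs over 5 shared seeds (criterion 4).
alpha_pairs <- function() {
  cached("alpha_pairs", function() {
    task <- make_periodic("sine", 60, 1.5)
    lapply(1:5, function(sd) {
      conn <- init_connectivity(connectivity_spec(N = 300, seed = sd))
      cfg <- train_config(T_train = 60000, seed = 100 + sd)
      f1 <- train(conn, task, cfg, rule = "pa")
      f0 <- train(conn, task, cfg, rule = "alpha0")
      list(pa = f1, a0 = f0,
           err_pa = test_autonomous(f1, task, duration = 300)$rms,
           err_a0 = test_autonomous(f0, task, duration = 300)$rms,
           lam_pa = lyapunov_exponent(f1$conn, seed = 900 + sd),
           lam_a0 = lyapunov_exponent(f0$conn, seed = 900 + sd))
    })
  })
}

# Memory-bit fit at the desk scale used by criterion 7.
membit_fit <- function() {
  cached("membit_fit", function() {
    T_train <- 900000
    task <- make_memory_bits(n_bits = 3, T_total = T_train + 1000, seed = 7)
    conn <- init_connectivity(connectivity_spec(N = 300, K = 3, n_in = 3,
                                                seed = 41))
    fit <- train(conn, task, train_config(T_train = T_train, seed = 42))
    list(fit = fit, task = task)
  })
}

# Ready-Set-Go fit (criterion 9); scaled-down trial count.
rsg_fit <- function() {
  cached("rsg_fit", function() {
    n_trials <- 1200
    task <- make_rsg(n_trials = n_trials, seed = 8)
    conn <- init_connectivity(connectivity_spec(N = 400, n_in = 2,
                                                seed = 91))
    cfg <- train_config(T_train = n_trials * task$meta$trial_len, seed = 92)
    list(fit = train(conn, task, cfg), task = task)
  })
}

# RSG probe: run trained net on one test trial at a given delay with
# plasticity off and return the readout peak time relative to trial start.
rsg_peak_time <- function(fit, delay, record_r = FALSE) {
  params <- rsg_params()
  task <- make_rsg(params, n_trials = 1, delays = delay)
  te <- test_autonomous(fit, task, duration = params$trial_len, t0 = 0,
                        record_r = record_r)
  list(peak = te$t[which.max(te$z[1, ])], te = te)
}
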