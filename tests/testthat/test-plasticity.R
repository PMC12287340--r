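test_that("pa_update_M special cases and shapes", {
  conn <- small_conn(N = 5, K = 2, seed = 3)
  conn$W <- matrix(rnorm(10), 2, 5)
  z <- c(0.4, -0.2)

  expect_equal(pa_update_M(conn, z, rep(0, 5), alpha = 1, eta_m = 0.1),
               matrix(0, 5, 5))

  conn0 <- conn
  conn0$M <- matrix(0, 5, 5)
  r <- rnorm(5)
  expect_equal(pa_update_M(conn0, z, r, alpha = 0, eta_m = 0.1),
               0.1 * tcrossprod(as.numeric(conn0$Q %*% z), r),
               tolerance = 1e-14)
})

test_that("pa_update_M equals the finite-difference gradient of the cost", {
  # 20 random 5-unit instances; central differences of the instantaneous
  # integrand of the recurrent cost, relative error < 1e-6
  for (i in 1:20) {
    conn <- small_conn(N = 5, K = 1, seed = 200 + i)
    conn$W <- matrix(rnorm(5), 1, 5)
    conn$M <- matrix(rnorm(25, 0, 0.3), 5, 5)
    set.seed(300 + i)
    r <- tanh(rnorm(5))
    z <- as.numeric(conn$W %*% r)
    alpha <- sample(c(0, 0.5, 1), 1)
    eta <- 0.01
    analytic <- pa_update_M(conn, z, r, alpha, eta)
    fd <- -eta * pa_grad_fd(conn, z, r, alpha)
    expect_lt(max(abs(analytic - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("LMS update: zero error, selector case, and descent", {
  W <- matrix(rnorm(8), 2, 4)
  r <- rnorm(4)
  f <- as.numeric(W %*% r)
  expect_equal(lms_update_W(W, f, f, r, 0.1), matrix(0, 2, 4))

  W1 <- matrix(0, 1, 4)
  dW <- lms_update_W(W1, f = 3, z = 0.5, r = c(1, 0, 0, 0), eta_w = 0.1)
  expect_equal(dW, matrix(c(0.25, 0, 0, 0), 1, 4))

  # instantaneous squared error strictly decreases for small eta
  set.seed(4)
  W <- matrix(rnorm(12), 3, 4); r <- rnorm(4); f <- rnorm(3)
  z <- as.numeric(W %*% r)
  W2 <- W + lms_update_W(W, f, z, r, 1e-3)
  expect_lt(sum((f - W2 %*% r)^2), sum((f - z)^2))
})

test_that("RLS matches closed forms and converges to the ridge solution", {
  rls <- rls_state(3)
  W <- matrix(rnorm(3), 1, 3)
  r <- c(1, 0, 0)
  z <- as.numeric(W %*% r)
  up <- rls_update_W(rls, W, f = z, z = z, r = r)
  expect_equal(up$W, W)                        # zero error: W unchanged
  expect_equal(as.numeric(rls_state(3)$P %*% r) /
                 (1 + sum(r * (rls_state(3)$P %*% r))),
               c(0.5, 0, 0))                   # P = I, r = e1 -> k = e1/2

  # streaming one pass over a fixed regression problem reproduces ridge
  set.seed(8)
  n <- 40; p <- 6; lambda <- 1
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  rls <- rls_state(p, lambda)
  W <- matrix(0, 1, p)
  for (i in 1:n) {
    z <- as.numeric(W %*% X[i, ])
    up <- rls_update_W(rls, W, y[i], z, X[i, ])
    rls <- up$rls; W <- up$W
  }
  ridge <- solve(crossprod(X) + lambda * diag(p), crossprod(X, y))
  expect_equal(as.numeric(W), as.numeric(ridge), tolerance = 1e-8)
})

test_that("training leaves G untouched and zero rates freeze weights", {
  conn <- init_connectivity(connectivity_spec(N = 60, seed = 13))
  task <- make_periodic("sine", 60, 1.5)
  G_before <- as.matrix(conn$G)

  cfg0 <- train_config(T_train = 500, eta_m = 0, eta_w = 0, seed = 14)
  fit0 <- train(conn, task, cfg0)
  expect_identical(fit0$conn$M, conn$M)
  expect_identical(fit0$conn$W, conn$W)

  fit <- train(conn, task, train_config(T_train = 2000, seed = 14))
  expect_identical(as.matrix(fit$conn$G), G_before)
  expect_false(identical(fit$conn$M, conn$M))
})

test_that("one C++ training step reproduces the R update rules", {
  # dual route: the compiled trainer vs composing step_rate with the
  # R-level update functions, for both pa and the alpha0 control
  for (rule in c("pa", "alpha0")) {
    conn <- small_conn(N = 6, K = 1, seed = 21)
    conn$W <- matrix(rnorm(6, 0, 0.1), 1, 6)
    task <- make_periodic("sine", 60, 1.5)
    cfg <- train_config(dt = 1, T_train = 1, eta_m = 0.02, eta_w = 0.05,
                        seed = 22)
    fit <- train(conn, task, cfg, rule = rule)

    set.seed(22)
    x0 <- rnorm(6)
    r <- tanh(x0)
    z <- as.numeric(conn$W %*% r)
    f <- 1.5 * sin(0)
    alpha <- if (rule == "alpha0") 0 else 1
    W_exp <- conn$W + lms_update_W(conn$W, f, z, r, 0.05)
    M_exp <- conn$M + pa_update_M(conn, z, r, alpha, 0.02)
    expect_equal(fit$conn$W, W_exp, tolerance = 1e-13)
    expect_equal(fit$conn$M, M_exp, tolerance = 1e-13)
  }
})

test_that("plasticity schedules gate the two rules independently", {
  conn <- init_connectivity(connectivity_spec(N = 40, seed = 31))
  task <- make_periodic("sine", 60, 1.5)
  cfg <- train_config(T_train = 1000, seed = 32,
                      plasticity_schedule = list(
                        list(from = 0, to = 1000, M = FALSE, W = TRUE)))
  fit <- train(conn, task, cfg)
  expect_identical(fit$conn$M, conn$M)      # M gated off
  expect_false(identical(fit$conn$W, conn$W))

  expect_error(train_config(plasticity_schedule = list(
    list(from = 0, to = 500), list(from = 400, to = 900))),
    "non-overlapping")
})

test_that("train validates task compatibility", {
  conn <- init_connectivity(connectivity_spec(N = 30, K = 1, seed = 41))
  task5 <- make_multi_targets(5)
  expect_error(train(conn, task5, train_config(T_train = 100)), "K=5")

  mb <- make_memory_bits(T_total = 2000, seed = 1)
  conn3 <- init_connectivity(connectivity_spec(N = 30, K = 3, n_in = 3,
                                               seed = 41))
  expect_error(train(conn3, mb, train_config(T_train = 5000)), "horizon")
})

test_that("untrained readout error equals the target RMS and tests are deterministic", {
  conn <- init_connectivity(connectivity_spec(N = 80, seed = 51))
  task <- make_periodic("sine", 60, 1.5)
  te <- test_autonomous(conn, task, duration = 600, x0 = rnorm(80), t0 = 0)
  expect_equal(te$rms, sqrt(mean((1.5 * sin(2 * pi * (0:599) / 60))^2)),
               tolerance = 1e-10)

  fit <- train(conn, task, train_config(T_train = 3000, seed = 52))
  a <- test_autonomous(fit, task, duration = 300)
  b <- test_autonomous(fit, task, duration = 300)
  expect_identical(a$z, b$z)
})

test_that("two-phase training generalizes to targets spanned by phase 1", {
  # phase 2 stays short: the frozen reservoir free-runs, so its intrinsic
  # oscillation slowly drifts against the task clock over tens of seconds
  phase1 <- make_multi_targets(3, periods = c(60, 100, 150), phases = rep(0, 3))
  conn <- init_connectivity(connectivity_spec(N = 300, K = 3, seed = 61))
  cfg <- train_config(T_train = 90000, seed = 62)

  # phase-2 target: a superposition of two trained sinusoids
  sup <- pa_task("sum", 0, 1, function(t) {
    list(I = matrix(0, 0, length(t)),
         F = matrix(0.75 * sin(2 * pi * t / 60) +
                      0.75 * sin(2 * pi * t / 100), 1))
  })
  two <- train_two_phase(conn, phase1, sup, cfg,
                         cfg2 = train_config(T_train = 10000, seed = 63))
  expect_equal(dim(two$conn$W2), c(1L, 300L))

  # readout-only replay error of the second group
  conn2 <- two$conn
  conn2$W <- two$conn$W2
  conn2$spec$K <- 1L
  conn2$Q <- conn2$Q[, 1, drop = FALSE]
  te <- test_autonomous(conn2, sup, cfg = cfg, duration = 600,
                        x0 = two$x, t0 = two$t_end_phase2)
  expect_lt(te$rms, 0.25)

  # control: an untrained reservoir (no phase-1 recurrent learning)
  ctrl <- train_readout_only(conn, sup,
                             train_config(T_train = 10000, seed = 63))
  conn3 <- conn
  conn3$W <- ctrl$W2
  conn3$spec$K <- 1L
  conn3$Q <- conn3$Q[, 1, drop = FALSE]
  te_ctrl <- test_autonomous(conn3, sup, cfg = cfg, duration = 600,
                             x0 = ctrl$x, t0 = ctrl$t_end)
  expect_gt(te_ctrl$rms, te$rms)
})
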