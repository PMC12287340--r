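test_that("map-based Lyapunov estimator recovers closed forms", {
  # 1-D linear contraction/expansion: exponent log(a) exactly
  for (a in c(0.9, 1.05)) {
    lam <- lyapunov_map(function(x) a * x, x0 = 0.3,
                        cfg = lyapunov_config(n_warmup = 10,
                                              n_measure = 200))
    expect_equal(lam, log(a), tolerance = 1e-6)
  }
  # collapsing map: degenerate-direction error
  expect_error(lyapunov_map(function(x) 0 * x, x0 = c(1, 1)),
               "degenerate")
})

test_that("network Lyapunov sign separates chaotic from sub-critical", {
  # N = 500: at smaller sizes the g = 1.2 exponent is near zero and its
  # sign becomes realization-dependent
  chaotic <- init_connectivity(connectivity_spec(N = 500, seed = 4))
  lam_c <- lyapunov_exponent(chaotic, seed = 14)
  expect_gt(lam_c, 0)

  sub <- init_connectivity(connectivity_spec(N = 500, g_g = 0.5, seed = 4))
  lam_s <- lyapunov_exponent(sub, seed = 14)
  expect_lt(lam_s, 0)
})

test_that("recurrent error and alignment correlation match brute force", {
  conn <- small_conn(N = 4, K = 1, seed = 6)
  conn$W <- matrix(rnorm(4), 1, 4)
  traj <- matrix(tanh(rnorm(80)), 4, 20)
  alpha <- 0.7

  # naive double-loop oracle over units and time
  n_seg <- 4
  seg_id <- floor((seq_len(20) - 1) * n_seg / 20) + 1
  ss <- numeric(n_seg)
  corr_manual <- 0
  G <- as.matrix(conn$G)
  for (t in 1:20) {
    r <- traj[, t]
    z <- sum(conn$W[1, ] * r)
    for (i in 1:4) {
      pred <- sum((conn$M[i, ] - alpha * G[i, ]) * r)
      ss[seg_id[t]] <- ss[seg_id[t]] + (pred - conn$Q[i, 1] * z)^2
    }
    corr_manual <- corr_manual +
      sum((G %*% r) * (conn$M %*% r))
  }
  manual <- sqrt(ss / (4 * 5))
  expect_equal(recurrent_error(traj, conn, alpha, dt = 1, n_seg = 4),
               manual, tolerance = 1e-12)
  expect_equal(alignment_correlation(traj, conn, dt = 1), corr_manual,
               tolerance = 1e-10)

  # M = alpha G with W = 0 zeroes both terms
  conn0 <- conn
  conn0$M <- alpha * G
  conn0$W <- matrix(0, 1, 4)
  expect_equal(recurrent_error(traj, conn0, alpha),
               rep(0, 10), tolerance = 1e-12)

  conn0$M <- matrix(0, 4, 4)
  expect_equal(alignment_correlation(traj, conn0), 0)
  conn0$M <- G
  expect_gte(alignment_correlation(traj, conn0), 0)
})

test_that("efficiency index reproduces spectral limits", {
  # near-isotropic activity: H -> log n, PR -> n
  set.seed(2)
  n <- 8
  traj <- matrix(rnorm(n * 60000), n, 60000)
  eff <- efficiency_index(traj)
  expect_equal(eff$H_lambda, log(n), tolerance = 0.01)
  expect_equal(eff$PR, n, tolerance = 0.05 * n)
  expect_equal(eff$efficiency, eff$H_lambda / sqrt(eff$PR))

  # rank-1 activity: zero entropy, zero efficiency
  v <- rnorm(n)
  rank1 <- tcrossprod(v, sin((1:500) / 10))
  e1 <- efficiency_index(rank1)
  expect_equal(e1$H_lambda, 0, tolerance = 1e-10)
  expect_equal(e1$efficiency, 0, tolerance = 1e-10)

  # brute-force spectral oracle on a random trajectory
  traj2 <- matrix(rnorm(5 * 40), 5, 40)
  X <- traj2 - rowMeans(traj2)
  C <- X %*% t(X) / 40
  ev <- sort(eigen(C)$values, decreasing = TRUE)
  p <- ev / sum(ev)
  e2 <- efficiency_index(traj2)
  expect_equal(sort(e2$eigenvalues, decreasing = TRUE), ev,
               tolerance = 1e-10)
  expect_equal(e2$H_lambda, -sum(p * log(p)), tolerance = 1e-10)
  expect_equal(e2$PR, sum(ev)^2 / sum(ev^2), tolerance = 1e-10)

  expect_error(efficiency_index(matrix(0, 3, 10)), "degenerate")
})

test_that("eigenspectrum handles trivial matrices and the circular law", {
  conn <- small_conn(N = 4, seed = 3)
  conn$G <- Matrix::Matrix(matrix(0, 4, 4), sparse = TRUE)
  conn$M <- matrix(0, 4, 4)
  es <- eigenspectrum(conn, "J")
  expect_true(all(es$values == 0))
  expect_equal(es$n_outliers, 0)

  conn$M <- diag(c(3, -1, 0.5, 2))
  esd <- eigenspectrum(conn, "M", bulk_radius = 2.5, margin = 0)
  expect_setequal(Re(esd$values), c(3, -1, 0.5, 2))
  expect_equal(esd$n_outliers, 1)  # only the eigenvalue at 3

  # untrained J: spectral radius close to sqrt(g_g^2 + g_m^2), no outliers
  big <- init_connectivity(connectivity_spec(N = 800, seed = 5))
  esb <- eigenspectrum(big, "J")
  expect_equal(max(Mod(esb$values)), sqrt(1.2^2 + 0.5^2), tolerance = 0.1)
  expect_equal(esb$n_outliers, 0)
})

test_that("tent map finds strict maxima and handles plateaus", {
  t <- seq(0, 6 * pi, by = 0.01)
  tm <- tent_map(2 * sin(t))
  expect_true(all(abs(tm$prev - 2) < 1e-3))
  expect_true(all(abs(tm$curr - 2) < 1e-3))

  expect_equal(nrow(tent_map(1:100)), 0)

  plateau <- c(0, 1, 1, 1, 0, 2, 0, 3, 0)
  tmp <- tent_map(plateau)
  expect_equal(tmp$prev, c(1, 2))
  expect_equal(tmp$curr, c(2, 3))
})

test_that("PCA projection recovers lines and preserves geometry", {
  v <- rnorm(6)
  traj <- tcrossprod(v, seq(-1, 1, length.out = 50))
  p <- pca_project(traj, 2)
  expect_gt(abs(cor(p$scores[, 1], seq(-1, 1, length.out = 50))), 1 - 1e-10)
  expect_lt(sd(p$scores[, 2]), 1e-10)

  traj2 <- matrix(rnorm(5 * 30), 5, 30)
  full <- pca_project(traj2, 5)
  d_orig <- dist(t(traj2))
  d_proj <- dist(full$scores)
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-10)

  expect_error(pca_project(traj2, 9), "n_components")

  b <- pca_project(traj2, basis = cbind(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0)))
  expect_equal(dim(b$scores), c(30L, 2L))
})

test_that("efficiency is lowest in the sub-critical regime with an interior peak", {
  # gain sweep at reduced scale (N = 300, 3 seeds).  Under this package
  # correlation-matrix convention the efficiency curve has its minimum
  # at the sub-critical end and an interior maximum (see the decisions
  # ledger / methods vignette for why the exact argmax of the source
  # figure is not asserted).
  gains <- c(0.6, 0.8, 1.0, 1.2, 1.5, 2.0)
  for (sd in 1:3) {
    effs <- vapply(gains, function(g) {
      conn <- init_connectivity(connectivity_spec(N = 300, g_g = g,
                                                  seed = 70 + sd))
      set.seed(500 + sd)
      # window starts at the random initial state: in the sub-critical
      # regime the spectrum comes from the decaying transient
      sim <- simulate_rate(conn, 8000, record_every = 4)
      efficiency_index(sim$r)$efficiency
    }, numeric(1))
    expect_equal(which.min(effs), 1)          # weakest gain: least diverse
    expect_gt(max(effs[3:5]), effs[1] * 1.2)  # clear interior rise
  }
})
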