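test_that("periodic generators match their closed forms", {
  sine <- make_periodic("sine", 60, 1.5)
  sig <- task_signals(sine, 121, dt = 1)
  expect_equal(sig$F[1, 1], 0)
  expect_equal(sig$F[1, 16], 1.5)            # t = T/4
  expect_equal(mean(sig$F[1, 1:60]), 0, tolerance = 1e-12)

  step <- make_periodic("step", 100, 1)
  sg <- task_signals(step, 200, dt = 1)
  expect_setequal(unique(as.numeric(sg$F)), c(-1, 1))
  expect_equal(mean(sg$F[1, 1:100]), 0, tolerance = 1e-12)

  saw <- make_periodic("sawtooth", 80, 1)
  sw <- task_signals(saw, 4000, dt = 0.1)
  # period integral vanishes by symmetry of the ramp (numeric quadrature)
  expect_equal(mean(sw$F[1, 1:800]), 0, tolerance = 2e-3)
  expect_true(all(abs(sw$F) <= 1))
})

test_that("generators are pure functions of (params, seed)", {
  t1 <- make_memory_bits(T_total = 5000, seed = 3)
  t2 <- make_memory_bits(T_total = 5000, seed = 3)
  s1 <- task_signals(t1, 5000, 1)
  s2 <- task_signals(t2, 5000, 1)
  expect_identical(s1$I, s2$I)
  expect_identical(s1$F, s2$F)

  r1 <- make_rsg(n_trials = 10, seed = 5)
  r2 <- make_rsg(n_trials = 10, seed = 5)
  expect_identical(r1$meta$delays, r2$meta$delays)

  a <- task_signals(r1, 3000, 1)
  b <- task_signals(r1, 3000, 1)
  expect_identical(a$F, b$F)
})

test_that("multi-target channels are distinct sinusoids", {
  same <- make_multi_targets(3, periods = 60, phases = 0)
  s <- task_signals(same, 300, 1)
  expect_identical(s$F[1, ], s$F[2, ])

  multi <- make_multi_targets(5)
  expect_equal(multi$K, 5L)
  m <- task_signals(multi, 2000, 1)
  cors <- cor(t(m$F))
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 1))             # no identical pair
  expect_true(all(abs(m$F) <= 1.5 + 1e-12))
})

test_that("control-switch inputs are static, distinct and reproducible", {
  one <- make_control_switch(n_patterns = 1, n_in = 5, trial_dur = 200,
                             n_trials = 3, seed = 2,
                             targets = list(function(tt) sin(tt / 10)))
  s <- task_signals(one, 600, 1)
  expect_equal(nrow(unique(t(s$I))), 1)      # constant input throughout

  four <- make_control_switch(n_patterns = 4, n_in = 6, seed = 2)
  pats <- four$meta$patterns
  expect_equal(ncol(pats), 4)
  d <- as.matrix(dist(t(pats)))
  expect_true(all(d[upper.tri(d)] > 0))      # pairwise distinct
  four2 <- make_control_switch(n_patterns = 4, n_in = 6, seed = 2)
  expect_identical(four$meta$patterns, four2$meta$patterns)
  expect_identical(four$meta$pattern_seq, four2$meta$pattern_seq)
})

test_that("memory-bit targets hold the last pulse sign", {
  task <- make_memory_bits(n_bits = 2, T_total = 20000, seed = 11)
  sig <- task_signals(task, 20000, 1)
  sched <- task$meta$schedule

  # before the first pulse the target sits at the initial sign
  for (b in 1:2) {
    first <- min(sched$t_on[sched$bit == b])
    expect_true(all(sig$F[b, 1:floor(first)] == task$meta$init_sign[b]))
  }

  # independent scan oracle: last-pulse sign at every ms
  t_grid <- sig$t
  for (b in 1:2) {
    s <- sched[sched$bit == b, ]
    expected <- vapply(t_grid, function(tt) {
      past <- s$sign[s$t_on <= tt]
      if (length(past)) tail(past, 1) else task$meta$init_sign[b]
    }, numeric(1))
    expect_equal(sig$F[b, ], expected)
  }

  # consecutive same-sign pulses leave the target unchanged in between
  s1 <- sched[sched$bit == 1, ]
  rep_idx <- which(diff(s1$sign) == 0)
  if (length(rep_idx)) {
    i <- rep_idx[1]
    span <- (ceiling(s1$t_on[i]) + 2):floor(s1$t_on[i + 1])
    expect_true(all(sig$F[1, span] == s1$sign[i]))
  }

  # inputs: pulses have the right duration and amplitude
  on1 <- which(sig$I[1, ] != 0)
  expect_true(all(abs(sig$I[1, on1]) == 1))
  expect_equal(length(on1), 100 * nrow(s1))
})

test_that("the Lorenz generator agrees with an independent integrator", {
  # fixed point at the origin
  still <- make_lorenz(duration = 200, seed = 1, init = c(0, 0, 0))
  expect_true(all(still$meta$F_full == 0))

  # short trajectory versus a plain-R RK4 reference at a finer step
  p <- lorenz_params(transient = 0)
  task <- make_lorenz(p, duration = 1000, seed = 2, init = c(1, 1, 20))
  ref <- lorenz_reference(c(1, 1, 20), n_units = 10, h = 0.002)
  ref_samp <- ref[, seq(1, ncol(ref) - 1, by = 5)] / 10  # every 0.01 units
  expect_equal(dim(task$meta$F_full), c(3L, 1000L))
  expect_lt(max(abs(task$meta$F_full - ref_samp[, 1:1000])), 5e-4)

  # tent map of the third component is a tight single-humped curve
  long <- make_lorenz(lorenz_params(), duration = 60000, seed = 3)
  tm <- tent_map(long$meta$F_full[3, ])
  expect_gt(nrow(tm), 100)
  fit <- stats::smooth.spline(tm$prev, tm$curr, df = 10)
  resid <- tm$curr - stats::predict(fit, tm$prev)$y
  expect_lt(sd(resid), 0.05)                 # near-functional relation
})

test_that("Ready-Set-Go pulses follow the stated Gaussians", {
  params <- rsg_params()
  task <- make_rsg(params, n_trials = 4, delays = c(100, 120, 140, 160))
  sig <- task_signals(task, 4 * params$trial_len, dt = 1)

  expect_equal(sig$I[1, params$T0 + 1], 1)   # s1 peaks at T0
  expect_lt(max(abs(sig$I[1, 300:500] + 1)), 1e-8)  # baseline -1 far away

  # target peak sits at T0 + 2 * delay within each trial
  for (tr in 1:4) {
    off <- (tr - 1) * params$trial_len
    peak <- which.max(sig$F[1, off + 1:params$trial_len])
    expect_equal(peak - 1, params$T0 + 2 * c(100, 120, 140, 160)[tr])
  }

  # sampled training delays come from the printed set
  t2 <- make_rsg(params, n_trials = 200, seed = 3)
  expect_true(all(t2$meta$delays %in% c(100, 120, 140, 160)))
  expect_true(all(abs(task_signals(t2, 5000, 1)$F) <= 1))

  # Gaussian integral: (pulse - baseline) integrates to 2 * delta * sqrt(pi)
  fine <- task_signals(task, 60000, dt = 0.01)
  area <- sum(fine$I[1, 1:60000] + 1) * 0.01
  expect_equal(area, 2 * params$delta * sqrt(pi), tolerance = 1e-3)
})

test_that("synthetic movie geometry, interpolation and scaling", {
  m <- make_synthetic_movie(8, 9, 3, n_key_frames = 5, upsample_to = 9,
                            seed = 4)
  expect_equal(m$K, 8L * 9L * 3L)
  key <- m$meta$key_frames
  up <- m$meta$F_full
  expect_true(all(up >= -1 & up <= 1))
  # upsample_to = 2 * n_key - 1 puts every even frame exactly halfway
  expect_equal(up[, 2], (key[, 1] + key[, 2]) / 2, tolerance = 1e-12)
  expect_equal(up[, 1], key[, 1])
  expect_equal(up[, 9], key[, 5])

  single <- make_synthetic_movie(4, 4, 1, n_key_frames = 1, upsample_to = 6,
                                 seed = 1)
  expect_equal(max(abs(single$meta$F_full -
                         single$meta$F_full[, 1])), 0)

  # frames repeat with the epoch period
  sig <- task_signals(m, 20, dt = 1)
  expect_equal(sig$F[, 1], sig$F[, 10])
})
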