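#' Training configuration
#'
#' Collects the integration and learning parameters shared by all
#' training entry points.  Per-step learning rates default to
#' `eta_w = eta_m = 1e-2 * dt / tau`, chosen so the reference sine task
#' converges well within 100 s of simulated time; results are robust to
#' moderate variations of both.  `alpha` is the weight of the
#' alignment regularizer in the recurrent cost and equals 1 unless a
#' control run is requested.
#'
#' @param dt integration step (ms); 1 ms default, 0.5 ms for spiking runs.
#' @param tau membrane time constant (ms).
#' @param alpha alignment regularization weight (>= 0).
#' @param eta_m,eta_w per-step learning rates for `M` and `W`.
#' @param sigma noise scale injected into the dynamics during training.
#' @param T_train total training duration (ms).
#' @param plasticity_schedule optional list of windows
#'   `list(from =, to =, M =, W =)` (ms); plasticity is off outside all
#'   windows.  `NULL` means both rules are on for the whole run.
#' @param seed RNG seed used by [train()] for the initial state and noise.
#' @param sde_noise see [step_rate()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(dt = 1, tau = 10, alpha = 1,
                         eta_m = 1e-2 * dt / tau,
                         eta_w = 1e-2 * dt / tau,
                         sigma = 0, T_train = 60000,
                         plasticity_schedule = NULL, seed = 1L,
                         sde_noise = FALSE) {
  stopifnot(dt > 0, tau > 0, alpha >= 0, eta_m >= 0, eta_w >= 0, sigma >= 0)
  if (!is.null(plasticity_schedule)) {
    ivals <- vapply(plasticity_schedule,
                    function(w) c(w$from, w$to), numeric(2))
    o <- order(ivals[1, ])
    if (any(ivals[2, o][-ncol(ivals)] > ivals[1, o][-1])) {
      stop("plasticity_schedule windows must be non-overlapping")
    }
  }
  structure(list(dt = dt, tau = tau, alpha = alpha, eta_m = eta_m,
                 eta_w = eta_w, sigma = sigma, T_train = T_train,
                 plasticity_schedule = plasticity_schedule,
                 seed = as.integer(seed), sde_noise = sde_noise),
            class = "train_config")
}

schedule_flags <- function(schedule, n_steps, dt, which) {
  if (is.null(schedule)) return(rep(TRUE, n_steps))
  flags <- rep(FALSE, n_steps)
  t_grid <- (seq_len(n_steps) - 1) * dt
  for (w in schedule) {
    on <- if (is.null(w[[which]])) TRUE else isTRUE(w[[which]])
    if (on) flags[t_grid >= w$from & t_grid < w$to] <- TRUE
  }
  flags
}

#' Predictive-alignment update of the plastic recurrent weights
#'
#' Returns the weight increment
#' `delta M = eta_m * (Q z - (M - alpha G) r) r^T`,
#' the negative gradient of the instantaneous recurrent cost
#' `1/2 ||Q z - M r||^2 - alpha <G r, M r>` scaled by `eta_m`.  The
#' readout feedback `Q z` enters only this rule, never the dynamics.
#'
#' @param conn connectivity object (uses `G`, `M`, `Q`).
#' @param z current readout vector (length `K`).
#' @param r current rate vector (length `N`), from the same step as `z`.
#' @param alpha alignment weight.
#' @param eta_m learning rate.
#' @return An `N x N` matrix; the caller applies `M <- M + delta`.
#' @export
pa_update_M <- function(conn, z, r, alpha = 1, eta_m = 1e-4) {
  err <- as.numeric(conn$Q %*% z) -
    (as.numeric(conn$M %*% r) - alpha * as.numeric(conn$G %*% r))
  eta_m * tcrossprod(err, r)
}

#' Least-mean-square (Delta rule) readout update
#'
#' Returns `delta W = eta_w * (f - z) r^T`.
#'
#' @param W readout matrix (`K x N`); only used for shape checks.
#' @param f target vector (length `K`).
#' @param z readout vector (length `K`).
#' @param r rate vector (length `N`).
#' @param eta_w learning rate.
#' @return A `K x N` matrix.
#' @export
lms_update_W <- function(W, f, z, r, eta_w = 1e-3) {
  stopifnot(length(f) == nrow(W), length(z) == nrow(W), length(r) == ncol(W))
  eta_w * tcrossprod(f - z, r)
}

#' Recursive-least-squares state for the FORCE baseline
#'
#' `P` is the running inverse-correlation estimate, initialized to
#' `I / lambda_reg`; the regularization parameter defaults to unity, the
#' standard FORCE setting.
#'
#' @param N number of presynaptic units.
#' @param lambda_reg ridge regularization parameter.
#' @return An object of class `rls_state` with fields `P`, `lambda_reg`.
#' @export
rls_state <- function(N, lambda_reg = 1) {
  stopifnot(lambda_reg > 0)
  structure(list(P = diag(N) / lambda_reg, lambda_reg = lambda_reg),
            class = "rls_state")
}

#' One recursive-least-squares update of the readout
#'
#' Standard RLS step: `k = P r / (1 + r' P r)`, `P <- P - k (P r)'`,
#' `W <- W + (f - z) k'`.  If `P` drifts from symmetry beyond tolerance it
#' is re-symmetrized with a warning.
#'
#' @param rls an [rls_state()].
#' @param W readout matrix (`K x N`).
#' @param f,z,r target, readout and rate vectors for the current step.
#' @param sym_tol symmetry tolerance for `P`.
#' @return A list with the updated `rls` and `W`.
#' @export
rls_update_W <- function(rls, W, f, z, r, sym_tol = 1e-8) {
  Pr <- as.numeric(rls$P %*% r)
  c_ <- 1 / (1 + sum(r * Pr))
  k <- c_ * Pr
  rls$P <- rls$P - tcrossprod(k, Pr)
  asym <- max(abs(rls$P - t(rls$P)))
  if (asym > sym_tol) {
    warning(sprintf("RLS P lost symmetry (max asymmetry %.3g); re-symmetrizing",
                    asym))
    rls$P <- (rls$P + t(rls$P)) / 2
  }
  W <- W + tcrossprod(f - z, k)
  list(rls = rls, W = W)
}

build_log <- function(res, cfg, N, K, n_seg, t0 = 0) {
  steps <- res$seg_steps
  keep <- steps > 0
  seg_len <- steps * cfg$dt
  t_start <- t0 + cumsum(c(0, seg_len))[seq_len(n_seg)]
  data.frame(
    segment = seq_len(n_seg),
    t_start = t_start,
    t_end = t_start + seg_len,
    err_out = sqrt(res$err_out_ss / pmax(1, steps * K)),
    e_rec = sqrt(res$erec_ss / pmax(1, steps * N)),
    corr_GrMr = res$corr_seg,
    norm_M = res$norm_M,
    norm_W = res$norm_W)[keep, , drop = FALSE]
}

#' Train a network on a task
#'
#' Integrates the rate dynamics while applying online weight updates each
#' step.  Under `rule = "pa"` the plastic matrix `M` follows the
#' predictive-alignment rule and `W` the LMS rule; `"alpha0"` is the same
#' with the alignment regularizer switched off (`alpha = 0` control);
#' `"force"` trains only `W` by recursive least squares with the readout
#' fed back into the dynamics through `Q` (the classical FORCE setup on
#' the same reservoir).  `G` is never modified.  Progress is logged on 10
#' equal time segments.
#'
#' @param conn a [init_connectivity()] object.
#' @param task a task generator (see e.g. [make_periodic()]).
#' @param cfg a [train_config()].
#' @param rule one of `"pa"`, `"force"`, `"alpha0"`.
#' @param x0 optional initial membrane potential (default `N(0,1)` under
#'   `cfg$seed`).
#' @param n_seg number of logging segments.
#' @param lambda_reg RLS regularization (FORCE only).
#' @return An object of class `pa_training`: list with the updated `conn`,
#'   the `log` data frame (per-segment readout RMS error, recurrent error
#'   `E_rec`, alignment correlation, weight norms), final state `x`,
#'   `t_end`, `rule` and `cfg`.
#' @export
train <- function(conn, task, cfg = train_config(),
                  rule = c("pa", "force", "alpha0"),
                  x0 = NULL, n_seg = 10, lambda_reg = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(conn, "pa_connectivity"), inherits(task, "pa_task"))
  if (task$K != conn$spec$K) {
    stop(sprintf("task has K=%d targets but network has K=%d readouts",
                 task$K, conn$spec$K))
  }
  if (is.finite(task$horizon) && task$horizon < cfg$T_train) {
    stop("task horizon is shorter than cfg$T_train")
  }
  n_steps <- as.integer(round(cfg$T_train / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = 0)
  set.seed(cfg$seed)
  if (is.null(x0)) x0 <- rnorm(conn$spec$N)
  learnM <- schedule_flags(cfg$plasticity_schedule, n_steps, cfg$dt, "M")
  learnW <- schedule_flags(cfg$plasticity_schedule, n_steps, cfg$dt, "W")
  alpha <- if (rule == "alpha0") 0 else cfg$alpha
  rule_code <- if (rule == "force") 1L else 0L
  res <- rate_run_cpp(conn$G, conn$M, conn$W, conn$Q, conn$W_in,
                      sig$I, sig$F, x0, cfg$dt, cfg$tau, cfg$sigma,
                      cfg$eta_m, cfg$eta_w, alpha, rule_code,
                      learnM, learnW, rule == "force",
                      as.integer(n_seg), 0L, FALSE,
                      cfg$sde_noise, lambda_reg, 1e3)
  log <- build_log(res, cfg, conn$spec$N, conn$spec$K, n_seg)
  if (res$diverged > 0) {
    cond <- structure(
      class = c("predalign_divergence", "error", "condition"),
      list(message = sprintf(
             "training diverged at step %d (t = %g ms); partial log attached",
             res$diverged, res$diverged * cfg$dt),
           call = sys.call(), log = log))
    stop(cond)
  }
  conn$M <- res$M
  conn$W <- res$W
  conn$feedback <- if (rule == "force") "readout" else "none"
  structure(list(conn = conn, log = log, x = as.numeric(res$x),
                 t_end = n_steps * cfg$dt, rule = rule, cfg = cfg,
                 task = task$name),
            class = "pa_training")
}

#' @export
print.pa_training <- function(x, ...) {
  cat(sprintf("pa_training: task=%s rule=%s T=%g ms\n",
              x$task, x$rule, x$t_end))
  cat(sprintf("  readout RMS error: first segment %.4g -> last segment %.4g\n",
              x$log$err_out[1], tail(x$log$err_out, 1)))
  invisible(x)
}

#' Epoch-based training with state resets
#'
#' Repeats a fixed-duration trial (`epoch_duration` ms) `n_epochs`
#' times, resetting the network to the same predefined initial state at
#' time zero of every epoch — the protocol used for movie replay, where
#' identical initial conditions in learning and testing let the
#' autonomous dynamics retrace the stored sequence.  One log row per
#' epoch.
#'
#' @param conn connectivity object.
#' @param task a [pa_task()]; the target over `[0, epoch_duration)` is
#'   used every epoch.
#' @param cfg a [train_config()].
#' @param n_epochs number of epochs.
#' @param epoch_duration epoch length (ms).
#' @param x0 the predefined initial state (default: standard-normal
#'   under `cfg$seed`, as for the movie protocol).
#' @return A `pa_training`-like list with `conn`, per-epoch `log`
#'   (columns `epoch`, `err_out`, `e_rec`, `corr_GrMr`, `norm_M`,
#'   `norm_W`), `x0` and `cfg`.
#' @export
train_epochs <- function(conn, task, cfg = train_config(), n_epochs = 100,
                         epoch_duration = 1000, x0 = NULL) {
  stopifnot(inherits(conn, "pa_connectivity"), inherits(task, "pa_task"))
  n_steps <- as.integer(round(epoch_duration / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = 0)
  set.seed(cfg$seed)
  if (is.null(x0)) x0 <- rnorm(conn$spec$N)
  flags_on <- rep(TRUE, n_steps)
  rows <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    res <- rate_run_cpp(conn$G, conn$M, conn$W, conn$Q, conn$W_in,
                        sig$I, sig$F, x0, cfg$dt, cfg$tau, cfg$sigma,
                        cfg$eta_m, cfg$eta_w, cfg$alpha, 0L,
                        flags_on, flags_on, FALSE, 1L, 0L, FALSE,
                        cfg$sde_noise, 1, 1e3)
    if (res$diverged > 0) {
      stop(sprintf("epoch training diverged in epoch %d (step %d)",
                   e, res$diverged))
    }
    conn$M <- res$M
    conn$W <- res$W
    rows[[e]] <- data.frame(
      epoch = e,
      err_out = sqrt(res$err_out_ss[1] / (n_steps * conn$spec$K)),
      e_rec = sqrt(res$erec_ss[1] / (n_steps * conn$spec$N)),
      corr_GrMr = res$corr_seg[1],
      norm_M = res$norm_M[1], norm_W = res$norm_W[1])
  }
  structure(list(conn = conn, log = do.call(rbind, rows), x0 = x0,
                 x = as.numeric(res$x), t_end = epoch_duration,
                 rule = "pa", cfg = cfg, task = task$name),
            class = "pa_epoch_training")
}

#' Autonomous replay after epoch training
#'
#' Runs the trained network from the predefined initial state with
#' plasticity off and compares the readout with the epoch target.
#'
#' @param fit result of [train_epochs()].
#' @param task the task trained on.
#' @param duration replay duration (ms; defaults to one epoch).
#' @return As [test_autonomous()].
#' @export
replay_epochs <- function(fit, task, duration = fit$t_end) {
  conn <- fit$conn
  cfg <- fit$cfg
  n_steps <- as.integer(round(duration / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = 0)
  flags <- rep(FALSE, n_steps)
  res <- rate_run_cpp(conn$G, conn$M, conn$W, conn$Q, conn$W_in,
                      sig$I, sig$F, fit$x0, cfg$dt, cfg$tau, 0,
                      0, 0, cfg$alpha, 2L, flags, flags, FALSE,
                      1L, 1L, FALSE, FALSE, 1, 1e3)
  err <- sig$F - res$z_rec
  list(z = res$z_rec, f = sig$F, t = (seq_len(n_steps) - 1) * cfg$dt,
       rms = sqrt(mean(err^2)), rms_channel = sqrt(rowMeans(err^2)))
}

#' Autonomous test of a trained network
#'
#' Runs the dynamics with all plasticity off and returns the readout
#' trace and its RMS error against the task target.  By default the run
#' continues from the final state and time of the training phase so that
#' the target phase stays aligned.
#'
#' @param fit a `pa_training` result, or a `pa_connectivity` (then `x0`
#'   and `t0` should be given).
#' @param task task generator providing inputs and targets.
#' @param cfg a [train_config()] (only `dt`, `tau`, `sigma` are used).
#' @param duration test duration (ms).
#' @param x0,t0 initial state and start time (defaults from `fit`).
#' @param record_r also record the rate trajectory.
#' @return A list with `z` (`K x n` readout), `f` (targets), `t`, `rms`
#'   (overall), `rms_channel` (per readout) and `r` (rates or `NULL`).
#' @export
test_autonomous <- function(fit, task, cfg = train_config(), duration = 1000,
                            x0 = NULL, t0 = NULL, record_r = FALSE) {
  if (inherits(fit, "pa_training")) {
    conn <- fit$conn
    if (is.null(x0)) x0 <- fit$x
    if (is.null(t0)) t0 <- fit$t_end
    cfg <- fit$cfg
  } else {
    conn <- fit
    if (is.null(t0)) t0 <- 0
    if (is.null(x0)) x0 <- rnorm(conn$spec$N)
  }
  n_steps <- as.integer(round(duration / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = t0)
  flags <- rep(FALSE, n_steps)
  res <- rate_run_cpp(conn$G, conn$M, conn$W, conn$Q, conn$W_in,
                      sig$I, sig$F, x0, cfg$dt, cfg$tau, cfg$sigma,
                      0, 0, cfg$alpha, 2L, flags, flags,
                      identical(conn$feedback, "readout"),
                      1L, 1L, record_r, cfg$sde_noise, 1, 1e3)
  if (res$diverged > 0) {
    stop(sprintf("autonomous run diverged at step %d", res$diverged))
  }
  err <- sig$F - res$z_rec
  list(z = res$z_rec, f = sig$F,
       t = t0 + (seq_len(n_steps) - 1) * cfg$dt,
       rms = sqrt(mean(err^2)),
       rms_channel = sqrt(rowMeans(err^2)),
       r = if (record_r) res$r_rec else NULL,
       x = as.numeric(res$x))
}

#' Train an extra readout group with frozen recurrent weights
#'
#' Least-mean-square training of a fresh readout matrix on top of fixed
#' network dynamics (reservoir-computing mode).  Used for the second
#' phase of [train_two_phase()] and its untrained-reservoir control.
#'
#' @param conn connectivity (recurrent weights are not modified).
#' @param task task providing the new target group.
#' @param cfg a [train_config()].
#' @param x0 optional initial state.
#' @param n_seg logging segments.
#' @return A list with the trained readout `W2`, the training `log`, the
#'   final state `x` and `t_end`.
#' @export
train_readout_only <- function(conn, task, cfg = train_config(), x0 = NULL,
                               n_seg = 10) {
  K2 <- task$K
  n_steps <- as.integer(round(cfg$T_train / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = 0)
  set.seed(cfg$seed)
  if (is.null(x0)) x0 <- rnorm(conn$spec$N)
  W2 <- matrix(0, K2, conn$spec$N)
  Q2 <- matrix(0, conn$spec$N, K2)
  flags_on <- rep(TRUE, n_steps)
  flags_off <- rep(FALSE, n_steps)
  res <- rate_run_cpp(conn$G, conn$M, W2, Q2, conn$W_in,
                      sig$I, sig$F, x0, cfg$dt, cfg$tau, cfg$sigma,
                      0, cfg$eta_w, 0, 0L, flags_off, flags_on, FALSE,
                      as.integer(n_seg), 0L, FALSE, cfg$sde_noise, 1, 1e3)
  if (res$diverged > 0) {
    stop(sprintf("readout-only training diverged at step %d", res$diverged))
  }
  list(W2 = res$W, log = build_log(res, cfg, conn$spec$N, K2, n_seg),
       x = as.numeric(res$x), t_end = n_steps * cfg$dt)
}

#' Two-phase generalization protocol
#'
#' Phase 1 applies full predictive-alignment training of `M` and the
#' first readout group on a set of multi-frequency sinusoids.  Phase 2
#' freezes the recurrent weights and trains a second, disjoint readout
#' group on novel targets, using the pretrained network as a reservoir.
#'
#' @param conn untrained connectivity whose `K` matches `phase1_task$K`.
#' @param phase1_task,phase2_task the two task generators.
#' @param cfg1,cfg2 training configurations for the two phases.
#' @return A list with the trained `conn` (including the second-group
#'   readout `W2`), `log1`, `log2`, and the phase-2 final state.
#' @export
train_two_phase <- function(conn, phase1_task, phase2_task,
                            cfg1 = train_config(), cfg2 = cfg1) {
  if (phase1_task$K != conn$spec$K) {
    stop("phase-1 readout group must match the network's K readouts")
  }
  fit1 <- train(conn, phase1_task, cfg1, rule = "pa")
  ph2 <- train_readout_only(fit1$conn, phase2_task, cfg2, x0 = fit1$x)
  conn_out <- fit1$conn
  conn_out$W2 <- ph2$W2
  list(conn = conn_out, log1 = fit1$log, log2 = ph2$log,
       x = ph2$x, t_end_phase2 = ph2$t_end)
}
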