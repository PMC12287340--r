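#' Lyapunov estimator configuration
#'
#' Twin-trajectory settings: initial separation `1e-6`, 500 warm-up
#' steps, 1000 measurement steps with per-step renormalization of the
#' separation (direction preserved).
#'
#' @param gamma0 initial separation.
#' @param n_warmup warm-up steps (not measured).
#' @param n_measure measurement steps.
#' @return An object of class `lyapunov_config`.
#' @export
lyapunov_config <- function(gamma0 = 1e-6, n_warmup = 500,
                            n_measure = 1000) {
  stopifnot(gamma0 > 0, n_warmup >= 1, n_measure >= 1)
  structure(list(gamma0 = gamma0, n_warmup = n_warmup,
                 n_measure = n_measure), class = "lyapunov_config")
}

#' Leading Lyapunov exponent by the twin-trajectory method
#'
#' Two copies of the network are separated by `gamma0` along a random
#' direction and evolved without inputs or noise; after every step the
#' separation is rescaled back to `gamma0` while preserving its
#' direction, and the exponent is the mean of `log(gamma_k / gamma0)`
#' over the measurement steps, reported per millisecond.  Negative
#' values indicate a sub-critical (contracting) network, positive values
#' chaos.
#'
#' @param conn a `pa_connectivity` (rate) or spiking connectivity from
#'   [init_spike_connectivity()].
#' @param cfg a [lyapunov_config()].
#' @param dynamics `"rate"` or `"spiking"`.
#' @param dt,tau integration step and time constant (ms); for spiking
#'   dynamics the spike config's constants are used.
#' @param x0 initial state (default standard-normal draw for rate,
#'   uniform membrane draw for spiking).
#' @param seed optional seed for the initial state and perturbation
#'   direction.
#' @return The estimated exponent (1/ms).
#' @export
lyapunov_exponent <- function(conn, cfg = lyapunov_config(),
                              dynamics = c("rate", "spiking"),
                              dt = 1, tau = 10, x0 = NULL, seed = NULL) {
  dynamics <- match.arg(dynamics)
  if (!is.null(seed)) set.seed(seed)
  if (dynamics == "rate") {
    if (is.null(x0)) x0 <- rnorm(conn$spec$N)
    lyap_rate_cpp(conn$G, conn$M, x0, dt, tau,
                  cfg$n_warmup, cfg$n_measure, cfg$gamma0)
  } else {
    scfg <- conn$spike_cfg
    stopifnot(!is.null(scfg))
    st <- spike_state(scfg$N, cfg = scfg)
    if (!is.null(x0)) st$v <- x0
    lyap_spike_cpp(conn$G, conn$M, rep(scfg$I_bias, scfg$N),
                   st$v, st$r, st$refr, dt, scfg$tau_m, scfg$tau_s,
                   scfg$v_th, scfg$v_reset, scfg$tau_ref,
                   cfg$n_warmup, cfg$n_measure, cfg$gamma0)
  }
}

#' Lyapunov exponent of an arbitrary map
#'
#' Same twin-trajectory estimator applied to a user-supplied one-step
#' map `x -> step_fn(x)`; returns the exponent per step.  Used mainly as
#' a closed-form oracle (e.g. the linear map `x -> a x` has exponent
#' `log(a)` exactly).
#'
#' @param step_fn one-step map.
#' @param x0 initial state vector.
#' @param cfg a [lyapunov_config()].
#' @param direction optional perturbation direction (default random).
#' @return Exponent per step.
#' @export
lyapunov_map <- function(step_fn, x0, cfg = lyapunov_config(),
                         direction = NULL) {
  n <- length(x0)
  if (is.null(direction)) direction <- rnorm(n)
  u <- direction / sqrt(sum(direction^2))
  x1 <- x0
  x2 <- x0 + cfg$gamma0 * u
  acc <- 0
  for (k in seq_len(cfg$n_warmup + cfg$n_measure)) {
    x1 <- step_fn(x1)
    x2 <- step_fn(x2)
    gamma <- sqrt(sum((x2 - x1)^2))
    if (gamma <= 0) {
      stop("degenerate perturbation: twin trajectories collapsed")
    }
    if (k > cfg$n_warmup) acc <- acc + log(gamma / cfg$gamma0)
    x2 <- x1 + (cfg$gamma0 / gamma) * (x2 - x1)
  }
  acc / cfg$n_measure
}

#' Segment-wise recurrent prediction error
#'
#' `E_rec` is the root-mean-square deviation between the regularized
#' recurrent prediction `(M - alpha G) r` and the readout feedback
#' `Q z` (with `z = W r` from the same trajectory), normalized by the
#' number of units and the segment duration:
#' `E_rec = sqrt( sum_t dt sum_i e_i(t)^2 / (N T_seg) )`.
#'
#' @param traj_r `N x T` rate trajectory.
#' @param conn connectivity providing `G`, `M`, `Q`, `W`.
#' @param alpha regularization weight.
#' @param dt sampling step of the trajectory (ms).
#' @param n_seg number of equal segments.
#' @return Numeric vector of per-segment errors.
#' @export
recurrent_error <- function(traj_r, conn, alpha = 1, dt = 1, n_seg = 10) {
  T_ <- ncol(traj_r)
  N <- nrow(traj_r)
  Z <- conn$W %*% traj_r
  E <- (conn$M %*% traj_r - alpha * as.matrix(conn$G %*% traj_r)) -
    conn$Q %*% Z
  seg <- floor((seq_len(T_) - 1) * n_seg / T_) + 1
  ss <- vapply(seq_len(n_seg),
               function(s) sum(E[, seg == s, drop = FALSE]^2), numeric(1))
  n_in_seg <- tabulate(seg, n_seg)
  sqrt(ss / (N * pmax(1, n_in_seg)))
}

#' Alignment correlation between chaotic and predictive dynamics
#'
#' Time-integrated inner product `<G r, M r> = sum_t dt (G r)' (M r)`
#' over the trajectory window.  Growth of this quantity during learning
#' is the signature of the alignment regularizer.
#'
#' @param traj_r `N x T` rate trajectory.
#' @param conn connectivity providing `G` and `M`.
#' @param dt sampling step (ms).
#' @return Scalar correlation value.
#' @export
alignment_correlation <- function(traj_r, conn, dt = 1) {
  Gr <- as.matrix(conn$G %*% traj_r)
  Mr <- conn$M %*% traj_r
  dt * sum(Gr * Mr)
}

#' Representational efficiency of network activity
#'
#' From the time-averaged correlation matrix `C` of the mean-centered
#' rates, computes the eigenvalue entropy
#' `H = -sum p_i log p_i` with `p_i = lambda_i / sum lambda_j`
#' (representational diversity), the participation ratio
#' `PR = (sum lambda_i)^2 / sum lambda_i^2` (effective dimensionality),
#' and the efficiency index `H / sqrt(PR)`.  Numerically zero or
#' negative eigenvalues are clipped at zero and excluded from the
#' entropy sum.
#'
#' @param traj_r `N x T` rate trajectory (T > N recommended).
#' @return An object of class `efficiency_result` with fields
#'   `eigenvalues`, `p`, `H_lambda`, `PR`, `efficiency`.
#' @export
efficiency_index <- function(traj_r) {
  if (all(abs(traj_r) < 1e-12)) {
    stop("degenerate input: all-zero activity has no spectrum")
  }
  X <- traj_r - rowMeans(traj_r)
  C <- tcrossprod(X) / ncol(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p <- ev / sum(ev)
  pos <- p > 0
  H <- -sum(p[pos] * log(p[pos]))
  PR <- sum(ev)^2 / sum(ev^2)
  structure(list(eigenvalues = ev, p = p, H_lambda = H, PR = PR,
                 efficiency = H / sqrt(PR)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency_result: H = %.4g, PR = %.4g, efficiency = %.4g\n",
              x$H_lambda, x$PR, x$efficiency))
  invisible(x)
}

#' Eigenvalue spectrum of the recurrent weights
#'
#' Returns the complex eigenvalues of `J = G + M` (or of `G` or `M`
#' alone) together with the count of outliers, i.e. eigenvalues whose
#' real part exceeds the initial bulk radius by more than `margin`.
#' For the untrained network the circular-law bulk radius of `J` is
#' `sqrt(g_g^2 + g_m^2)`; training adds low-rank structure to `M` that
#' pushes a few eigenvalues outside this disk.
#'
#' @param conn connectivity object.
#' @param which `"J"`, `"G"` or `"M"`.
#' @param bulk_radius bulk radius estimate; default from the spec gains.
#' @param margin relative outlier margin (0.1 = 10% beyond the radius).
#' @return List with `values` (complex), `bulk_radius`, `outliers`
#'   (complex subset) and `n_outliers`.
#' @export
eigenspectrum <- function(conn, which = c("J", "G", "M"),
                          bulk_radius = NULL, margin = 0.1) {
  which <- match.arg(which)
  A <- switch(which,
              J = as.matrix(conn$G) + conn$M,
              G = as.matrix(conn$G),
              M = conn$M)
  if (is.null(bulk_radius)) {
    sp <- conn$spec
    bulk_radius <- switch(which,
                          J = sqrt(sp$g_g^2 + sp$g_m^2),
                          G = sp$g_g, M = sp$g_m)
  }
  ev <- eigen(A, only.values = TRUE)$values
  out <- ev[Re(ev) > bulk_radius * (1 + margin)]
  list(values = ev, bulk_radius = bulk_radius, outliers = out,
       n_outliers = length(out))
}

#' Tent map of successive local maxima
#'
#' Finds strict local maxima of a series (plateaus are collapsed to
#' their first index) and returns consecutive pairs
#' `(max_k, max_{k+1})`.  For a Lorenz-type signal the pairs trace the
#' single-humped tent curve characteristic of the attractor.
#'
#' @param series numeric vector (length >= 3).
#' @return Data frame with columns `prev` and `curr`; zero rows when the
#'   series has fewer than two local maxima.
#' @export
tent_map <- function(series) {
  stopifnot(length(series) >= 3)
  rl <- rle(series)
  v <- rl$values
  n <- length(v)
  if (n < 3) return(data.frame(prev = numeric(0), curr = numeric(0)))
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
              FALSE)
  m <- v[is_max]
  if (length(m) < 2) return(data.frame(prev = numeric(0), curr = numeric(0)))
  data.frame(prev = m[-length(m)], curr = m[-1])
}

#' Perturbation probe of learned fixed points
#'
#' For a network trained on the memory-bit task, applies a single input
#' pulse of each probe amplitude against the current state of one bit
#' and classifies the post-pulse steady state by the sign of that bit's
#' readout: `"return"` (back to the original fixed point), `"switch"`
#' (crossed the saddle to the other fixed point) or `"undetermined"`
#' (no clean steady state).  The pulse sign always opposes the current
#' memory state, so sufficiently strong pulses switch it.
#'
#' @param conn trained connectivity (`n_in = K = n_bits`).
#' @param bit which bit to probe.
#' @param amplitudes probe amplitudes (training pulses have amplitude 1).
#' @param pulse_dur pulse duration (ms).
#' @param settle_dur pre-pulse settling time (ms).
#' @param post_dur post-pulse observation time (ms).
#' @param cfg a [train_config()] for integration constants.
#' @param x0 initial state (default standard-normal draw).
#' @return List with `outcomes` (data frame `amplitude`, `outcome`) and
#'   `threshold` (smallest switching amplitude, `NA` when none).
#' @export
fixed_point_probe <- function(conn, bit = 1,
                              amplitudes = seq(0.27, 0.33, by = 0.01),
                              pulse_dur = 100, settle_dur = 2000,
                              post_dur = 1500, cfg = train_config(),
                              x0 = NULL) {
  n_in <- ncol(conn$W_in)
  stopifnot(bit >= 1, bit <= n_in)
  if (is.null(x0)) x0 <- rnorm(conn$spec$N)
  # settle onto a fixed point with no input
  settle <- simulate_rate(conn, settle_dur, dt = cfg$dt, tau = cfg$tau,
                          x0 = x0, record_every = 1)
  z_tail <- settle$z[bit, max(1, ncol(settle$z) - 499):ncol(settle$z)]
  s0 <- sign(mean(z_tail))
  steady0 <- abs(mean(z_tail)) > 0.3 && all(sign(z_tail) == s0)
  classify <- function(a) {
    n_pulse <- as.integer(round(pulse_dur / cfg$dt))
    n_post <- as.integer(round(post_dur / cfg$dt))
    I <- matrix(0, n_in, n_pulse + n_post)
    I[bit, seq_len(n_pulse)] <- -s0 * a
    run <- simulate_rate(conn, (n_pulse + n_post) * cfg$dt, dt = cfg$dt,
                         tau = cfg$tau, input = I, x0 = settle$x,
                         record_every = 1)
    z_end <- run$z[bit, (ncol(run$z) - min(499, n_post - 1)):ncol(run$z)]
    if (abs(mean(z_end)) < 0.3 || any(sign(z_end) != sign(mean(z_end)))) {
      return("undetermined")
    }
    if (sign(mean(z_end)) == s0) "return" else "switch"
  }
  if (!steady0) {
    outcomes <- data.frame(amplitude = amplitudes,
                           outcome = rep("undetermined", length(amplitudes)))
    return(list(outcomes = outcomes, threshold = NA_real_, base_sign = s0))
  }
  outcome <- vapply(amplitudes, classify, character(1))
  sw <- amplitudes[outcome == "switch"]
  list(outcomes = data.frame(amplitude = amplitudes, outcome = outcome),
       threshold = if (length(sw)) min(sw) else NA_real_, base_sign = s0)
}

#' Principal-component projection of a rate trajectory
#'
#' Mean-centered linear projection onto the leading principal axes, or
#' onto a custom basis (e.g. the plane spanned by PC1 and an input
#' vector for fixed-point analyses; the basis is orthonormalized by QR).
#'
#' @param traj_r `N x T` rate trajectory.
#' @param n_components number of components (<= N).
#' @param basis optional `N x m` matrix of basis vectors replacing the
#'   principal axes.
#' @return List with `scores` (`T x m` projected trajectory), `rotation`
#'   (`N x m`), `center` and `sdev` (PCA mode only).
#' @export
pca_project <- function(traj_r, n_components = 2, basis = NULL) {
  N <- nrow(traj_r)
  if (is.null(basis) && n_components > N) {
    stop("n_components must not exceed the number of units")
  }
  X <- t(traj_r)  # T x N
  if (!is.null(basis)) {
    basis <- qr.Q(qr(as.matrix(basis)))
    ctr <- colMeans(X)
    scores <- sweep(X, 2, ctr) %*% basis
    return(list(scores = scores, rotation = basis, center = ctr,
                sdev = NULL))
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       center = p$center, sdev = p$sdev)
}
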