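#' Rate-network state
#'
#' Holds the membrane potential vector `x`, the firing rates
#' \eqn{r = tanh(x)} and the current time in ms.  Rates are recomputed from
#' `x` whenever the state is advanced, so \eqn{r = tanh(x)} holds at all times.
#'
#' @param x initial membrane potentials, or a single integer `N` to draw
#'   `x ~ N(0, 1)` (seedable via [set.seed()]).
#' @param t current time in ms.
#' @return An object of class `rate_state` with fields `x`, `r`, `t`.
#' @export
rate_state <- function(x, t = 0) {
  if (length(x) == 1 && x == round(x) && x >= 1) x <- rnorm(as.integer(x))
  structure(list(x = as.numeric(x), r = tanh(as.numeric(x)), t = t),
            class = "rate_state")
}

#' One forward-Euler step of the rate dynamics
#'
#' Advances `tau dx/dt = -x + (G + M) r + W_in I + sigma xi` by `dt` ms
#' with `xi` a fresh standard Gaussian per unit per step, then recomputes
#' \eqn{r = tanh(x)}.  By default the noise term is injected exactly as
#' written (held constant within the step); set `sde_noise = TRUE` for the
#' SDE-consistent scaling `sigma * xi * sqrt(tau / dt)`.
#'
#' @param state a [rate_state()].
#' @param conn a [init_connectivity()] object.
#' @param input input vector of length `n_in` (ignored when `n_in = 0`).
#' @param sigma noise scale.
#' @param dt,tau integration step and membrane time constant (ms).
#' @param sde_noise use `sqrt(tau/dt)` noise scaling instead of the plain
#'   per-step injection.
#' @return The advanced `rate_state`.
#' @export
step_rate <- function(state, conn, input = NULL, sigma = 0,
                      dt = 1, tau = 10, sde_noise = FALSE) {
  stopifnot(inherits(state, "rate_state"), dt > 0, tau > 0)
  x <- state$x
  r <- state$r
  drive <- as.numeric(conn$G %*% r) + as.numeric(conn$M %*% r)
  if (!is.null(input) && ncol(conn$W_in) > 0) {
    drive <- drive + as.numeric(conn$W_in %*% input)
  }
  if (sigma > 0) {
    scale <- if (sde_noise) sqrt(tau / dt) else 1
    drive <- drive + sigma * scale * rnorm(length(x))
  }
  x_new <- x + (dt / tau) * (-x + drive)
  if (!all(is.finite(x_new))) {
    stop(sprintf("numerical divergence in step_rate at t = %g ms", state$t))
  }
  structure(list(x = x_new, r = tanh(x_new), t = state$t + dt),
            class = "rate_state")
}

#' Linear readout of the network rates
#'
#' Returns `z = W r` for the current state.
#'
#' @param state a [rate_state()].
#' @param conn a connectivity object.
#' @return Numeric vector of length `K`.
#' @export
readout <- function(state, conn) {
  as.numeric(conn$W %*% state$r)
}

#' Simulate the rate network without plasticity
#'
#' Runs the forward-Euler dynamics for `duration` ms and records the rate
#' and readout trajectories.  All randomness (initial state when `x0` is
#' missing, and the noise stream) is drawn from R's RNG, so a prior
#' [set.seed()] makes the run reproducible bit-for-bit.
#'
#' @param conn a connectivity object.
#' @param duration simulated time (ms).
#' @param dt,tau integration step and time constant (ms).
#' @param sigma noise scale (0 = deterministic).
#' @param input optional `n_in x n_steps` input matrix.
#' @param x0 initial membrane potential (default `N(0,1)` draw).
#' @param record_every record every k-th step (1 = all).
#' @param sde_noise see [step_rate()].
#' @param feedback add `Q z` to the dynamics (used by FORCE-trained nets).
#' @return A list with `r` (`N x n_rec` rates), `z` (`K x n_rec` readout),
#'   `t` (recorded times, ms), `x` (final state).
#' @export
simulate_rate <- function(conn, duration, dt = 1, tau = 10, sigma = 0,
                          input = NULL, x0 = NULL, record_every = 1,
                          sde_noise = FALSE,
                          feedback = identical(conn$feedback, "readout")) {
  n_steps <- max(1L, as.integer(round(duration / dt)))
  N <- conn$spec$N
  if (is.null(x0)) x0 <- rnorm(N)
  if (is.null(input)) {
    input <- matrix(0, 0, n_steps)
  } else {
    stopifnot(ncol(input) == n_steps)
  }
  Fz <- matrix(0, conn$spec$K, n_steps)
  flags <- rep(FALSE, n_steps)
  res <- rate_run_cpp(conn$G, conn$M, conn$W, conn$Q, conn$W_in,
                      input, Fz, x0, dt, tau, sigma,
                      0, 0, 1, 2L, flags, flags, feedback,
                      1L, as.integer(record_every), TRUE,
                      sde_noise, 1, 1e3)
  if (res$diverged > 0) {
    stop(sprintf("numerical divergence in simulate_rate at step %d",
                 res$diverged))
  }
  n_rec <- ncol(res$r_rec)
  list(r = res$r_rec, z = res$z_rec,
       t = (seq_len(n_rec) - 1) * dt * record_every, x = as.numeric(res$x))
}
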