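#' Configuration for the leaky integrate-and-fire network
#'
#' Parameter defaults follow the standard spiking setting: membrane time
#' constant 10 ms, threshold 1, reset -1, refractory period 2 ms,
#' synaptic filter 20 ms, constant background current at threshold, and
#' connectivity gains `(p, g) = (0.1, 0.3)` for `G`, `(1.0, 0.05)` for
#' `M`.  The realized mean of each weight matrix is explicitly set to
#' zero to counterbalance firing-rate heterogeneity.
#'
#' @param N number of neurons.
#' @param tau_m membrane time constant (ms).
#' @param v_th,v_reset spike threshold and reset potential.
#' @param tau_ref refractory period (ms).
#' @param tau_s synaptic filter time constant (ms).
#' @param I_bias background current (scalar, applied to all neurons).
#' @param p_g,g_g,p_m,g_m connectivity parameters as in
#'   [connectivity_spec()].
#' @param K number of readouts.
#' @param seed RNG seed.
#' @return An object of class `spike_config`.
#' @export
spike_config <- function(N = 500, tau_m = 10, v_th = 1, v_reset = -1,
                         tau_ref = 2, tau_s = 20, I_bias = v_th,
                         p_g = 0.1, g_g = 0.3, p_m = 1.0, g_m = 0.05,
                         K = 1, seed = 1L) {
  stopifnot(v_reset < v_th, tau_m > 0, tau_s > 0, tau_ref > 0)
  structure(list(N = as.integer(N), tau_m = tau_m, v_th = v_th,
                 v_reset = v_reset, tau_ref = tau_ref, tau_s = tau_s,
                 I_bias = I_bias, p_g = p_g, g_g = g_g, p_m = p_m,
                 g_m = g_m, K = as.integer(K), seed = as.integer(seed)),
            class = "spike_config")
}

#' Initialize spiking-network connectivity
#'
#' As [init_connectivity()], but with the spiking gain defaults and the
#' realized mean of `G` and `M` explicitly subtracted so each matrix sums
#' to zero exactly.
#'
#' @param cfg a [spike_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return A `pa_connectivity` whose `spec` carries the spiking gains;
#'   the spike parameters travel in `conn$spike_cfg`.
#' @export
init_spike_connectivity <- function(cfg, seed = cfg$seed) {
  spec <- connectivity_spec(N = cfg$N, p_g = cfg$p_g, g_g = cfg$g_g,
                            p_m = cfg$p_m, g_m = cfg$g_m, K = cfg$K,
                            n_in = 0, seed = seed)
  conn <- init_connectivity(spec, zero_mean = TRUE)
  conn$spike_cfg <- cfg
  conn
}

#' Spiking-network state
#'
#' @param v membrane potentials, or an integer `N` for a uniform draw
#'   spanning `[v_reset, v_th + (v_th - v_reset)/2)`.  The upper part of
#'   the range lies above threshold so that a fraction of neurons fires
#'   immediately: with the background current fixed exactly at threshold
#'   the membrane equation alone never crosses `v_th` from below, so
#'   ignition of network activity has to come from the initial
#'   condition.
#' @param r filtered spike-train vector (defaults to zeros).
#' @param refr remaining refractory time per neuron (ms).
#' @param t current time (ms).
#' @param cfg a [spike_config()] (used for the random init range).
#' @return An object of class `spike_state`.
#' @export
spike_state <- function(v, r = NULL, refr = NULL, t = 0,
                        cfg = spike_config()) {
  if (length(v) == 1 && v == round(v) && v >= 1) {
    v <- runif(as.integer(v), cfg$v_reset,
               cfg$v_th + (cfg$v_th - cfg$v_reset) / 2)
  }
  n <- length(v)
  if (is.null(r)) r <- rep(0, n)
  if (is.null(refr)) refr <- rep(0, n)
  structure(list(v = as.numeric(v), r = as.numeric(r),
                 refr = as.numeric(refr), spikes = integer(0), t = t),
            class = "spike_state")
}

#' One Euler step of the LIF dynamics
#'
#' Non-refractory neurons integrate
#' `tau_m dv/dt = -v + (G + M) r + I_bias`; neurons whose potential
#' reaches `v >= v_th` fire, are reset to `v_reset` and clamped there for
#' `tau_ref` ms.  The synaptic trace decays by `(1 - dt / tau_s)` and
#' each spike adds `1 / tau_s` to its neuron's trace (the exact Euler
#' image of the delta-driven filter).
#'
#' @param state a [spike_state()].
#' @param conn connectivity from [init_spike_connectivity()] (or any
#'   object with `G`, `M`).
#' @param cfg a [spike_config()].
#' @param dt step (ms); must not exceed `tau_ref`.
#' @return The advanced `spike_state`; indices of neurons that fired this
#'   step are in `$spikes`.
#' @export
step_lif <- function(state, conn, cfg = spike_config(), dt = 0.5) {
  stopifnot(dt > 0, dt <= cfg$tau_ref)
  v <- state$v; r <- state$r; refr <- state$refr
  drive <- as.numeric(conn$G %*% r) + as.numeric(conn$M %*% r) + cfg$I_bias
  refractory <- refr > 0
  v[refractory] <- cfg$v_reset
  refr[refractory] <- refr[refractory] - dt
  v[!refractory] <- v[!refractory] +
    (dt / cfg$tau_m) * (-v[!refractory] + drive[!refractory])
  r <- r * (1 - dt / cfg$tau_s)
  fired <- which(refr <= 0 & v >= cfg$v_th)
  if (length(fired)) {
    v[fired] <- cfg$v_reset
    refr[fired] <- cfg$tau_ref
    r[fired] <- r[fired] + 1 / cfg$tau_s
  }
  structure(list(v = v, r = r, refr = refr, spikes = fired, t = state$t + dt),
            class = "spike_state")
}

#' Train a spiking network on a task
#'
#' Same plasticity rules as the rate network (predictive alignment for
#' `M`, LMS for `W`), applied to the filtered spike trains.  Spiking runs
#' use `dt = 0.5` ms by default.
#'
#' @param conn from [init_spike_connectivity()].
#' @param task a [pa_task()] (targets only; external input is not wired
#'   into the spiking model).
#' @param cfg a [train_config()]; `cfg$tau` is ignored in favor of the
#'   spike config's `tau_m`.
#' @param n_seg logging segments.
#' @param state optional initial [spike_state()].
#' @return A `pa_spike_training` list with the updated `conn`, `log`,
#'   final `state`, `t_end` and `cfg`.
#' @export
train_spike <- function(conn, task, cfg = train_config(dt = 0.5),
                        n_seg = 10, state = NULL) {
  scfg <- conn$spike_cfg
  stopifnot(!is.null(scfg), cfg$dt <= scfg$tau_ref)
  n_steps <- as.integer(round(cfg$T_train / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = 0)
  set.seed(cfg$seed)
  if (is.null(state)) state <- spike_state(scfg$N, cfg = scfg)
  learnM <- schedule_flags(cfg$plasticity_schedule, n_steps, cfg$dt, "M")
  learnW <- schedule_flags(cfg$plasticity_schedule, n_steps, cfg$dt, "W")
  res <- spike_run_cpp(conn$G, conn$M, conn$W, conn$Q,
                       rep(scfg$I_bias, scfg$N), sig$F,
                       state$v, state$r, state$refr,
                       cfg$dt, scfg$tau_m, scfg$tau_s,
                       scfg$v_th, scfg$v_reset, scfg$tau_ref,
                       cfg$eta_m, cfg$eta_w, cfg$alpha, 0L,
                       learnM, learnW, as.integer(n_seg), 0L, FALSE,
                       FALSE, 1e3)
  if (res$diverged > 0) {
    stop(sprintf("spiking training diverged at step %d", res$diverged))
  }
  conn$M <- res$M
  conn$W <- res$W
  out_state <- structure(list(v = as.numeric(res$v), r = as.numeric(res$r),
                              refr = as.numeric(res$refr),
                              spikes = integer(0), t = n_steps * cfg$dt),
                         class = "spike_state")
  structure(list(conn = conn,
                 log = build_log(res, cfg, scfg$N, scfg$K, n_seg),
                 state = out_state, t_end = n_steps * cfg$dt, cfg = cfg,
                 task = task$name),
            class = "pa_spike_training")
}

#' Autonomous test of a trained spiking network
#'
#' @param fit a `pa_spike_training` result.
#' @param task target task.
#' @param duration test duration (ms).
#' @param record_spikes also return the spike raster.
#' @return List with `z`, `f`, `t`, `rms`, and optionally `spikes`
#'   (a data frame `time_ms`, `neuron_id`).
#' @export
test_spike_autonomous <- function(fit, task, duration = 1000,
                                  record_spikes = FALSE) {
  conn <- fit$conn
  scfg <- conn$spike_cfg
  cfg <- fit$cfg
  n_steps <- as.integer(round(duration / cfg$dt))
  sig <- task_signals(task, n_steps, cfg$dt, t0 = fit$t_end)
  flags <- rep(FALSE, n_steps)
  res <- spike_run_cpp(conn$G, conn$M, conn$W, conn$Q,
                       rep(scfg$I_bias, scfg$N), sig$F,
                       fit$state$v, fit$state$r, fit$state$refr,
                       cfg$dt, scfg$tau_m, scfg$tau_s,
                       scfg$v_th, scfg$v_reset, scfg$tau_ref,
                       0, 0, cfg$alpha, 2L, flags, flags, 1L, 1L, FALSE,
                       record_spikes, 1e3)
  err <- sig$F - res$z_rec
  spikes <- NULL
  if (record_spikes) {
    spikes <- data.frame(time_ms = fit$t_end + res$spike_t,
                         neuron_id = res$spike_id)
  }
  list(z = res$z_rec, f = sig$F,
       t = fit$t_end + (seq_len(n_steps) - 1) * cfg$dt,
       rms = sqrt(mean(err^2)), spikes = spikes)
}

#' Simulate a spiking network (optionally recording the raster)
#'
#' No plasticity; useful for spontaneous-activity diagnostics and spike
#' raster export.
#'
#' @param conn from [init_spike_connectivity()].
#' @param duration ms.
#' @param dt step (ms).
#' @param state optional initial state.
#' @param record_r record filtered traces.
#' @return List with `r` (traces or `NULL`), `spikes` raster data frame,
#'   and the final `state`.
#' @export
simulate_spike <- function(conn, duration, dt = 0.5, state = NULL,
                           record_r = TRUE) {
  scfg <- conn$spike_cfg
  n_steps <- as.integer(round(duration / dt))
  if (is.null(state)) state <- spike_state(scfg$N, cfg = scfg)
  flags <- rep(FALSE, n_steps)
  Fz <- matrix(0, scfg$K, n_steps)
  res <- spike_run_cpp(conn$G, conn$M, conn$W, conn$Q,
                       rep(scfg$I_bias, scfg$N), Fz,
                       state$v, state$r, state$refr,
                       dt, scfg$tau_m, scfg$tau_s,
                       scfg$v_th, scfg$v_reset, scfg$tau_ref,
                       0, 0, 1, 2L, flags, flags, 1L,
                       if (record_r) 1L else 0L, record_r, TRUE, 1e3)
  list(r = if (record_r) res$r_rec else NULL,
       z = res$z_rec,
       spikes = data.frame(time_ms = res$spike_t, neuron_id = res$spike_id),
       state = structure(list(v = as.numeric(res$v), r = as.numeric(res$r),
                              refr = as.numeric(res$refr),
                              spikes = integer(0), t = n_steps * dt),
                         class = "spike_state"))
}

#' Two-population (excitatory/inhibitory) LIF connectivity
#'
#' All eight weight blocks are element-wise non-negative: blocks are
#' drawn Gaussian as in the single-population case and any negative
#' values are flipped to positive; inhibition enters the dynamics with
#' an explicit minus sign.  During learning, plastic blocks are
#' rectified at zero after every update so the sign structure (Dale's
#' law) is preserved.
#'
#' @param N_E,N_I population sizes.
#' @param cfg a [spike_config()] providing neuron and gain parameters.
#' @param seed RNG seed.
#' @return An object of class `two_pop_connectivity` with blocks `G_XY`,
#'   `M_XY` (X, Y in E, I), readouts `W_E`, `W_I`, feedbacks `Q_E`,
#'   `Q_I`, biases and the config.
#' @export
init_two_pop <- function(N_E = 400, N_I = 100, cfg = spike_config(),
                         seed = cfg$seed) {
  set.seed(seed)
  draw_block <- function(nr, nc, p, g) {
    # gain normalization uses the source (presynaptic) population size
    sd <- if (g > 0) g / sqrt(p * nc) else 0
    mask <- matrix(runif(nr * nc) < p, nr, nc)
    vals <- matrix(0, nr, nc)
    if (sd > 0) vals[mask] <- abs(rnorm(sum(mask), 0, sd))
    vals
  }
  G_EE <- draw_block(N_E, N_E, cfg$p_g, cfg$g_g)
  G_EI <- draw_block(N_E, N_I, cfg$p_g, cfg$g_g)
  G_IE <- draw_block(N_I, N_E, cfg$p_g, cfg$g_g)
  G_II <- draw_block(N_I, N_I, cfg$p_g, cfg$g_g)
  M_EE <- draw_block(N_E, N_E, cfg$p_m, cfg$g_m)
  M_EI <- draw_block(N_E, N_I, cfg$p_m, cfg$g_m)
  M_IE <- draw_block(N_I, N_E, cfg$p_m, cfg$g_m)
  M_II <- draw_block(N_I, N_I, cfg$p_m, cfg$g_m)
  K <- cfg$K
  structure(list(G_EE = G_EE, G_EI = G_EI, G_IE = G_IE, G_II = G_II,
                 M_EE = M_EE, M_EI = M_EI, M_IE = M_IE, M_II = M_II,
                 W_E = matrix(0, K, N_E), W_I = matrix(0, K, N_I),
                 Q_E = matrix(runif(N_E * K, -3 / sqrt(K), 3 / sqrt(K)),
                              N_E, K),
                 Q_I = matrix(runif(N_I * K, -3 / sqrt(K), 3 / sqrt(K)),
                              N_I, K),
                 bias_E = rep(cfg$I_bias, N_E),
                 bias_I = rep(cfg$I_bias, N_I),
                 N_E = N_E, N_I = N_I, cfg = cfg),
            class = "two_pop_connectivity")
}

#' One Euler step of the two-population LIF dynamics
#'
#' Excitatory input enters with a plus sign, inhibitory with a minus
#' sign; both populations follow the LIF update of [step_lif()].
#'
#' @param state_E,state_I [spike_state()] objects for the two populations.
#' @param conn an [init_two_pop()] object.
#' @param cfg a [spike_config()].
#' @param dt step (ms).
#' @return `list(E =, I =)` advanced states.
#' @export
step_lif_two_pop <- function(state_E, state_I, conn, cfg = conn$cfg,
                             dt = 0.5) {
  if (any(conn$M_EE < 0) || any(conn$M_EI < 0) ||
      any(conn$M_IE < 0) || any(conn$M_II < 0)) {
    stop("two-population plastic weights must be non-negative")
  }
  drive_E <- as.numeric((conn$G_EE + conn$M_EE) %*% state_E$r) -
    as.numeric((conn$G_EI + conn$M_EI) %*% state_I$r) + conn$bias_E
  drive_I <- as.numeric((conn$G_IE + conn$M_IE) %*% state_E$r) -
    as.numeric((conn$G_II + conn$M_II) %*% state_I$r) + conn$bias_I
  adv <- function(st, drive) {
    v <- st$v; r <- st$r; refr <- st$refr
    refractory <- refr > 0
    v[refractory] <- cfg$v_reset
    refr[refractory] <- refr[refractory] - dt
    v[!refractory] <- v[!refractory] +
      (dt / cfg$tau_m) * (-v[!refractory] + drive[!refractory])
    r <- r * (1 - dt / cfg$tau_s)
    fired <- which(refr <= 0 & v >= cfg$v_th)
    if (length(fired)) {
      v[fired] <- cfg$v_reset
      refr[fired] <- cfg$tau_ref
      r[fired] <- r[fired] + 1 / cfg$tau_s
    }
    structure(list(v = v, r = r, refr = refr, spikes = fired,
                   t = st$t + dt), class = "spike_state")
  }
  list(E = adv(state_E, drive_E), I = adv(state_I, drive_I))
}

#' Simulate (and optionally train) the two-population network
#'
#' Runs the E/I dynamics with the predictive-alignment extension applied
#' blockwise when `plastic = TRUE`: updates follow the signed recurrent
#' prediction and are rectified at zero, so all blocks remain
#' non-negative.
#'
#' @param conn an [init_two_pop()] object.
#' @param task target task (`K` must match).
#' @param duration ms.
#' @param dt step (ms).
#' @param plastic apply plasticity.
#' @param cfg a [train_config()] for the learning rates.
#' @param record_every recording stride (0 = none).
#' @return List with updated `conn`, readout trace `z`, membrane traces
#'   and final states.
#' @export
simulate_two_pop <- function(conn, task = NULL, duration = 1000, dt = 0.5,
                             plastic = FALSE, cfg = train_config(dt = dt),
                             record_every = 1) {
  scfg <- conn$cfg
  n_steps <- as.integer(round(duration / dt))
  Fz <- if (is.null(task)) {
    matrix(0, nrow(conn$W_E), n_steps)
  } else {
    task_signals(task, n_steps, dt)$F
  }
  sE <- spike_state(conn$N_E, cfg = scfg)
  sI <- spike_state(conn$N_I, cfg = scfg)
  res <- two_pop_run_cpp(conn$G_EE, conn$G_EI, conn$G_IE, conn$G_II,
                         conn$M_EE, conn$M_EI, conn$M_IE, conn$M_II,
                         conn$W_E, conn$W_I, conn$Q_E, conn$Q_I,
                         conn$bias_E, conn$bias_I, Fz,
                         sE$v, sI$v, sE$r, sI$r, sE$refr, sI$refr,
                         dt, scfg$tau_m, scfg$tau_s, scfg$v_th,
                         scfg$v_reset, scfg$tau_ref,
                         cfg$eta_m, cfg$eta_w, cfg$alpha, plastic,
                         as.integer(record_every), 1e3)
  if (res$diverged > 0) {
    stop(sprintf("two-population run diverged at step %d", res$diverged))
  }
  conn$M_EE <- res$M_EE; conn$M_EI <- res$M_EI
  conn$M_IE <- res$M_IE; conn$M_II <- res$M_II
  conn$W_E <- res$W_E; conn$W_I <- res$W_I
  list(conn = conn, z = res$z_rec, v_E = res$vE_rec, v_I = res$vI_rec,
       state_E = structure(list(v = as.numeric(res$v_E),
                                r = as.numeric(res$r_E),
                                refr = as.numeric(res$refr_E),
                                spikes = integer(0), t = n_steps * dt),
                           class = "spike_state"),
       state_I = structure(list(v = as.numeric(res$v_I),
                                r = as.numeric(res$r_I),
                                refr = as.numeric(res$refr_I),
                                spikes = integer(0), t = n_steps * dt),
                           class = "spike_state"))
}

#' Write a spike raster to CSV
#'
#' Two columns: `time_ms`, `neuron_id`.
#'
#' @param spikes data frame from [simulate_spike()] or
#'   [test_spike_autonomous()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_raster <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}
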