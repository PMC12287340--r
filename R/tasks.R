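#' Task objects
#'
#' A task bundles a (deterministic) generator of time-indexed input
#' currents and target readout signals.  All randomness is realized when
#' the task is constructed, so a task is a pure function of its
#' parameters and seed: evaluating it twice on the same time grid yields
#' identical signals.
#'
#' @param name task name.
#' @param n_in number of input channels.
#' @param K number of target channels.
#' @param gen function of a numeric time vector (ms) returning
#'   `list(I = n_in x n matrix, F = K x n matrix)`.
#' @param horizon total defined duration (ms); `Inf` for periodic tasks.
#' @param meta free-form metadata (trial structure, schedules, ...).
#' @return An object of class `pa_task`.
#' @export
pa_task <- function(name, n_in, K, gen, horizon = Inf, meta = list()) {
  structure(list(name = name, n_in = as.integer(n_in), K = as.integer(K),
                 gen = gen, horizon = horizon, meta = meta),
            class = "pa_task")
}

#' @export
print.pa_task <- function(x, ...) {
  cat(sprintf("pa_task '%s': n_in=%d, K=%d, horizon=%s ms\n",
              x$name, x$n_in, x$K,
              if (is.finite(x$horizon)) format(x$horizon) else "Inf"))
  invisible(x)
}

#' Evaluate a task on a time grid
#'
#' @param task a [pa_task()].
#' @param n_steps number of steps.
#' @param dt step (ms).
#' @param t0 start time (ms).
#' @return `list(I, F, t)` with signal matrices and the time grid.
#' @export
task_signals <- function(task, n_steps, dt = 1, t0 = 0) {
  t <- t0 + (seq_len(n_steps) - 1) * dt
  out <- task$gen(t)
  stopifnot(nrow(out$F) == task$K, ncol(out$F) == n_steps)
  out$t <- t
  out
}

#' Periodic single-channel targets
#'
#' `sine` is `amplitude * sin(2 pi t / period)`; `step` is a square wave
#' with 50% duty cycle; `sawtooth` is a rising linear ramp with an
#' instantaneous reset.  All are normalized to
#' `[-amplitude, amplitude]`.
#'
#' @param kind one of `"sine"`, `"step"`, `"sawtooth"`.
#' @param period period in ms.
#' @param amplitude peak amplitude (the classic sine example uses 3/2).
#' @param phase phase offset in radians (sine only).
#' @return A [pa_task()] with `K = 1`, no inputs.
#' @export
make_periodic <- function(kind = c("sine", "step", "sawtooth"),
                          period = 60, amplitude = 1.5, phase = 0) {
  kind <- match.arg(kind)
  stopifnot(period > 0)
  f <- switch(kind,
    sine = function(t) amplitude * sin(2 * pi * t / period + phase),
    step = function(t) ifelse((t %% period) < period / 2,
                              amplitude, -amplitude),
    sawtooth = function(t) amplitude * (2 * ((t %% period) / period) - 1))
  pa_task(paste0(kind, "_T", period), 0, 1,
          function(t) list(I = matrix(0, 0, length(t)),
                           F = matrix(f(t), 1)),
          meta = list(kind = kind, period = period, amplitude = amplitude))
}

#' Multiple simultaneous periodic targets
#'
#' `K = n_targets` sinusoidal channels with distinct periods and phases;
#' the output feedback during learning remains all-to-all across the
#' recurrent population via `Q`.
#'
#' @param n_targets number of channels.
#' @param periods vector of periods (ms), recycled to `n_targets`.
#' @param phases vector of phases (radians).
#' @param amplitude common amplitude.
#' @return A [pa_task()] with `K = n_targets`.
#' @export
make_multi_targets <- function(n_targets = 5,
                               periods = c(60, 90, 120, 180, 240),
                               phases = 2 * pi * (seq_len(n_targets) - 1) /
                                 n_targets,
                               amplitude = 1.5) {
  periods <- rep_len(periods, n_targets)
  phases <- rep_len(phases, n_targets)
  pa_task(sprintf("multi%d", n_targets), 0, n_targets,
          function(t) {
            F <- vapply(seq_len(n_targets), function(k) {
              amplitude * sin(2 * pi * t / periods[k] + phases[k])
            }, numeric(length(t)))
            list(I = matrix(0, 0, length(t)), F = t(F))
          },
          meta = list(periods = periods, phases = phases,
                      amplitude = amplitude))
}

#' Static control inputs switching between output patterns
#'
#' Each trial presents one of `n_patterns` static random input vectors
#' (no temporal information); the single target channel is the waveform
#' paired with that pattern.  The pattern sequence, drawn at
#' construction, is available as `meta$pattern_seq`.
#'
#' @param n_patterns number of input patterns.
#' @param n_in number of input channels.
#' @param targets list of `n_patterns` functions of within-trial time
#'   (ms) returning the target value; defaults to sinusoids of distinct
#'   periods.
#' @param trial_dur trial duration (ms).
#' @param n_trials number of trials realized in the schedule.
#' @param seed RNG seed for input vectors and the trial sequence.
#' @return A [pa_task()] with `K = 1`.
#' @export
make_control_switch <- function(n_patterns = 4, n_in = 10, targets = NULL,
                                trial_dur = 600, n_trials = 200, seed = 1L) {
  if (is.null(targets)) {
    periods <- c(60, 100, 150, 240)[seq_len(n_patterns)]
    targets <- lapply(periods, function(p) {
      force(p)
      function(tt) 1.5 * sin(2 * pi * tt / p)
    })
  }
  stopifnot(length(targets) == n_patterns)
  set.seed(seed)
  patterns <- matrix(runif(n_in * n_patterns, -1, 1), n_in, n_patterns)
  pattern_seq <- sample.int(n_patterns, n_trials, replace = TRUE)
  pa_task("control_switch", n_in, 1,
          function(t) {
            trial <- pmin(floor(t / trial_dur) + 1, n_trials)
            tt <- t - (trial - 1) * trial_dur
            pat <- pattern_seq[trial]
            F <- vapply(seq_along(t),
                        function(i) targets[[pat[i]]](tt[i]), numeric(1))
            list(I = patterns[, pat, drop = FALSE], F = matrix(F, 1))
          },
          horizon = n_trials * trial_dur,
          meta = list(patterns = patterns, pattern_seq = pattern_seq,
                      trial_dur = trial_dur))
}

#' Memory-bit (flip-flop) task
#'
#' Each of `n_bits` input channels emits transient pulses of random sign
#' (+1 or -1, 100 ms duration by default) at random intervals drawn
#' uniformly from `interval`.  The corresponding target holds the sign
#' of the last pulse on that bit until the next pulse arrives; before
#' the first pulse it holds a random initial sign.
#'
#' @param n_bits number of independent bits.
#' @param pulse_amp pulse magnitude.
#' @param pulse_dur pulse duration (ms).
#' @param interval range (ms) of inter-pulse intervals, e.g. `c(500, 700)`.
#' @param T_total schedule length (ms).
#' @param seed RNG seed for the pulse schedule.
#' @return A [pa_task()] with `n_in = K = n_bits`; the realized schedule
#'   is in `meta$schedule` (columns `bit`, `t_on`, `sign`).
#' @export
make_memory_bits <- function(n_bits = 3, pulse_amp = 1, pulse_dur = 100,
                             interval = c(500, 700), T_total = 300000,
                             seed = 1L) {
  stopifnot(T_total > 2 * max(interval))
  set.seed(seed)
  init_sign <- sample(c(-1, 1), n_bits, replace = TRUE)
  sched <- list()
  for (b in seq_len(n_bits)) {
    t_on <- numeric(0)
    t_cur <- runif(1, interval[1], interval[2])
    while (t_cur + pulse_dur < T_total) {
      t_on <- c(t_on, t_cur)
      t_cur <- t_cur + runif(1, interval[1], interval[2])
    }
    sched[[b]] <- data.frame(bit = b, t_on = t_on,
                             sign = sample(c(-1, 1), length(t_on),
                                           replace = TRUE))
  }
  schedule <- do.call(rbind, sched)
  pa_task("memory_bits", n_bits, n_bits,
          function(t) {
            n <- length(t)
            I <- matrix(0, n_bits, n)
            F <- matrix(0, n_bits, n)
            for (b in seq_len(n_bits)) {
              s <- schedule[schedule$bit == b, ]
              idx <- findInterval(t, s$t_on)  # last pulse at or before t
              F[b, ] <- c(init_sign[b], s$sign)[idx + 1]
              active <- idx > 0 & (t - s$t_on[pmax(idx, 1)]) < pulse_dur
              I[b, active] <- pulse_amp * s$sign[idx[active]]
            }
            list(I = I, F = F)
          },
          horizon = T_total,
          meta = list(schedule = schedule, init_sign = init_sign,
                      pulse_amp = pulse_amp, pulse_dur = pulse_dur,
                      interval = interval))
}

#' Lorenz-system parameters
#'
#' Chaotic regime defaults `(s, rho, b) = (10, 28, 8/3)`; targets are the
#' state divided by `scale = 10`.  `speed` maps Lorenz time units to
#' network time: 0.01 units per ms (one unit = 100 ms).  `h` is the
#' internal RK4 step in Lorenz units.
#'
#' @param s,rho,b Lorenz parameters.
#' @param scale output division factor.
#' @param speed Lorenz time units per network ms.
#' @param h internal integration step (Lorenz units).
#' @param transient initial stretch (Lorenz units) discarded so the
#'   trajectory starts on the attractor.
#' @return A parameter list of class `lorenz_params`.
#' @export
lorenz_params <- function(s = 10, rho = 28, b = 8 / 3, scale = 10,
                          speed = 0.01, h = 0.005, transient = 50) {
  stopifnot(s > 0, rho > 0, b > 0, scale > 0, speed > 0, h > 0)
  structure(list(s = s, rho = rho, b = b, scale = scale, speed = speed,
                 h = h, transient = transient),
            class = "lorenz_params")
}

#' Lorenz-attractor target task
#'
#' Integrates the Lorenz system with a fixed-step RK4 integrator from a
#' randomized initial point, discards a transient, scales the state by
#' `1/scale` and resamples it onto the network time grid.  Three target
#' channels, no inputs.
#'
#' @param params a [lorenz_params()].
#' @param duration network-time duration (ms) of the realized target.
#' @param dt network time step (ms); `dt * speed / h` must be an integer.
#' @param seed seed for the initial point.
#' @param init optional explicit initial state (length 3); overrides the
#'   random draw (e.g. `c(0, 0, 0)` stays at the fixed point).
#' @return A [pa_task()] with `K = 3`; the realized target matrix is in
#'   `meta$F_full`.
#' @export
make_lorenz <- function(params = lorenz_params(), duration = 300000,
                        dt = 1, seed = 1L, init = NULL) {
  stopifnot(duration > 0)
  thin <- (dt * params$speed) / params$h
  if (abs(thin - round(thin)) > 1e-9) {
    stop("dt * speed / h must be an integer number of internal steps")
  }
  thin <- as.integer(round(thin))
  if (is.null(init)) {
    set.seed(seed)
    init <- c(rnorm(2, 0, 5), rnorm(1, 25, 5))
  }
  n_transient <- as.integer(round(params$transient / params$h))
  if (n_transient > 0 && any(init != 0)) {
    warm <- lorenz_rk4_cpp(init, n_transient, params$h,
                           params$s, params$rho, params$b, n_transient)
    init <- warm[, ncol(warm)]
  }
  n_steps <- as.integer(round(duration / dt))
  traj <- lorenz_rk4_cpp(init, n_steps * thin, params$h,
                         params$s, params$rho, params$b, thin)
  F_full <- traj[, seq_len(n_steps), drop = FALSE] / params$scale
  pa_task("lorenz", 0, 3,
          function(t) {
            idx <- pmin(floor(t / dt) + 1, n_steps)
            list(I = matrix(0, 0, length(t)),
                 F = F_full[, idx, drop = FALSE])
          },
          horizon = duration,
          meta = list(params = params, F_full = F_full, dt = dt))
}

#' Ready-Set-Go parameters
#'
#' Gaussian pulses of width `delta = 15` ms, a uniform offset
#' `T0 = 60` ms, and the four training delays 100, 120, 140, 160 ms.
#'
#' @param delta pulse standard deviation (ms).
#' @param T0 offset of the first pulse within a trial (ms).
#' @param delays training delay set (ms).
#' @param trial_len trial duration (ms); must leave room for the target
#'   pulse at `T0 + 2 * max(delays)`.
#' @return A parameter list of class `rsg_params`.
#' @export
rsg_params <- function(delta = 15, T0 = 60,
                       delays = c(100, 120, 140, 160), trial_len = 600) {
  stopifnot(T0 + 2 * max(delays) + 3 * delta < trial_len)
  structure(list(delta = delta, T0 = T0, delays = delays,
                 trial_len = trial_len),
            class = "rsg_params")
}

#' Ready-Set-Go task
#'
#' Two input channels carry the ready and set pulses
#' `s1(t) = 2 exp(-(t - T0)^2 / delta^2) - 1` and its copy delayed by
#' `T_delay`; the single target is a pulse a further `T_delay` after the
#' set pulse (peak at `T0 + 2 T_delay`).  Baseline value is -1 away from
#' the pulses.  Per-trial delays are sampled from the training set at
#' construction, or supplied explicitly for testing.
#'
#' @param params an [rsg_params()].
#' @param n_trials number of trials.
#' @param delays optional explicit per-trial delays (recycled); when
#'   `NULL`, delays are sampled uniformly from `params$delays`.
#' @param seed seed for the delay sequence.
#' @return A [pa_task()] with `n_in = 2`, `K = 1`; per-trial delays in
#'   `meta$delays`.
#' @export
make_rsg <- function(params = rsg_params(), n_trials = 100, delays = NULL,
                     seed = 1L) {
  if (is.null(delays)) {
    set.seed(seed)
    delays <- sample(params$delays, n_trials, replace = TRUE)
  } else {
    delays <- rep_len(delays, n_trials)
  }
  trial_len <- params$trial_len
  pulse <- function(tt, center) {
    2 * exp(-(tt - center)^2 / params$delta^2) - 1
  }
  pa_task("rsg", 2, 1,
          function(t) {
            trial <- pmin(floor(t / trial_len) + 1, n_trials)
            tt <- t - (trial - 1) * trial_len
            d <- delays[trial]
            I <- rbind(pulse(tt, params$T0), pulse(tt, params$T0 + d))
            F <- matrix(pulse(tt, params$T0 + 2 * d), 1)
            list(I = I, F = F)
          },
          horizon = n_trials * trial_len,
          meta = list(params = params, delays = delays,
                      trial_len = trial_len))
}

render_blob_frame <- function(height, width, cx, cy, amp, sigma) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  img <- matrix(0, height, width)
  for (j in seq_along(cx)) {
    img <- img + amp[j] *
      exp(-((xs - cx[j])^2 + (ys - cy[j])^2) / (2 * sigma[j]^2))
  }
  pmin(img, 1)
}

#' Synthetic movie task
#'
#' A deterministic, seeded stand-in for a natural video clip: Gaussian
#' blobs move along smooth paths across RGB key frames, which are then
#' linearly interpolated in time to `upsample_to` frames and flattened to
#' `height * width * channels` target channels scaled to `[-1, 1]`.  One
#' frame is presented per millisecond of network time; the frame sequence
#' repeats every `upsample_to` ms (one epoch).
#'
#' @param height,width,channels frame geometry (paper-scale default
#'   80 x 92 x 3 gives 22,080 channels).
#' @param n_key_frames number of rendered key frames.
#' @param upsample_to number of interpolated frames per epoch.
#' @param seed seed for blob paths.
#' @param n_blobs moving blobs per channel.
#' @return A [pa_task()] with `K = height * width * channels`; the
#'   interpolated frame matrix is `meta$F_full` (`K x upsample_to`).
#' @export
make_synthetic_movie <- function(height = 80, width = 92, channels = 3,
                                 n_key_frames = 100, upsample_to = 1000,
                                 seed = 1L, n_blobs = 2) {
  stopifnot(height > 0, width > 0, channels > 0, n_key_frames >= 1,
            upsample_to >= 1)
  set.seed(seed)
  K <- height * width * channels
  key <- matrix(0, K, n_key_frames)
  for (ch in seq_len(channels)) {
    f_x <- runif(n_blobs, 0.5, 2)
    f_y <- runif(n_blobs, 0.5, 2)
    ph_x <- runif(n_blobs, 0, 2 * pi)
    ph_y <- runif(n_blobs, 0, 2 * pi)
    amp <- runif(n_blobs, 0.6, 1)
    sigma <- runif(n_blobs, 0.12, 0.25) * min(height, width)
    for (k in seq_len(n_key_frames)) {
      u <- if (n_key_frames > 1) (k - 1) / (n_key_frames - 1) else 0
      cx <- width / 2 + (width / 2 - 1) * sin(2 * pi * f_x * u + ph_x)
      cy <- height / 2 + (height / 2 - 1) * sin(2 * pi * f_y * u + ph_y)
      img <- render_blob_frame(height, width, cx, cy, amp, sigma)
      rows <- ((ch - 1) * height * width + 1):(ch * height * width)
      key[rows, k] <- as.numeric(img)
    }
  }
  key <- 2 * key - 1  # [0,1] -> [-1,1]
  pos <- if (n_key_frames > 1) {
    seq(1, n_key_frames, length.out = upsample_to)
  } else {
    rep(1, upsample_to)
  }
  lo <- pmin(floor(pos), n_key_frames)
  hi <- pmin(lo + 1, n_key_frames)
  wgt <- pos - lo
  F_full <- key[, lo, drop = FALSE] * rep(1 - wgt, each = K) +
    key[, hi, drop = FALSE] * rep(wgt, each = K)
  pa_task("synthetic_movie", 0, K,
          function(t) {
            idx <- (floor(t) %% upsample_to) + 1
            list(I = matrix(0, 0, length(t)),
                 F = F_full[, idx, drop = FALSE])
          },
          meta = list(height = height, width = width, channels = channels,
                      n_key_frames = n_key_frames, upsample_to = upsample_to,
                      key_frames = key, F_full = F_full))
}

#' Export a task's signals to CSV
#'
#' Writes a table with columns `time`, input channels `I1..`, and target
#' channels `F1..`.
#'
#' @param task a [pa_task()].
#' @param path output CSV path.
#' @param duration,dt time grid.
#' @return `path`, invisibly.
#' @export
write_task_csv <- function(task, path, duration, dt = 1) {
  sig <- task_signals(task, as.integer(round(duration / dt)), dt)
  df <- data.frame(time = sig$t)
  if (nrow(sig$I) > 0) {
    Im <- t(sig$I)
    colnames(Im) <- paste0("I", seq_len(ncol(Im)))
    df <- cbind(df, Im)
  }
  Fm <- t(sig$F)
  colnames(Fm) <- paste0("F", seq_len(ncol(Fm)))
  df <- cbind(df, Fm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
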