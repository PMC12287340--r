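#' Build a task from a config entry
#'
#' Dispatches on `name` to the task generators; `params` are passed on
#' as arguments.
#'
#' @param name one of `"sine"`, `"step"`, `"sawtooth"`, `"multi"`,
#'   `"control_switch"`, `"memory_bits"`, `"lorenz"`, `"rsg"`, `"movie"`.
#' @param params named list of generator arguments.
#' @return A [pa_task()].
#' @export
task_from_config <- function(name, params = list()) {
  known <- c("sine", "step", "sawtooth", "multi", "control_switch",
             "memory_bits", "lorenz", "rsg", "movie")
  if (!name %in% known) {
    stop(sprintf("unknown task '%s'; valid tasks: %s", name,
                 paste(known, collapse = ", ")))
  }
  switch(name,
    sine = ,
    step = ,
    sawtooth = do.call(make_periodic, c(list(kind = name), params)),
    multi = do.call(make_multi_targets, params),
    control_switch = do.call(make_control_switch, params),
    memory_bits = do.call(make_memory_bits, params),
    lorenz = do.call(make_lorenz, params),
    rsg = do.call(make_rsg, params),
    movie = do.call(make_synthetic_movie, params))
}

default_experiment <- function() {
  list(task = list(name = "sine", params = list()),
       spec = list(N = 300, p_g = 0.1, g_g = 1.2, p_m = 1, g_m = 0.5,
                   K = 1, n_in = 0),
       train = list(dt = 1, tau = 10, alpha = 1, sigma = 0,
                    T_train = 60000),
       rule = "pa",
       test = list(duration = 1000),
       analyses = character(0),
       seed = 1L)
}

#' Resolve an experiment configuration
#'
#' Fills in defaults for all unspecified fields; the resolved config is
#' what [run_experiment()] records alongside its outputs, so a run
#' directory is self-describing.
#'
#' @param config named list, or path to a JSON config file.
#' @return Resolved configuration list of class `experiment_config`.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_experiment()
  cfg <- modifyList(base, config)
  if (!cfg$rule %in% c("pa", "force", "alpha0")) {
    stop(sprintf("unknown rule '%s'; valid rules: pa, force, alpha0",
                 cfg$rule))
  }
  # the task name is validated here so bad configs fail before any work
  task_from_config(cfg$task$name, list())
  cfg$task$params <- as.list(cfg$task$params)
  cfg$analyses <- as.character(cfg$analyses)
  structure(cfg, class = "experiment_config")
}

#' Run a configured experiment end-to-end
#'
#' Initializes connectivity, trains with the configured rule, runs an
#' autonomous test, applies the requested analyses and writes
#' everything to `out_dir`: the resolved `config.json`, `train_log.csv`
#' (segment, err_out, e_rec, corr_GrMr, norm_M, norm_W),
#' `test_trace.csv`, a `weights/` directory of plain-text arrays,
#' per-analysis CSVs and a structured `run.log`.
#'
#' @param config list or JSON path (see [experiment_config()]).
#' @param out_dir output directory (created).
#' @return The output directory, invisibly; the in-memory results as the
#'   attribute `"results"`.
#' @export
run_experiment <- function(config, out_dir = tempfile("predalign_run_")) {
  cfg <- experiment_config(if (inherits(config, "experiment_config"))
    unclass(config) else config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), line))
  }

  task_params <- cfg$task$params
  if (cfg$task$name %in% c("memory_bits", "rsg", "control_switch", "lorenz",
                           "movie") && is.null(task_params$seed)) {
    task_params$seed <- cfg$seed
  }
  task <- task_from_config(cfg$task$name, task_params)
  spec_args <- cfg$spec
  spec_args$K <- task$K
  spec_args$n_in <- task$n_in
  spec_args$seed <- cfg$seed
  spec <- do.call(connectivity_spec, spec_args)
  conn <- init_connectivity(spec)
  say("initialized N=%d network for task %s", spec$N, task$name)

  tcfg_args <- cfg$train
  tcfg_args$seed <- cfg$seed
  tcfg <- do.call(train_config, tcfg_args)

  if (cfg$task$name == "movie") {
    n_epochs <- if (is.null(cfg$n_epochs)) 100 else cfg$n_epochs
    fit <- train_epochs(conn, task, tcfg, n_epochs = n_epochs,
                        epoch_duration = task$meta$upsample_to)
    test <- replay_epochs(fit, task)
    say("movie training: %d epochs, final err_out %.4g, replay RMS %.4g",
        n_epochs, tail(fit$log$err_out, 1), test$rms)
  } else {
    fit <- train(conn, task, tcfg, rule = cfg$rule)
    test <- test_autonomous(fit, task, duration = cfg$test$duration)
    say("training done (%s): err_out %.4g -> %.4g; test RMS %.4g",
        cfg$rule, fit$log$err_out[1], tail(fit$log$err_out, 1), test$rms)
  }

  write.csv(fit$log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  trace <- data.frame(t = test$t)
  zt <- t(test$z); colnames(zt) <- paste0("z", seq_len(ncol(zt)))
  ft <- t(test$f); colnames(ft) <- paste0("f", seq_len(ncol(ft)))
  write.csv(cbind(trace, zt, ft), file.path(out_dir, "test_trace.csv"),
            row.names = FALSE)
  write_connectivity(fit$conn, file.path(out_dir, "weights"))

  analyses <- list()
  for (an in cfg$analyses) {
    if (an == "lyapunov") {
      lam <- lyapunov_exponent(fit$conn, dt = tcfg$dt, tau = tcfg$tau,
                               seed = cfg$seed)
      analyses$lyapunov <- lam
      write.csv(data.frame(lambda_per_ms = lam),
                file.path(out_dir, "lyapunov.csv"), row.names = FALSE)
      say("lyapunov exponent: %.5g /ms", lam)
    } else if (an == "eigenspectrum") {
      es <- eigenspectrum(fit$conn, "J")
      analyses$eigenspectrum <- es
      write.csv(data.frame(re = Re(es$values), im = Im(es$values)),
                file.path(out_dir, "eigenspectrum.csv"), row.names = FALSE)
      say("eigenspectrum: %d outliers beyond radius %.3g",
          es$n_outliers, es$bulk_radius)
    } else if (an == "efficiency") {
      sim <- simulate_rate(fit$conn, 5000, dt = tcfg$dt, tau = tcfg$tau,
                           record_every = 5)
      eff <- efficiency_index(sim$r)
      analyses$efficiency <- eff
      write.csv(data.frame(H_lambda = eff$H_lambda, PR = eff$PR,
                           efficiency = eff$efficiency),
                file.path(out_dir, "efficiency.csv"), row.names = FALSE)
      say("efficiency: %.4g", eff$efficiency)
    } else {
      stop(sprintf(
        "unknown analysis '%s'; valid: lyapunov, eigenspectrum, efficiency",
        an))
    }
  }

  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  structure(invisible(out_dir),
            results = list(fit = fit, test = test, analyses = analyses))
}

#' Preset experiment registry
#'
#' One preset per headline experiment: periodic toy targets, frequency
#' variants, multi-readout, input-switched outputs, the alignment
#' (alpha) comparison, memory bits, the Lorenz attractor, Ready-Set-Go,
#' spiking variants, the synthetic movie, a gain sweep and the
#' two-phase generalization protocol.  Desk-scale sizes by default;
#' `paper_scale = TRUE` restores the full network sizes and durations.
#'
#' @param paper_scale use full (publication) sizes instead of desk-scale
#'   defaults.
#' @return Named list of experiment configurations (plus, for the
#'   presets that need special drivers, a `driver` hint field).
#' @export
presets <- function(paper_scale = FALSE) {
  N_rate <- if (paper_scale) 500 else 300
  T_rate <- if (paper_scale) 100000 else 60000
  p <- list()
  add <- function(name, task_name, task_params = list(), ...) {
    p[[name]] <<- modifyList(
      default_experiment(),
      c(list(task = list(name = task_name, params = task_params)),
        list(...)))
  }
  add("fig2a_sine", "sine", list(period = 60, amplitude = 1.5),
      spec = list(N = N_rate), train = list(T_train = T_rate))
  add("fig2d_frequencies", "sine",
      list(period = if (paper_scale) 2000 else 600, amplitude = 1.5),
      spec = list(N = N_rate), train = list(T_train = 2 * T_rate))
  add("fig2e_step", "step", list(period = 120, amplitude = 1),
      spec = list(N = N_rate), train = list(T_train = T_rate))
  add("fig2f_sawtooth", "sawtooth", list(period = 120, amplitude = 1),
      spec = list(N = N_rate), train = list(T_train = T_rate))
  add("fig2g_multi", "multi", list(n_targets = 5),
      spec = list(N = if (paper_scale) 500 else 400, K = 5),
      train = list(T_train = 2 * T_rate))
  add("fig2h_switch", "control_switch",
      list(n_patterns = 4, n_in = 10, n_trials = if (paper_scale) 500
           else 150),
      spec = list(N = N_rate), train = list(T_train = 90000))
  add("fig3_alpha_sweep", "sine", list(period = 60, amplitude = 1.5),
      spec = list(N = N_rate), train = list(T_train = T_rate),
      rule = "alpha0",
      analyses = c("lyapunov"))
  add("membits", "memory_bits",
      list(T_total = if (paper_scale) 300000 else 200000),
      spec = list(N = if (paper_scale) 500 else 300, K = 3, n_in = 3),
      train = list(T_train = if (paper_scale) 300000 else 200000))
  add("lorenz", "lorenz",
      list(duration = if (paper_scale) 15000000 else 300000),
      spec = list(N = 500, K = 3),
      train = list(T_train = if (paper_scale) 15000000 else 300000))
  add("rsg", "rsg",
      list(n_trials = if (paper_scale) 200000 else 2000),
      spec = list(N = if (paper_scale) 1200 else 400, n_in = 2),
      train = list(T_train = (if (paper_scale) 200000 else 2000) * 600))
  add("spiking_sine", "sine", list(period = 200, amplitude = 1),
      spec = list(N = if (paper_scale) 1000 else 500),
      train = list(dt = 0.5, T_train = 60000), driver = "spike")
  add("spiking_twopop", "sine", list(period = 200, amplitude = 1),
      spec = list(N = if (paper_scale) 1000 else 500),
      train = list(dt = 0.5, T_train = 30000), driver = "two_pop")
  add("movie_synth", "movie",
      if (paper_scale) list() else
        list(height = 16, width = 16, channels = 3, n_key_frames = 10,
             upsample_to = 100),
      spec = list(N = if (paper_scale) 800 else 200),
      n_epochs = if (paper_scale) 1500 else 150)
  add("g_sweep", "sine", list(period = 60, amplitude = 1.5),
      spec = list(N = N_rate), analyses = c("efficiency", "lyapunov"))
  add("generalization", "multi", list(n_targets = 3),
      spec = list(N = N_rate, K = 3), train = list(T_train = T_rate),
      driver = "two_phase")
  p
}

#' Command-line interface
#'
#' Subcommands: `train` (`--preset` or `--config`, `--out`), `test`
#' (`--run`), `analyze` (`--run`, `--what`), `preset-list`.  Installed
#' as `exec/predalign`; call `Rscript -e 'predalign::predalign_cli()'`
#' or the installed script directly.
#'
#' @param args character vector of CLI arguments (default:
#'   [commandArgs()] after `--args`).
#' @return Exit status (0 on success), invisibly.
#' @export
predalign_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: predalign <command> [options]",
    "  train       --preset NAME | --config FILE   [--out DIR]",
    "  test        --run DIR [--duration MS]",
    "  analyze     --run DIR --what lyapunov|eigenspectrum",
    "  preset-list [--paper-scale]",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) return(default)
    if (i == length(args)) stop(sprintf("missing value for --%s", name))
    args[i + 1]
  }
  cmd <- args[1]
  if (cmd == "preset-list") {
    ps <- presets(paper_scale = "--paper-scale" %in% args)
    for (nm in names(ps)) {
      message(sprintf("%-20s task=%s N=%s", nm, ps[[nm]]$task$name,
                      ps[[nm]]$spec$N))
    }
    return(invisible(0L))
  }
  if (cmd == "train") {
    preset <- opt("preset")
    cfg <- if (!is.null(preset)) {
      ps <- presets(paper_scale = "--paper-scale" %in% args)
      if (!preset %in% names(ps)) {
        stop(sprintf("unknown preset '%s'; see preset-list", preset))
      }
      ps[[preset]]
    } else {
      path <- opt("config")
      if (is.null(path)) stop("train needs --preset or --config")
      path
    }
    out <- opt("out", tempfile("predalign_run_"))
    run_experiment(cfg, out)
    message(sprintf("run written to %s", out))
    return(invisible(0L))
  }
  if (cmd == "test") {
    run_dir <- opt("run")
    if (is.null(run_dir)) stop("test needs --run DIR")
    cfg <- experiment_config(file.path(run_dir, "config.json"))
    conn <- read_connectivity(file.path(run_dir, "weights"))
    task <- task_from_config(cfg$task$name, cfg$task$params)
    dur <- as.numeric(opt("duration", cfg$test$duration))
    res <- test_autonomous(conn, task,
                           cfg = do.call(train_config, cfg$train),
                           duration = dur, t0 = 0)
    message(sprintf("test RMS error over %g ms: %.4g", dur, res$rms))
    return(invisible(0L))
  }
  if (cmd == "analyze") {
    run_dir <- opt("run")
    what <- opt("what", "lyapunov")
    if (is.null(run_dir)) stop("analyze needs --run DIR")
    conn <- read_connectivity(file.path(run_dir, "weights"))
    if (what == "lyapunov") {
      lam <- lyapunov_exponent(conn, seed = 1)
      message(sprintf("lyapunov exponent: %.5g /ms", lam))
    } else if (what == "eigenspectrum") {
      es <- eigenspectrum(conn, "J")
      out_path <- file.path(run_dir, "eigenspectrum.csv")
      write.csv(data.frame(re = Re(es$values), im = Im(es$values)),
                out_path, row.names = FALSE)
      message(sprintf("%d outliers; spectrum written to %s",
                      es$n_outliers, out_path))
    } else {
      stop(sprintf("unknown analysis '%s'", what))
    }
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
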