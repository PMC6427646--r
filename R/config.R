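#' Default run configuration
#'
#' Nested list of every tunable the pipeline uses: `lif` (kernel time
#' constants, threshold, rest, voltage grid step), `train` (learning rate,
#' epochs, group size, rule variant, init scale, patience), `synth`
#' (generator settings), `experiment` (repetitions and split size) and
#' `master_seed`. A single master seed spawns all substreams (synthesis,
#' weight init, shuffling, splits) so one number reproduces a whole run.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    lif = list(tau = 0.2, tau_s = 0.05, theta = 1, v_rest = 0,
               grid_dt = 1e-3),
    train = list(lambda = 5e-3, max_epochs = 100, group_size = 5,
                 use_vr = TRUE, init_scale = 0.01, early_stop_patience = 10),
    synth = list(n_channels = 11, n_classes = 4, trials_per_class = 20,
                 duration = 5, base_rate = 5,
                 template_spikes_per_channel = 6, jitter_sd = 0.01,
                 rate_contrast = 0),
    experiment = list(n_reps = 100, train_per_class = 16),
    master_seed = 1
  ), class = "run_config")
}

merge_into <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      warning("unknown config key `", here, "` ignored", call. = FALSE)
      next
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_into(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  l <- cfg$lif
  if (!is.numeric(l$tau) || !is.numeric(l$tau_s) || l$tau_s <= 0 ||
      l$tau <= l$tau_s) {
    stop("invalid `lif.tau_s`: need tau > tau_s > 0", call. = FALSE)
  }
  if (l$grid_dt <= 0) stop("invalid `lif.grid_dt`: must be > 0", call. = FALSE)
  t <- cfg$train
  if (t$lambda <= 0) stop("invalid `train.lambda`: must be > 0", call. = FALSE)
  if (t$max_epochs < 1) {
    stop("invalid `train.max_epochs`: must be >= 1", call. = FALSE)
  }
  if (t$group_size < 1) {
    stop("invalid `train.group_size`: must be >= 1", call. = FALSE)
  }
  s <- cfg$synth
  ok <- tryCatch({do.call(synth_config, c(s, list(seed = 1))); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok)) {
    stop("invalid `synth`: ", conditionMessage(ok), call. = FALSE)
  }
  e <- cfg$experiment
  if (e$n_reps < 1) {
    stop("invalid `experiment.n_reps`: must be >= 1", call. = FALSE)
  }
  if (e$train_per_class < 1) {
    stop("invalid `experiment.train_per_class`: must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Load and save YAML run configurations
#'
#' Absent fields take the [default_run_config()] values; unknown keys raise a
#' warning naming the key path; invalid values are rejected with the
#' offending key path in the message. An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return `load_config()` a validated `run_config`; `save_config()` the path,
#'   invisibly.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  cfg <- merge_into(unclass(default_run_config()), user)
  cfg <- structure(cfg, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg A `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build component settings from a run configuration
#'
#' @param cfg A `run_config`.
#' @param seed Seed override for the generator (defaults to the master seed).
#' @return [lif_params()], [train_config()] or [synth_config()] respectively.
#' @export
config_lif <- function(cfg) {
  lif_params(cfg$lif$tau, cfg$lif$tau_s, cfg$lif$theta, cfg$lif$v_rest)
}

#' @rdname config_lif
#' @export
config_train <- function(cfg) {
  train_config(lambda = cfg$train$lambda, max_epochs = cfg$train$max_epochs,
               group_size = cfg$train$group_size, use_vr = cfg$train$use_vr,
               shuffle_seed = cfg$master_seed,
               init_scale = cfg$train$init_scale,
               early_stop_patience = cfg$train$early_stop_patience)
}

#' @rdname config_lif
#' @export
config_synth <- function(cfg, seed = cfg$master_seed) {
  do.call(synth_config, c(cfg$synth, list(seed = seed)))
}
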