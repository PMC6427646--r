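# master seed -> independent per-repetition substream seeds
rep_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

# stratified split: `train_per_class` trials of every class train, rest test
stratified_split <- function(trials, train_per_class) {
  by_class <- split(trials$trial_id, trials$label)
  if (any(lengths(by_class) < train_per_class + 1)) {
    stop("every class needs at least train_per_class + 1 trials",
         call. = FALSE)
  }
  train <- unlist(lapply(by_class, sample, size = train_per_class),
                  use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(trials$trial_id, train)))
}

# sample-group split: one trial per class forms a group; k random groups train
group_split <- function(trials, k) {
  by_class <- split(trials$trial_id, trials$label)
  if (any(lengths(by_class) < k + 1)) {
    stop("every class needs at least k + 1 trials", call. = FALSE)
  }
  train <- unlist(lapply(by_class, function(ids) sample(ids)[seq_len(k)]),
                  use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(trials$trial_id, train)))
}

accuracy_of <- function(fit, test_data) {
  pred <- predict_decoder(fit, test_data)
  truth <- trial_info(test_data)
  joined <- dplyr::left_join(pred, truth, by = "trial_id")
  mean(joined$.pred == joined$label)
}

run_one_rep <- function(data, spec, split, param_grid, cv_seed) {
  train_data <- filter_trials(data, split$train)
  test_data <- filter_trials(data, split$test)
  fit <- if (is.null(param_grid)) {
    fit_decoder(spec, train_data)
  } else {
    cv_select(train_data, spec, param_grid, seed = cv_seed)$model
  }
  accuracy_of(fit, test_data)
}

new_experiment_result <- function(df, spec, seed) {
  structure(df,
            mean_accuracy = mean(df$accuracy), sd_accuracy = stats::sd(df$accuracy),
            spec = spec, seed = seed,
            class = c("experiment_result", class(tibble::tibble())))
}

#' Repeated random-split evaluation
#'
#' The standard protocol for small trial-based recordings: in each of
#' `n_reps` repetitions, a seeded stratified split keeps `train_per_class`
#' trials of every class for training and the remainder for testing, a fresh
#' decoder is trained, and its test accuracy recorded. With the recorded
#' defaults (20 trials per class) this is the 16-train / 4-test random test
#' repeated 100 times. Splits depend only on `(seed, repetition)`, so
#' different decoders evaluated with the same seed see identical splits.
#'
#' @param data A labeled `spike_tbl`.
#' @param spec A [decoder_spec()].
#' @param n_reps Number of repetitions.
#' @param train_per_class Training trials per class in each split.
#' @param seed Master seed; spawns one substream per repetition.
#' @param param_grid Optional list of hyperparameter overrides (named lists);
#'   when given, [cv_select()] picks the best on each repetition's training
#'   set before refitting.
#' @return An `experiment_result` tibble (`rep`, `accuracy`, `n_test`) with
#'   attributes `mean_accuracy` and `sd_accuracy`; see
#'   [glance.experiment_result()].
#' @export
#' @examples
#' d <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 5,
#'                                      duration = 1, seed = 2))
#' r <- random_test_protocol(d, decoder_spec("mle", bin_size = 0.5),
#'                           n_reps = 3, train_per_class = 3, seed = 9)
#' glance(r)
random_test_protocol <- function(data, spec, n_reps = 100,
                                 train_per_class = 16, seed = 1,
                                 param_grid = NULL) {
  stopifnot(inherits(data, "spike_tbl"))
  trials <- trial_info(data)
  seeds <- rep_seeds(seed, n_reps)
  acc <- vapply(seq_len(n_reps), function(r) {
    withr::with_seed(seeds[r], {
      split <- stratified_split(trials, train_per_class)
      run_one_rep(data, spec, split, param_grid, cv_seed = seeds[r])
    })
  }, 0.0)
  n_test <- nrow(trials) - train_per_class * length(unique(trials$label))
  new_experiment_result(
    tibble::tibble(rep = seq_len(n_reps), accuracy = acc, n_test = n_test),
    spec, seed)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %d reps, mean accuracy %.3f (sd %.3f)>\n",
              nrow(x), attr(x, "mean_accuracy"), attr(x, "sd_accuracy")))
  NextMethod()
}

#' Summarize an evaluation run
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A one-row tibble: decoder method, repetitions, mean and sd of the
#'   per-repetition accuracies.
#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(method = attr(x, "spec")$method,
                 n_reps = nrow(x),
                 mean_accuracy = attr(x, "mean_accuracy"),
                 sd_accuracy = attr(x, "sd_accuracy"))
}

#' Hyperparameter selection by stratified holdout
#'
#' Holds out 20% of the training trials (stratified by class, at least one
#' per class), fits the decoder on the remaining 80% for every candidate in
#' `param_grid`, scores on the holdout, keeps the best candidate (ties go to
#' the earlier grid entry), and refits it on the full training set.
#'
#' @param train_data A labeled `spike_tbl`.
#' @param spec A [decoder_spec()].
#' @param param_grid Non-empty list of named lists of overrides, e.g.
#'   `list(list(tau = 0.1), list(tau = 0.5))`; names may address decoder,
#'   LIF, or training fields.
#' @param seed Seed for the holdout split.
#' @param holdout_frac Validation fraction (default 0.2).
#' @return A list: `best` (the winning overrides), `spec` (updated),
#'   `model` (refit on all of `train_data`), `scores` (per-candidate holdout
#'   accuracy tibble).
#' @export
cv_select <- function(train_data, spec, param_grid, seed = 1,
                      holdout_frac = 0.2) {
  if (!length(param_grid)) stop("`param_grid` is empty", call. = FALSE)
  trials <- trial_info(train_data)
  withr::with_seed(as.integer(seed), {
    by_class <- split(trials$trial_id, trials$label)
    val <- unlist(lapply(by_class, function(ids) {
      sample(ids, size = max(1L, round(holdout_frac * length(ids))))
    }), use.names = FALSE)
    fit_ids <- setdiff(trials$trial_id, val)
    fit_data <- filter_trials(train_data, fit_ids)
    val_data <- filter_trials(train_data, val)
    scores <- vapply(param_grid, function(ov) {
      cand <- update_spec(spec, ov)
      accuracy_of(fit_decoder(cand, fit_data), val_data)
    }, 0.0)
  })
  best_i <- which.max(scores)                 # first grid entry on ties
  best_spec <- update_spec(spec, param_grid[[best_i]])
  list(best = param_grid[[best_i]], spec = best_spec,
       model = fit_decoder(best_spec, train_data),
       scores = tibble::tibble(candidate = seq_along(scores),
                               accuracy = scores))
}

#' Sweep an experimental axis
#'
#' Reruns the repeated random-split evaluation along one axis:
#' * `bin_size` — bin width of a bin-based decoder (values must divide the
#'   observation window);
#' * `train_groups` — training-set size in sample groups, where one group is
#'   one randomly chosen trial from each class and the remaining trials are
#'   tested;
#' * `time_period` — both training and test trials truncated to the first
#'   `value` seconds (the quick-recognition setting).
#'
#' Per-repetition seeds depend only on the master seed, so
#' `time_period = trial_duration(data)` reproduces [random_test_protocol()]
#' exactly, and all axis values share splits.
#'
#' @inheritParams random_test_protocol
#' @param axis One of `"bin_size"`, `"train_groups"`, `"time_period"`.
#' @param values Numeric vector of axis values.
#' @return A `sweep_result` tibble: one row per (value, repetition) with the
#'   test accuracy; `tidy()` gives per-value means.
#' @export
run_sweep <- function(data, spec, axis = c("bin_size", "train_groups",
                                           "time_period"),
                      values, n_reps = 20, train_per_class = 16, seed = 1,
                      param_grid = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(data, "spike_tbl"), length(values) >= 1)
  trials <- trial_info(data)
  per_class <- min(table(trials$label))
  dur <- trial_duration(data)
  if (axis == "train_groups" &&
      any(values < 1 | values > per_class - 1)) {
    stop("train_groups values must be in 1 .. per-class count - 1",
         call. = FALSE)
  }
  if (axis == "time_period" && any(values <= 0 | values > dur)) {
    stop("time_period values must be in (0, duration]", call. = FALSE)
  }
  if (axis == "bin_size" && is_spiking(spec)) {
    stop("bin_size sweep applies to bin-based decoders", call. = FALSE)
  }
  seeds <- rep_seeds(seed, n_reps)
  rows <- lapply(values, function(v) {
    v_data <- if (axis == "time_period") truncate_trials(data, v) else data
    v_spec <- if (axis == "bin_size") update_spec(spec, list(bin_size = v))
              else spec
    acc <- vapply(seq_len(n_reps), function(r) {
      withr::with_seed(seeds[r], {
        split <- if (axis == "train_groups") {
          group_split(trials, as.integer(v))
        } else {
          stratified_split(trials, train_per_class)
        }
        run_one_rep(v_data, v_spec, split, param_grid, cv_seed = seeds[r])
      })
    }, 0.0)
    tibble::tibble(axis = axis, value = v, rep = seq_len(n_reps),
                   accuracy = acc)
  })
  structure(dplyr::bind_rows(rows),
            axis = axis, spec = spec, seed = seed,
            class = c("sweep_result", class(tibble::tibble())))
}

#' Per-value summary of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with one row per axis value: mean, sd and standard error
#'   of the repetition accuracies.
#' @export
tidy.sweep_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$axis,
                                   .data$value),
                   mean_accuracy = mean(.data$accuracy),
                   sd_accuracy = stats::sd(.data$accuracy),
                   se_accuracy = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
                   n_reps = dplyr::n(), .groups = "drop")
}
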