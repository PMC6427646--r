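#' Describe a decoder to be trained inside an evaluation protocol
#'
#' A decoder spec bundles a method name with its hyperparameters so the
#' evaluation protocols can train it fresh on every split. Spiking decoders:
#' `"tempotron"` (classic error-gated rule) and `"tempotron_vr"`
#' (voltage-regulated rule). Bin-based decoders operate on [bin_features()]:
#' `"dt"` (decision tree, rpart), `"knn"` (k-nearest neighbours),
#' `"lda"` (linear discriminant analysis), `"mle"` (diagonal Gaussian
#' maximum likelihood), `"svm_l"` / `"svm_r"` (linear / RBF support vector
#' machine).
#'
#' @param method One of the method names above.
#' @param bin_size Bin width for bin-based decoders, seconds.
#' @param period Observation window; defaults to the trial duration at fit
#'   time.
#' @param lif [lif_params()] for spiking decoders.
#' @param train [train_config()] for spiking decoders (`use_vr` is set from
#'   `method`).
#' @param grid_dt Voltage grid step for spiking decoders, seconds.
#' @param k Neighbours for `"knn"`.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses the e1071
#'   default `1/n_features`).
#' Two stub decoders exist for testing protocol plumbing: `"oracle"`
#' (always returns the true label) and `"uniform_random"` (picks uniformly
#' among the training classes).
#'
#' @return A list of class `decoder_spec`.
#' @export
decoder_spec <- function(method = c("tempotron", "tempotron_vr", "dt", "knn",
                                    "lda", "mle", "svm_l", "svm_r",
                                    "oracle", "uniform_random"),
                         bin_size = 0.5, period = NULL,
                         lif = lif_params(), train = train_config(),
                         grid_dt = 1e-3, k = 5, cost = 1, gamma = NULL) {
  method <- match.arg(method)
  structure(list(method = method, bin_size = bin_size, period = period,
                 lif = lif, train = train, grid_dt = grid_dt,
                 k = k, cost = cost, gamma = gamma),
            class = "decoder_spec")
}

# apply named overrides (e.g. from a CV grid) to a decoder_spec; nested
# fields of `lif` and `train` can be addressed directly by name
update_spec <- function(spec, overrides) {
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (nm %in% names(spec$train)) {
      spec$train[[nm]] <- val
    } else if (nm %in% c("tau", "tau_s", "theta", "v_rest")) {
      lp <- spec$lif
      lp[[nm]] <- val
      if (nm == "tau" && !("tau_s" %in% names(overrides))) {
        lp$tau_s <- val / 4
      }
      spec$lif <- lif_params(lp$tau, lp$tau_s, lp$theta, lp$v_rest)
    } else if (nm %in% names(spec)) {
      spec[[nm]] <- val
    } else {
      stop("unknown decoder parameter `", nm, "`", call. = FALSE)
    }
  }
  if (!inherits(spec$train, "train_config")) {
    spec$train <- do.call(train_config, spec$train[names(spec$train) %in%
                                                     names(formals(train_config))])
  }
  spec
}

is_spiking <- function(spec) spec$method %in% c("tempotron", "tempotron_vr")

#' Train a decoder described by a spec
#'
#' @param spec A [decoder_spec()].
#' @param data A labeled `spike_tbl` of training trials.
#' @return A `fitted_decoder` usable with [predict_decoder()].
#' @export
fit_decoder <- function(spec, data) {
  stopifnot(inherits(spec, "decoder_spec"), inherits(data, "spike_tbl"))
  if (spec$method %in% c("oracle", "uniform_random")) {
    return(structure(list(spec = spec,
                          model = list(classes = sort(unique(trial_info(data)$label)))),
                     class = "fitted_decoder"))
  }
  if (is_spiking(spec)) {
    cfg <- spec$train
    cfg$use_vr <- spec$method == "tempotron_vr"
    model <- train_tempotron(data, cfg, spec$lif, grid_dt = spec$grid_dt)
    return(structure(list(spec = spec, model = model), class = "fitted_decoder"))
  }
  period <- spec$period %||% trial_duration(data)
  feats <- bin_features(data, spec$bin_size, period)
  X <- feature_matrix(feats)
  y <- factor(feats$label)
  model <- switch(
    spec$method,
    dt = rpart::rpart(label ~ ., method = "class",
                      data = data.frame(label = y, X, check.names = FALSE),
                      control = rpart::rpart.control(minsplit = 4, xval = 0)),
    knn = list(X = X, y = y, k = spec$k),
    lda = {
      keep <- apply(X, 2, function(col) stats::sd(col) > 0)
      if (!any(keep)) {
        list(majority = names(which.max(table(y))))
      } else {
        list(fit = MASS::lda(X[, keep, drop = FALSE], grouping = y),
             keep = keep)
      }
    },
    mle = fit_gaussian_mle(feats),
    svm_l = e1071::svm(X, y, kernel = "linear", cost = spec$cost,
                       type = "C-classification", scale = FALSE),
    svm_r = e1071::svm(X, y, kernel = "radial", cost = spec$cost,
                       gamma = spec$gamma %||% (1 / ncol(X)),
                       type = "C-classification", scale = FALSE)
  )
  structure(list(spec = spec, model = model, period = period,
                 feature_names = colnames(X)),
            class = "fitted_decoder")
}

#' Predict with a fitted decoder
#'
#' @param fit A `fitted_decoder` from [fit_decoder()].
#' @param data A `spike_tbl` of trials to classify.
#' @return A tibble with `trial_id` and `.pred`.
#' @export
predict_decoder <- function(fit, data) {
  stopifnot(inherits(fit, "fitted_decoder"))
  spec <- fit$spec
  if (spec$method == "oracle") {
    tr <- trial_info(data)
    return(tibble::tibble(trial_id = tr$trial_id, .pred = tr$label))
  }
  if (spec$method == "uniform_random") {
    tr <- trial_info(data)
    return(tibble::tibble(trial_id = tr$trial_id,
                          .pred = sample(fit$model$classes, nrow(tr),
                                         replace = TRUE)))
  }
  if (is_spiking(spec)) {
    return(stats::predict(fit$model, data))
  }
  feats <- bin_features(data, spec$bin_size, fit$period)
  X <- feature_matrix(feats)[, fit$feature_names, drop = FALSE]
  pred <- switch(
    spec$method,
    dt = as.character(stats::predict(
      fit$model, data.frame(X, check.names = FALSE), type = "class")),
    knn = as.character(class::knn(fit$model$X, X, fit$model$y,
                                  k = min(fit$model$k, nrow(fit$model$X)))),
    lda = {
      if (!is.null(fit$model$majority)) {
        rep(fit$model$majority, nrow(X))
      } else {
        as.character(stats::predict(
          fit$model$fit, X[, fit$model$keep, drop = FALSE])$class)
      }
    },
    mle = stats::predict(fit$model, X),
    svm_l = as.character(stats::predict(fit$model, X)),
    svm_r = as.character(stats::predict(fit$model, X))
  )
  tibble::tibble(trial_id = feats$trial_id, .pred = pred)
}
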