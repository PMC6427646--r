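#' Binned spike-count features
#'
#' Divides the observation window `[0, period)` into `M = period / bin_size`
#' half-open bins per channel and counts spikes per bin. Channel vectors are
#' concatenated channel-major into one feature vector per trial, the standard
#' rate-based representation that conventional classifiers consume.
#'
#' @param data A `spike_tbl`.
#' @param bin_size Bin width in seconds; `period` must be an integer multiple
#'   of it.
#' @param period Observation window in seconds (default: the trial duration).
#' @return A tibble with `trial_id`, `label` and `n_channels * M` integer
#'   count columns named `c<channel>_b<bin>`, plus attributes `bin_size`,
#'   `period`, `M`, `n_channels`.
#' @export
#' @examples
#' d <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 2,
#'                                      duration = 5, seed = 3))
#' f <- bin_features(d, bin_size = 0.5)
#' attr(f, "M")  # 10 bins per channel
bin_features <- function(data, bin_size, period = trial_duration(data)) {
  stopifnot(inherits(data, "spike_tbl"))
  bin_size <- as.double(bin_size); period <- as.double(period)
  if (bin_size <= 0 || period <= 0) {
    stop("`bin_size` and `period` must be > 0", call. = FALSE)
  }
  if (period > trial_duration(data) + 1e-12) {
    stop("`period` exceeds trial duration", call. = FALSE)
  }
  M <- period / bin_size
  if (abs(M - round(M)) > 1e-9) {
    stop("`period` must be an integer multiple of `bin_size`", call. = FALSE)
  }
  M <- as.integer(round(M))
  nch <- n_channels(data)
  tr <- trial_info(data)

  ev <- tibble::as_tibble(data)
  ev <- ev[ev$time < period, , drop = FALSE]
  ev$bin <- pmin(floor(ev$time / bin_size), M - 1)  # guard float edge at period
  counts <- matrix(0L, nrow = nrow(tr), ncol = nch * M)
  if (nrow(ev)) {
    row_i <- match(ev$trial_id, tr$trial_id)
    col_i <- ev$channel * M + ev$bin + 1L             # channel-major layout
    tab <- table(factor(row_i, levels = seq_len(nrow(tr))),
                 factor(col_i, levels = seq_len(nch * M)))
    counts <- matrix(as.integer(tab), nrow = nrow(tr))
  }
  colnames(counts) <- paste0("c", rep(0:(nch - 1), each = M),
                             "_b", rep(seq_len(M), times = nch))
  out <- dplyr::bind_cols(tr, tibble::as_tibble(counts))
  attr(out, "bin_size") <- bin_size
  attr(out, "period") <- period
  attr(out, "M") <- M
  attr(out, "n_channels") <- nch
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), c("trial_id", "label")),
                     drop = FALSE])
}

#' Diagonal Gaussian maximum-likelihood classifier
#'
#' Fits an independent Gaussian per (class, feature) on binned spike counts
#' and classifies by the largest summed per-dimension log-likelihood.
#' Variances are floored at `var_floor` so constant features cannot produce
#' degenerate densities. A diagonal model is used because with few training
#' trials and `n_channels * M` features a full covariance is singular.
#'
#' @param features A feature tibble from [bin_features()] (columns `trial_id`,
#'   `label`, counts), or any data frame shaped that way.
#' @param var_floor Minimum per-feature variance.
#' @return An object of class `gaussian_mle`.
#' @export
fit_gaussian_mle <- function(features, var_floor = 1e-6) {
  y <- features$label
  if (any(is.na(y))) stop("all training trials must be labeled", call. = FALSE)
  X <- feature_matrix(features)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  n_k <- table(factor(y, levels = classes))
  if (any(n_k < 2)) {
    stop("every class needs at least 2 training samples", call. = FALSE)
  }
  mu <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(ncol(X))))
  sig2 <- t(vapply(classes, function(k) {
    pmax(apply(X[y == k, , drop = FALSE], 2, stats::var), var_floor)
  }, numeric(ncol(X))))
  structure(list(classes = classes, mu = mu, sig2 = sig2,
                 features = colnames(X), var_floor = var_floor),
            class = "gaussian_mle")
}

#' @rdname fit_gaussian_mle
#' @param object A fitted `gaussian_mle`.
#' @param newdata Feature tibble or matrix of the same feature set.
#' @param ... Unused.
#' @return `predict()` returns a character vector of class labels.
#' @export
predict.gaussian_mle <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  X <- X[, object$features, drop = FALSE]
  ll <- vapply(seq_along(object$classes), function(k) {
    mu <- object$mu[k, ]; s2 <- object$sig2[k, ]
    # summed log density of independent normals
    rowSums(-0.5 * (sweep(X, 2, mu)^2) / rep(s2, each = nrow(X)) -
              0.5 * log(2 * pi * rep(s2, each = nrow(X))))
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  object$classes[max.col(ll, ties.method = "first")]
}
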