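#' Training settings for the Tempotron network
#'
#' @param lambda Learning rate; the maximum weight change contributed by a
#'   single input spike per update.
#' @param max_epochs Maximum passes over the training set.
#' @param group_size Output neurons per class group.
#' @param use_vr Use the voltage-regulation rule (update every neuron on
#'   every presentation with the softplus voltage-share gradient) instead of
#'   the classic error-gated rule?
#' @param shuffle_seed Seed controlling weight initialization and the
#'   per-epoch presentation order; identical seeds give identical models.
#' @param init_scale Standard deviation of the Gaussian weight
#'   initialization. Small values keep all neurons below threshold at the
#'   start of training.
#' @param early_stop_patience Stop when the training accuracy has not
#'   improved for this many consecutive epochs.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda = 5e-3, max_epochs = 100, group_size = 5,
                         use_vr = FALSE, shuffle_seed = 1, init_scale = 0.01,
                         early_stop_patience = 10) {
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("`max_epochs` must be >= 1", call. = FALSE)
  if (group_size < 1) stop("`group_size` must be >= 1", call. = FALSE)
  structure(list(lambda = as.double(lambda),
                 max_epochs = as.integer(max_epochs),
                 group_size = as.integer(group_size),
                 use_vr = isTRUE(use_vr),
                 shuffle_seed = as.integer(shuffle_seed),
                 init_scale = as.double(init_scale),
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "train_config")
}

#' Classic Tempotron weight update magnitudes
#'
#' For each input channel, the update magnitude is the learning rate times
#' the summed kernel contribution of that channel's spikes arriving before
#' the voltage maximum: `lambda * sum_{t_i < t_max} K(t_max - t_i)`. The sign
#' is applied by the caller: positive when the target neuron missed its
#' spike, negative when a non-target neuron fired erroneously.
#'
#' @inheritParams membrane_voltage_at
#' @param t_max Time of the neuron's maximal voltage on this trial.
#' @param lambda Learning rate.
#' @return Numeric vector of per-channel update magnitudes.
#' @export
tempotron_delta <- function(trial, t_max, params, lambda) {
  tr <- as_one_trial(trial)
  vapply(tr$spikes, function(st) {
    if (!length(st)) return(0.0)
    lambda * sum(psp_kernel(t_max - st, params))
  }, 0.0)
}

# numerically safe softplus and logistic
softplus <- function(v) ifelse(v > 30, v, log1p(exp(pmin(v, 30))))

#' Voltage-regulation factor across output groups
#'
#' Transforms each group's maximal voltage with the softplus
#' `f(V) = log(exp(V) + 1)` and differentiates the log voltage share of the
#' target group, `log(f(V_target) / sum_m f(V_m))`. The derivative is
#' `f'(V) * (1/f(V) - 1/sum_m f(V_m))` for the target group (always
#' positive) and `f'(V) * (-1/sum_m f(V_m))` for every other group (always
#' negative), so scaling updates by it raises the target group's voltage
#' maxima while suppressing the others.
#'
#' @param v_max_by_group Numeric vector of maximal voltages, one per class
#'   group, for a fixed within-group neuron index.
#' @param target_group 1-based index of the group representing the trial's
#'   true class.
#' @return Numeric vector of factors, one per group.
#' @export
vr_factor <- function(v_max_by_group, target_group) {
  C <- length(v_max_by_group)
  if (C < 2) stop("need at least 2 groups", call. = FALSE)
  if (target_group < 1 || target_group > C) {
    stop("`target_group` out of range", call. = FALSE)
  }
  f <- softplus(v_max_by_group)
  fp <- stats::plogis(v_max_by_group)
  S <- sum(f)
  out <- fp * (-1 / S)
  out[target_group] <- fp[target_group] * (1 / f[target_group] - 1 / S)
  out
}

#' Voltage-regulated weight update
#'
#' The classic update magnitudes scaled by the regulation factor:
#' `lambda * sum_{t_i < t_max} K(t_max - t_i) * f_prime`. The factor carries
#' the sign, so target-group neurons are strengthened and all others
#' weakened on every presentation.
#'
#' @inheritParams tempotron_delta
#' @param f_prime Scalar factor from [vr_factor()] for this neuron's group.
#' @return Numeric vector of per-channel signed updates.
#' @export
vr_delta <- function(trial, t_max, params, lambda, f_prime) {
  tempotron_delta(trial, t_max, params, lambda) * f_prime
}

# cache the per-trial evaluation grid and per-channel PSP-sum matrices so
# that every neuron's voltage over the whole trial is one matrix product
precompute_psp <- function(trial_list, params, duration, grid_dt) {
  lapply(trial_list, function(tr) {
    grid <- voltage_grid(tr$spikes, duration, grid_dt)
    P <- psp_matrix(tr$spikes, grid, params)
    list(grid = grid, P = P, tP = t(P),
         label = tr$label, trial_id = tr$trial_id)
  })
}

# grid-based voltage maxima for all neurons at once; returns v_max vector,
# argmax column index vector (earliest on ties), and fired flags
network_vmax <- function(W, cache_entry, params) {
  V <- W %*% cache_entry$P                    # n_neurons x n_grid
  idx <- max.col(V, ties.method = "first")
  v_max <- V[cbind(seq_len(nrow(V)), idx)] + params$v_rest
  list(v_max = v_max, idx = idx, fired = v_max > params$theta)
}

# majority vote with ties broken by total group v_max, then lowest index
vote_from_vmax <- function(v_max, fired, n_classes, group_size) {
  grp <- rep(seq_len(n_classes), each = group_size)
  counts <- vapply(seq_len(n_classes), function(m) sum(fired[grp == m]), 0L)
  top <- which(counts == max(counts))
  if (length(top) > 1) {
    sums <- vapply(top, function(m) sum(v_max[grp == m]), 0.0)
    top <- top[sums == max(sums)]
  }
  top[1]
}

#' Train a Tempotron spike-train classifier
#'
#' Fits a two-layer spiking network: every input channel projects to
#' `n_classes * group_size` leaky integrate-and-fire output neurons, one
#' group of `group_size` neurons per class. In classic mode
#' (`use_vr = FALSE`) weights change only on errors: a silent target-group
#' neuron is strengthened, a firing non-target neuron is weakened, each by
#' the kernel-weighted spike contributions at its own voltage maximum. In
#' voltage-regulation mode (`use_vr = TRUE`) every neuron is updated on every
#' presentation, scaled by [vr_factor()] computed across the groups at that
#' neuron's within-group index. Trials are presented in a seeded shuffled
#' order each epoch; training stops at `max_epochs`, when classic training
#' reaches zero errors, or when accuracy stops improving for
#' `early_stop_patience` epochs. The weights with the best training accuracy
#' are returned.
#'
#' @param data A labeled `spike_tbl` with at least two classes.
#' @param config A [train_config()].
#' @param params A [lif_params()].
#' @param grid_dt Voltage evaluation grid step, seconds.
#' @param init_weights Optional initial weight matrix
#'   (`n_classes * group_size` rows, `n_channels` columns); defaults to a
#'   seeded Gaussian with sd `init_scale`.
#' @return A `tempotron_model`: weights, class labels, LIF parameters,
#'   per-epoch training-accuracy history.
#' @export
#' @examples
#' d <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 5,
#'                                      duration = 1, base_rate = 2, seed = 7))
#' m <- train_tempotron(d, train_config(max_epochs = 20, group_size = 2),
#'                      lif_params(tau = 0.1))
#' predict(m, d)
train_tempotron <- function(data, config = train_config(),
                            params = lif_params(), grid_dt = 1e-3,
                            init_weights = NULL) {
  stopifnot(inherits(data, "spike_tbl"))
  tr_info <- trial_info(data)
  if (nrow(tr_info) == 0) stop("empty dataset", call. = FALSE)
  if (any(is.na(tr_info$label))) stop("all trials must be labeled", call. = FALSE)
  classes <- class_labels(data)
  classes <- classes[classes %in% tr_info$label]
  if (length(classes) < 2) {
    stop("need at least 2 classes to train", call. = FALSE)
  }
  C <- length(classes); G <- config$group_size
  nch <- n_channels(data)
  n_neurons <- C * G

  trial_list <- as_trial_list(data)
  cache <- precompute_psp(trial_list, params, trial_duration(data), grid_dt)
  y <- match(tr_info$label, classes)
  n_trials <- length(cache)

  withr::with_seed(config$shuffle_seed, {
    W <- if (is.null(init_weights)) {
      matrix(stats::rnorm(n_neurons * nch, 0, config$init_scale),
             nrow = n_neurons, ncol = nch)
    } else {
      stopifnot(identical(dim(init_weights), c(n_neurons, nch)))
      init_weights
    }
    grp <- rep(seq_len(C), each = G)          # neuron row -> group
    history <- numeric(0)
    best_acc <- -Inf; best_W <- W; stall <- 0L
    epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample.int(n_trials)
      changed <- FALSE
      for (ti in order_idx) {
        ce <- cache[[ti]]
        nv <- network_vmax(W, ce, params)
        D <- ce$tP[nv$idx, , drop = FALSE]    # per-neuron kernel sums at t_max
        if (config$use_vr) {
          Vmat <- matrix(nv$v_max, nrow = C, ncol = G, byrow = TRUE)
          Fp <- matrix(0.0, nrow = C, ncol = G)
          for (n in seq_len(G)) Fp[, n] <- vr_factor(Vmat[, n], y[ti])
          fvec <- as.vector(t(Fp))            # group-major neuron order
          W <- W + config$lambda * D * fvec
          changed <- TRUE
        } else {
          sign <- ifelse(grp == y[ti], 1, -1)
          gate <- ifelse(grp == y[ti], !nv$fired, nv$fired)
          upd <- sign * as.numeric(gate)
          if (any(upd != 0)) {
            W <- W + config$lambda * D * upd
            changed <- TRUE
          }
        }
      }
      # training accuracy with the post-epoch weights
      pred <- vapply(cache, function(ce) {
        nv <- network_vmax(W, ce, params)
        vote_from_vmax(nv$v_max, nv$fired, C, G)
      }, 0L)
      acc <- mean(pred == y)
      history <- c(history, acc)
      epochs_run <- epoch
      if (acc > best_acc) {
        best_acc <- acc; best_W <- W; stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (!config$use_vr && !changed) break   # converged: zero errors all epoch
      if (stall >= config$early_stop_patience) break
    }
  })

  structure(list(weights = best_W, final_weights = W,
                 class_labels = classes, group_size = G,
                 n_channels = nch, params = params, config = config,
                 grid_dt = grid_dt, duration = trial_duration(data),
                 history = tibble::tibble(epoch = seq_along(history),
                                          accuracy = history),
                 epochs_run = epochs_run, train_accuracy = best_acc),
            class = "tempotron_model")
}

#' @export
print.tempotron_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<tempotron_model: %d classes x %d neurons/group, %d channels, %s rule>\n",
    "  epochs run: %d, best training accuracy: %.3f\n"),
    length(x$class_labels), x$group_size, x$n_channels,
    if (x$config$use_vr) "voltage-regulated" else "classic",
    x$epochs_run, x$train_accuracy))
  invisible(x)
}

#' Predict class labels for spike-train trials
#'
#' Each output neuron fires if its maximal voltage exceeds the threshold;
#' the predicted class is the group with the most firing neurons. Ties
#' (including the all-silent case) are broken by the largest summed maximal
#' voltage over the tied groups, then by the lowest class index.
#'
#' @param object A `tempotron_model`.
#' @param newdata A `spike_tbl` with matching channel count.
#' @param type `"class"` for labels only, `"votes"` to add per-group firing
#'   counts and summed maximal voltages.
#' @param ... Unused.
#' @return A tibble with `trial_id` and `.pred` (plus vote columns when
#'   `type = "votes"`).
#' @export
predict.tempotron_model <- function(object, newdata,
                                    type = c("class", "votes"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "spike_tbl"))
  if (n_channels(newdata) != object$n_channels) {
    stop("channel count of `newdata` does not match the model", call. = FALSE)
  }
  C <- length(object$class_labels); G <- object$group_size
  grp <- rep(seq_len(C), each = G)
  cache <- precompute_psp(as_trial_list(newdata), object$params,
                          trial_duration(newdata), object$grid_dt)
  rows <- lapply(cache, function(ce) {
    nv <- network_vmax(object$weights, ce, object$params)
    k <- vote_from_vmax(nv$v_max, nv$fired, C, G)
    out <- tibble::tibble(trial_id = ce$trial_id,
                          .pred = object$class_labels[k])
    if (type == "votes") {
      for (m in seq_len(C)) {
        out[[paste0("votes_", object$class_labels[m])]] <-
          sum(nv$fired[grp == m])
        out[[paste0("vsum_", object$class_labels[m])]] <-
          sum(nv$v_max[grp == m])
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Tidy a fitted Tempotron network
#'
#' @param x A `tempotron_model`.
#' @param ... Unused.
#' @return One row per synaptic weight: `class`, `neuron` (within-group
#'   index), `channel`, `weight`.
#' @export
tidy.tempotron_model <- function(x, ...) {
  C <- length(x$class_labels); G <- x$group_size
  tibble::tibble(
    class = rep(x$class_labels, each = G * x$n_channels),
    neuron = rep(rep(seq_len(G), each = x$n_channels), times = C),
    channel = rep(0:(x$n_channels - 1), times = C * G),
    weight = as.vector(t(x$weights)))
}

#' One-row summary of a fitted Tempotron network
#'
#' @param x A `tempotron_model`.
#' @param ... Unused.
#' @return A one-row tibble: rule, dimensions, epochs run, best training
#'   accuracy.
#' @export
glance.tempotron_model <- function(x, ...) {
  tibble::tibble(rule = if (x$config$use_vr) "tempotron_vr" else "tempotron",
                 n_classes = length(x$class_labels),
                 group_size = x$group_size,
                 n_channels = x$n_channels,
                 lambda = x$config$lambda,
                 epochs_run = x$epochs_run,
                 train_accuracy = x$train_accuracy)
}
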