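#' Leaky integrate-and-fire kernel parameters
#'
#' The postsynaptic potential (PSP) evoked by a single input spike is the
#' double-exponential kernel
#' `K(dt) = V0 * (exp(-dt / tau) - exp(-dt / tau_s))` for `dt >= 0`, where
#' `tau` is the membrane integration time constant, `tau_s` the synaptic
#' current time constant, and `V0` the normalizer that makes the kernel peak
#' equal 1. The peak occurs at
#' `t_peak = tau * tau_s / (tau - tau_s) * log(tau / tau_s)`.
#'
#' @param tau Membrane time constant, seconds.
#' @param tau_s Synaptic time constant, seconds; must satisfy
#'   `0 < tau_s < tau`. Defaults to `tau / 4`, the usual ratio in the
#'   Tempotron literature.
#' @param theta Firing threshold of the output neurons (dimensionless,
#'   default 1).
#' @param v_rest Resting potential (default 0).
#' @return A list of class `lif_params` with fields `tau`, `tau_s`, `theta`,
#'   `v_rest`, plus the derived `v0` and `t_peak`.
#' @export
#' @examples
#' p <- lif_params(tau = 0.1)
#' psp_kernel(p$t_peak, p)  # 1 by construction
lif_params <- function(tau = 0.2, tau_s = tau / 4, theta = 1, v_rest = 0) {
  tau <- as.double(tau); tau_s <- as.double(tau_s)
  if (!is.finite(tau) || !is.finite(tau_s) || tau_s <= 0 || tau <= tau_s) {
    stop("need tau > tau_s > 0", call. = FALSE)
  }
  t_peak <- tau * tau_s / (tau - tau_s) * log(tau / tau_s)
  structure(list(tau = tau, tau_s = tau_s, theta = as.double(theta),
                 v_rest = as.double(v_rest),
                 v0 = normalizer_v0(tau, tau_s), t_peak = t_peak),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "<lif_params: tau=%g s, tau_s=%g s, theta=%g, v_rest=%g, V0=%.6g>\n",
    x$tau, x$tau_s, x$theta, x$v_rest, x$v0))
  invisible(x)
}

#' PSP normalization constant
#'
#' Returns `V0` such that the kernel `V0 * (exp(-dt/tau) - exp(-dt/tau_s))`
#' has maximum exactly 1 over `dt >= 0`.
#'
#' @inheritParams lif_params
#' @return The scalar `V0 > 0`.
#' @export
normalizer_v0 <- function(tau, tau_s) {
  if (!is.finite(tau) || !is.finite(tau_s) || tau_s <= 0 || tau <= tau_s) {
    stop("need tau > tau_s > 0", call. = FALSE)
  }
  t_peak <- tau * tau_s / (tau - tau_s) * log(tau / tau_s)
  1 / (exp(-t_peak / tau) - exp(-t_peak / tau_s))
}

#' Evaluate the PSP kernel
#'
#' Causal: returns 0 for negative lags (an input spike cannot influence the
#' voltage before it arrives), and `V0*(exp(-dt/tau) - exp(-dt/tau_s))` for
#' `dt >= 0`. Vectorized over `dt`.
#'
#' @param dt Lag(s) `t - t_i` in seconds.
#' @param params A [lif_params()].
#' @return Kernel value(s), dimensionless, peaking at 1.
#' @export
psp_kernel <- function(dt, params) {
  out <- ifelse(dt > 0,
                params$v0 * (exp(-dt / params$tau) - exp(-dt / params$tau_s)),
                0)
  out[!is.finite(dt)] <- NA_real_
  out
}

#' Default time-constant grid for hyperparameter selection
#'
#' Candidate membrane time constants for [cv_select()], each with
#' `tau_s = tau / 4` (the customary ratio). Covers fast to slow integration
#' relative to multi-second trials.
#'
#' @return A list of override lists usable as a `param_grid`.
#' @export
default_tau_grid <- function() {
  lapply(c(0.05, 0.1, 0.2, 0.5, 1.0), function(t) list(tau = t))
}

# coerce a one-trial argument to the list(spikes=..., ...) view.
# Accepts a spike_tbl (must contain exactly one trial), a trial-list element,
# or a bare list of per-channel spike-time vectors.
as_one_trial <- function(trial, n_channels = NULL) {
  if (inherits(trial, "spike_tbl")) {
    tl <- as_trial_list(trial)
    if (length(tl) != 1L) {
      stop("expected a single trial, got ", length(tl), call. = FALSE)
    }
    tl[[1]]
  } else if (is.list(trial) && !is.null(trial$spikes)) {
    trial
  } else if (is.list(trial)) {
    list(trial_id = NA_integer_, label = NA_character_,
         spikes = lapply(trial, as.double))
  } else {
    stop("cannot interpret `trial`", call. = FALSE)
  }
}

#' Membrane voltage at a time point
#'
#' The voltage of an output neuron is a weighted sum of the PSPs of all input
#' spikes arriving strictly before `t`, plus the resting potential:
#' `V(t) = sum_i w_i * sum_{t_i < t} K(t - t_i) + v_rest`.
#'
#' @param trial A single trial: a one-trial `spike_tbl` or a list of
#'   per-channel spike-time vectors.
#' @param weights Numeric vector of synaptic weights, one per channel.
#' @param t Evaluation time(s), seconds; vectorized.
#' @param params A [lif_params()].
#' @return Voltage value(s).
#' @export
membrane_voltage_at <- function(trial, weights, t, params) {
  tr <- as_one_trial(trial)
  if (length(weights) != length(tr$spikes)) {
    stop("length(weights) must equal the number of channels", call. = FALSE)
  }
  all_t <- unlist(tr$spikes, use.names = FALSE)
  if (!length(all_t)) return(rep(params$v_rest, length(t)))
  w_per_spike <- rep(as.double(weights), times = lengths(tr$spikes))
  vapply(t, function(tt) {
    k <- psp_kernel(tt - all_t, params)       # K is 0 at and before the spike
    sum(w_per_spike * k) + params$v_rest
  }, 0.0)
}

# per-channel PSP sums on a grid of times: matrix [n_channels x n_grid]
# P[ch, g] = sum over that channel's spikes of K(grid[g] - t_i)
psp_matrix <- function(spikes, grid, params) {
  nch <- length(spikes)
  P <- matrix(0.0, nrow = nch, ncol = length(grid))
  for (ch in seq_len(nch)) {
    st <- spikes[[ch]]
    if (!length(st)) next
    dt <- outer(grid, st, "-")                # n_grid x n_spikes
    pos <- dt > 0
    k <- matrix(0.0, nrow = nrow(dt), ncol = ncol(dt))
    k[pos] <- params$v0 * (exp(-dt[pos] / params$tau) -
                             exp(-dt[pos] / params$tau_s))
    P[ch, ] <- rowSums(k)
  }
  P
}

# evaluation grid: uniform grid_dt steps over [0, duration] plus all spike
# arrival times (the voltage is piecewise smooth between arrivals)
voltage_grid <- function(spikes, duration, grid_dt) {
  sort(unique(c(seq(0, duration, by = grid_dt), duration,
                unlist(spikes, use.names = FALSE))))
}

#' Maximal membrane voltage over a trial
#'
#' Scans the voltage over a grid made of all spike arrival times plus a
#' uniform grid of step `grid_dt`, then (optionally) refines the best grid
#' point with a local golden-section search (tolerance 1e-6 s), since the
#' true maximum generally falls between grid points. Ties in the grid argmax
#' resolve to the earliest time.
#'
#' @inheritParams membrane_voltage_at
#' @param grid_dt Uniform grid step in seconds (default 1 ms).
#' @param duration Trial duration; taken from the `spike_tbl` when available.
#' @param refine Refine the grid maximum with [stats::optimize()]?
#' @return A one-row tibble: `v_max`, `t_max` (earliest argmax), `fired`
#'   (`v_max > theta`), `fire_time` (first grid time with voltage above
#'   threshold, `NA` if the neuron stays silent).
#' @export
max_voltage <- function(trial, weights, params, grid_dt = 1e-3,
                        duration = NULL, refine = TRUE) {
  if (inherits(trial, "spike_tbl") && is.null(duration)) {
    duration <- trial_duration(trial)
  }
  tr <- as_one_trial(trial)
  if (is.null(duration)) {
    duration <- max(c(unlist(tr$spikes, use.names = FALSE), 0)) + 10 * params$tau
  }
  if (length(weights) != length(tr$spikes)) {
    stop("length(weights) must equal the number of channels", call. = FALSE)
  }
  if (grid_dt <= 0) stop("`grid_dt` must be > 0", call. = FALSE)
  grid <- voltage_grid(tr$spikes, duration, grid_dt)
  P <- psp_matrix(tr$spikes, grid, params)
  v <- as.vector(crossprod(P, as.double(weights))) + params$v_rest
  i <- which.max(v)                            # earliest on exact ties
  v_max <- v[i]; t_max <- grid[i]
  if (refine && length(grid) > 1) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    if (hi > lo) {
      opt <- stats::optimize(function(tt) {
        membrane_voltage_at(tr, weights, tt, params)
      }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
      if (opt$objective > v_max) {
        v_max <- opt$objective
        t_max <- opt$maximum
      }
    }
  }
  fired <- v_max > params$theta
  fire_time <- if (any(v > params$theta)) grid[which(v > params$theta)[1]]
               else if (fired) t_max else NA_real_
  tibble::tibble(v_max = v_max, t_max = t_max, fired = fired,
                 fire_time = fire_time)
}
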