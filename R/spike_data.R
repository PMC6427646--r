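#' Build a spike-train dataset
#'
#' A spike dataset is an event-level tibble with one row per spike and columns
#' `trial_id` (integer), `channel` (integer, `0 .. n_channels - 1`), `time`
#' (seconds from stimulus onset) and `label` (character class label, `NA` for
#' unlabeled trials). Dataset-level metadata — the channel count, the common
#' trial duration, the ordered class labels and the per-trial label table —
#' is carried in attributes so that trials with zero spikes are not lost.
#'
#' @param events A data frame with columns `trial_id`, `channel`, `time` and
#'   optionally `label`.
#' @param n_channels Number of recording channels. Channels are indexed
#'   `0 .. n_channels - 1` as in the on-disk format.
#' @param duration Common trial duration in seconds; every spike time must lie
#'   in `[0, duration)`.
#' @param classes Ordered character vector of class labels. Defaults to the
#'   sorted unique labels present in `events`.
#' @param trials Optional data frame with columns `trial_id` and `label`
#'   declaring every trial (needed to represent trials without spikes).
#'   Defaults to the trials present in `events`.
#' @return A tibble of class `spike_tbl` with the metadata attributes
#'   `n_channels`, `duration`, `classes` and `trials`.
#' @seealso [generate_synthetic()], [read_spike_data()], [truncate_trials()]
#' @export
#' @examples
#' ev <- tibble::tibble(trial_id = 0L, channel = 0L, time = c(0.1, 0.2),
#'                      label = "a")
#' spike_data(ev, n_channels = 2, duration = 1)
spike_data <- function(events, n_channels, duration, classes = NULL,
                       trials = NULL) {
  stopifnot(is.data.frame(events))
  if (!all(c("trial_id", "channel", "time") %in% names(events))) {
    stop("`events` needs columns trial_id, channel, time", call. = FALSE)
  }
  if (!"label" %in% names(events)) events$label <- NA_character_
  events <- tibble::as_tibble(events)[, c("trial_id", "channel", "time", "label")]
  events$trial_id <- as.integer(events$trial_id)
  events$channel <- as.integer(events$channel)
  events$time <- as.double(events$time)
  events$label <- as.character(events$label)

  n_channels <- as.integer(n_channels)
  duration <- as.double(duration)
  if (n_channels < 1L) stop("`n_channels` must be >= 1", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be > 0", call. = FALSE)
  }

  if (is.null(trials)) {
    trials <- dplyr::distinct(events, .data$trial_id, .data$label)
  } else {
    trials <- tibble::as_tibble(trials)
    trials$trial_id <- as.integer(trials$trial_id)
    trials$label <- as.character(trials$label)
  }
  trials <- dplyr::arrange(trials[, c("trial_id", "label")], .data$trial_id)
  if (anyDuplicated(trials$trial_id)) {
    stop("conflicting labels within a trial", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- sort(unique(trials$label[!is.na(trials$label)]))
  }
  classes <- as.character(classes)

  bad <- which(events$channel < 0L | events$channel >= n_channels)
  if (length(bad)) stop("channel out of range in event ", bad[1], call. = FALSE)
  bad <- which(events$time < 0)
  if (length(bad)) stop("negative spike time in event ", bad[1], call. = FALSE)
  bad <- which(events$time >= duration)
  if (length(bad)) {
    stop("spike time >= duration in event ", bad[1], call. = FALSE)
  }
  lab <- trials$label
  if (any(!is.na(lab) & !(lab %in% classes))) {
    stop("trial label not in class list", call. = FALSE)
  }

  events <- dplyr::arrange(events, .data$trial_id, .data$channel, .data$time)
  dup <- duplicated(events[, c("trial_id", "channel", "time")])
  if (any(dup)) {
    stop("duplicated spike (trial, channel, time) in event ", which(dup)[1],
         call. = FALSE)
  }

  structure(events,
            n_channels = n_channels, duration = duration, classes = classes,
            trials = trials,
            class = c("spike_tbl", class(tibble::tibble())))
}

#' @export
print.spike_tbl <- function(x, ...) {
  cat(sprintf("<spike_tbl: %d trials, %d channels, %.3g s, classes: %s>\n",
              nrow(trial_info(x)), n_channels(x), trial_duration(x),
              paste(class_labels(x), collapse = ", ")))
  NextMethod()
}

#' Metadata accessors for spike datasets
#'
#' @param x A `spike_tbl`.
#' @return `n_channels()` the channel count; `trial_duration()` the common
#'   trial duration in seconds; `class_labels()` the ordered class labels;
#'   `trial_info()` a tibble with one row per trial (`trial_id`, `label`).
#' @export
n_channels <- function(x) attr(x, "n_channels")

#' @rdname n_channels
#' @export
trial_duration <- function(x) attr(x, "duration")

#' @rdname n_channels
#' @export
class_labels <- function(x) attr(x, "classes")

#' @rdname n_channels
#' @export
trial_info <- function(x) attr(x, "trials")

# rebuild a spike_tbl around a filtered copy of `events`, keeping metadata
restore_spike_meta <- function(events, template, duration = NULL,
                               trials = NULL) {
  spike_data(events,
             n_channels = n_channels(template),
             duration = duration %||% trial_duration(template),
             classes = class_labels(template),
             trials = trials %||% trial_info(template))
}

#' Keep a subset of trials
#'
#' Convenience filter that keeps the dataset metadata (including zero-spike
#' trials) intact.
#'
#' @param x A `spike_tbl`.
#' @param trial_ids Integer vector of trial ids to keep.
#' @return A `spike_tbl` containing only the requested trials.
#' @export
filter_trials <- function(x, trial_ids) {
  tr <- trial_info(x)
  keep <- tr[tr$trial_id %in% as.integer(trial_ids), , drop = FALSE]
  ev <- x[x$trial_id %in% keep$trial_id, , drop = FALSE]
  restore_spike_meta(tibble::as_tibble(ev), x, trials = keep)
}

#' Truncate every trial to a shorter observation window
#'
#' Retains only spikes with `time < period` and sets the dataset duration to
#' `period`, emulating a quick-recognition setting where the decoder sees only
#' the first fraction of a second of the response.
#'
#' @param x A `spike_tbl`.
#' @param period New duration in seconds; must satisfy
#'   `0 < period <= trial_duration(x)`.
#' @return A `spike_tbl` with duration `period`.
#' @export
truncate_trials <- function(x, period) {
  period <- as.double(period)
  if (!is.finite(period) || period <= 0) {
    stop("`period` must be > 0", call. = FALSE)
  }
  if (period > trial_duration(x)) {
    stop("`period` exceeds trial duration", call. = FALSE)
  }
  ev <- tibble::as_tibble(x)[x$time < period, , drop = FALSE]
  restore_spike_meta(ev, x, duration = period)
}

#' Synthetic-data generator settings
#'
#' Describes the synthetic multi-channel recordings the generator emulates:
#' a latency template per (class, channel) — a fixed set of preferred spike
#' times drawn once per class — jittered per trial, on top of homogeneous
#' Poisson background spiking. Defaults mirror a single-animal olfactory-bulb
#' session: 11 recorded units, 4 odors, 20 presentations per odor, 5-s
#' stimulation windows.
#'
#' @param n_channels Number of recording channels.
#' @param n_classes Number of stimulus classes.
#' @param trials_per_class Trials recorded per class.
#' @param duration Trial length, seconds.
#' @param base_rate Background Poisson rate per channel, Hz.
#' @param template_spikes_per_channel Spikes in each (class, channel) latency
#'   template.
#' @param jitter_sd Gaussian jitter applied to template spike times per trial,
#'   seconds.
#' @param rate_contrast Non-negative scaling of class-specific Poisson rates;
#'   class `c` (0-based) fires background spikes at
#'   `base_rate * (1 + rate_contrast * c)`. With `rate_contrast = 0` the
#'   expected spike count per channel is identical across classes, so classes
#'   differ only in spike timing.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 11, n_classes = 4, trials_per_class = 20,
                         duration = 5, base_rate = 5,
                         template_spikes_per_channel = 6, jitter_sd = 0.01,
                         rate_contrast = 0, seed = 1) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_classes = as.integer(n_classes),
              trials_per_class = as.integer(trials_per_class),
              duration = as.double(duration),
              base_rate = as.double(base_rate),
              template_spikes_per_channel = as.integer(template_spikes_per_channel),
              jitter_sd = as.double(jitter_sd),
              rate_contrast = as.double(rate_contrast),
              seed = as.integer(seed))
  if (cfg$n_channels < 1L || cfg$n_classes < 1L || cfg$trials_per_class < 1L ||
      cfg$template_spikes_per_channel < 1L) {
    stop("counts in synth_config must be >= 1", call. = FALSE)
  }
  if (cfg$duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (cfg$base_rate < 0) stop("`base_rate` must be >= 0", call. = FALSE)
  if (cfg$jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  if (cfg$rate_contrast < 0) stop("`rate_contrast` must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# enforce strictly increasing times by nudging exact ties up by 1 microsecond
make_strictly_increasing <- function(times, duration) {
  times <- sort(times)
  if (length(times) > 1) {
    for (i in seq_along(times)[-1]) {
      if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + 1e-6
    }
  }
  times[times < duration]
}

#' Generate a class-structured synthetic spike dataset
#'
#' Each class owns a fixed latency template per channel (spike times drawn
#' once from `Uniform(0, duration)`). Every trial of that class re-emits the
#' template with Gaussian timing jitter (clipped to the trial window), plus
#' homogeneous Poisson background spikes. With `rate_contrast = 0` all
#' classes have equal expected spike counts and are separable only through
#' spike timing; increasing `rate_contrast` adds firing-rate structure.
#'
#' @param config A [synth_config()].
#' @return A `spike_tbl` with `n_classes * trials_per_class` trials and class
#'   labels `"c1" ... "cK"`.
#' @export
#' @examples
#' d <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 3,
#'                                      duration = 1, seed = 42))
#' trial_info(d)
generate_synthetic <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  withr::with_seed(config$seed, {
    labels <- paste0("c", seq_len(config$n_classes))
    templates <- lapply(seq_len(config$n_classes), function(k) {
      matrix(stats::runif(config$n_channels * config$template_spikes_per_channel,
                          0, config$duration),
             nrow = config$n_channels)
    })
    rates <- config$base_rate * (1 + config$rate_contrast *
                                   (seq_len(config$n_classes) - 1))
    rows <- list()
    trial_id <- 0L
    trial_tab <- list()
    for (k in seq_len(config$n_classes)) {
      for (r in seq_len(config$trials_per_class)) {
        for (ch in seq_len(config$n_channels)) {
          tmpl <- templates[[k]][ch, ]
          jit <- tmpl + stats::rnorm(length(tmpl), 0, config$jitter_sd)
          jit <- pmin(pmax(jit, 0), config$duration - 1e-9)
          n_bg <- stats::rpois(1, rates[k] * config$duration)
          bg <- stats::runif(n_bg, 0, config$duration)
          tt <- make_strictly_increasing(c(jit, bg), config$duration)
          if (length(tt)) {
            rows[[length(rows) + 1L]] <-
              tibble::tibble(trial_id = trial_id, channel = ch - 1L,
                             time = tt, label = labels[k])
          }
        }
        trial_tab[[length(trial_tab) + 1L]] <-
          tibble::tibble(trial_id = trial_id, label = labels[k])
        trial_id <- trial_id + 1L
      }
    }
    spike_data(dplyr::bind_rows(rows),
               n_channels = config$n_channels, duration = config$duration,
               classes = labels, trials = dplyr::bind_rows(trial_tab))
  })
}

#' Write / read the spike-event text format
#'
#' The format is a plain CSV preceded by `#`-prefixed header lines:
#' `#channels=N`, `#duration=T`, `#classes=a,b,...`, then one
#' `#trial=<id>,label=<label>` line per trial (so spike-less trials survive a
#' round trip), a column-header row, and one
#' `trial_id,channel_id,spike_time_s,label` row per spike with times printed
#' to 12 significant digits. `read_spike_data()` validates sortedness,
#' nonnegative times and label membership, and reports the offending row
#' number on failure.
#'
#' @param x A `spike_tbl`.
#' @param path File path.
#' @return `write_spike_data()` returns `path` invisibly; `read_spike_data()`
#'   returns a `spike_tbl`.
#' @export
write_spike_data <- function(x, path) {
  stopifnot(inherits(x, "spike_tbl"))
  tr <- trial_info(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#channels=%d", n_channels(x)),
               sprintf("#duration=%.12g", trial_duration(x)),
               paste0("#classes=", paste(class_labels(x), collapse = ","))),
             con)
  writeLines(sprintf("#trial=%d,label=%s", tr$trial_id,
                     ifelse(is.na(tr$label), "", tr$label)), con)
  writeLines("trial_id,channel_id,spike_time_s,label", con)
  if (nrow(x)) {
    writeLines(sprintf("%d,%d,%.12g,%s", x$trial_id, x$channel, x$time,
                       ifelse(is.na(x$label), "", x$label)), con)
  }
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  get1 <- function(key) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(m)) stop("missing header #", key, call. = FALSE)
    sub(paste0("^#", key, "="), "", m[1])
  }
  nch <- as.integer(get1("channels"))
  dur <- as.double(get1("duration"))
  cls_raw <- get1("classes")
  classes <- if (nzchar(cls_raw)) strsplit(cls_raw, ",")[[1]] else character()

  tr_lines <- grep("^#trial=", meta, value = TRUE)
  trials <- NULL
  if (length(tr_lines)) {
    mm <- regmatches(tr_lines,
                     regexec("^#trial=([0-9]+),label=(.*)$", tr_lines))
    trials <- tibble::tibble(
      trial_id = as.integer(vapply(mm, `[`, "", 2)),
      label = vapply(mm, `[`, "", 3))
    trials$label[!nzchar(trials$label)] <- NA_character_
  }

  body <- lines[!hdr]
  body_rows <- which(!hdr)             # original line numbers for diagnostics
  if (length(body) && grepl("^trial_id", body[1])) {
    body <- body[-1]
    body_rows <- body_rows[-1]
  }
  body_rows <- body_rows[nzchar(body)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 3)) {
      stop("malformed row at line ", body_rows[which(nfield < 3)[1]],
           call. = FALSE)
    }
    ev <- tibble::tibble(
      trial_id = as.integer(vapply(parts, `[`, "", 1)),
      channel = as.integer(vapply(parts, `[`, "", 2)),
      time = as.double(vapply(parts, `[`, "", 3)),
      label = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""))
    ev$label[!nzchar(ev$label)] <- NA_character_
    bad <- which(is.na(ev$trial_id) | is.na(ev$channel) | is.na(ev$time))
    if (length(bad)) {
      stop("malformed row at line ", body_rows[bad[1]], call. = FALSE)
    }
    bad <- which(ev$time < 0)
    if (length(bad)) {
      stop("negative spike time at line ", body_rows[bad[1]], call. = FALSE)
    }
    bad <- which(!is.na(ev$label) & !(ev$label %in% classes))
    if (length(bad)) {
      stop("label not in header class list at line ", body_rows[bad[1]],
           call. = FALSE)
    }
    # per (trial, channel), file order must be strictly ascending in time
    key <- paste(ev$trial_id, ev$channel)
    same <- key[-1] == key[-length(key)]
    viol <- which(same & diff(ev$time) <= 0)
    if (length(viol)) {
      stop("unsorted or duplicated spike times at line ",
           body_rows[viol[1] + 1], call. = FALSE)
    }
    # a channel's rows must be contiguous within a trial (no duplicated block)
    blocks <- rle(key)$values
    if (anyDuplicated(blocks)) {
      stop("duplicated channel block within a trial", call. = FALSE)
    }
  } else {
    ev <- tibble::tibble(trial_id = integer(), channel = integer(),
                         time = double(), label = character())
  }
  spike_data(ev, n_channels = nch, duration = dur, classes = classes,
             trials = trials)
}

# list-of-trials view used by the numeric core: per trial, a list of
# n_channels spike-time vectors (1-based channel index = channel + 1)
as_trial_list <- function(x) {
  tr <- trial_info(x)
  nch <- n_channels(x)
  by_trial <- split(tibble::as_tibble(x)[, c("channel", "time")],
                    factor(x$trial_id, levels = tr$trial_id))
  lapply(seq_len(nrow(tr)), function(i) {
    df <- by_trial[[i]]
    spikes <- split(df$time, factor(df$channel, levels = 0:(nch - 1)))
    spikes <- lapply(spikes, as.double)
    list(trial_id = tr$trial_id[i], label = tr$label[i], spikes = spikes)
  })
}
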