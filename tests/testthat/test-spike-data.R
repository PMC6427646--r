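test_that("file round trip reproduces datasets exactly", {
  # empty dataset: header-only file
  empty <- spike_data(tibble::tibble(trial_id = integer(), channel = integer(),
                                     time = double(), label = character()),
                      n_channels = 11, duration = 5, classes = character())
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_data(empty, f)
  back <- read_spike_data(f)
  expect_equal(nrow(back), 0)
  expect_equal(n_channels(back), 11)
  expect_equal(trial_duration(back), 5)

  # minimal one-trial dataset
  one <- make_trial(list(c(0.1, 0.2)), duration = 1)
  write_spike_data(one, f)
  back <- read_spike_data(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(one))

  # a full synthetic dataset, field by field (times at full precision)
  d <- generate_synthetic(synth_config(seed = 3))
  write_spike_data(d, f)
  back <- read_spike_data(f)
  expect_identical(back$trial_id, d$trial_id)
  expect_identical(back$channel, d$channel)
  expect_identical(back$label, d$label)
  expect_equal(back$time, d$time, tolerance = 1e-11)
  expect_equal(trial_info(back), trial_info(d))
  expect_equal(class_labels(back), class_labels(d))
})

test_that("zero-spike trials survive a round trip", {
  d <- spike_data(tibble::tibble(trial_id = 0L, channel = 0L, time = 0.5,
                                 label = "a"),
                  n_channels = 2, duration = 1, classes = c("a", "b"),
                  trials = tibble::tibble(trial_id = 0:1,
                                          label = c("a", "b")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_data(d, f)
  back <- read_spike_data(f)
  expect_equal(trial_info(back), trial_info(d))
})

test_that("malformed files are rejected with a row number", {
  f <- withr::local_tempfile(fileext = ".csv")
  base <- c("#channels=2", "#duration=1", "#classes=a",
            "trial_id,channel_id,spike_time_s,label")
  writeLines(c(base, "0,0,0.5,a", "0,0,0.2,a"), f)
  expect_error(read_spike_data(f), "unsorted.*line 6")
  writeLines(c(base, "0,0,-0.1,a"), f)
  expect_error(read_spike_data(f), "negative.*line 5")
  writeLines(c(base, "0,0,0.5,zzz"), f)
  expect_error(read_spike_data(f), "class list.*line 5")
  writeLines(c(base, "0,0,0.1,a", "0,1,0.1,a", "0,0,0.3,a"), f)
  expect_error(read_spike_data(f), "duplicated channel")
  writeLines(c(base, "0,0"), f)
  expect_error(read_spike_data(f), "malformed.*line 5")
})

test_that("constructor enforces the spike-train invariants", {
  ev <- tibble::tibble(trial_id = 0L, channel = 0L, time = 1.5, label = "a")
  expect_error(spike_data(ev, 1, 1), ">= duration")
  ev$time <- -0.1
  expect_error(spike_data(ev, 1, 1), "negative")
  ev$time <- 0.5; ev$channel <- 3L
  expect_error(spike_data(ev, 2, 1), "out of range")
})

test_that("truncation keeps exactly the spikes before the cut", {
  tr <- make_trial(list(c(0.05, 0.4, 0.9)), duration = 1)
  out <- truncate_trials(tr, 0.5)
  expect_equal(out$time, c(0.05, 0.4))
  expect_equal(trial_duration(out), 0.5)
  expect_equal(trial_info(out)$label, "a")

  # period = duration is the identity
  same <- truncate_trials(tr, 1)
  expect_equal(tibble::as_tibble(same), tibble::as_tibble(tr))

  # linear-scan oracle on a random trial
  withr::with_seed(42, {
    spikes <- random_spike_list(5, 2, rate = 20)
    trial <- make_trial(spikes, duration = 2)
    for (period in c(0.3, 1.1, 1.9)) {
      kept <- truncate_trials(trial, period)
      expect_equal(nrow(kept), sum(unlist(spikes) < period))
    }
  })

  expect_error(truncate_trials(tr, 0), "> 0")
  expect_error(truncate_trials(tr, 2), "exceeds")
})

test_that("generator is seed-deterministic and seed-sensitive", {
  cfg <- synth_config(n_classes = 2, trials_per_class = 3, duration = 1,
                      seed = 1)
  d1 <- generate_synthetic(cfg)
  d2 <- generate_synthetic(cfg)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  d3 <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 3,
                                        duration = 1, seed = 2))
  expect_false(identical(d1$time, d3$time))
})

test_that("jitter-free, background-free trials repeat the class template", {
  d <- generate_synthetic(synth_config(n_classes = 2, trials_per_class = 4,
                                       duration = 1, base_rate = 0,
                                       jitter_sd = 0, seed = 8))
  by_trial <- split(tibble::as_tibble(d)[c("channel", "time")],
                    paste(d$label, d$trial_id))
  for (lab in c("c1", "c2")) {
    trials <- by_trial[grepl(paste0("^", lab, " "), names(by_trial))]
    for (t in trials[-1]) expect_equal(t, trials[[1]], ignore_attr = TRUE)
  }
})

test_that("with zero rate contrast, per-channel counts match across classes", {
  # Poisson background + fixed-size template implies equal expected counts
  d <- generate_synthetic(synth_config(n_classes = 4, trials_per_class = 500,
                                       duration = 1, base_rate = 5,
                                       template_spikes_per_channel = 4,
                                       jitter_sd = 0.01, rate_contrast = 0,
                                       seed = 77))
  tr <- trial_info(d)
  tot <- dplyr::count(tibble::as_tibble(d), .data$trial_id)
  tot <- dplyr::left_join(tot, tr, by = "trial_id")
  s <- dplyr::summarise(dplyr::group_by(tot, .data$label),
                        m = mean(.data$n) / 11,
                        se = stats::sd(.data$n) / sqrt(dplyr::n()) / 11,
                        .groups = "drop")
  # all class means agree pairwise and match the theoretical expectation
  # of template_spikes + base_rate * duration = 4 + 5 spikes per channel
  expect_lt(max(s$m) - min(s$m), 3 * sqrt(2) * max(s$se))
  expect_true(all(abs(s$m - 9) < 3 * s$se))
})

test_that("invalid generator settings are rejected", {
  expect_error(synth_config(jitter_sd = -1), ">= 0")
  expect_error(synth_config(base_rate = -1), ">= 0")
  expect_error(synth_config(n_channels = 0), ">= 1")
  expect_error(synth_config(duration = 0), "> 0")
})

test_that("spike times are strictly increasing within every channel", {
  d <- generate_synthetic(synth_config(n_classes = 3, trials_per_class = 5,
                                       duration = 0.5, base_rate = 40,
                                       jitter_sd = 0.2, seed = 4))
  bad <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(d), .data$trial_id, .data$channel),
    ok = all(diff(.data$time) > 0) || dplyr::n() == 1, .groups = "drop")
  expect_true(all(bad$ok))
  expect_true(all(d$time >= 0 & d$time < 0.5))
})
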