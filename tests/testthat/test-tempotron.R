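test_that("classic update magnitudes follow the kernel sums before t_max", {
  p <- lif_params(0.1, 0.025)
  lam <- 0.01
  # single spike exactly one kernel peak before t_max contributes lambda * 1
  tr <- list(c(0.5 - p$t_peak), numeric(0))
  d <- tempotron_delta(tr, 0.5, p, lam)
  expect_equal(d[1], lam, tolerance = 1e-9)
  expect_equal(d[2], 0)
  # spikes at or after t_max contribute nothing
  late <- list(c(0.5, 0.7), c(0.5 - 1e-9))
  d <- tempotron_delta(late, 0.5, p, lam)
  expect_equal(d[1], 0)
  expect_gt(d[2], 0)
  # three-spike loop oracle
  st <- c(0.1, 0.22, 0.31)
  d <- tempotron_delta(list(st), 0.4, p, lam)
  manual <- lam * sum(vapply(st, function(ti) psp_kernel(0.4 - ti, p), 0.0))
  expect_equal(d[1], manual, tolerance = 1e-12)
})

test_that("regulation factor has the documented closed form and signs", {
  # equal voltages, C = 2, V = 0: target factor is 1 / (4 log 2)
  f <- vr_factor(c(0, 0), target_group = 1)
  expect_equal(f[1], 1 / (4 * log(2)), tolerance = 1e-12)
  expect_equal(f[2], -0.5 / (2 * log(2)), tolerance = 1e-12)
  # equal voltages, general C: target factor f'(V) (C-1) / (C f(V))
  for (C in c(2, 4, 6)) {
    V <- 0.7
    f <- vr_factor(rep(V, C), target_group = 2)
    fp <- stats::plogis(V); fv <- log1p(exp(V))
    expect_equal(f[2], fp * (C - 1) / (C * fv), tolerance = 1e-12)
  }
  # signs hold for arbitrary finite voltages
  withr::with_seed(5, {
    for (i in 1:200) {
      C <- sample(2:6, 1)
      v <- stats::rnorm(C, 0, 3)
      tg <- sample(C, 1)
      f <- vr_factor(v, tg)
      expect_gt(f[tg], 0)
      expect_true(all(f[-tg] < 0))
    }
  })
  expect_error(vr_factor(1, 1), "at least 2")
})

test_that("regulated update is the classic update times the factor", {
  p <- lif_params(0.2, 0.05)
  withr::with_seed(9, {
    for (i in 1:10) {
      spikes <- random_spike_list(6, 1, rate = 10)
      t_max <- stats::runif(1, 0.2, 1)
      fp <- stats::rnorm(1)
      expect_equal(vr_delta(spikes, t_max, p, 0.01, fp),
                   tempotron_delta(spikes, t_max, p, 0.01) * fp,
                   tolerance = 1e-12)
    }
  })
  spikes <- list(c(0.1, 0.3))
  expect_equal(vr_delta(spikes, 0.5, lif_params(0.1), 0.01, 0), c(0))
  expect_equal(vr_delta(spikes, 0.5, lif_params(0.1), 0.01, 1),
               tempotron_delta(spikes, 0.5, lif_params(0.1), 0.01))
})

test_that("training is deterministic and rejects degenerate datasets", {
  d <- latency_two_class(trials_per_class = 4)
  cfg <- train_config(max_epochs = 5, group_size = 2, shuffle_seed = 3)
  p <- lif_params(0.2)
  m1 <- train_tempotron(d, cfg, p)
  m2 <- train_tempotron(d, cfg, p)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)

  vr1 <- train_tempotron(d, train_config(max_epochs = 5, group_size = 2,
                                         use_vr = TRUE, shuffle_seed = 3), p)
  expect_false(identical(m1$weights, vr1$weights))

  single <- filter_trials(d, trial_info(d)$trial_id[trial_info(d)$label == "c1"])
  expect_error(train_tempotron(single, cfg, p), "2 classes")
  expect_error(train_tempotron(filter_trials(d, integer()), cfg, p), "empty")
})

test_that("an epoch with zero errors changes no weights", {
  # class c1 spikes on channels 0-4, class c2 on channels 5-9; weights are
  # hand-set so every target neuron fires and every non-target stays silent
  rows <- list()
  tid <- 0L
  for (k in 1:2) {
    chans <- if (k == 1) 0:4 else 5:9
    for (r in 1:3) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial_id = tid,
        channel = rep(chans, each = 3),
        time = rep(c(0.1, 0.3, 0.5), times = 5),
        label = paste0("c", k))
      tid <- tid + 1L
    }
  }
  d <- spike_data(dplyr::bind_rows(rows), n_channels = 10, duration = 1,
                  classes = c("c1", "c2"))
  G <- 2
  W <- rbind(matrix(rep(c(rep(3, 5), rep(0, 5)), G), nrow = G, byrow = TRUE),
             matrix(rep(c(rep(0, 5), rep(3, 5)), G), nrow = G, byrow = TRUE))
  p <- lif_params(0.2)
  m <- train_tempotron(d, train_config(max_epochs = 3, group_size = G),
                       p, init_weights = W)
  expect_identical(m$weights, W)
  expect_equal(m$train_accuracy, 1)
  # sanity: the same data with small silent initial weights does update
  W0 <- matrix(0.01, nrow = 2 * G, ncol = 10)
  m2 <- train_tempotron(d, train_config(max_epochs = 3, group_size = G),
                        p, init_weights = W0)
  expect_false(identical(m2$final_weights, W0))
})

test_that("voltage regulation raises target and suppresses other groups", {
  p <- lif_params(0.2, 0.05)
  withr::with_seed(17, {
    for (i in 1:5) {
      spikes <- random_spike_list(6, 1, rate = 12)
      W <- matrix(stats::rnorm(2 * 6, 0, 0.3), nrow = 2)   # C = 2, G = 1
      mv <- lapply(1:2, function(j) {
        max_voltage(spikes, W[j, ], p, duration = 1, refine = FALSE)
      })
      v0 <- vapply(mv, function(m) m$v_max, 0.0)
      f <- vr_factor(v0, target_group = 1)
      for (j in 1:2) {
        W[j, ] <- W[j, ] + vr_delta(spikes, mv[[j]]$t_max, p, 0.01, f[j])
      }
      v1 <- vapply(1:2, function(j) {
        max_voltage(spikes, W[j, ], p, duration = 1, refine = FALSE)$v_max
      }, 0.0)
      expect_gte(v1[1], v0[1] - 1e-12)
      expect_lte(v1[2], v0[2] + 1e-12)
    }
  })
})

test_that("majority voting breaks ties by voltage sum, then class index", {
  vote <- spiketempo:::vote_from_vmax
  # clear majority
  expect_equal(vote(v_max = rep(2, 8), fired = c(rep(TRUE, 3), TRUE,
                                                 rep(FALSE, 4)),
                    n_classes = 2, group_size = 4), 1)
  # counts (2, 2): tie broken by summed v_max
  vm <- c(0.7, 0.7, 0.95, 0.95)
  expect_equal(vote(vm, fired = c(TRUE, TRUE, TRUE, TRUE),
                    n_classes = 2, group_size = 2), 2)
  # all silent: group with the larger voltage sum wins
  expect_equal(vote(c(0.1, 0.2, 0.4, 0.3), fired = rep(FALSE, 4),
                    n_classes = 2, group_size = 2), 2)
  # full tie falls back to the lowest class index
  expect_equal(vote(rep(0.5, 4), fired = rep(FALSE, 4),
                    n_classes = 2, group_size = 2), 1)
})

test_that("prediction validates channel counts and returns votes", {
  d <- latency_two_class(trials_per_class = 3)
  m <- train_tempotron(d, train_config(max_epochs = 10, group_size = 2),
                       lif_params(0.2))
  v <- predict(m, d, type = "votes")
  expect_true(all(c("votes_c1", "votes_c2", "vsum_c1", "vsum_c2") %in%
                    names(v)))
  other <- generate_synthetic(synth_config(n_channels = 5, n_classes = 2,
                                           trials_per_class = 2,
                                           duration = 1, seed = 1))
  expect_error(predict(m, other), "channel count")
})

test_that("tidy and glance expose the fitted network", {
  d <- latency_two_class(trials_per_class = 3)
  m <- train_tempotron(d, train_config(max_epochs = 5, group_size = 2),
                       lif_params(0.2))
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 2 * 11)
  expect_equal(unique(td$class), c("c1", "c2"))
  expect_equal(td$weight[td$class == "c1" & td$neuron == 1],
               unname(m$weights[1, ]))
  g <- glance(m)
  expect_equal(g$rule, "tempotron")
  expect_equal(g$n_classes, 2)
  expect_true(g$train_accuracy >= 0 && g$train_accuracy <= 1)
})
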