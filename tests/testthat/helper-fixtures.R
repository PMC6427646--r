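# build a one-trial spike_tbl from a list of per-channel spike-time vectors
make_trial <- function(spikes, duration = 1, label = "a",
                       classes = label, trial_id = 0L) {
  rows <- lapply(seq_along(spikes), function(ch) {
    tt <- spikes[[ch]]
    if (!length(tt)) return(NULL)
    tibble::tibble(trial_id = trial_id, channel = ch - 1L, time = tt,
                   label = label)
  })
  spike_data(dplyr::bind_rows(rows), n_channels = length(spikes),
             duration = duration, classes = classes,
             trials = tibble::tibble(trial_id = trial_id, label = label))
}

# random trial as a bare per-channel spike list
random_spike_list <- function(n_channels, duration, rate = 10) {
  lapply(seq_len(n_channels), function(ch) {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
}

# two perfectly latency-coded classes: every trial of a class repeats the
# class's fixed latency template exactly (no jitter, no background spikes)
latency_two_class <- function(trials_per_class = 10, n_channels = 11,
                              duration = 2) {
  generate_synthetic(synth_config(
    n_channels = n_channels, n_classes = 2,
    trials_per_class = trials_per_class, duration = duration,
    base_rate = 0, template_spikes_per_channel = 5, jitter_sd = 0,
    rate_contrast = 0, seed = 101))
}

# jittered timing-coded multi-class data used by the heavier tests
timing_coded_data <- function(n_classes = 4, trials_per_class = 10,
                              duration = 2, seed = 11) {
  generate_synthetic(synth_config(
    n_channels = 11, n_classes = n_classes,
    trials_per_class = trials_per_class, duration = duration,
    base_rate = 5, template_spikes_per_channel = 6, jitter_sd = 0.01,
    rate_contrast = 0, seed = seed))
}

# quick settings for spiking decoders in protocol tests
fast_tempotron_spec <- function(use_vr = FALSE, max_epochs = 25,
                                group_size = 3, tau = 0.2) {
  decoder_spec(if (use_vr) "tempotron_vr" else "tempotron",
               lif = lif_params(tau = tau),
               train = train_config(max_epochs = max_epochs,
                                    group_size = group_size,
                                    early_stop_patience = 5),
               grid_dt = 2e-3)
}

binomial_band <- function(p, n, sigma = 3) sigma * sqrt(p * (1 - p) / n)
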