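# Small programmatic fixtures shared across test files.

# tiny deterministic epoch set
tiny_epochs <- function(n_trials = 4, n_channels = 2, n_samples = 10,
                        srate = 100, t0_ms = -20, seed = 1,
                        labels = NULL) {
  if (is.null(labels)) labels <- rep(c(1L, -1L), length.out = n_trials)
  dat <- with_test_seed(seed,
    array(rnorm(n_trials * n_channels * n_samples),
          c(n_trials, n_channels, n_samples)))
  epoch_set(dat, labels = labels, srate = srate, t0_ms = t0_ms,
            channel_names = paste0("CH", seq_len(n_channels)))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# epochs holding one deterministic waveform per trial/channel
waveform_epochs <- function(wave_fun, n_trials = 1, channel_names = "CZ",
                            srate = 200, t0_ms = -500, n_samples = 600,
                            labels = rep(1L, n_trials)) {
  tms <- t0_ms + 1000 * (seq_len(n_samples) - 1) / srate
  dat <- array(0, c(n_trials, length(channel_names), n_samples))
  for (tr in seq_len(n_trials))
    for (ch in seq_along(channel_names))
      dat[tr, ch, ] <- wave_fun(tms / 1000)  # seconds
  epoch_set(dat, labels = labels, srate = srate, t0_ms = t0_ms,
            channel_names = channel_names)
}

# small but realistic simulated subject for classifier tests
quick_cfg <- function(..., seed = 101)
  sim_config(n_trials_per_class = 20, seed = seed, ...)

window_indices_for_test <- function(x, start = -100, end = 0) {
  which(epoch_times(x) >= start - 1e-6 & epoch_times(x) < end - 1e-6)
}

# envelope-free amplitude of a sinusoidal probe, central portion only
probe_amp <- function(x, guard_s = 0.1) {
  n <- length(x)
  g <- ceiling(guard_s * 200)
  max(abs(x[(g + 1):(n - g)]))
}
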