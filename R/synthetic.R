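#' Central-region channel set used for classification
#'
#' The 18 centro-temporal/centro-parietal electrodes over which the
#' timing-prediction effects are concentrated and on which both classifiers
#' operate by default.
#'
#' @return character vector of 18 channel names.
#' @export
central_channels <- function() {
  c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")
}

#' Simulation configuration for the synthetic timing-prediction EEG generator
#'
#' Bundles every knob of the generator. Defaults emulate the structure the
#' decoding pipeline assumes: epochs of -500..2500 ms at 200 Hz around a
#' first-flash onset, a class-independent visual N1, a slow negative drift
#' (CNV) from ~200 ms that is terminated by a smooth positive-going
#' deflection beginning about 200 ms after the predicted moment (400 ms for
#' T400, 600 ms for T600), a class-dependent onset of 20-60 Hz power
#' suppression, a second-flash response at 900 ms in all conditions, and
#' pink + white background noise. Amplitudes are free parameters of the
#' generator (chosen as typical scalp-EEG magnitudes), not measured values.
#'
#' @param n_trials_per_class trials per condition (default 40).
#' @param srate sampling rate, Hz.
#' @param epoch_span_ms epoch limits relative to first-flash onset, ms.
#' @param channels channel names; defaults to the 18 central classification
#'   channels plus FP1, FP2 and OZ for realism.
#' @param predicted_moment_ms named pair, predicted moment per timing class.
#' @param erp_amp_uv amplitude of the post-expectancy positive deflection,
#'   microvolts. `0` removes the whole timing effect from the ERP (the CNV
#'   then runs identically in all classes).
#' @param erp_offset_ms latency of the deflection onset after the predicted
#'   moment (default 200 ms).
#' @param erp_rise_ms rise time of the deflection.
#' @param cnv_slope_uv_s slope of the negative anticipatory drift, uV/s
#'   (negative).
#' @param n1_amp_uv,n1_latency_ms first-flash N1 amplitude (uV, applied
#'   negatively) and peak latency; class-independent.
#' @param second_flash_ms onset of the second flash (all analysis windows
#'   end before its response).
#' @param supp_band [band_spec()] of the power suppression (default 20-60 Hz).
#' @param supp_depth fractional amplitude reduction of in-band noise after
#'   suppression onset, in `[0, 1)`; at a channel with spatial gain 1 and a
#'   condition with depth scale 1, the in-band power drops by
#'   `20*log10(1 - supp_depth)` dB.
#' @param supp_onset_ms named onsets of suppression per condition, ms.
#' @param supp_depth_scale named per-condition multiplier on `supp_depth`
#'   (the suppression is strongest for T400, weaker for T600, weakest for
#'   NT). Per channel, the depth is additionally scaled by
#'   `spatial_profile`, concentrating the effect centrally; a spatially
#'   uniform power change would be invisible to trace-normalized
#'   covariances.
#' @param supp_ramp_ms duration of the ramp from full to suppressed gain.
#' @param noise_scale_uv RMS of the background noise per channel, uV.
#' @param pink_weight,white_weight relative amplitude weights of the 1/f and
#'   flat components of the background spectrum.
#' @param spatial_profile named per-channel gain applied to the ERP kernel;
#'   `NULL` gives gain 1 on central channels and 0.3 elsewhere.
#' @param subject_jitter multiplicative inter-subject variability (uniform
#'   `1 +/- jitter`) applied to `erp_amp_uv` and `supp_depth` by
#'   [simulate_cohort()]; 0 makes all subjects share the effect size.
#' @param include_nt also simulate the no-timing (NT) condition.
#' @param seed RNG seed used by [simulate_subject()].
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_trials_per_class = 40,
                       srate = 200,
                       epoch_span_ms = c(-500, 2500),
                       channels = c(central_channels(), "FP1", "FP2", "OZ"),
                       predicted_moment_ms = c(T400 = 400, T600 = 600),
                       erp_amp_uv = 2,
                       erp_offset_ms = 200,
                       erp_rise_ms = 300,
                       cnv_slope_uv_s = -10,
                       n1_amp_uv = 8,
                       n1_latency_ms = 160,
                       second_flash_ms = 900,
                       supp_band = band_spec("high", 20, 60),
                       supp_depth = 0.4,
                       supp_onset_ms = c(T400 = 100, T600 = 220, NT = 300),
                       supp_depth_scale = c(T400 = 1, T600 = 0.8, NT = 0.7),
                       supp_ramp_ms = 100,
                       noise_scale_uv = 8,
                       pink_weight = 1,
                       white_weight = 0.1,
                       spatial_profile = NULL,
                       subject_jitter = 0.2,
                       include_nt = FALSE,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "SimConfig")
  stopifnot(cfg$n_trials_per_class >= 1, cfg$srate > 0,
            cfg$supp_depth >= 0, cfg$supp_depth < 1,
            cfg$noise_scale_uv > 0, cfg$subject_jitter >= 0)
  if (is.null(cfg$spatial_profile)) {
    g <- ifelse(toupper(cfg$channels) %in% central_channels(), 1, 0.3)
    names(g) <- cfg$channels
    cfg$spatial_profile <- g
  }
  cfg
}

label_code <- function(label) {
  if (is.character(label))
    switch(label, T400 = 1L, T600 = -1L, NT = 0L,
           stop(sprintf("unknown label '%s'", label)))
  else {
    l <- as.integer(label)
    if (!l %in% c(1L, -1L, 0L)) stop(sprintf("unknown label '%d'", l))
    l
  }
}

label_name <- function(code) c(`1` = "T400", `-1` = "T600", `0` = "NT")[as.character(code)]

smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

#' Deterministic single-trial ERP kernel for one condition
#'
#' Evaluates the noise-free ERP waveform (microvolts, unit spatial gain) on
#' the epoch time grid of `cfg`: a Gaussian N1 at `n1_latency_ms`, a linear
#' CNV drift from 200 ms, and -- for timing conditions with a non-zero
#' effect amplitude -- termination of the drift plus a smooth positive
#' deflection starting `erp_offset_ms` after the predicted moment. A
#' smaller second-flash response is added at `second_flash_ms + n1_latency_ms`
#' in every condition. With `erp_amp_uv = 0` the drift runs to the second
#' flash in all conditions and the kernels are identical across classes.
#'
#' @param label `"T400"`, `"T600"`, `"NT"` or the codes `1`, `-1`, `0`.
#' @param cfg a [sim_config()].
#' @return numeric waveform of length `n_samples`, with attribute
#'   `times_ms`.
#' @export
make_erp_kernel <- function(label, cfg) {
  code <- label_code(label)
  ns <- round((cfg$epoch_span_ms[2] - cfg$epoch_span_ms[1]) * cfg$srate / 1000)
  t <- cfg$epoch_span_ms[1] + 1000 * (seq_len(ns) - 1L) / cfg$srate
  k <- numeric(ns)
  sigma <- 25  # ms, width of the flash-evoked deflections
  # class-independent first-flash N1
  k <- k - cfg$n1_amp_uv * exp(-(t - cfg$n1_latency_ms)^2 / (2 * sigma^2))
  # second-flash response, present in all conditions (analysis windows end
  # before it; it must not leak into features)
  k <- k - 0.8 * cfg$n1_amp_uv *
    exp(-(t - (cfg$second_flash_ms + cfg$n1_latency_ms))^2 / (2 * sigma^2))
  # CNV: negative drift from 200 ms, terminated by the positive deflection
  cnv_start <- 200
  t_term <- if (cfg$erp_amp_uv > 0 && code != 0L)
    unname(cfg$predicted_moment_ms[label_name(code)]) + cfg$erp_offset_ms
  else cfg$second_flash_ms
  ramp <- pmin(pmax(t - cnv_start, 0), t_term - cnv_start)
  k <- k + cfg$cnv_slope_uv_s / 1000 * ramp
  if (cfg$erp_amp_uv > 0 && code != 0L)
    k <- k + cfg$erp_amp_uv * smoothstep((t - t_term) / cfg$erp_rise_ms)
  attr(k, "times_ms") <- t
  k
}

# In-band amplitude gain envelope for one condition at spatial gain 1.
# Ramps from 1 down to 1 - supp_depth * supp_depth_scale over supp_ramp_ms
# starting at the condition's suppression onset.
supp_envelope <- function(label, cfg) {
  code <- label_code(label)
  nm <- label_name(code)
  ns <- round((cfg$epoch_span_ms[2] - cfg$epoch_span_ms[1]) * cfg$srate / 1000)
  t <- cfg$epoch_span_ms[1] + 1000 * (seq_len(ns) - 1L) / cfg$srate
  onset <- unname(cfg$supp_onset_ms[nm])
  if (is.na(onset)) onset <- cfg$supp_onset_ms[["NT"]]
  scale <- unname(cfg$supp_depth_scale[nm])
  if (is.na(scale)) scale <- 1
  d <- cfg$supp_depth * scale
  1 - d * pmin(pmax((t - onset) / cfg$supp_ramp_ms, 0), 1)
}

# Frequency-domain shaped noise. `X` is the FFT of a unit white-noise draw;
# returns the time series obtained by multiplying the spectrum with the
# amplitude profile `amp` (length n, symmetric in |f|).
shape_noise <- function(X, amp) {
  Re(stats::fft(X * amp, inverse = TRUE)) / length(X)
}

# amplitude profile of the pink + white background at FFT bin frequencies
background_profile <- function(f, cfg) {
  cfg$pink_weight / sqrt(pmax(abs(f), 1)) + cfg$white_weight
}

# raised-cosine band mask in |f| with 2 Hz transition edges
band_mask <- function(f, band, trans = 2) {
  af <- abs(f)
  up <- smoothstep((af - (band$lo_hz - trans)) / trans)
  dn <- smoothstep(((band$hi_hz + trans) - af) / trans)
  up * dn
}

#' Simulate one subject's epoched EEG
#'
#' Draws `n_trials_per_class` trials per condition. Each trial is the
#' spatially weighted ERP kernel plus background noise built in the
#' frequency domain: one pink + white spectrum per trial and channel is
#' split into its `supp_band` component -- which is multiplied in time by
#' the condition's suppression gain envelope, scaled per channel by the
#' spatial profile -- and its out-of-band remainder, so at a unit-gain
#' channel the planted in-band power change is exactly
#' `20*log10(1 - supp_depth * supp_depth_scale)` dB while the summed
#' spectrum is otherwise the unmodified background. Identical seeds give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return an [epoch_set()] with labels `+1` (T400), `-1` (T600) and, if
#'   `cfg$include_nt`, `0` (NT).
#' @export
simulate_subject <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  codes <- c(1L, -1L, if (cfg$include_nt) 0L)
  ns <- round((cfg$epoch_span_ms[2] - cfg$epoch_span_ms[1]) * cfg$srate / 1000)
  nc <- length(cfg$channels)
  ntr <- cfg$n_trials_per_class * length(codes)
  f <- (seq_len(ns) - 1L) * cfg$srate / ns
  f <- ifelse(f > cfg$srate / 2, f - cfg$srate, f)
  amp <- background_profile(f, cfg)
  mask <- band_mask(f, cfg$supp_band)
  # scale so the full (unsuppressed) background has RMS noise_scale_uv
  scl <- cfg$noise_scale_uv / sqrt(mean(amp^2))
  kernels <- lapply(codes, make_erp_kernel, cfg = cfg)
  envs <- lapply(codes, supp_envelope, cfg = cfg)
  gain <- unname(cfg$spatial_profile[cfg$channels])
  dat <- array(0, c(ntr, nc, ns))
  labels <- integer(ntr)
  with_seed(cfg$seed, {
    tr <- 0L
    for (ci in seq_along(codes)) {
      for (i in seq_len(cfg$n_trials_per_class)) {
        tr <- tr + 1L
        labels[tr] <- codes[ci]
        for (ch in seq_len(nc)) {
          X <- stats::fft(stats::rnorm(ns))
          inband <- shape_noise(X, amp * mask) * scl
          outband <- shape_noise(X, amp * (1 - mask)) * scl
          env_ch <- 1 - (1 - envs[[ci]]) * gain[ch]
          dat[tr, ch, ] <- gain[ch] * kernels[[ci]] +
            outband + env_ch * inband
        }
      }
    }
  })
  epoch_set(dat, labels = labels, srate = cfg$srate,
            t0_ms = cfg$epoch_span_ms[1], channel_names = cfg$channels)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from `base_seed`.
#' With `cfg$subject_jitter > 0`, each subject's effect sizes
#' (`erp_amp_uv`, `supp_depth`) are scaled by an independent uniform factor
#' in `1 +/- jitter`, emulating inter-subject variability in effect
#' strength; noise realizations always differ across subjects.
#'
#' @param cfg a [sim_config()].
#' @param n_subjects number of subjects (the study retained 18).
#' @param base_seed integer seed for the whole cohort.
#' @return list of `EpochSet`s, one per subject.
#' @export
simulate_cohort <- function(cfg, n_subjects, base_seed = cfg$seed) {
  stopifnot(n_subjects >= 1)
  base_seed <- as.integer(base_seed) %% 1000000L
  lapply(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$seed <- base_seed + 1000L * s
    if (cfg$subject_jitter > 0) {
      fac <- with_seed(base_seed + 1000L * s + 1L,
                       stats::runif(2, 1 - cfg$subject_jitter,
                                    1 + cfg$subject_jitter))
      scfg$erp_amp_uv <- cfg$erp_amp_uv * fac[1]
      scfg$supp_depth <- min(cfg$supp_depth * fac[2], 0.95)
    }
    simulate_subject(scfg)
  })
}
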