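#' Grand-average ERP waveform
#'
#' Arithmetic mean over all trials carrying `label` (or all trials if
#' `label` is `NULL`), per channel and sample.
#'
#' @param x an `EpochSet`.
#' @param label label value to average (`1`, `-1`, `0`, or `"T400"` etc.);
#'   `NULL` averages every trial.
#' @return an `erp_waveform`: a `[n_channels x n_samples]` matrix with
#'   channel names as rownames and attributes `srate` and `t0_ms`.
#' @export
grand_average <- function(x, label = NULL) {
  validate_epoch_set(x)
  idx <- if (is.null(label)) seq_len(n_trials(x))
         else which(x$labels == label_code(label))
  if (length(idx) == 0L)
    stop(sprintf("no trials with label %s", as.character(label)))
  m <- apply(x$data[idx, , , drop = FALSE], c(2L, 3L), mean)
  rownames(m) <- x$channel_names
  structure(m, srate = x$srate, t0_ms = x$t0_ms, class = "erp_waveform")
}

waveform_times <- function(w) {
  attr(w, "t0_ms") + 1000 * (seq_len(ncol(w)) - 1L) / attr(w, "srate")
}

waveform_window_cols <- function(w, window) {
  tms <- waveform_times(w)
  idx <- which(tms >= window$start_ms - 1e-6 & tms < window$end_ms - 1e-6)
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g) ms selects no samples",
                 window$start_ms, window$end_ms))
  idx
}

#' Mean amplitude in a time window
#'
#' The component amplitude convention used throughout: the mean value over
#' the half-open analysis window, per channel.
#'
#' @param w an `erp_waveform` (from [grand_average()]) or any matrix with
#'   `srate`/`t0_ms` attributes.
#' @param window a [window_spec()].
#' @return named numeric vector, one mean amplitude (uV) per channel.
#' @export
window_amplitude <- function(w, window) {
  idx <- waveform_window_cols(w, window)
  rowMeans(w[, idx, drop = FALSE])
}

#' Fractional-area latency of an ERP component
#'
#' The time before which `fraction` (default 50%) of the component area in
#' the analysis window has accumulated. The waveform is rectified by
#' default (so biphasic windows are handled); area is accumulated by the
#' trapezoidal rule and the crossing time is linearly interpolated between
#' samples.
#'
#' @param w numeric waveform vector with `srate`/`t0_ms` attributes, or a
#'   single-row `erp_waveform`.
#' @param window a [window_spec()].
#' @param fraction area fraction in (0, 1); default 0.5.
#' @param rectify use `abs(w)` (default); `FALSE` clips negative values to
#'   zero instead (signed-positive area).
#' @return latency in ms.
#' @export
fractional_area_latency <- function(w, window, fraction = 0.5,
                                    rectify = TRUE) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.matrix(w)) {
    if (nrow(w) != 1L) stop("supply a single-channel waveform")
    w <- structure(drop(w), srate = attr(w, "srate"), t0_ms = attr(w, "t0_ms"))
  }
  tms <- attr(w, "t0_ms") + 1000 * (seq_along(w) - 1L) / attr(w, "srate")
  idx <- which(tms >= window$start_ms - 1e-6 & tms < window$end_ms - 1e-6)
  if (length(idx) < 2L) stop("window must contain at least two samples")
  a <- if (rectify) abs(w[idx]) else pmax(w[idx], 0)
  t <- tms[idx]
  seg <- diff(t) * (utils::head(a, -1L) + utils::tail(a, -1L)) / 2
  total <- sum(seg)
  if (total <= 0) stop("zero total area in window; latency undefined")
  cum <- c(0, cumsum(seg))
  target <- fraction * total
  i <- which(cum >= target)[1L]
  if (i == 1L) return(t[1L])
  # invert the quadratic cumulative area on segment [i-1, i]
  t0 <- t[i - 1L]; dt <- t[i] - t0
  a0 <- a[i - 1L]; a1 <- a[i]
  need <- target - cum[i - 1L]
  if (abs(a1 - a0) < 1e-12 * max(a0, a1, 1)) {
    if (a0 <= 0) return(t[i])
    return(t0 + dt * need / seg[i - 1L])
  }
  slope <- (a1 - a0) / dt
  # solve a0*s + slope*s^2/2 = need for s in [0, dt]
  disc <- a0^2 + 2 * slope * need
  s <- (-a0 + sqrt(max(disc, 0))) / slope
  t0 + min(max(s, 0), dt)
}

#' Across-trial signal-to-noise ratio in dB
#'
#' The energy of the mean single-trial amplitude relative to its
#' across-trial variance, with population (1/N) moments:
#' `10*log10(mean(a)^2 / (mean(a^2) - mean(a)^2))`.
#'
#' @param amplitudes numeric vector of per-trial amplitudes (one value per
#'   trial, e.g. the trial's mean in an analysis window at one channel).
#' @return SNR in dB.
#' @export
snr_db <- function(amplitudes) {
  a <- as.numeric(amplitudes)
  if (length(a) < 2L) stop("need at least two trials")
  m <- mean(a)
  v <- mean(a^2) - m^2
  if (v <= 0) stop("degenerate: identical trials (zero variance)")
  if (m == 0) stop("degenerate: zero signal (zero mean)")
  10 * log10(m^2 / v)
}

#' Fisher discriminative ratio between two samples
#'
#' Squared difference of group means over the sum of group variances,
#' `(m1 - m2)^2 / (s1^2 + s2^2)`: a unit-free separability index between
#' the two timing conditions.
#'
#' @param samples1,samples2 numeric vectors (e.g. per-trial amplitudes of
#'   the two classes at one channel/time).
#' @param var_type `"population"` (1/N, default, consistent with [snr_db()])
#'   or `"sample"` (1/(N-1)).
#' @return the ratio (non-negative).
#' @export
fdr_score <- function(samples1, samples2,
                      var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  s1 <- as.numeric(samples1); s2 <- as.numeric(samples2)
  if (length(s1) == 0L || length(s2) == 0L) stop("both groups must be non-empty")
  vfun <- function(v) {
    if (var_type == "population") mean(v^2) - mean(v)^2
    else if (length(v) > 1L) stats::var(v) else 0
  }
  denom <- vfun(s1) + vfun(s2)
  if (denom <= 0) stop("degenerate: both groups have zero variance")
  (mean(s1) - mean(s2))^2 / denom
}

#' Per-time-point Fisher discriminative ratio profile
#'
#' Computes [fdr_score()] across trials at every channel and sample between
#' two label groups, the single-trial analogue of the separability profiles
#' used to choose classification windows.
#'
#' @param x an `EpochSet` containing both labels.
#' @param labels pair of label values to contrast (default T400 vs T600).
#' @return `[n_channels x n_samples]` matrix of FDR values.
#' @export
fdr_profile <- function(x, labels = c(1, -1)) {
  validate_epoch_set(x)
  i1 <- which(x$labels == label_code(labels[[1]]))
  i2 <- which(x$labels == label_code(labels[[2]]))
  if (length(i1) == 0L || length(i2) == 0L)
    stop("both contrasted labels must be present")
  m1 <- apply(x$data[i1, , , drop = FALSE], c(2L, 3L), mean)
  m2 <- apply(x$data[i2, , , drop = FALSE], c(2L, 3L), mean)
  v1 <- apply(x$data[i1, , , drop = FALSE], c(2L, 3L),
              function(v) mean(v^2) - mean(v)^2)
  v2 <- apply(x$data[i2, , , drop = FALSE], c(2L, 3L),
              function(v) mean(v^2) - mean(v)^2)
  (m1 - m2)^2 / (v1 + v2)
}

# complex Morlet wavelet at frequency f, unit energy
morlet_wavelet <- function(f, srate, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * srate)
  t <- (-half:half) / srate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# same-length centered complex convolution via FFT
conv_same <- function(x, kern, nfft, Kf = NULL) {
  n <- length(x); l <- length(kern); half <- (l - 1L) %/% 2L
  if (is.null(Kf)) Kf <- stats::fft(c(kern, rep(0, nfft - l)))
  Xf <- stats::fft(c(x, rep(0, nfft - n)))
  full <- stats::fft(Xf * Kf, inverse = TRUE) / nfft
  full[(half + 1L):(half + n)]
}

#' Event-related spectral perturbation (ERSP)
#'
#' Time-frequency power via complex Morlet wavelets (default 7 cycles),
#' averaged over trials, divided by the mean baseline power per frequency
#' (and channel), and expressed as `10*log10` dB. Baseline columns
#' therefore average 0 dB at every frequency. Power is averaged over the
#' requested channels before the dB conversion.
#'
#' @param x an `EpochSet`.
#' @param freqs_hz analysis frequencies (each below Nyquist and with a full
#'   wavelet support inside the epoch).
#' @param baseline a [window_spec()]; default `[-100, 0)` ms.
#' @param n_cycles wavelet width in cycles (default 7).
#' @param channels channel names to include (`NULL` = all); power is
#'   averaged across them.
#' @param label restrict to trials with this label (`NULL` = all trials).
#' @return an `ErspGrid`: list with `power_db` `[n_freqs x n_samples]`,
#'   `freqs_hz`, `times_ms` and `baseline`.
#' @export
ersp <- function(x, freqs_hz, baseline = window_spec(-100, 0),
                 n_cycles = 7, channels = NULL, label = NULL) {
  validate_epoch_set(x)
  if (!is.null(channels)) x <- select_epochs(x, channels = channels)
  if (!is.null(label)) x <- select_epochs(x, labels = label_code(label))
  ns <- n_samples(x); nt <- n_trials(x); nc <- n_channels(x)
  if (any(freqs_hz >= x$srate / 2)) stop("frequencies must be below Nyquist")
  kerns <- lapply(freqs_hz, morlet_wavelet, srate = x$srate,
                  n_cycles = n_cycles)
  if (any(vapply(kerns, length, 1L) > ns))
    stop("frequency too low: wavelet support exceeds epoch length")
  lmax <- max(vapply(kerns, length, 1L))
  nfft <- 2^ceiling(log2(ns + lmax))
  Kf <- lapply(kerns, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  bl_idx <- window_indices(x, baseline)
  nf <- length(freqs_hz)
  pow <- array(0, c(nf, nc, ns))  # trial-mean power per freq/channel/sample
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      sig <- x$data[tr, ch, ]
      for (fi in seq_len(nf)) {
        cx <- conv_same(sig, kerns[[fi]], nfft, Kf[[fi]])
        pow[fi, ch, ] <- pow[fi, ch, ] + Mod(cx)^2
      }
    }
  }
  pow <- pow / nt
  # divisive baseline per frequency and channel, then dB, then channel mean
  db <- array(0, c(nf, nc, ns))
  for (fi in seq_len(nf))
    for (ch in seq_len(nc)) {
      b <- mean(pow[fi, ch, bl_idx])
      db[fi, ch, ] <- 10 * log10(pow[fi, ch, ] / b)
    }
  power_db <- apply(db, c(1L, 3L), mean)
  structure(list(power_db = power_db, freqs_hz = freqs_hz,
                 times_ms = epoch_times(x), baseline = baseline),
            class = "ErspGrid")
}

#' Mean ERSP value in a time-frequency box
#'
#' @param grid an `ErspGrid` from [ersp()].
#' @param window a [window_spec()] for time.
#' @param band a [band_spec()] for frequency (frequencies in
#'   `[lo_hz, hi_hz]` are included).
#' @return mean dB value over the box.
#' @export
ersp_box_mean <- function(grid, window, band) {
  ti <- which(grid$times_ms >= window$start_ms - 1e-6 &
              grid$times_ms < window$end_ms - 1e-6)
  fi <- which(grid$freqs_hz >= band$lo_hz & grid$freqs_hz <= band$hi_hz)
  if (length(ti) == 0L || length(fi) == 0L) stop("empty time-frequency box")
  mean(grid$power_db[fi, ti, drop = FALSE])
}
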