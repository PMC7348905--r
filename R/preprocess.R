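#' Zero-phase filter specification
#'
#' Describes a Butterworth filter applied forward-backward (zero net phase,
#' squared magnitude response). The default order 4 gives an effective
#' order-8 magnitude response after the two passes; a flat passband
#' protects ERP morphology.
#'
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param edges_hz one edge (lowpass) or two increasing edges (bandpass), Hz.
#' @param order Butterworth order per pass, `>= 2`.
#' @return a `FilterSpec`.
#' @export
filter_spec <- function(kind = c("lowpass", "bandpass"), edges_hz, order = 4) {
  kind <- match.arg(kind)
  edges_hz <- as.numeric(edges_hz)
  if (kind == "lowpass" && length(edges_hz) != 1L)
    stop("lowpass needs exactly one edge")
  if (kind == "bandpass" &&
      (length(edges_hz) != 2L || edges_hz[1] >= edges_hz[2]))
    stop("bandpass needs two increasing edges")
  if (any(edges_hz <= 0)) stop("filter edges must be positive")
  if (order < 2) stop("filter order must be >= 2")
  structure(list(kind = kind, edges_hz = edges_hz, order = as.integer(order),
                 zero_phase = TRUE), class = "FilterSpec")
}

# Design the signal::butter object for a FilterSpec at a given rate.
design_filter <- function(spec, srate) {
  nyq <- srate / 2
  if (any(spec$edges_hz >= nyq))
    stop(sprintf("filter edge(s) %s Hz must lie below Nyquist (%g Hz)",
                 paste(spec$edges_hz, collapse = "/"), nyq))
  w <- spec$edges_hz / nyq
  flt <- if (spec$kind == "lowpass") signal::butter(spec$order, w, type = "low")
         else signal::butter(spec$order, w, type = "pass")
  if (any(!is.finite(unlist(flt))) || any(abs(polyroot(rev(flt$a))) > 1 + 1e-8))
    stop("unstable filter design; try a lower order or wider band")
  flt
}

# Forward-backward filtering with odd (point-mirror) reflection padding of
# at least `pad_s` seconds, trimmed after filtering. Epochs are short
# relative to delta-band impulse responses, so padding matters.
zp_filter_vec <- function(x, flt, srate, pad_s = 0.5) {
  n <- length(x)
  p <- min(n - 1L, max(as.integer(ceiling(pad_s * srate)), 24L))
  left <- 2 * x[1L] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(flt, c(left, x, right))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth filtering of epoched data
#'
#' Applies `spec` forward and backward (via [signal::filtfilt()]) to every
#' trial and channel, after reflection-padding each epoch by at least 0.5 s
#' to suppress edge transients. Output has the same shape and metadata as
#' the input.
#'
#' @param x an `EpochSet`.
#' @param spec a [filter_spec()].
#' @return the filtered `EpochSet`.
#' @export
zero_phase_filter <- function(x, spec) {
  validate_epoch_set(x)
  flt <- design_filter(spec, x$srate)
  out <- x$data
  for (tr in seq_len(n_trials(x)))
    for (ch in seq_len(n_channels(x)))
      out[tr, ch, ] <- zp_filter_vec(x$data[tr, ch, ], flt, x$srate)
  x$data <- out
  x
}

#' Downsample epoched data by integer decimation
#'
#' Applies a zero-phase anti-alias low-pass at 80% of the new Nyquist
#' frequency, then keeps every `srate/target_hz`-th sample starting from the
#' first, so `t0_ms` is preserved exactly.
#'
#' @param x an `EpochSet`.
#' @param target_hz new sampling rate; must divide `srate`.
#' @return the decimated `EpochSet`.
#' @export
downsample <- function(x, target_hz) {
  validate_epoch_set(x)
  if (target_hz > x$srate)
    stop(sprintf("target rate (%g Hz) exceeds current rate (%g Hz)",
                 target_hz, x$srate))
  if (target_hz == x$srate) return(x)
  fac <- x$srate / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop(sprintf("target rate %g Hz is not an integer divisor of %g Hz",
                 target_hz, x$srate))
  fac <- as.integer(round(fac))
  x <- zero_phase_filter(x, filter_spec("lowpass", 0.8 * target_hz / 2,
                                        order = 4))
  keep <- seq(1L, n_samples(x), by = fac)
  x$data <- x$data[, , keep, drop = FALSE]
  x$srate <- as.numeric(target_hz)
  validate_epoch_set(x)
  x
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 100 ms before the time-locking event). Idempotent.
#'
#' @param x an `EpochSet`.
#' @param window a [window_spec()]; default `[-100, 0)` ms.
#' @return the corrected `EpochSet`.
#' @export
baseline_correct <- function(x, window = window_spec(-100, 0)) {
  validate_epoch_set(x)
  idx <- window_indices(x, window)
  if (length(idx) == 0L) stop("baseline window contains no samples")
  bl <- apply(x$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  x$data <- x$data - as.vector(bl)  # recycles over the samples dimension
  x
}

#' Decompose epochs into frequency bands
#'
#' Filters the input once per band (a band with `lo_hz = 0` becomes a
#' low-pass at `hi_hz`; any other band a band-pass) and returns one
#' `EpochSet` per band, all sharing labels, sampling metadata and shape.
#'
#' @param x an `EpochSet`.
#' @param bands list of [band_spec()]s (possibly named).
#' @param order Butterworth order per pass.
#' @return named list of filtered `EpochSet`s (names taken from the band
#'   names).
#' @export
band_decompose <- function(x, bands, order = 4) {
  if (length(bands) == 0L) return(structure(list(), names = character(0)))
  if (inherits(bands, "BandSpec")) bands <- list(bands)
  out <- lapply(bands, function(b) {
    spec <- if (b$lo_hz == 0) filter_spec("lowpass", b$hi_hz, order)
            else filter_spec("bandpass", c(b$lo_hz, b$hi_hz), order)
    tryCatch(zero_phase_filter(x, spec),
             error = function(e)
               stop(sprintf("band '%s': %s", b$name, conditionMessage(e))))
  })
  names(out) <- vapply(bands, `[[`, "", "name")
  out
}

# Band-filter an EpochSet according to a BandSpec (single band).
filter_band <- function(x, band, order = 4) {
  band_decompose(x, list(band), order)[[1L]]
}
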