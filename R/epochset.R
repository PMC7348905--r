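#' Labelled epoched EEG container
#'
#' An `EpochSet` is the currency passed between every stage of the pipeline:
#' a real-valued tensor of `n_trials x n_channels x n_samples` (microvolts)
#' together with per-trial class labels and sampling metadata. Sample `i`
#' (1-based) occurs at `t0_ms + 1000 * (i - 1) / srate` milliseconds relative
#' to the time-locking event (the first flash in the timing-prediction task).
#'
#' Labels follow the two-class decoding contract: `+1` for the T400 condition
#' (predicted moment 400 ms), `-1` for T600 (600 ms). A third label `0` (NT,
#' no timing) is permitted for descriptive metrics but is rejected by the
#' two-class classifiers.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, microvolts.
#' @param labels integer-ish vector of length `n_trials` with values in
#'   `{+1, -1, 0}`.
#' @param srate sampling rate in Hz, positive scalar.
#' @param t0_ms time of the first sample relative to the time-locking event,
#'   in milliseconds.
#' @param channel_names character vector of channel identifiers (10-20 system
#'   names), length `n_channels`.
#' @return An object of class `EpochSet`.
#' @examples
#' x <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)),
#'                labels = c(1, -1), srate = 100, t0_ms = -20,
#'                channel_names = c("C3", "CZ", "C4"))
#' n_trials(x)
#' epoch_times(x)
#' @export
epoch_set <- function(data, labels, srate, t0_ms, channel_names) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [n_trials x n_channels x n_samples]")
  storage.mode(data) <- "double"
  x <- structure(
    list(data = data,
         labels = as.integer(round(labels)),
         srate = as.numeric(srate),
         t0_ms = as.numeric(t0_ms),
         channel_names = as.character(channel_names)),
    class = "EpochSet")
  validate_epoch_set(x)
  x
}

#' Validate an EpochSet against its invariants
#'
#' Checks dimension/metadata consistency, finiteness of the payload and
#' positivity of the sampling rate. Called by every constructor-like path.
#'
#' @param x an `EpochSet`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "EpochSet"))
  d <- dim(x$data)
  if (length(x$labels) != d[1L])
    stop(sprintf("labels length (%d) must equal n_trials (%d)",
                 length(x$labels), d[1L]))
  if (length(x$channel_names) != d[2L])
    stop(sprintf("channel_names length (%d) must equal n_channels (%d)",
                 length(x$channel_names), d[2L]))
  if (!is.finite(x$srate) || x$srate <= 0)
    stop("srate must be a positive finite number")
  if (!is.finite(x$t0_ms))
    stop("t0_ms must be finite")
  if (d[1L] > 0L && !all(is.finite(x$data)))
    stop("data contains non-finite values")
  if (!all(x$labels %in% c(-1L, 0L, 1L)))
    stop("labels must be +1 (T400), -1 (T600) or 0 (NT)")
  invisible(x)
}

#' @rdname epoch_set
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' Sample times of an EpochSet
#'
#' @param x an `EpochSet`.
#' @return numeric vector of sample times in ms relative to the time-locking
#'   event (first-flash onset).
#' @export
epoch_times <- function(x) {
  x$t0_ms + 1000 * (seq_len(n_samples(x)) - 1L) / x$srate
}

#' @export
print.EpochSet <- function(x, ...) {
  tms <- epoch_times(x)
  cat(sprintf("<EpochSet> %d trials x %d channels x %d samples @ %g Hz\n",
              n_trials(x), n_channels(x), n_samples(x), x$srate))
  if (n_samples(x) > 0)
    cat(sprintf("  span %g..%g ms; labels: %s\n",
                tms[1L], tms[length(tms)] + 1000 / x$srate,
                paste(sprintf("%s=%d", names(table(x$labels)),
                              as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Frequency band specification
#'
#' A named frequency band with edges in Hz. `lo_hz = 0` denotes a low-pass
#' band (delta, "0-4 Hz", is a 4 Hz low-pass; any DC offset is removed by
#' baseline correction rather than a high-pass edge).
#'
#' @param name band label, e.g. `"delta"`.
#' @param lo_hz,hi_hz band edges in Hz, `0 <= lo_hz < hi_hz`.
#' @return A `BandSpec` object.
#' @seealso [canonical_bands()]
#' @export
band_spec <- function(name, lo_hz, hi_hz) {
  lo_hz <- as.numeric(lo_hz); hi_hz <- as.numeric(hi_hz)
  if (!(lo_hz >= 0 && lo_hz < hi_hz))
    stop("band edges must satisfy 0 <= lo_hz < hi_hz")
  structure(list(name = as.character(name), lo_hz = lo_hz, hi_hz = hi_hz),
            class = "BandSpec")
}

#' Canonical EEG analysis bands
#'
#' The band definitions used throughout the pipeline: delta (0-4 Hz), theta
#' (4-8), alpha (8-13), beta (15-30), mid-gamma (45-65), the broadband
#' reference 0-90 Hz, and the fused high band 20-60 Hz used for CSP.
#'
#' @return named list of [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(delta  = band_spec("delta", 0, 4),
       theta  = band_spec("theta", 4, 8),
       alpha  = band_spec("alpha", 8, 13),
       beta   = band_spec("beta", 15, 30),
       mgamma = band_spec("mgamma", 45, 65),
       broad  = band_spec("broad", 0, 90),
       high   = band_spec("high", 20, 60))
}

#' Analysis window specification
#'
#' Half-open time window `[start_ms, end_ms)` relative to the time-locking
#' event. Half-openness makes windows tile exactly: at 200 Hz the window
#' 500-850 ms holds exactly 70 samples.
#'
#' @param start_ms,end_ms window edges in ms, `start_ms < end_ms`.
#' @return A `WindowSpec` object.
#' @export
window_spec <- function(start_ms, end_ms) {
  start_ms <- as.numeric(start_ms); end_ms <- as.numeric(end_ms)
  if (!(start_ms < end_ms)) stop("window must satisfy start_ms < end_ms")
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "WindowSpec")
}

# Sample indices whose times fall in [start, end). A small tolerance guards
# against floating-point drift in t0 + i/srate arithmetic.
window_indices <- function(x, window) {
  tms <- epoch_times(x)
  eps <- 1e-6
  idx <- which(tms >= window$start_ms - eps & tms < window$end_ms - eps)
  span_lo <- x$t0_ms
  span_hi <- x$t0_ms + 1000 * n_samples(x) / x$srate
  if (window$start_ms < span_lo - eps || window$end_ms > span_hi + eps)
    stop(sprintf("window [%g, %g) ms outside epoch span [%g, %g) ms",
                 window$start_ms, window$end_ms, span_lo, span_hi))
  idx
}

match_channels <- function(x, channels) {
  have <- toupper(x$channel_names)
  want <- toupper(channels)
  idx <- match(want, have)
  if (anyNA(idx))
    stop(sprintf("unknown channel(s): %s; available: %s",
                 paste(channels[is.na(idx)], collapse = ", "),
                 paste(x$channel_names, collapse = ", ")))
  idx
}

#' Subset an EpochSet by channels, time window and labels
#'
#' Returns a new `EpochSet` restricted to the requested channels (output
#' order follows the request; matching is case-insensitive on 10-20 names),
#' the half-open time window (with `t0_ms` reset to `window$start_ms`) and
#' the requested label values.
#'
#' @param x an `EpochSet`.
#' @param channels character vector of channel names, or `NULL` to keep all.
#' @param window a [window_spec()], or `NULL` to keep the full epoch.
#' @param labels label values to keep, or `NULL` to keep all trials.
#' @return the restricted `EpochSet`.
#' @examples
#' x <- epoch_set(array(0, c(4, 2, 600)), labels = c(1, 1, -1, -1),
#'                srate = 200, t0_ms = -500, channel_names = c("CZ", "CPZ"))
#' sel <- select_epochs(x, window = window_spec(500, 850))
#' n_samples(sel)  # 70
#' @export
select_epochs <- function(x, channels = NULL, window = NULL, labels = NULL) {
  validate_epoch_set(x)
  ch_idx <- if (is.null(channels)) seq_len(n_channels(x))
            else match_channels(x, channels)
  smp_idx <- if (is.null(window)) seq_len(n_samples(x))
             else window_indices(x, window)
  tr_idx <- if (is.null(labels)) seq_len(n_trials(x))
            else which(x$labels %in% as.integer(labels))
  if (length(tr_idx) == 0L || length(ch_idx) == 0L || length(smp_idx) == 0L)
    stop("empty selection: no trials/channels/samples match the request")
  t0 <- if (is.null(window)) x$t0_ms
        else x$t0_ms + 1000 * (smp_idx[1L] - 1L) / x$srate
  epoch_set(x$data[tr_idx, ch_idx, smp_idx, drop = FALSE],
            labels = x$labels[tr_idx], srate = x$srate, t0_ms = t0,
            channel_names = x$channel_names[ch_idx])
}

#' Save an EpochSet as a portable epoch bundle
#'
#' Writes a directory holding `metadata.json` (keys `n_trials`, `n_channels`,
#' `n_samples`, `srate_hz`, `t0_ms`, `channel_names`, `labels`) and
#' `data.bin`, the payload as little-endian float32 in trial-major, then
#' channel-major, then sample order. The write is atomic: files are staged
#' in a temporary sibling directory and renamed into place.
#'
#' @param x an `EpochSet`.
#' @param path directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(x, path) {
  validate_epoch_set(x)
  stage <- paste0(path, ".tmp", Sys.getpid())
  if (dir.exists(stage)) unlink(stage, recursive = TRUE)
  ok <- dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create directory '%s'", stage))
  meta <- list(n_trials = n_trials(x), n_channels = n_channels(x),
               n_samples = n_samples(x), srate_hz = x$srate,
               t0_ms = x$t0_ms, channel_names = x$channel_names,
               labels = x$labels)
  jsonlite::write_json(meta, file.path(stage, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # payload order: trial-major, then channel, then sample
  con <- file(file.path(stage, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  if (n_trials(x) > 0) {
    perm <- aperm(x$data, c(3L, 2L, 1L))  # samples fastest, trials slowest
    writeBin(as.numeric(perm), con, size = 4L, endian = "little")
  }
  close(con); on.exit()
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  if (!file.rename(stage, path))
    stop(sprintf("cannot move bundle into place at '%s'", path))
  invisible(path)
}

#' Load an epoch bundle from disk
#'
#' Reads the directory format written by [save_epochs()]. If `data.bin` is
#' absent, a CSV fallback `data.csv` is accepted: one row per trial-channel
#' pair (trial-major), samples as columns, no header.
#'
#' @param path bundle directory.
#' @return an `EpochSet`.
#' @export
load_epochs <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop(sprintf("not an epoch bundle: missing '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("n_trials", "n_channels", "n_samples", "srate_hz", "t0_ms",
                "channel_names", "labels"))
    if (is.null(meta[[key]]))
      stop(sprintf("epoch bundle metadata is missing field '%s'", key))
  nt <- as.integer(meta$n_trials); nc <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  if (length(meta$labels) != nt && !(nt == 0L && length(meta$labels) == 0L))
    stop("metadata field 'labels' length does not match n_trials")
  if (length(meta$channel_names) != nc)
    stop("metadata field 'channel_names' length does not match n_channels")
  bin_path <- file.path(path, "data.bin")
  csv_path <- file.path(path, "data.csv")
  if (file.exists(bin_path)) {
    n_vals <- nt * nc * ns
    raw_len <- file.info(bin_path)$size
    if (raw_len != 4 * n_vals)
      stop(sprintf(
        "payload size mismatch: data.bin has %d bytes, metadata implies %d",
        raw_len, 4 * n_vals))
    con <- file(bin_path, "rb")
    on.exit(close(con), add = TRUE)
    vals <- readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
    dat <- aperm(array(vals, c(ns, nc, max(nt, 0L))), c(3L, 2L, 1L))
  } else if (file.exists(csv_path)) {
    m <- as.matrix(utils::read.csv(csv_path, header = FALSE))
    if (nrow(m) != nt * nc || (nt * nc > 0 && ncol(m) != ns))
      stop(sprintf(
        "payload shape mismatch: data.csv is %d x %d, metadata implies %d x %d",
        nrow(m), ncol(m), nt * nc, ns))
    dat <- array(0, c(nt, nc, ns))
    for (tr in seq_len(nt))
      dat[tr, , ] <- m[(tr - 1L) * nc + seq_len(nc), , drop = FALSE]
  } else {
    stop(sprintf("not an epoch bundle: '%s' has neither data.bin nor data.csv",
                 path))
  }
  epoch_set(dat, labels = if (nt == 0L) integer(0) else meta$labels,
            srate = meta$srate_hz, t0_ms = meta$t0_ms,
            channel_names = meta$channel_names)
}
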