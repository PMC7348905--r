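# ---- Fisher read-outs, decision fusion and the evaluation harness ----------

#' Fit a Fisher discriminant read-out
#'
#' Two-class Fisher discriminant over arbitrary feature vectors:
#' `w = Sw^-1 (m+ - m-)` with `Sw` the pooled within-class scatter
#' (shrunk by `reg * trace(Sw)/d * I`), and bias `b` placing the midpoint
#' of the projected class means at zero. The positive class (+1) projects
#' positive on the training means.
#'
#' @param features numeric matrix `[n x d]` (a vector is treated as
#'   `d = 1`).
#' @param labels length-`n` vector of `+1`/`-1`.
#' @param reg relative shrinkage of the pooled scatter.
#' @return an `FdaModel` with fields `w` and `b`.
#' @export
fda_fit <- function(features, labels, reg = 1e-6) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (!all(y %in% c(1L, -1L))) stop("labels must be +1/-1")
  if (nrow(X) != length(y)) stop("features/labels length mismatch")
  i1 <- which(y == 1L); i2 <- which(y == -1L)
  if (length(i1) == 0L || length(i2) == 0L)
    stop("both classes must be present")
  d <- ncol(X)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  Sw <- matrix(0, d, d)
  for (i in i1) Sw <- Sw + tcrossprod(X[i, ] - m1)
  for (i in i2) Sw <- Sw + tcrossprod(X[i, ] - m2)
  tr <- sum(diag(Sw))
  if (tr <= 0 && sum(abs(m1 - m2)) == 0)
    stop("degenerate: identical class means and zero scatter")
  Sw <- Sw + max(reg * tr / d, 1e-12) * diag(d)
  w <- solve(Sw, m1 - m2)
  b <- -sum(w * (m1 + m2)) / 2
  structure(list(w = as.numeric(w), b = as.numeric(b)), class = "FdaModel")
}

#' Project features through a Fisher read-out
#'
#' @param model an `FdaModel`.
#' @param features matrix `[n x d]` or a single length-`d` vector.
#' @return numeric vector of decision values `w'x + b`.
#' @export
fda_project <- function(model, features) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  as.numeric(X %*% model$w + model$b)
}

#' Decision-level fusion of two classifier outputs
#'
#' The fused label is the sign of `F1 + F2`: `+1` (T400) when positive,
#' `-1` (T600) when negative, with exact ties breaking deterministically
#' to `+1`. Vectorized over trials.
#'
#' @param F1,F2 finite numeric decision values (DCPM and CSP read-outs).
#' @return integer labels `+1`/`-1`.
#' @export
fuse_decision <- function(F1, F2) {
  if (any(!is.finite(F1)) || any(!is.finite(F2)))
    stop("decision values must be finite")
  ifelse(F1 + F2 >= 0, 1L, -1L)
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds, stratified by label with seeded
#' shuffling. The assignment depends only on the label vector, `k` and
#' `seed`, never on the data values, so identical designs share folds.
#'
#' @param labels per-trial labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold index per trial, in `1..k`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop(sprintf(
          "class %d has %d trials; need at least k = %d per class",
          cls, length(idx), k))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

cv_config_digest <- function(...) {
  parts <- list(...)
  paste(vapply(seq_along(parts), function(i) {
    v <- parts[[i]]
    sprintf("%s=%s", names(parts)[i],
            paste(format(unlist(v), digits = 12), collapse = ","))
  }, ""), collapse = ";")
}

new_cv_result <- function(method, bands, windows, per_fold_acc, fold_sizes,
                          k, seed, digest) {
  structure(list(method = method, bands = bands, windows = windows,
                 per_fold_acc = per_fold_acc, fold_sizes = fold_sizes,
                 mean_acc = sum(per_fold_acc * fold_sizes) / sum(fold_sizes),
                 n_folds = k, seed = seed, config_digest = digest),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("<CvResult> %s: mean accuracy %.2f%% over %d folds (seed %d)\n",
              x$method, 100 * x$mean_acc, x$n_folds, x$seed))
  invisible(x)
}

# Shared preprocessing + per-fold fit/predict for all three methods.
# Returns per-fold decision values and truths so the three read-outs can be
# assembled without refitting. Every model component is refitted strictly
# on the training fold.
cv_engine <- function(epochs, dcpm_band, csp_band, dcpm_window, csp_window,
                      channels, k, seed, n_components, folds = NULL,
                      need = c("dcpm", "csp")) {
  x <- select_epochs(epochs, labels = c(1L, -1L))
  if (is.null(folds)) folds <- make_folds(x$labels, k, seed)
  prep <- list()
  if ("dcpm" %in% need)
    prep$dcpm <- select_epochs(
      baseline_correct(filter_band(x, dcpm_band)),
      channels = channels, window = dcpm_window)
  if ("csp" %in% need)
    prep$csp <- select_epochs(filter_band(x, csp_band),
                              channels = channels, window = csp_window)
  res <- list(folds = folds, truth = x$labels,
              F1 = numeric(n_trials(x)), F2 = numeric(n_trials(x)))
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    if ("dcpm" %in% need) {
      m <- dcpm_fit(subset_trials(prep$dcpm, tr), n_components = n_components)
      res$F1[te] <- dcpm_predict(m, subset_trials(prep$dcpm, te))$decision_values
    }
    if ("csp" %in% need) {
      m <- csp_fit(subset_trials(prep$csp, tr))
      res$F2[te] <- csp_predict(m, subset_trials(prep$csp, te))$decision_values
    }
  }
  res
}

# trial subset without label filtering (keeps both classes' bookkeeping)
subset_trials <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], labels = x$labels[idx],
            srate = x$srate, t0_ms = x$t0_ms,
            channel_names = x$channel_names)
}

fold_accuracies <- function(pred, truth, folds, k) {
  vapply(seq_len(k), function(f) mean(pred[folds == f] == truth[folds == f]),
         0)
}

#' Cross-validated decoding accuracy
#'
#' Stratified seeded k-fold cross-validation of one of the three decoders.
#' DCPM operates on band-filtered (default delta, 0-4 Hz),
#' baseline-corrected data in its analysis window (default 500-850 ms);
#' CSP on band-filtered data (default 20-60 Hz) in 100-800 ms; fusion
#' fits both per training fold and classifies each test trial by the sign
#' of the summed Fisher decision values. All model components (templates,
#' DSP, CCA, CSP filters, read-outs) are refitted on each training fold.
#'
#' @param epochs an `EpochSet` (full epochs; filtering/windowing happens
#'   inside). Trials with labels other than +1/-1 are dropped.
#' @param method `"dcpm"`, `"csp"` or `"fusion"`.
#' @param dcpm_band,csp_band [band_spec()]s for the two feature streams.
#' @param dcpm_window,csp_window [window_spec()]s.
#' @param channels channels used by the classifiers (`NULL` = all present;
#'   the study design uses [central_channels()]).
#' @param k folds (default 10).
#' @param seed fold-shuffling seed.
#' @param n_components DSP components for DCPM (`NULL` = automatic).
#' @param folds optional precomputed fold assignment (overrides
#'   `k`/`seed`-based assignment; used by [band_sweep()] for paired
#'   comparisons).
#' @return a `CvResult` with weighted mean and per-fold accuracies.
#' @export
cross_validate <- function(epochs,
                           method = c("fusion", "dcpm", "csp"),
                           dcpm_band = canonical_bands()$delta,
                           csp_band = canonical_bands()$high,
                           dcpm_window = window_spec(500, 850),
                           csp_window = window_spec(100, 800),
                           channels = NULL,
                           k = 10L, seed = 1L, n_components = NULL,
                           folds = NULL) {
  method <- match.arg(method)
  need <- switch(method, dcpm = "dcpm", csp = "csp", fusion = c("dcpm", "csp"))
  eng <- cv_engine(epochs, dcpm_band, csp_band, dcpm_window, csp_window,
                   channels, k, seed, n_components, folds, need)
  pred <- switch(method,
                 dcpm = ifelse(eng$F1 >= 0, 1L, -1L),
                 csp = ifelse(eng$F2 >= 0, 1L, -1L),
                 fusion = fuse_decision(eng$F1, eng$F2))
  acc <- fold_accuracies(pred, eng$truth, eng$folds, k)
  sizes <- vapply(seq_len(k), function(f) sum(eng$folds == f), 0L)
  digest <- cv_config_digest(
    method = method, dcpm_band = unlist(dcpm_band), csp_band = unlist(csp_band),
    dcpm_window = unlist(dcpm_window), csp_window = unlist(csp_window),
    channels = if (is.null(channels)) "all" else channels, k = k, seed = seed)
  bands <- switch(method, dcpm = list(dcpm_band), csp = list(csp_band),
                  fusion = list(dcpm = dcpm_band, csp = csp_band))
  windows <- switch(method, dcpm = list(dcpm_window), csp = list(csp_window),
                    fusion = list(dcpm = dcpm_window, csp = csp_window))
  new_cv_result(method, bands, windows, acc, sizes, k, as.integer(seed),
                digest)
}

#' Accuracy of one decoder across frequency bands
#'
#' Runs [cross_validate()] once per band with a fold assignment computed
#' once and shared across bands, so band accuracies are paired.
#'
#' @param epochs an `EpochSet`.
#' @param method `"dcpm"` or `"csp"`.
#' @param bands list of [band_spec()]s.
#' @param k,seed,channels,n_components as in [cross_validate()].
#' @param window analysis window; defaults to the method's standard window
#'   (500-850 ms for DCPM, 100-800 ms for CSP).
#' @return data frame: one row per band with `band`, `lo_hz`, `hi_hz`,
#'   `mean_acc` and per-fold accuracy columns `fold1..foldk`.
#' @export
band_sweep <- function(epochs, method = c("dcpm", "csp"), bands,
                       k = 10L, seed = 1L, channels = NULL,
                       n_components = NULL, window = NULL) {
  method <- match.arg(method)
  if (length(bands) == 0L)
    return(data.frame(band = character(0), lo_hz = numeric(0),
                      hi_hz = numeric(0), mean_acc = numeric(0)))
  if (is.null(window))
    window <- if (method == "dcpm") window_spec(500, 850)
              else window_spec(100, 800)
  x <- select_epochs(epochs, labels = c(1L, -1L))
  folds <- make_folds(x$labels, k, seed)
  rows <- lapply(bands, function(b) {
    r <- cross_validate(x, method = method, dcpm_band = b, csp_band = b,
                        dcpm_window = window, csp_window = window,
                        channels = channels, k = k, seed = seed,
                        n_components = n_components, folds = folds)
    cbind(data.frame(band = b$name, lo_hz = b$lo_hz, hi_hz = b$hi_hz,
                     mean_acc = r$mean_acc),
          as.data.frame(as.list(stats::setNames(
            r$per_fold_acc, paste0("fold", seq_len(k))))))
  })
  do.call(rbind, rows)
}

#' Three-method comparison across a cohort
#'
#' For every subject, evaluates DCPM (delta band, 500-850 ms), CSP
#' (20-60 Hz, 100-800 ms) and their decision fusion with shared folds and
#' shared preprocessing, and returns a per-subject accuracy table (in
#' percent) followed by cohort `Mean` and `Std` rows -- the layout of a
#' classification accuracy comparison table.
#'
#' @param cohort list of `EpochSet`s, one per subject.
#' @param k,seed,channels,n_components as in [cross_validate()].
#' @return data frame with columns `subject`, `dcpm`, `csp`, `fusion`
#'   (accuracies in percent).
#' @export
compare_methods <- function(cohort, k = 10L, seed = 1L, channels = NULL,
                            n_components = NULL) {
  stopifnot(length(cohort) >= 1L)
  per <- t(vapply(seq_along(cohort), function(s) {
    x <- select_epochs(cohort[[s]], labels = c(1L, -1L))
    eng <- cv_engine(x, canonical_bands()$delta, canonical_bands()$high,
                     window_spec(500, 850), window_spec(100, 800),
                     channels, k, seed + s - 1L, n_components)
    truth <- eng$truth
    c(dcpm = mean(ifelse(eng$F1 >= 0, 1L, -1L) == truth),
      csp = mean(ifelse(eng$F2 >= 0, 1L, -1L) == truth),
      fusion = mean(fuse_decision(eng$F1, eng$F2) == truth))
  }, c(dcpm = 0, csp = 0, fusion = 0)))
  df <- data.frame(subject = as.character(seq_along(cohort)),
                   round(100 * per, 2))
  summary_rows <- data.frame(
    subject = c("Mean", "Std"),
    dcpm = c(round(mean(100 * per[, "dcpm"]), 2),
             round(stats::sd(100 * per[, "dcpm"]), 2)),
    csp = c(round(mean(100 * per[, "csp"]), 2),
            round(stats::sd(100 * per[, "csp"]), 2)),
    fusion = c(round(mean(100 * per[, "fusion"]), 2),
               round(stats::sd(100 * per[, "fusion"]), 2)))
  if (length(cohort) == 1L) summary_rows$dcpm[2] <-
      summary_rows$csp[2] <- summary_rows$fusion[2] <- NA_real_
  rbind(df, summary_rows)
}

#' Write an accuracy table as CSV
#'
#' Plain deterministic CSV emission (no row names, fixed field order), so
#' identical inputs give byte-identical files.
#'
#' @param df a data frame (e.g. from [compare_methods()] or
#'   [band_sweep()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
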