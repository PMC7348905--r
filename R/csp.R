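# ---- Common Spatial Patterns (CSP) ------------------------------------------
# Paired spatial filters maximizing band-power variance for one class while
# minimizing it for the other: trace-normalized per-trial covariances, class
# means, whitening of the composite covariance, shared-basis eigenanalysis
# (eigenvalue pairs sum to one), and 4-dimensional log-variance features
# read out by a Fisher discriminant.

#' Trace-normalized trial covariance
#'
#' `R = X X' / trace(X X')`: symmetric, positive semidefinite, unit trace,
#' so trials contribute equally regardless of overall amplitude.
#'
#' @param trial matrix `[n_channels x n_samples]`, not identically zero.
#' @return `[n_channels x n_channels]` covariance matrix.
#' @export
normalized_covariance <- function(trial) {
  trial <- as.matrix(trial)
  C <- trial %*% t(trial)
  tr <- sum(diag(C))
  if (tr <= 0) stop("all-zero trial: covariance undefined")
  C / tr
}

#' Fit a CSP model
#'
#' Computes per-class mean normalized covariances `R1`, `R2`; whitens their
#' sum `R = R1 + R2 = U L U'` with `P = L^(-1/2) U'` so that
#' `P R P' = I`; eigendecomposes `S1 = P R1 P' = B L1 B'` (eigenvalues
#' descending). Because `S1 + S2 = I`, the same basis diagonalizes `S2`
#' with `L2 = 1 - L1`, so the class-2 bank is the class-1 bank in reverse
#' order. The filter banks are `W1 = B1' P` (rows are filters) and
#' `W2 = B2' P`; the feature filters are the top two rows of each. A
#' Fisher read-out over the 4 log-variance features is fitted on the
#' training trials.
#'
#' A strict mode with the whitening exponent -1 instead of -1/2 is kept
#' behind `whiten_exponent` for auditability; only the default satisfies
#' `P R P' = I`. Shrinkage toward the scaled identity is applied to `R`
#' only when it is numerically rank-deficient, so the whitening identity
#' holds to machine precision on well-conditioned problems.
#'
#' @param train an `EpochSet` (band-filtered and windowed upstream) with at
#'   least 2 trials per class.
#' @param n_pairs filters kept per class (default 2, giving 4 features).
#' @param whiten_exponent `-0.5` (default, true whitening) or `-1`.
#' @param reg relative shrinkage used when the composite covariance is
#'   rank-deficient.
#' @return a `CspModel`.
#' @export
csp_fit <- function(train, n_pairs = 2L, whiten_exponent = -0.5,
                    reg = 1e-6) {
  validate_epoch_set(train)
  if (!all(train$labels %in% c(1L, -1L)))
    stop("CSP is two-class: labels must be +1/-1 (select first)")
  i1 <- which(train$labels == 1L); i2 <- which(train$labels == -1L)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need at least 2 trials per class")
  nc <- n_channels(train)
  if (n_pairs > nc) stop("n_pairs too large for the channel count")
  mean_cov <- function(idx) {
    S <- matrix(0, nc, nc)
    for (i in idx) S <- S + normalized_covariance(train$data[i, , ])
    S / length(idx)
  }
  R1 <- mean_cov(i1); R2 <- mean_cov(i2)
  R <- R1 + R2
  es <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(es$values) <= max(es$values) * 1e-10) {
    R <- R + reg * (sum(diag(R)) / nc) * diag(nc)
    es <- eigen((R + t(R)) / 2, symmetric = TRUE)
    if (min(es$values) <= 0) stop("composite covariance is rank-deficient")
  }
  P <- diag(es$values^whiten_exponent, nc) %*% t(es$vectors)
  S1 <- P %*% R1 %*% t(P)
  eb <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)  # descending
  B1 <- fix_signs(eb$vectors)
  lambda1 <- eb$values
  B2 <- B1[, rev(seq_len(nc)), drop = FALSE]
  W1 <- t(B1) %*% P
  W2 <- t(B2) %*% P
  sel <- rbind(W1[seq_len(n_pairs), , drop = FALSE],
               W2[seq_len(n_pairs), , drop = FALSE])
  model <- structure(
    list(W1 = W1, W2 = W2, selected = sel, n_pairs = as.integer(n_pairs),
         lambda1 = lambda1, lambda2 = rev(1 - lambda1),
         R1 = R1, R2 = R2, P = P, readout = NULL,
         srate = train$srate, t0_ms = train$t0_ms,
         channels = train$channel_names),
    class = "CspModel")
  feats <- t(apply(train$data, 1L, function(tr) csp_features(model, tr)))
  model$readout <- fda_fit(feats, train$labels)
  model
}

#' CSP log-variance features of one trial
#'
#' Projects the trial through the `2 * n_pairs` selected spatial filters
#' and returns `log(var_i / sum(var))` per projected row (population
#' variance about the row mean). The exponentials of the features sum to
#' one; the features are invariant to a global positive rescaling of the
#' trial.
#'
#' @param model a fitted `CspModel`.
#' @param trial matrix `[n_channels x n_samples]`.
#' @return numeric feature vector of length `2 * n_pairs`.
#' @export
csp_features <- function(model, trial) {
  trial <- as.matrix(trial)
  if (nrow(trial) != ncol(model$selected))
    stop("trial channel count does not match the fitted model")
  Z <- model$selected %*% trial
  v <- apply(Z, 1L, function(z) mean(z^2) - mean(z)^2)
  if (any(v <= 0)) stop("zero projected variance: features undefined")
  log(v / sum(v))
}

#' Predict labels and decision values with a CSP model
#'
#' Each trial's log-variance feature vector is projected by the fitted
#' Fisher read-out to a scalar `F2`; labels follow the same sign and
#' tie-break contract as [dcpm_predict()].
#'
#' @param model a fitted `CspModel`.
#' @param test an `EpochSet` with matching channels/samples.
#' @return list with `labels`, `decision_values` (`F2`) and `features`.
#' @export
csp_predict <- function(model, test) {
  validate_epoch_set(test)
  feats <- t(apply(test$data, 1L, function(tr) csp_features(model, tr)))
  F2 <- fda_project(model$readout, feats)
  list(labels = ifelse(F2 >= 0, 1L, -1L), decision_values = as.numeric(F2),
       features = feats)
}
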