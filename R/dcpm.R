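# ---- Discriminative Canonical Pattern Matching (DCPM) -----------------------
# Template-based single-trial ERP classifier: a discriminative spatial
# projection (DSP) solving a between- vs within-class generalized
# eigenproblem, per-class canonical correlation projections between the
# projected class template and the projected training trials, and three
# pattern-matching features (2-D correlation against each template in the
# DSP space, 2-D correlation and Euclidean distance in the CCA-rotated
# space), read out by a Fisher discriminant.

#' Per-class trial-average templates
#'
#' @param train an `EpochSet` containing both classes (+1 and -1).
#' @return list with `X1` (label +1 / T400) and `X2` (label -1 / T600),
#'   each `[n_channels x n_samples]`.
#' @export
class_templates <- function(train) {
  validate_epoch_set(train)
  i1 <- which(train$labels == 1L); i2 <- which(train$labels == -1L)
  if (length(i1) == 0L || length(i2) == 0L)
    stop("both classes (+1 and -1) must be present")
  list(X1 = apply(train$data[i1, , , drop = FALSE], c(2L, 3L), mean),
       X2 = apply(train$data[i2, , , drop = FALSE], c(2L, 3L), mean))
}

# symmetric inverse square root with relative eigenvalue floor
inv_sqrt_sym <- function(S, tol = 1e-12) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(es$values, tol * max(es$values, tol))
  es$vectors %*% diag(1 / sqrt(v), length(v)) %*% t(es$vectors)
}

# deterministic sign convention: largest-magnitude entry of each column > 0
fix_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Discriminative spatial projection (DSP)
#'
#' Solves the generalized eigenproblem `Sw^-1 SB u = lambda u` where
#' `SB = (X1 - X2)(X1 - X2)'` is the between-class scatter of the two class
#' templates and `Sw = sigma1^2 + sigma2^2` sums the within-class scatter
#' of the trials about their templates (1/M per class). `Sw` is
#' regularized by `reg * trace(Sw)/Nc * I` before inversion. Eigenvectors
#' are returned in descending eigenvalue order, unit-normalized, with a
#' deterministic sign convention (largest-magnitude entry positive).
#'
#' @param train an `EpochSet` with both classes.
#' @param n_components number of leading filters to keep; `NULL` keeps all
#'   (use [dcpm_fit()] for the automatic rule).
#' @param reg relative ridge added to `Sw` (default 1e-6); 0 disables.
#' @return list with `U` `[n_channels x n_components]`, `lambda` (all
#'   eigenvalues, descending) and `Sw`, `SB`.
#' @export
dsp_projection <- function(train, n_components = NULL, reg = 1e-6) {
  tmpl <- class_templates(train)
  i1 <- which(train$labels == 1L); i2 <- which(train$labels == -1L)
  nc <- n_channels(train)
  D <- tmpl$X1 - tmpl$X2
  SB <- D %*% t(D)
  scatter <- function(idx, Xhat) {
    S <- matrix(0, nc, nc)
    for (i in idx) {
      E <- train$data[i, , ] - Xhat
      S <- S + E %*% t(E)
    }
    S / length(idx)
  }
  Sw <- scatter(i1, tmpl$X1) + scatter(i2, tmpl$X2)
  if (reg > 0) Sw <- Sw + reg * (sum(diag(Sw)) / nc) * diag(nc)
  W <- inv_sqrt_sym(Sw)
  es <- eigen(W %*% SB %*% W, symmetric = TRUE)
  lambda <- pmax(es$values, 0)
  U <- W %*% es$vectors
  U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
  U <- fix_signs(U)
  if (!is.null(n_components)) {
    if (n_components < 1L || n_components > nc)
      stop("n_components must be in 1..n_channels")
    U <- U[, seq_len(n_components), drop = FALSE]
  }
  list(U = U, lambda = lambda, Sw = Sw, SB = SB)
}

# automatic component count: eigenvalues >= 1% of the largest, capped at 10
default_n_components <- function(lambda, cap = 10L) {
  if (max(lambda) <= 0) return(1L)
  min(max(sum(lambda >= 0.01 * lambda[1L]), 1L), cap)
}

#' Canonical correlation analysis of two matrix views
#'
#' Finds projection pairs `(P, Q)` maximizing the correlation between the
#' columns of `A %*% P` and `B %*% Q`, via SVD of the whitened
#' cross-covariance. Projections are orthonormal in the whitened metric;
#' correlations are returned sorted descending and clipped to `[0, 1]`.
#'
#' @param A,B matrices sharing the sample (row) dimension.
#' @param n_comp number of pairs; default all available (min of the
#'   whitened ranks).
#' @return list with `P`, `Q` (columns are projection vectors) and
#'   `correlations`.
#' @export
cca_projection <- function(A, B, n_comp = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must share the sample dimension")
  n <- nrow(A)
  Ac <- scale(A, center = TRUE, scale = FALSE)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  if (all(abs(Ac) < 1e-14) || all(abs(Bc) < 1e-14))
    stop("degenerate: zero-variance input to CCA")
  Caa <- crossprod(Ac) / n; Cbb <- crossprod(Bc) / n
  Cab <- crossprod(Ac, Bc) / n
  Wa <- inv_sqrt_sym(Caa); Wb <- inv_sqrt_sym(Cbb)
  sv <- svd(Wa %*% Cab %*% Wb)
  r <- if (is.null(n_comp)) length(sv$d) else min(n_comp, length(sv$d))
  list(P = fix_signs(Wa %*% sv$u[, seq_len(r), drop = FALSE]),
       Q = fix_signs(Wb %*% sv$v[, seq_len(r), drop = FALSE]),
       correlations = pmin(pmax(sv$d[seq_len(r)], 0), 1))
}

# 2-D Pearson correlation between two equally shaped matrices
corr2 <- function(A, B) {
  a <- as.vector(A) - mean(A); b <- as.vector(B) - mean(B)
  da <- sqrt(sum(a^2)); db <- sqrt(sum(b^2))
  if (da == 0 || db == 0) stop("degenerate: constant matrix in corr2")
  sum(a * b) / (da * db)
}

#' Fit a DCPM model
#'
#' Fits, on the training set only: the two class templates, the DSP
#' projection (reduced to `n_components` filters), one CCA projection pair
#' per class between the DSP-projected class template (tiled over trials)
#' and the DSP-projected training trials of that class, and a Fisher
#' discriminant read-out over the training trials' 3-dimensional
#' pattern-matching feature vectors.
#'
#' @param train an `EpochSet` (band-filtered and windowed upstream) with
#'   at least 2 trials per class.
#' @param n_components DSP filters kept; `NULL` uses the automatic rule
#'   (eigenvalues >= 1% of the largest, capped at 10).
#' @param n_cca CCA pairs used for the template-matching features; `NULL`
#'   uses all available.
#' @param use_full_u use the unreduced DSP matrix for the first
#'   (correlation-in-DSP-space) feature instead of the reduced one.
#' @param reg relative regularization of the within-class scatter.
#' @return a `DcpmModel`.
#' @export
dcpm_fit <- function(train, n_components = NULL, n_cca = NULL,
                     use_full_u = FALSE, reg = 1e-6) {
  validate_epoch_set(train)
  if (!all(train$labels %in% c(1L, -1L)))
    stop("DCPM is two-class: labels must be +1/-1 (select first)")
  if (sum(train$labels == 1L) < 2L || sum(train$labels == -1L) < 2L)
    stop("need at least 2 trials per class")
  tmpl <- class_templates(train)
  dsp <- dsp_projection(train, n_components = NULL, reg = reg)
  k <- if (is.null(n_components)) default_n_components(dsp$lambda)
       else n_components
  if (k < 1L || k > n_channels(train))
    stop("n_components must be in 1..n_channels")
  Uhat <- dsp$U[, seq_len(k), drop = FALSE]
  # per-class CCA between projected template (tiled) and projected trials
  cca <- lapply(c(1L, -1L), function(lbl) {
    Xhat <- if (lbl == 1L) tmpl$X1 else tmpl$X2
    Tm <- t(Xhat) %*% Uhat
    idx <- which(train$labels == lbl)
    A <- do.call(rbind, rep(list(Tm), length(idx)))
    B <- do.call(rbind, lapply(idx, function(i) t(train$data[i, , ]) %*% Uhat))
    cca_projection(A, B, n_comp = n_cca)
  })
  model <- structure(
    list(templates = tmpl, U = dsp$U, Uhat = Uhat, lambda = dsp$lambda,
         cca = list(class1 = cca[[1L]], class2 = cca[[2L]]),
         use_full_u = use_full_u, readout = NULL,
         srate = train$srate, t0_ms = train$t0_ms,
         channels = train$channel_names),
    class = "DcpmModel")
  feats <- t(apply(train$data, 1L, function(tr) dcpm_features(model, tr)))
  model$readout <- fda_fit(feats, train$labels)
  model
}

#' DCPM pattern-matching features of one trial
#'
#' Returns the 3-vector of class-1-minus-class-2 differences of: the 2-D
#' correlation between projected template and projected trial in DSP
#' space, the same correlation after the per-class CCA rotation, and the
#' negated Euclidean (Frobenius) distance in the CCA-rotated space.
#'
#' @param model a fitted `DcpmModel`.
#' @param trial matrix `[n_channels x n_samples]` matching the model.
#' @return numeric length-3 feature vector.
#' @export
dcpm_features <- function(model, trial) {
  trial <- as.matrix(trial)
  if (nrow(trial) != nrow(model$templates$X1) ||
      ncol(trial) != ncol(model$templates$X1))
    stop("trial shape does not match the fitted model")
  U1 <- if (model$use_full_u) model$U else model$Uhat
  Yt <- t(trial)
  rho <- matrix(0, 3L, 2L)
  for (k in 1:2) {
    Xhat <- if (k == 1L) model$templates$X1 else model$templates$X2
    Qk <- if (k == 1L) model$cca$class1$Q else model$cca$class2$Q
    rho[1L, k] <- corr2(t(Xhat) %*% U1, Yt %*% U1)
    Tq <- t(Xhat) %*% model$Uhat %*% Qk
    Yq <- Yt %*% model$Uhat %*% Qk
    rho[2L, k] <- corr2(Tq, Yq)
    rho[3L, k] <- -sqrt(sum((Tq - Yq)^2))
  }
  rho[, 1L] - rho[, 2L]
}

#' Predict labels and decision values with a DCPM model
#'
#' Each trial's 3-feature vector is projected by the fitted Fisher
#' read-out to a scalar decision value `F1`; the standalone label is
#' `+1` when `F1 > 0`, `-1` when `F1 < 0`, and ties (`F1 == 0`) break
#' deterministically to `+1`. `decision = "sumrho"` instead sums the three
#' raw features (direct template comparison, no read-out).
#'
#' @param model a fitted `DcpmModel`.
#' @param test an `EpochSet` with matching channels/samples.
#' @param decision `"fda"` (default) or `"sumrho"`.
#' @return list with `labels` (+1/-1), `decision_values` (`F1`) and
#'   `features` (`n x 3`).
#' @export
dcpm_predict <- function(model, test, decision = c("fda", "sumrho")) {
  decision <- match.arg(decision)
  validate_epoch_set(test)
  feats <- t(apply(test$data, 1L, function(tr) dcpm_features(model, tr)))
  F1 <- if (decision == "fda") fda_project(model$readout, feats)
        else rowSums(feats)
  list(labels = ifelse(F1 >= 0, 1L, -1L), decision_values = as.numeric(F1),
       features = feats)
}
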