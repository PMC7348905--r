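# independent re-implementations used as oracles
oracle_corr2 <- function(A, B) {
  a <- c(A) - mean(c(A)); b <- c(B) - mean(c(B))
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
oracle_dist <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + (A[i, j] - B[i, j])^2
  sqrt(s)
}
rayleigh <- function(u, SB, Sw) as.numeric(t(u) %*% SB %*% u) /
  as.numeric(t(u) %*% Sw %*% u)

test_that("class templates are per-class trial means", {
  x <- tiny_epochs(2, 2, 12, labels = c(1L, -1L))
  tm <- class_templates(x)
  expect_equal(tm$X1, x$data[1, , ])
  expect_equal(tm$X2, x$data[2, , ])
  # duplicating trials leaves the template unchanged
  dup <- epoch_set(x$data[c(1, 1, 2, 2), , ], c(1L, 1L, -1L, -1L),
                   x$srate, x$t0_ms, x$channel_names)
  expect_equal(class_templates(dup)$X1, tm$X1)
  # two-pass summation oracle
  y <- tiny_epochs(40, 3, 20, labels = rep(c(1L, -1L), 20), seed = 5)
  i1 <- which(y$labels == 1L)
  acc <- matrix(0, 3, 20)
  for (i in i1) acc <- acc + y$data[i, , ]
  expect_equal(class_templates(y)$X1, acc / length(i1), tolerance = 1e-12)
  expect_error(class_templates(tiny_epochs(2, 2, 5, labels = c(1L, 1L))),
               "both classes")
})

test_that("DSP returns zero eigenvalues for identical class distributions", {
  base <- tiny_epochs(6, 3, 30, labels = rep(1L, 6), seed = 2)
  x <- epoch_set(base$data[c(1:6, 1:6), , ], c(rep(1L, 6), rep(-1L, 6)),
                 base$srate, base$t0_ms, base$channel_names)
  d <- dsp_projection(x)
  expect_lt(max(d$lambda), 1e-10)
})

test_that("DSP recovers a planted single-channel contrast", {
  # class templates differ only in channel 1; isotropic within-class noise
  ns <- 50
  kern <- sin(seq(0, 2 * pi, length.out = ns))
  dat <- with_test_seed(21, {
    d <- array(rnorm(40 * 2 * ns, sd = 0.5), c(40, 2, ns))
    for (i in 1:20) d[i, 1, ] <- d[i, 1, ] + kern
    for (i in 21:40) d[i, 1, ] <- d[i, 1, ] - kern
    d
  })
  x <- epoch_set(dat, c(rep(1L, 20), rep(-1L, 20)), 100, 0, c("A", "B"))
  d <- dsp_projection(x)
  u <- d$U[, 1]
  expect_gt(abs(u[1]), 0.98)
  expect_lt(abs(u[2]), 0.2)
  # 1-degree grid-search oracle over directions
  ang <- seq(0, 179, by = 1) * pi / 180
  quot <- vapply(ang, function(a)
    rayleigh(c(cos(a), sin(a)), d$SB, d$Sw), 0)
  best <- c(cos(ang[which.max(quot)]), sin(ang[which.max(quot)]))
  expect_gt(abs(sum(best * u)), 0.999)
})

test_that("the leading DSP filter maximizes the Rayleigh quotient", {
  x <- tiny_epochs(30, 4, 40, labels = rep(c(1L, -1L), 15), seed = 31)
  # plant a weak contrast so SB is non-trivial
  x$data[x$labels == 1L, 2, ] <- x$data[x$labels == 1L, 2, ] + 0.3
  d <- dsp_projection(x)
  q0 <- rayleigh(d$U[, 1], d$SB, d$Sw)
  dirs <- with_test_seed(32, matrix(rnorm(4 * 10000), 4))
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  qs <- colSums((t(dirs) %*% d$SB) * t(dirs)) /
    colSums((t(dirs) %*% d$Sw) * t(dirs))
  expect_gte(q0, max(qs) - 1e-9)
  # eigenvalues are non-negative and sum to trace(Sw^-1 SB)
  expect_true(all(d$lambda >= 0))
  expect_equal(sum(d$lambda), sum(diag(solve(d$Sw, d$SB))), tolerance = 1e-6)
})

test_that("CCA matches the SVD-of-whitened-cross-covariance structure", {
  A <- with_test_seed(41, matrix(rnorm(200 * 4), 200))
  B <- with_test_seed(42, A %*% matrix(rnorm(16), 4) +
                        0.5 * matrix(rnorm(200 * 4), 200))
  cc <- cca_projection(A, B)
  expect_true(all(diff(cc$correlations) <= 1e-12))
  expect_true(all(cc$correlations >= 0 & cc$correlations <= 1))
  # independent oracle: stats::cancor canonical correlations
  oracle <- stats::cancor(A, B)$cor
  expect_equal(cc$correlations, oracle, tolerance = 1e-8)
  # realized correlations of the projected columns agree too
  for (j in 1:2)
    expect_equal(as.numeric(abs(stats::cor(A %*% cc$P[, j], B %*% cc$Q[, j]))),
                 cc$correlations[j], tolerance = 1e-8)
  # B = A gives perfect correlations; orthogonal construction near zero
  cs <- cca_projection(A, A)
  expect_equal(cs$correlations, rep(1, 4), tolerance = 1e-10)
  Ao <- cbind(sin(2 * pi * (1:100) / 10))
  Bo <- cbind(cos(2 * pi * (1:100) / 10))
  expect_lt(cca_projection(Ao, Bo)$correlations[1], 0.05)
  expect_error(cca_projection(matrix(1, 10, 2), B[1:10, ]), "degenerate")
})

test_that("DCPM features match brute-force recomputation and its symmetries", {
  cfg <- quick_cfg()
  x <- simulate_subject(cfg)
  pre <- select_epochs(
    baseline_correct(timingbci:::filter_band(x, canonical_bands()$delta)),
    channels = central_channels(), window = window_spec(500, 850))
  m <- dcpm_fit(pre)
  trial <- pre$data[3, , ]
  f <- dcpm_features(m, trial)
  # brute-force recomputation with independent corr2/dist
  Y <- t(trial)
  rho <- matrix(0, 3, 2)
  for (k in 1:2) {
    Xh <- if (k == 1) m$templates$X1 else m$templates$X2
    Q <- if (k == 1) m$cca$class1$Q else m$cca$class2$Q
    rho[1, k] <- oracle_corr2(t(Xh) %*% m$Uhat, Y %*% m$Uhat)
    rho[2, k] <- oracle_corr2(t(Xh) %*% m$Uhat %*% Q, Y %*% m$Uhat %*% Q)
    rho[3, k] <- -oracle_dist(t(Xh) %*% m$Uhat %*% Q, Y %*% m$Uhat %*% Q)
  }
  expect_equal(f, rho[, 1] - rho[, 2], tolerance = 1e-8)
  # rho bounds: correlations in [-1,1] implies features in [-2,2]
  expect_true(all(abs(f[1:2]) <= 2))
  # the class-1 template itself is matched perfectly by its own template
  f1 <- dcpm_features(m, m$templates$X1)
  expect_gt(f1[1], 0)
  # swapping the two class templates (and CCA pairs) negates all features
  ms <- m
  ms$templates <- list(X1 = m$templates$X2, X2 = m$templates$X1)
  ms$cca <- list(class1 = m$cca$class2, class2 = m$cca$class1)
  expect_equal(dcpm_features(ms, trial), -f, tolerance = 1e-10)
  expect_error(dcpm_features(m, trial[, 1:10]), "shape")
})

test_that("DCPM learns a planted low-frequency effect and stays at chance on null data", {
  x <- simulate_subject(quick_cfg(supp_depth = 0))
  r <- cross_validate(x, "dcpm", k = 5, seed = 1)
  n <- n_trials(select_epochs(x, labels = c(1, -1)))
  correct <- round(r$mean_acc * n)
  expect_lt(stats::binom.test(correct, n, 0.5, "greater")$p.value, 0.01)
  xn <- simulate_subject(quick_cfg(erp_amp_uv = 0, supp_depth = 0, seed = 55))
  rn <- cross_validate(xn, "dcpm", k = 5, seed = 1)
  expect_lt(rn$mean_acc, 0.7)
  expect_gt(rn$mean_acc, 0.3)
})

test_that("DCPM predictions are scale invariant and honor the tie contract", {
  cfg <- quick_cfg(seed = 7)
  x <- simulate_subject(cfg)
  pre <- select_epochs(
    baseline_correct(timingbci:::filter_band(x, canonical_bands()$delta)),
    channels = central_channels(), window = window_spec(500, 850))
  tr_idx <- c(1:15, 21:35); te_idx <- c(16:20, 36:40)
  train <- timingbci:::subset_trials(pre, tr_idx)
  test <- timingbci:::subset_trials(pre, te_idx)
  m <- dcpm_fit(train)
  p <- dcpm_predict(m, test)
  # global positive rescaling of train and test leaves predictions unchanged
  scale_set <- function(s, f) epoch_set(s$data * f, s$labels, s$srate,
                                        s$t0_ms, s$channel_names)
  m10 <- dcpm_fit(scale_set(train, 10))
  p10 <- dcpm_predict(m10, scale_set(test, 10))
  expect_identical(p$labels, p10$labels)
  # accuracy equals the confusion-matrix count
  cm <- table(factor(p$labels, c(-1, 1)), factor(test$labels, c(-1, 1)))
  expect_equal(mean(p$labels == test$labels), sum(diag(cm)) / sum(cm))
  # boundary component counts run
  expect_s3_class(dcpm_fit(train, n_components = n_channels(train)),
                  "DcpmModel")
  expect_error(dcpm_fit(train, n_components = 0), "n_components")
})
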