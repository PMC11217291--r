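test_that("rank-1 data put all variance on PC1", {
  set.seed(1)
  direction <- rnorm(50)
  mat <- outer(seq(-2, 2, length.out = 8), direction)
  mat <- mat + matrix(rnorm(8 * 50, sd = 1e-12), 8)
  pca <- fit_pca_standardized(mat, n_components = 2L)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-6)
})

test_that("PCA loadings match the analytic eigenvector of a known covariance", {
  set.seed(2)
  n <- 1e4
  rho <- 0.6
  z <- matrix(rnorm(2 * n), n)
  x <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  pca <- fit_pca_standardized(x, 2L)
  # standardised bivariate normal: first eigenvector is (1,1)/sqrt(2)
  ang <- acos(abs(sum(pca$loadings[, 1] * c(1, 1) / sqrt(2)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("scores are uncorrelated and reconstruct the standardised data", {
  set.seed(3)
  mat <- matrix(rnorm(12 * 40), 12)
  k <- 11L
  pca <- fit_pca_standardized(mat, k)
  cv <- crossprod(pca$scores) / (nrow(mat) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  z <- scale(mat)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(unclass(z), recon, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fit_pca_standardized(mat, 12L), "n_components")
})

test_that("constant spectral channels are zeroed and flagged", {
  set.seed(4)
  mat <- matrix(rnorm(10 * 20), 10)
  mat[, 5] <- 3
  pca <- fit_pca_standardized(mat, 3L)
  expect_identical(pca$n_constant, 1L)
  expect_equal(pca$loadings[5, ] %*% t(pca$scores) * 0,
               matrix(0, 1, 10), ignore_attr = TRUE)
})

test_that("MLR coefficients match the normal-equations oracle", {
  set.seed(5)
  scores <- matrix(rnorm(15 * 10), 15)
  y <- rnorm(15)
  fit <- mlr_on_scores(scores, y)
  X <- cbind(1, scores)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_identical(fit$df, 4L)
  # and the t p-values use df = n - k - 1
  sm <- fit$coefficients
  expect_equal(sm$p.value, 2 * pt(-abs(sm$statistic), 4), tolerance = 1e-12)
})

test_that("an exactly linear response gives zero residuals and tiny p-values", {
  set.seed(6)
  scores <- matrix(rnorm(20 * 3), 20)
  y <- 1 + scores %*% c(2, -1, 0.5)
  fit <- mlr_on_scores(scores, as.numeric(y))
  expect_lt(max(abs(residuals(fit$fit))), 1e-9)
  expect_true(all(fit$coefficients$p.value < 1e-8))
})

test_that("type-I error of the coefficient t-test is calibrated", {
  set.seed(7)
  hits <- 0L
  n_sims <- 500L
  scores <- matrix(rnorm(15 * 10), 15)
  for (i in seq_len(n_sims)) {
    y <- rnorm(15)
    fit <- mlr_on_scores(scores, y)
    p1 <- fit$coefficients$p.value[2] # first non-intercept coefficient
    hits <- hits + (p1 < 0.05)
  }
  expect_lt(abs(hits / n_sims - 0.05), 0.02)
})

test_that("partial leverage obeys the Frisch-Waugh identity", {
  set.seed(8)
  scores <- matrix(rnorm(15 * 10), 15)
  y <- rnorm(15)
  fit <- mlr_on_scores(scores, y)
  for (j in c(1L, 5L, 10L)) {
    pl <- partial_leverage(fit, j)
    expect_equal(attr(pl, "slope"),
                 fit$coefficients$estimate[j + 1L], tolerance = 1e-9)
  }
  # predictors orthogonal to each other and to the intercept:
  # x-residuals equal the centred predictor
  q <- qr.Q(qr(cbind(1, matrix(rnorm(12 * 3), 12))))[, -1]
  fit_o <- mlr_on_scores(q, rnorm(12))
  pl1 <- partial_leverage(fit_o, 1L)
  expect_equal(pl1$x_residual, q[, 1] - mean(q[, 1]), tolerance = 1e-9)
})

test_that("a planted null coefficient has partial slope within 2 se of zero", {
  set.seed(9)
  scores <- matrix(rnorm(60 * 4), 60)
  y <- scores[, 1] * 2 + scores[, 2] * -1 + rnorm(60, sd = 0.5)
  fit <- mlr_on_scores(scores, y)
  pl <- partial_leverage(fit, 4L)
  se <- fit$coefficients$std.error[5L]
  expect_lt(abs(attr(pl, "slope")), 2 * se)
})

test_that("significant-PC selection applies the two-sided 0.05 screen", {
  fake <- structure(list(coefficients = tibble::tibble(
    term = c("(Intercept)", paste0("PC", 1:10)),
    estimate = 0, std.error = 1, statistic = 0,
    p.value = c(0.5, 0.4, 0.026, 0.9, 0.2, 0.003, 0.6, 0.008, 0.7, 0.3, 0.055)
  )), class = "pc_mlr")
  expect_identical(select_significant_pcs(fake), c(2L, 5L, 7L))
  fake$coefficients$p.value <- c(0.5, rep(0.5, 10))
  expect_identical(select_significant_pcs(fake), integer())
  expect_identical(select_significant_pcs(fake, alpha = 1), 1:10)
})

test_that("loading annotation matches peaks and reports unassigned bands", {
  axis <- as.numeric(test_axis())
  loading <- rep(0, length(axis))
  loading[which.min(abs(axis - 1007))] <- 1
  ann <- annotate_loading(loading, axis, top_n = 1L)
  expect_match(ann$assignment[1], "phenylalanine")
  loading2 <- rep(0, length(axis))
  loading2[which.min(abs(axis - 1700))] <- -1
  ann2 <- annotate_loading(loading2, axis, top_n = 1L)
  expect_identical(ann2$assignment[1], "unassigned")
  # a nucleus-minus-protein contrast names the pyrimidine band
  lib <- test_library()
  contrast <- lib$components[, "nucleus"] - lib$components[, "protein"]
  ann3 <- annotate_loading(contrast, axis, top_n = 5L)
  expect_true(any(grepl("pyrimidine", ann3$assignment)))
})

test_that("the screen recovers a planted single-contrast direction", {
  lib <- test_library()
  hits <- 0L
  n_runs <- 100L
  pp <- default_phenotype_params()
  # one contrast only: nucleic-acid weight rises with the phenotype code
  for (nm in names(pp)) {
    pp[[nm]]$component_weights$mean <- c(1.0, 1.0, 0.5, 0.7)
    pp[[nm]]$component_weights$sd <- c(0.06, 0.08, 0.04, 0.056)
  }
  pp$HT29$component_weights$mean[1] <- 0.8
  pp$T84$component_weights$mean[1] <- 1.2
  contrast <- lib$components[, "nucleus"]
  for (s in seq_len(n_runs)) {
    sim <- simulate_cell_spectra(5, seed = 5000 + s, params_by_type = pp,
                                 library = lib)
    pca <- fit_pca_standardized(cell_spectra_matrix(sim$records), 10L)
    fit <- mlr_on_scores(pca$scores, sim$records$label)
    sel <- select_significant_pcs(fit)
    align <- abs(crossprod(lib$components[, "nucleus"] - rowMeans(lib$components),
                           pca$loadings))
    best_aligned <- which.max(align)
    if (best_aligned %in% sel) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
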