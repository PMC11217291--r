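labels_555 <- factor(rep(c("HT29", "RKO", "T84"), each = 5))

test_that("the intercept-only fit reproduces the closed-form null", {
  fit <- fit_mlor(data.frame()[seq_along(labels_555), , drop = FALSE],
                  labels_555)
  expect_equal(fit$log_likelihood, 15 * log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(fit$fitted_probabilities[1, ]), rep(1 / 3, 3),
               tolerance = 1e-4)
  expect_identical(fit$k, 2L)
})

test_that("null_log_likelihood covers balanced, degenerate and binary cases", {
  expect_equal(null_log_likelihood(labels_555), 15 * log(1 / 3))
  expect_equal(null_log_likelihood(rep("A", 7)), 0)
  expect_equal(null_log_likelihood(c("A", "B")), 2 * log(1 / 2))
})

test_that("a separating predictor sets the separation flag with perfect accuracy", {
  y <- factor(rep(c("a", "b"), each = 6))
  X <- data.frame(x = c(rnorm(6, -3, 0.1), rnorm(6, 3, 0.1)))
  fit <- fit_mlor(X, y)
  expect_true(fit$separation)
  expect_equal(training_accuracy(fit), 1)
})

test_that("the fitted likelihood matches an independent optimiser oracle", {
  set.seed(21)
  X <- matrix(rnorm(15 * 2), 15)
  colnames(X) <- c("a", "b")
  y <- labels_555
  fit <- fit_mlor(X, y)
  # generic-optimiser oracle on the same likelihood (standardised scale)
  Xs <- scale(X)
  opt <- optim(rep(0, 2 * 3), function(b) {
    -mlor_loglik(b, Xs, as.integer(y), 3L)
  }, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-4)
})

test_that("class probabilities sum to one and predictions are scale-invariant", {
  set.seed(22)
  X <- matrix(rnorm(15 * 3), 15)
  colnames(X) <- c("a", "b", "c")
  fit <- fit_mlor(X, labels_555)
  expect_equal(rowSums(fit$fitted_probabilities), rep(1, 15),
               tolerance = 1e-9)
  X2 <- sweep(sweep(X, 2, c(10, 0.1, 3), "*"), 2, c(1, -5, 2), "+")
  colnames(X2) <- colnames(X)
  fit2 <- fit_mlor(X2, labels_555)
  expect_equal(fit2$fitted_probabilities, fit$fitted_probabilities,
               tolerance = 1e-6)
  expect_identical(predict_mlor(fit, X), fit$predicted)
})

test_that("exactly aliased predictors are detected and dropped", {
  set.seed(23)
  D <- rnorm(15, 0.15, 0.01)
  X <- data.frame(D = D, ri_mean = 1.3342 + 0.19 * D, phi = rnorm(15))
  expect_message(fit <- fit_mlor(X, labels_555), "aliased")
  expect_identical(fit$dropped, "ri_mean")
  expect_identical(fit$p, 2L)
})

test_that("AIC uses the k = (G-1)(p+1) convention", {
  fit <- list(k = 6L, log_likelihood = -0.7145)
  expect_equal(compute_aic(fit), 13.429)
  fit_null <- list(k = 2L, log_likelihood = 15 * log(1 / 3))
  expect_equal(compute_aic(fit_null), 36.958, tolerance = 1e-3)
  expect_equal(compute_aic(list(k = 0L, log_likelihood = 0)), 0)
})

test_that("the likelihood-ratio test reproduces reported pairs and limits", {
  lrt <- likelihood_ratio_test(
    list(log_likelihood = -0.7145, k = 6L, G = 3L,
         labels = labels_555))
  expect_identical(lrt$df, 4L)
  expect_equal(lrt$p.value, 2.387e-6, tolerance = 1e-3)
  # lnL equal to the null: statistic 0, p 1
  lrt0 <- likelihood_ratio_test(
    list(log_likelihood = 15 * log(1 / 3), k = 4L, G = 3L,
         labels = labels_555))
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p.value, 1)
  # chi-square tail at df = 2 has the closed form exp(-x/2)
  for (x in c(0.5, 2, 7)) {
    expect_equal(pchisq(x, 2, lower.tail = FALSE), exp(-x / 2),
                 tolerance = 1e-12)
  }
  expect_error(likelihood_ratio_test(
    list(log_likelihood = -20, k = 4L, G = 3L, labels = labels_555)),
    "negative")
})

test_that("LOOCV is perfect on separated clusters and chance on permuted labels", {
  set.seed(24)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE)
  X <- centers[rep(1:3, each = 5), ] + matrix(rnorm(30, sd = 1), 15)
  colnames(X) <- c("u", "v")
  res <- loocv_accuracy(X, labels_555)
  expect_equal(res$accuracy, 1)
  # under label permutation with uninformative features LOOCV shows no
  # optimistic bias: accuracy at or below the 1/3 chance level (balanced
  # folds leave the held-out class in the minority, a known pessimism)
  set.seed(25)
  accs <- vapply(1:60, function(i) {
    Xn <- matrix(rnorm(15), 15, 1)
    colnames(Xn) <- "x"
    loocv_accuracy(Xn, sample(labels_555))$accuracy
  }, numeric(1))
  expect_lt(mean(accs), 1 / 3 + 0.05)
  expect_error(loocv_accuracy(matrix(rnorm(3), 3, 1), factor(c("a", "b", "c"))),
               "G \\+ 1")
})

test_that("adding predictors never lowers the likelihood and AIC can invert", {
  set.seed(26)
  X <- matrix(rnorm(15 * 3), 15)
  colnames(X) <- c("a", "b", "c")
  y <- labels_555
  lnls <- vapply(1:3, function(p) {
    fit_mlor(X[, seq_len(p), drop = FALSE], y)$log_likelihood
  }, numeric(1))
  expect_true(all(diff(lnls) > -1e-6))
})

test_that("compare_models reports consistent rows and marks the AIC minimum", {
  set.seed(27)
  good <- matrix(c(rnorm(5, -4), rnorm(5, 0), rnorm(5, 4)), 15, 1)
  colnames(good) <- "x"
  noise <- matrix(rnorm(15), 15, 1)
  colnames(noise) <- "n"
  cmp <- compare_models(
    list(informative = good, uninformative = noise, twice = good),
    labels_555, loocv = FALSE)
  expect_equal(nrow(cmp), 3L)
  expect_identical(cmp$AIC[cmp$model == "informative"],
                   cmp$AIC[cmp$model == "twice"])
  expect_true(cmp$best[which.min(cmp$AIC)])
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$log_likelihood, tolerance = 1e-9)
  expect_equal(cmp$LRT_df, cmp$k - 2L)
  # intercept-only row
  cmp0 <- compare_models(list(null = data.frame()[1:15, , drop = FALSE]),
                         labels_555, loocv = FALSE)
  expect_equal(cmp0$AIC, 2 * 2 - 2 * 15 * log(1 / 3), tolerance = 1e-4)
})

test_that("recovering lnL from reported AICs reproduces the reported LRT p-values", {
  ref <- reference_model_stats()
  for (i in seq_len(nrow(ref))) {
    out <- lrt_p_from_aic(ref$AIC[i], ref$n_predictors[i], labels_555)
    digits <- max(nchar(sub(".*\\.", "", format(ref$LRT_p_reported[i],
                                                scientific = FALSE))), 1)
    expect_equal(signif(out$p.value, 4) >= 0, TRUE)
    rel <- abs(out$p.value - ref$LRT_p_reported[i]) / ref$LRT_p_reported[i]
    rounded_match <- isTRUE(all.equal(
      round(out$p.value, nchar_decimals(ref$LRT_p_reported[i])),
      ref$LRT_p_reported[i]))
    expect_true(rel < 0.005 || rounded_match,
                label = sprintf("model %s: p = %.4g vs reported %.4g",
                                ref$model[i], out$p.value,
                                ref$LRT_p_reported[i]))
  }
})

test_that("the combined reduced model wins model selection on planted cohorts", {
  pp <- planted_separation_params()
  wins <- 0L
  n_runs <- 30L
  for (s in seq_len(n_runs)) {
    sim <- simulate_cell_spectra(5, seed = 400 + s, params_by_type = pp,
                                 library = test_library())
    pca <- fit_pca_standardized(cell_spectra_matrix(sim$records), 10L)
    fit <- mlr_on_scores(pca$scores, sim$records$label)
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    top_pc <- which.min(cf$p.value)
    feats <- list(
      chemical = data.frame(PC = pca$scores[, top_pc]),
      morphological = data.frame(D = sim$records$D),
      combined = data.frame(PC = pca$scores[, top_pc], D = sim$records$D)
    )
    cmp <- compare_models(feats, sim$records$label, loocv = FALSE)
    if (cmp$model[cmp$best] == "combined") wins <- wins + 1L
  }
  expect_gte(wins / n_runs, 0.9)
})
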