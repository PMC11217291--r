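# Multinomial logistic phenotype inference and model comparison: maximum-
# likelihood fits, null likelihood, AIC with k = (G-1)(p+1), likelihood-
# ratio tests against the intercept-only null, training accuracy and LOOCV.

#' Fit a multinomial logistic phenotype model
#'
#' Maximum-likelihood multinomial logistic regression (softmax link, first
#' label alphabetically as the reference class). Predictors are standardised
#' internally and coefficients back-transformed for reporting. Exactly
#' aliased predictors (e.g. mean RI vs dry-mass density, which satisfy
#' RI = n0 + alpha D) are detected by QR and dropped with a message.
#' Quasi-complete separation is flagged when any standardised-scale
#' coefficient magnitude exceeds `separation_limit`; the fit is still
#' returned with the likelihood reached at the iteration cap.
#'
#' @param features data frame or matrix of predictors (may have zero
#'   columns for the intercept-only model).
#' @param labels factor or character vector of phenotypes (G >= 2 classes).
#' @param ridge quadratic penalty on the standardised coefficients (0 = pure
#'   maximum likelihood; a small value stabilises separated fits).
#' @param separation_limit standardised-coefficient magnitude that flags
#'   quasi-complete separation.
#' @param max_iter optimiser iteration cap.
#' @return object of class `mlor_fit`: list with `coefficients`
#'   ((G-1) x (p+1), original scale), `log_likelihood`, `k`, `n`,
#'   `fitted_probabilities`, `predicted`, `labels`, `separation`,
#'   `converged`, `dropped` (aliased columns removed).
#' @export
fit_mlor <- function(features, labels, ridge = 0,
                     separation_limit = 50, max_iter = 200L) {
  labels <- factor(labels)
  G <- nlevels(labels)
  if (G < 2L) stop("need at least two phenotype classes")
  X <- as.matrix(as.data.frame(features))
  if (is.null(dim(X)) || nrow(X) == 0L) stop("empty feature table")
  n <- length(labels)
  stopifnot(nrow(X) == n)
  if (anyNA(X)) stop("feature table contains missing values")
  dropped <- character()
  if (ncol(X) > 0L) {
    qrd <- qr(cbind(1, X))
    if (qrd$rank < ncol(X) + 1L) {
      keep_idx <- sort(qrd$pivot[seq_len(qrd$rank)])
      keep_idx <- setdiff(keep_idx, 1L) - 1L
      dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
      message("dropping aliased predictor(s): ", paste(dropped, collapse = ", "))
      X <- X[, keep_idx, drop = FALSE]
    }
  }
  p <- ncol(X)
  if (p > 0L) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    dat <- data.frame(.y = labels, Xs)
    fml <- stats::as.formula(paste(".y ~", paste(colnames(Xs), collapse = " + ")))
  } else {
    dat <- data.frame(.y = labels)
    fml <- .y ~ 1
  }
  fit <- nnet::multinom(fml, data = dat, decay = ridge, maxit = max_iter,
                        trace = FALSE, Hess = FALSE)
  lnL <- -fit$deviance / 2
  cf_std <- coef(fit)
  if (G == 2L) cf_std <- matrix(cf_std, nrow = 1L,
                                dimnames = list(levels(labels)[2L],
                                                names(cf_std)))
  separation <- max(abs(cf_std)) > separation_limit
  # back-transform to the original predictor scale
  cf <- cf_std
  if (p > 0L) {
    slopes <- cf_std[, -1L, drop = FALSE]
    cf[, -1L] <- sweep(slopes, 2L, scl, "/")
    cf[, 1L] <- cf_std[, 1L] - slopes %*% (ctr / scl)
  }
  probs <- predict(fit, newdata = dat, type = "probs")
  if (G == 2L) probs <- cbind(1 - probs, probs)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = n)
  dimnames(probs) <- list(NULL, levels(labels))
  predicted <- levels(labels)[max.col(probs)]
  # the optimiser may stop before coefficients blow past the magnitude
  # limit; a perfectly classified sample with saturated probabilities is
  # quasi-complete separation all the same
  if (!separation && p > 0L && all(predicted == as.character(labels))) {
    top <- probs[cbind(seq_len(n), as.integer(labels))]
    if (min(top) > 0.999) separation <- TRUE
  }
  structure(list(
    coefficients = cf,
    coefficients_std = cf_std,
    log_likelihood = lnL,
    k = (G - 1L) * (p + 1L),
    n = n, p = p, G = G,
    fitted_probabilities = probs,
    predicted = predicted,
    labels = labels,
    reference = levels(labels)[1L],
    separation = separation,
    converged = fit$convergence == 0,
    dropped = dropped,
    ridge = ridge,
    center = if (p > 0L) ctr else numeric(),
    scale = if (p > 0L) scl else numeric()
  ), class = "mlor_fit")
}

#' @export
print.mlor_fit <- function(x, ...) {
  cat("<mlor_fit> ", x$G, " classes (ref ", x$reference, "), ",
      x$p, " predictors, n = ", x$n, "\n", sep = "")
  cat(sprintf("  lnL = %.4f, k = %d, training accuracy = %.3f%s\n",
              x$log_likelihood, x$k, training_accuracy(x),
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Training accuracy of a fitted model
#'
#' @param fit [fit_mlor()] result.
#' @return fraction of cells whose maximum-probability class matches the
#'   label.
#' @export
training_accuracy <- function(fit) {
  stopifnot(inherits(fit, "mlor_fit"))
  mean(fit$predicted == as.character(fit$labels))
}

#' Null (intercept-only) log-likelihood
#'
#' lnL0 = sum_g n_g log(n_g / n), the saturated-proportions likelihood of
#' the intercept-only multinomial model.
#'
#' @param labels phenotype labels.
#' @return scalar log-likelihood (0 when one class).
#' @export
null_log_likelihood <- function(labels) {
  stopifnot(length(labels) > 0)
  n_g <- table(labels)
  n_g <- n_g[n_g > 0]
  sum(n_g * log(n_g / sum(n_g)))
}

#' Akaike information criterion of a multinomial fit
#'
#' AIC = 2k - 2 lnL with k = (G-1)(p+1) parameters (intercepts included).
#'
#' @param fit [fit_mlor()] result, or a list with `log_likelihood` and `k`.
#' @return scalar AIC.
#' @export
compute_aic <- function(fit) {
  2 * fit$k - 2 * fit$log_likelihood
}

#' Likelihood-ratio test against a nested null
#'
#' statistic = 2 (lnL - lnL0), df = k - k_null, chi-square upper tail.
#'
#' @param fit [fit_mlor()] result (or list with `log_likelihood`, `k`).
#' @param lnL0 null log-likelihood (defaults to the intercept-only value of
#'   the fit's own labels).
#' @param k_null parameters of the null (defaults to G - 1 intercepts).
#' @return tibble with `statistic`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(fit, lnL0 = NULL, k_null = NULL) {
  if (is.null(lnL0)) lnL0 <- null_log_likelihood(fit$labels)
  if (is.null(k_null)) k_null <- fit$G - 1L
  stat <- 2 * (fit$log_likelihood - lnL0)
  if (stat < -1e-6) {
    stop("negative likelihood-ratio statistic: the null is not nested or the fit failed")
  }
  stat <- max(stat, 0)
  df <- fit$k - k_null
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-square LRT p-value from a reported AIC
#'
#' Inverts AIC = 2k - 2 lnL under the k = (G-1)(p+1) parameter convention
#' and tests 2(lnL - lnL0) against chi-square with df = k - (G-1). Used to
#' check internal consistency of reported model-selection tables.
#'
#' @param aic reported AIC.
#' @param n_predictors number of predictors p of the model.
#' @param labels the cohort labels (give lnL0 and G).
#' @return tibble with `lnL`, `statistic`, `df`, `p.value`.
#' @export
lrt_p_from_aic <- function(aic, n_predictors, labels) {
  labels <- factor(labels)
  G <- nlevels(labels)
  k <- (G - 1L) * (n_predictors + 1L)
  lnL <- (2 * k - aic) / 2
  lnL0 <- null_log_likelihood(labels)
  stat <- 2 * (lnL - lnL0)
  df <- k - (G - 1L)
  tibble::tibble(lnL = lnL, statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Leave-one-out cross-validated accuracy
#'
#' Each cell is predicted by a model refit on the remaining n - 1 cells;
#' accuracy is the fraction predicted correctly. Unfittable folds count as
#' incorrect and are flagged.
#'
#' @param features predictor data frame/matrix.
#' @param labels phenotype labels.
#' @param ridge per-fold ridge penalty (a small default stabilises separated
#'   folds).
#' @return tibble with `accuracy`, `n`, `n_failed_folds`,
#'   `n_separated_folds`.
#' @export
loocv_accuracy <- function(features, labels, ridge = 1e-4) {
  labels <- factor(labels)
  G <- nlevels(labels)
  n <- length(labels)
  if (n < G + 1L) stop("need at least G + 1 cells for leave-one-out folds")
  X <- as.matrix(as.data.frame(features))
  correct <- logical(n)
  failed <- 0L; separated <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      f <- fit_mlor(X[-i, , drop = FALSE], labels[-i], ridge = ridge)
      if (f$separation) separated <- separated + 1L
      pred <- predict_mlor(f, X[i, , drop = FALSE])
      pred == as.character(labels[i])
    }, error = function(e) NA)
    if (is.na(res)) { failed <- failed + 1L; correct[i] <- FALSE }
    else correct[i] <- res
  }
  tibble::tibble(accuracy = mean(correct), n = n,
                 n_failed_folds = failed, n_separated_folds = separated)
}

#' Predict phenotypes from a fitted model
#'
#' @param fit [fit_mlor()] result.
#' @param newdata matrix/data frame with the fit's predictors.
#' @return character vector of predicted labels.
#' @export
predict_mlor <- function(fit, newdata) {
  stopifnot(inherits(fit, "mlor_fit"))
  X <- as.matrix(as.data.frame(newdata))
  if (length(fit$dropped)) {
    X <- X[, setdiff(colnames(X), fit$dropped), drop = FALSE]
  }
  lev <- levels(fit$labels)
  if (fit$p == 0L) {
    eta <- matrix(rep(fit$coefficients[, 1L], each = nrow(X)), nrow(X))
  } else {
    eta <- cbind(1, X) %*% t(fit$coefficients)
  }
  eta <- cbind(0, eta) # reference class
  pr <- exp(eta - apply(eta, 1L, max))
  pr <- pr / rowSums(pr)
  lev[max.col(pr)]
}

#' Compare candidate phenotype models
#'
#' Fits one multinomial model per named feature set and reports, per model:
#' number of predictors, log-likelihood, k, AIC, LRT statistic/df/p against
#' the intercept-only null, training accuracy and LOOCV accuracy. The
#' minimum-AIC model is marked.
#'
#' @param feature_sets named list of predictor data frames/matrices (an
#'   empty data frame gives the intercept-only row).
#' @param labels phenotype labels shared by all sets.
#' @param ridge ridge used for the LOOCV refits (the headline fit is pure
#'   maximum likelihood).
#' @param loocv compute LOOCV accuracy (TRUE) or skip it.
#' @return tibble of class `mlor_comparison`, one row per model.
#' @export
compare_models <- function(feature_sets, labels, ridge = 1e-4, loocv = TRUE) {
  stopifnot(length(feature_sets) >= 1L, !is.null(names(feature_sets)))
  rows <- purrr::imap(feature_sets, function(X, nm) {
    tryCatch({
      fit <- fit_mlor(X, labels)
      lrt <- likelihood_ratio_test(fit)
      cv <- if (loocv && fit$p > 0L) loocv_accuracy(X, labels, ridge = ridge)
            else tibble::tibble(accuracy = NA_real_)
      tibble::tibble(
        model = nm,
        n_predictors = fit$p,
        log_likelihood = fit$log_likelihood,
        k = fit$k,
        AIC = compute_aic(fit),
        LRT_statistic = lrt$statistic,
        LRT_df = lrt$df,
        LRT_p = lrt$p.value,
        training_accuracy = training_accuracy(fit),
        loocv_accuracy = cv$accuracy,
        separation = fit$separation
      )
    }, error = function(e) {
      tibble::tibble(model = nm, n_predictors = NA_integer_,
                     log_likelihood = NA_real_, k = NA_integer_,
                     AIC = NA_real_, LRT_statistic = NA_real_,
                     LRT_df = NA_integer_, LRT_p = NA_real_,
                     training_accuracy = NA_real_, loocv_accuracy = NA_real_,
                     separation = NA)
    })
  })
  out <- dplyr::bind_rows(rows)
  out$best <- !is.na(out$AIC) & out$AIC == min(out$AIC, na.rm = TRUE)
  class(out) <- c("mlor_comparison", class(out))
  out
}
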