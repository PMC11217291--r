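# PCA-MLR screening of cell-averaged spectra: which principal components
# carry phenotype-discriminating chemistry.

#' Assemble a cells x wavenumbers spectra matrix
#'
#' @param records tibble with `cell_id`, `label` and list-column `spectrum`
#'   (as produced by [extract_cell_records()] or [simulate_cell_spectra()]).
#' @return numeric matrix, cells in rows (named by cell_id), with attribute
#'   `labels`.
#' @export
cell_spectra_matrix <- function(records) {
  stopifnot(all(c("cell_id", "spectrum") %in% names(records)))
  mat <- do.call(rbind, records$spectrum)
  rownames(mat) <- records$cell_id
  attr(mat, "labels") <- records$label
  mat
}

#' Standardised PCA of cell-averaged spectra
#'
#' Column-standardises (mean 0, sample sd 1; constant columns are set to
#' zero and flagged) and decomposes by SVD. Loading signs are fixed so each
#' loading's largest-magnitude element is positive.
#'
#' @param mat cells x wavenumbers matrix (see [cell_spectra_matrix()]).
#' @param n_components number of components to keep.
#' @return object of class `spectra_pca`: list with `loadings` (wavenumbers
#'   x k), `scores` (cells x k), `explained_variance_ratio`, `n_constant`
#'   and the standardisation `center`/`scale`.
#' @export
fit_pca_standardized <- function(mat, n_components = 10L) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  n <- nrow(mat); p <- ncol(mat)
  if (n_components > min(n - 1L, p)) {
    stop("n_components must be <= min(cells - 1, wavenumbers) = ",
         min(n - 1L, p))
  }
  ctr <- colMeans(mat)
  scl <- apply(mat, 2L, sd)
  constant <- scl < .Machine$double.eps^0.5
  scl[constant] <- 1
  z <- sweep(sweep(mat, 2L, ctr), 2L, scl, "/")
  z[, constant] <- 0
  sv <- svd(z, nu = n_components, nv = n_components)
  loadings <- sv$v
  flip <- vapply(seq_len(n_components), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2L, flip, "*")
  scores <- z %*% loadings
  ev <- sv$d^2
  structure(list(
    loadings = loadings,
    scores = scores,
    explained_variance_ratio = (sv$d[seq_len(n_components)]^2 / sum(ev)),
    n_constant = sum(constant),
    center = ctr, scale = scl
  ), class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("<spectra_pca> ", nrow(x$scores), " cells, ", k, " components; ",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)),
      " cumulative variance\n", sep = "")
  invisible(x)
}

#' Multiple linear regression of a phenotype code on PC scores
#'
#' Ordinary least squares with intercept; per-coefficient two-tailed t-test
#' with df = n - k - 1. The phenotype coding (which numeric value each label
#' gets) is recorded with the fit.
#'
#' @param scores cells x k score matrix.
#' @param phenotype numeric response, or a factor/character vector encoded
#'   through `coding`.
#' @param coding named numeric mapping labels to codes. The default orders
#'   the reference phenotypes by disease progression
#'   (HT29 = 1, RKO = 2, T84 = 3).
#' @return object of class `pc_mlr`: list with the underlying `lm` fit, a
#'   tidy `coefficients` tibble (term, estimate, std.error, statistic,
#'   p.value), `df`, and the `coding` used.
#' @export
mlr_on_scores <- function(scores, phenotype,
                          coding = c(HT29 = 1, RKO = 2, T84 = 3)) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (n <= k + 1L) stop("need more cells than predictors + 1")
  if (is.numeric(phenotype)) {
    y <- phenotype
  } else {
    phenotype <- as.character(phenotype)
    if (!all(phenotype %in% names(coding))) {
      stop("phenotype labels missing from the coding map: ",
           paste(setdiff(phenotype, names(coding)), collapse = ", "))
    }
    y <- unname(coding[phenotype])
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  dat <- data.frame(y = y, scores)
  fit <- lm(y ~ ., data = dat)
  if (fit$rank < k + 1L) stop("singular design: PC scores are collinear")
  # summary.lm warns on numerically perfect fits; that case is legitimate here
  sm <- suppressWarnings(summary(fit))$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
  structure(list(fit = fit, coefficients = coefs, df = n - k - 1L,
                 coding = coding, scores = scores, response = y),
            class = "pc_mlr")
}

#' @export
print.pc_mlr <- function(x, ...) {
  cat("<pc_mlr> ", length(x$response), " cells, ",
      ncol(x$scores), " predictors, df = ", x$df, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Partial leverage of one predictor
#'
#' x-residuals: predictor j regressed on all other predictors (with
#' intercept); y-residuals: response regressed on all other predictors. The
#' slope of y-residuals on x-residuals equals the multiple-regression
#' coefficient beta_j (Frisch-Waugh).
#'
#' @param fit a [mlr_on_scores()] fit.
#' @param j predictor index (1-based, excluding the intercept).
#' @return tibble with `x_residual`, `y_residual`, and attributes `slope`
#'   and `term`.
#' @export
partial_leverage <- function(fit, j) {
  stopifnot(inherits(fit, "pc_mlr"))
  k <- ncol(fit$scores)
  if (!(j %in% seq_len(k))) stop("predictor index out of range")
  others <- fit$scores[, -j, drop = FALSE]
  xj <- fit$scores[, j]
  x_res <- residuals(lm(xj ~ others))
  y_res <- residuals(lm(fit$response ~ others))
  slope <- unname(coef(lm(y_res ~ x_res))[2])
  out <- tibble::tibble(x_residual = unname(x_res), y_residual = unname(y_res))
  attr(out, "slope") <- slope
  attr(out, "term") <- colnames(fit$scores)[j]
  out
}

#' Select significant principal components
#'
#' Indexes of the non-intercept coefficients with p below `alpha`,
#' ascending.
#'
#' @param fit a [mlr_on_scores()] fit.
#' @param alpha significance level.
#' @return integer vector of PC indexes.
#' @export
select_significant_pcs <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "pc_mlr"))
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  sort(which(cf$p.value < alpha))
}

#' Default Raman peak annotation table
#'
#' Standard fingerprint-region assignments used to label loading extremes.
#'
#' @return tibble with `center` (cm^-1) and `assignment`.
#' @export
default_peak_annotations <- function() {
  tibble::tribble(
    ~center, ~assignment,
    719,  "choline / phospholipid head",
    788,  "pyrimidine ring breathing (DNA/RNA)",
    815,  "RNA backbone",
    828,  "DNA backbone / tyrosine",
    856,  "proline / hydroxyproline, C-C collagen",
    970,  "phosphate (PBS)",
    1007, "phenylalanine ring breathing",
    1033, "phenylalanine C-H",
    1095, "DNA PO2- backbone",
    1131, "C-N proteins / C-C lipids",
    1152, "C-N / C-C stretch",
    1240, "Amide III / RNA",
    1304, "lipid CH2 twist",
    1340, "nucleic acid / CH deformation",
    1385, "CH3 proteins",
    1440, "CH2 bending (lipids)",
    1460, "CH2/CH3 deformation",
    1578, "adenine/guanine ring",
    1604, "phenylalanine / tyrosine",
    1656, "Amide I (proteins)"
  )
}

#' Annotate the extremes of a loading
#'
#' The `top_n` axis positions by absolute loading weight, each matched to
#' the nearest annotation within +/- `tol` cm^-1 ("unassigned" otherwise).
#' Neighbouring samples of an already-reported extreme are suppressed so the
#' top list names distinct bands.
#'
#' @param loading numeric loading vector.
#' @param axis wavenumber axis.
#' @param table annotation table (see [default_peak_annotations()]).
#' @param top_n number of extremes to report.
#' @param tol matching tolerance in cm^-1.
#' @param min_separation minimum distance (cm^-1) between reported extremes.
#' @return tibble with `wavenumber`, `weight`, `assignment`.
#' @export
annotate_loading <- function(loading, axis, table = default_peak_annotations(),
                             top_n = 5L, tol = 15, min_separation = 20) {
  stopifnot(length(loading) == length(axis), nrow(table) > 0)
  ord <- order(abs(loading), decreasing = TRUE)
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= top_n) break
    if (all(abs(axis[i] - axis[picked]) >= min_separation)) {
      picked <- c(picked, i)
    }
  }
  purrr::map_dfr(picked, function(i) {
    d <- abs(table$center - axis[i])
    assignment <- if (min(d) <= tol) table$assignment[which.min(d)] else "unassigned"
    tibble::tibble(wavenumber = axis[i], weight = loading[i],
                   assignment = assignment)
  })
}
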