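# Group comparisons: exact Mann-Whitney tests, Pearson correlation matrices
# with t-based significance, and the origin-fixed protein-vs-dry-mass fit.

#' Exact Mann-Whitney U test
#'
#' Two-sided p by full enumeration of all C(n+m, n) label assignments when
#' n + m <= `exact_limit` (midranks for ties; the p-value is the probability
#' of a U at least as extreme as observed, measured by distance from the
#' null mean). Larger samples use the normal approximation with tie
#' correction.
#'
#' @param a,b numeric samples.
#' @param exact_limit largest pooled size enumerated exactly.
#' @return tibble with `U` (statistic of sample `a`), `p.value`, `method`.
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 12L) {
  stopifnot(length(a) > 0, length(b) > 0)
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # midranks
  U_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n + m <= exact_limit) {
    idx <- combn(n + m, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U_a - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    N <- n + m
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U_a - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(U = U_a, p.value = p, method = method)
}

#' Pairwise Mann-Whitney comparisons of morphological indexes
#'
#' Every phenotype pair for every index column.
#'
#' @param morphology tibble with a `label` column and numeric index columns.
#' @param columns which columns to compare (default: all numeric ones).
#' @return tibble with `index`, `group1`, `group2`, `U`, `p.value`.
#' @export
morphology_comparisons <- function(morphology, columns = NULL) {
  stopifnot("label" %in% names(morphology))
  if (is.null(columns)) {
    columns <- names(morphology)[vapply(morphology, is.numeric, logical(1))]
    columns <- setdiff(columns, "n_clipped")
  }
  labs <- unique(morphology$label)
  pairs <- combn(labs, 2, simplify = FALSE)
  purrr::map_dfr(columns, function(col) {
    purrr::map_dfr(pairs, function(pr) {
      a <- morphology[[col]][morphology$label == pr[1]]
      b <- morphology[[col]][morphology$label == pr[2]]
      res <- mann_whitney_exact(a, b)
      tibble::tibble(index = col, group1 = pr[1], group2 = pr[2],
                     U = res$U, p.value = res$p.value)
    })
  })
}

#' Pearson correlation matrix with t-based significance
#'
#' Pearson correlation for every pair of index columns, with two-sided p
#' from t = r sqrt((n - 2) / (1 - r^2)) at df = n - 2; |r| = 1 is reported
#' with p = 0. Zero-variance columns give NA and are flagged.
#'
#' @param morphology tibble with a `label` column and numeric index columns.
#' @param per_label compute one matrix per phenotype (TRUE) or pooled.
#' @param columns index columns (default: the eight standard indexes present).
#' @return tibble with `label` (or "all"), `var1`, `var2`, `r`, `p.value`,
#'   `n`.
#' @export
pearson_matrix <- function(morphology, per_label = TRUE, columns = NULL) {
  if (is.null(columns)) {
    std <- c("ri_mean", "DM", "D", "phi", "V", "S", "A", "T")
    columns <- intersect(std, names(morphology))
    if (!length(columns)) {
      columns <- names(morphology)[vapply(morphology, is.numeric, logical(1))]
    }
  }
  groups <- if (per_label) split(morphology, morphology$label) else list(all = morphology)
  purrr::imap_dfr(groups, function(g, lab) {
    n <- nrow(g)
    if (n < 3L) stop("need at least 3 observations per correlation")
    prs <- expand.grid(var1 = columns, var2 = columns,
                       stringsAsFactors = FALSE)
    purrr::map_dfr(seq_len(nrow(prs)), function(i) {
      x <- g[[prs$var1[i]]]; y <- g[[prs$var2[i]]]
      if (sd(x) == 0 || sd(y) == 0) {
        return(tibble::tibble(label = lab, var1 = prs$var1[i],
                              var2 = prs$var2[i], r = NA_real_,
                              p.value = NA_real_, n = n))
      }
      r <- stats::cor(x, y)
      p <- pearson_p(r, n)
      tibble::tibble(label = lab, var1 = prs$var1[i], var2 = prs$var2[i],
                     r = r, p.value = p, n = n)
    })
  })
}

#' Two-sided p-value of a Pearson correlation
#'
#' @param r correlation coefficient.
#' @param n sample size (df = n - 2).
#' @return two-sided p (0 when |r| = 1).
#' @export
pearson_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Origin-fixed linear fit of protein band integrals on dry mass
#'
#' Least-squares slope through the origin (slope = sum(xy)/sum(x^2) with
#' x = DM), its t-based p at df = n - 1, and both the ordinary Pearson
#' correlation and the origin-fixed fit correlation sqrt(1 - RSS/TSS0).
#'
#' @param protein_integrals protein-content proxies (response).
#' @param dm dry masses in pg (regressor; all > 0).
#' @return tibble with `slope`, `slope_se`, `p.value`, `pcc`, `fit_r`, `n`.
#' @export
protein_dm_fit <- function(protein_integrals, dm) {
  stopifnot(length(protein_integrals) == length(dm),
            length(dm) >= 3L, all(dm > 0))
  if (all(dm == 0)) stop("dry masses are all zero")
  n <- length(dm)
  slope <- sum(protein_integrals * dm) / sum(dm^2)
  res <- protein_integrals - slope * dm
  se <- sqrt(sum(res^2) / (n - 1) / sum(dm^2))
  t <- slope / se
  p <- 2 * pt(-abs(t), df = n - 1)
  fit_r <- sqrt(max(0, 1 - sum(res^2) / sum(protein_integrals^2)))
  tibble::tibble(
    slope = slope, slope_se = se, p.value = p,
    pcc = stats::cor(protein_integrals, dm), fit_r = fit_r, n = n
  )
}
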