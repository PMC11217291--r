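# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.pc_mlr <- function(x, ...) x$coefficients

#' @export
glance.pc_mlr <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df.residual = x$df,
    nobs = length(x$response)
  )
}

#' @export
tidy.spectra_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained_variance_ratio)),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative_variance = cumsum(x$explained_variance_ratio)
  )
}

#' @export
tidy.mlor_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    class = rep(rownames(cf), times = ncol(cf)),
    term = rep(colnames(cf), each = nrow(cf)),
    estimate = as.numeric(cf)
  )
}

#' @export
glance.mlor_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    k = x$k,
    AIC = compute_aic(x),
    training_accuracy = training_accuracy(x),
    separation = x$separation,
    nobs = x$n
  )
}

#' Plot a band-integral image of a hypercube
#'
#' @param object [raman_hypercube()].
#' @param window band window (one row of [default_band_windows()]); default
#'   is the organic-matter window.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.raman_hypercube <- function(object, window = NULL, ...) {
  wins <- default_band_windows()
  window <- window %||% wins[wins$name == "organic_matter", ]
  img <- band_integral(object, window = window)$image
  df <- tibble::tibble(
    x = rep(seq_len(nrow(img)), times = ncol(img)) * object$pixel_pitch,
    y = rep(seq_len(ncol(img)), each = nrow(img)) * object$pixel_pitch,
    intensity = as.numeric(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = window$name) +
    ggplot2::labs(x = "x [um]", y = "y [um]")
}

#' Plot PCA loadings
#'
#' @param object [fit_pca_standardized()] result.
#' @param components which components to draw.
#' @param axis wavenumber axis for the x coordinate.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectra_pca <- function(object, components = 1:3, axis = NULL, ...) {
  axis <- axis %||% seq_len(nrow(object$loadings))
  df <- purrr::map_dfr(components, function(j) {
    tibble::tibble(component = paste0("PC", j), wavenumber = axis,
                   loading = object$loadings[, j])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$loading)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Raman shift [cm^-1]", y = "loading")
}

#' Plot a model-comparison table
#'
#' AIC per model with the minimum-AIC model highlighted.
#'
#' @param object [compare_models()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mlor_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(stats::reorder(.data$model, .data$AIC),
                               .data$AIC, fill = .data$best)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "seagreen"),
                               guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AIC")
}

#' Partial-leverage plot of one predictor
#'
#' @param fit [mlr_on_scores()] result.
#' @param j predictor index.
#' @return a ggplot of partial residuals with the beta_j regression line.
#' @export
plot_partial_leverage <- function(fit, j) {
  pl <- partial_leverage(fit, j)
  ggplot2::ggplot(pl, ggplot2::aes(.data$x_residual, .data$y_residual)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = attr(pl, "slope"), intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s partial leverage (slope = %.3f)",
                      attr(pl, "term"), attr(pl, "slope")),
      x = "partial regressor residual", y = "partial response residual")
}

#' Box plots of morphological indexes by phenotype
#'
#' @param morphology tibble from [cohort_morphology()] (or any table with
#'   `label` and numeric index columns).
#' @param columns indexes to draw.
#' @return a ggplot.
#' @export
plot_morphology <- function(morphology,
                            columns = c("ri_mean", "DM", "D", "phi",
                                        "V", "S", "A", "T")) {
  columns <- intersect(columns, names(morphology))
  df <- tidyr::pivot_longer(morphology[, c("label", columns)],
                            dplyr::all_of(columns),
                            names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
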