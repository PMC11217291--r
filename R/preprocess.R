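# Raman preprocessing, applied in the fixed order: cosmic-spike removal ->
# per-pixel asPLS baseline subtraction -> per-pixel Savitzky-Golay smoothing
# -> whole-cube Frobenius normalisation.

#' Calibrate a wavenumber axis from reference lines
#'
#' Least-squares quadratic fit of Raman shift against detector pixel index,
#' the standard calibration against a reference sample with known lines.
#'
#' @param pixel_positions detector pixel indices of the reference lines.
#' @param known_shifts their Raman shifts in cm^-1.
#' @param detector_range pixel index range to evaluate the axis over
#'   (defaults to the span of `pixel_positions`).
#' @param n_samples number of samples of the returned axis.
#' @return numeric axis of class `wavenumber_axis` with attributes
#'   `coefficients` (a0, a1, a2) and `residuals`.
#' @examples
#' calibrate_axis(c(100, 400, 800), c(700, 1007, 1450))
#' @export
calibrate_axis <- function(pixel_positions, known_shifts,
                           detector_range = range(pixel_positions),
                           n_samples = 870L) {
  if (length(pixel_positions) < 3L) {
    stop("calibration needs at least 3 reference points")
  }
  if (anyDuplicated(pixel_positions)) {
    stop("reference pixel positions must be distinct")
  }
  stopifnot(length(pixel_positions) == length(known_shifts))
  fit <- lm(known_shifts ~ pixel_positions + I(pixel_positions^2))
  cf <- unname(coef(fit))
  px <- seq(detector_range[1], detector_range[2], length.out = n_samples)
  axis <- cf[1] + cf[2] * px + cf[3] * px^2
  if (any(diff(axis) <= 0)) {
    stop("fitted axis is not strictly increasing over the detector range")
  }
  structure(axis, class = "wavenumber_axis",
            coefficients = c(a0 = cf[1], a1 = cf[2], a2 = cf[3]),
            residuals = unname(residuals(fit)))
}

#' Remove cosmic-ray spikes from a hypercube
#'
#' Per spectrum, samples whose residual from a 5-point spectral running
#' median exceeds `z_threshold` robust standard deviations (median absolute
#' deviation x 1.4826 of that spectrum's residuals) are replaced by the
#' running median; all other samples are left bit-unchanged. The ends use
#' Tukey's shrinking-median end rule, so a spike in the very first or last
#' sample is still detected.
#'
#' @param cube [raman_hypercube()], not yet normalised.
#' @param z_threshold robust z cut for flagging a sample as a spike.
#' @return the corrected hypercube; attribute `n_replaced` counts replaced
#'   samples.
#' @export
remove_cosmic_spikes <- function(cube, z_threshold = 8) {
  stopifnot(inherits(cube, "raman_hypercube"), z_threshold > 0)
  d <- dim(cube$intensities)
  if (d[3] < 5L) stop("spectral window longer than the spectrum")
  mat <- matrix(cube$intensities, d[1] * d[2], d[3])
  n_replaced <- 0L
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ]
    med <- running_median5(y)
    res <- y - med
    # the residual of a sample from a median window containing it has a
    # MAD well below the noise sd, so the robust scale is the larger of
    # the residual MAD and the second-difference noise estimate
    sig <- max(stats::mad(res),
               stats::mad(diff(y, differences = 2L)) / sqrt(6))
    if (sig <= 0) sig <- max(abs(res)) / z_threshold / 2 + 1e-30
    hit <- abs(res) > z_threshold * sig
    if (any(hit)) {
      y[hit] <- med[hit]
      mat[i, ] <- y
      n_replaced <- n_replaced + sum(hit)
    }
  }
  out <- raman_hypercube(array(mat, d), cube$axis, cube$pixel_pitch,
                         provenance = c(cube$provenance, "spikes"))
  attr(out, "n_replaced") <- n_replaced
  out
}

#' Baseline subtraction by adaptive smoothness penalised least squares
#'
#' Iteratively solves the penalised weighted least-squares system
#' (W + lambda * A * D2'D2) z = W y with a second-difference penalty, weights
#' w_i = 1 / (1 + exp(2 (y_i - z_i) / sigma)) where sigma is the standard
#' deviation of the negative residuals, and the adaptive per-point vector
#' A = |y - z| / max|y - z| scaling the penalty. Iteration stops when the
#' relative change of the weight vector drops below `tol` or at `max_iter`
#' (in which case a warning flag is set on the result, not an error).
#'
#' @param intensity numeric spectrum.
#' @param smoothness penalty weight lambda (default the instrument-scale
#'   5e6).
#' @param max_iter,tol stopping rule.
#' @return list with `corrected` (y - baseline), `baseline`, `iterations`,
#'   `converged`.
#' @export
subtract_baseline_aspls <- function(intensity, smoothness = 5e6,
                                    max_iter = 50L, tol = 1e-3) {
  stopifnot(is.numeric(intensity), all(is.finite(intensity)), smoothness > 0)
  if (all(intensity == 0)) {
    return(list(corrected = intensity, baseline = intensity,
                iterations = 0L, converged = TRUE))
  }
  fit <- cpp_aspls(as.numeric(intensity), smoothness, as.integer(max_iter), tol)
  if (!fit$converged) {
    warning("asPLS did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  list(corrected = intensity - fit$baseline, baseline = fit$baseline,
       iterations = fit$iterations, converged = fit$converged)
}

#' Savitzky-Golay smoothing
#'
#' Standard SG convolution (polynomial `order`, odd `window`); the filter
#' ends are handled by the polynomial fit on the truncated window.
#'
#' @param intensity numeric spectrum.
#' @param window odd filter length, > order.
#' @param order polynomial order.
#' @return smoothed numeric vector.
#' @export
smooth_savitzky_golay <- function(intensity, window = 7L, order = 2L) {
  if (window %% 2L == 0L || window <= order) {
    stop("Savitzky-Golay window must be odd and greater than the order")
  }
  as.numeric(signal::sgolayfilt(intensity, p = order, n = window))
}

#' Frobenius normalisation of a hypercube
#'
#' Divides the whole cube by its Frobenius norm sqrt(sum I^2) so pixel-to-
#' pixel ratios are unchanged and the cube norm is exactly 1.
#'
#' @param cube [raman_hypercube()].
#' @return normalised hypercube.
#' @export
normalize_frobenius <- function(cube) {
  stopifnot(inherits(cube, "raman_hypercube"))
  nrm <- sqrt(sum(cube$intensities^2))
  if (nrm == 0) stop("cannot normalise an all-zero hypercube")
  raman_hypercube(cube$intensities / nrm, cube$axis, cube$pixel_pitch,
                  provenance = c(cube$provenance, "frobenius"))
}

#' Full preprocessing of a raw hypercube
#'
#' Applies, in this fixed order: cosmic-spike removal, per-pixel asPLS
#' baseline subtraction, per-pixel Savitzky-Golay smoothing, whole-cube
#' Frobenius normalisation. Each enabled stage appends its name to the
#' cube's provenance.
#'
#' @param cube raw [raman_hypercube()].
#' @param spike_z robust z threshold of the spike detector (NULL disables).
#' @param aspls_lambda asPLS smoothness (NULL disables baseline removal).
#' @param savgol_window,savgol_order SG parameters (NULL window disables).
#' @param frobenius logical, apply the final normalisation.
#' @return preprocessed hypercube with provenance
#'   `c("spikes", "aspls", "savgol", "frobenius")` when all stages run.
#' @export
preprocess_map <- function(cube,
                           spike_z = 8,
                           aspls_lambda = 5e6,
                           savgol_window = 7L,
                           savgol_order = 2L,
                           frobenius = TRUE) {
  stopifnot(inherits(cube, "raman_hypercube"))
  if (!is.null(spike_z)) cube <- remove_cosmic_spikes(cube, spike_z)
  d <- dim(cube$intensities)
  if (!is.null(aspls_lambda)) {
    mat <- matrix(cube$intensities, d[1] * d[2], d[3])
    for (i in seq_len(nrow(mat))) {
      mat[i, ] <- mat[i, ] - cpp_aspls(mat[i, ], aspls_lambda, 50L, 1e-3)$baseline
    }
    cube <- raman_hypercube(array(mat, d), cube$axis, cube$pixel_pitch,
                            provenance = c(cube$provenance, "aspls"))
  }
  if (!is.null(savgol_window)) {
    mat <- matrix(cube$intensities, d[1] * d[2], d[3])
    mat <- t(apply(mat, 1L, smooth_savitzky_golay,
                   window = savgol_window, order = savgol_order))
    cube <- raman_hypercube(array(mat, d), cube$axis, cube$pixel_pitch,
                            provenance = c(cube$provenance, "savgol"))
  }
  if (isTRUE(frobenius)) cube <- normalize_frobenius(cube)
  cube
}
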