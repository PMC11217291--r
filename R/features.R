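# Chemical feature extraction from preprocessed hypercubes: PC1-based cell
# segmentation, cell-averaged spectra, and band integrals over the marker
# windows.

#' Default marker band windows
#'
#' Integration windows (cm^-1) centred on the standard biomolecular
#' assignments: nucleic acids 780-790, lipids 1440-1450, cytoplasm 715-725,
#' organic matter 1400-1680, phenylalanine 1002-1012 (peak 1007) and Amide I
#' 1640-1680 (peak 1660).
#'
#' @return tibble with columns `name`, `lower`, `upper`.
#' @export
default_band_windows <- function() {
  tibble::tribble(
    ~name,            ~lower, ~upper,
    "nuclei",            780,    790,
    "lipids",           1440,   1450,
    "cytoplasm",         715,    725,
    "organic_matter",   1400,   1680,
    "phenylalanine",    1002,   1012,
    "amide_I",          1640,   1680
  )
}

#' Segment cell pixels by the first principal component
#'
#' Runs a per-cube PCA over pixels (observations = pixels, variables =
#' wavenumbers) and fixes the PC1 sign so high scores mean more
#' organic-matter band signal (1400-1680 cm^-1). The cell core is the
#' largest 8-connected component above an Otsu threshold of the scores
#' (computed on log-compressed scores, whose long thickness-graded right
#' tail otherwise defeats the two-class criterion; when that selects an
#' implausibly large area for a single-cell field of view the raw-score
#' Otsu cut is used instead). The faint cell rim is then recovered by
#' hysteresis: pixels above a permissive background-outlier floor
#' (median + 1.5 MAD) that are 8-connected to the core join the mask.
#'
#' @param cube preprocessed [raman_hypercube()].
#' @param low_k MAD multiplier of the permissive hysteresis floor.
#' @param max_cell_fraction largest credible single-cell fraction of the
#'   field of view; an Otsu cut selecting more than this triggers the
#'   raw-score fallback.
#' @return list with `mask` (logical matrix), `scores` (PC1 score image) and
#'   `threshold` (the core threshold on the raw score scale).
#' @export
segment_cell_pixels <- function(cube, low_k = 1.5, max_cell_fraction = 0.25) {
  stopifnot(inherits(cube, "raman_hypercube"))
  d <- dim(cube$intensities)
  mat <- matrix(cube$intensities, d[1] * d[2], d[3])
  if (all(abs(apply(mat, 2L, var)) < 1e-30)) {
    stop("degenerate hypercube: identical spectra everywhere, PCA undefined")
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = 1L)
  scores <- pc$x[, 1L]
  # sign convention: high scores = cell (larger organic-matter integral)
  win <- cube$axis >= 1400 & cube$axis <= 1680
  om <- mat[, win, drop = FALSE] %*% diff_weights(cube$axis[win])
  if (stats::cor(scores, om) < 0) scores <- -scores
  med <- median(scores)
  sdev <- stats::mad(scores)
  compressed <- log(pmax(scores - med + 3 * sdev, .Machine$double.xmin))
  hi <- compressed > otsu_threshold(compressed)
  if (mean(hi) > max_cell_fraction) hi <- scores > otsu_threshold(scores)
  if (!any(hi)) stop("empty mask after Otsu thresholding of PC1 scores")
  # when the Otsu selection is spatially incoherent (scattered background
  # pixels rather than one blob) the cut landed inside residual background
  # structure; the background-outlier floor then takes over. Coherent
  # selections - including cells filling much of the field of view, where
  # the median/MAD floor itself breaks down - keep the Otsu cut.
  floor_thr <- med + low_k * sdev
  thr <- min(scores[hi])
  core <- largest_component(matrix(scores >= thr, d[1], d[2]))
  coherence <- sum(core) / max(sum(scores >= thr), 1L)
  if (coherence < 0.5 && floor_thr > thr) {
    thr <- floor_thr
    core2 <- largest_component(matrix(scores >= thr, d[1], d[2]))
    if (any(core2)) core <- core2
  }
  # hysteresis rim recovery
  low <- matrix(scores > floor_thr, d[1], d[2]) | core
  labs <- label_components(low)
  in_core <- labs[core]
  in_core <- in_core[in_core > 0L]
  mask <- if (length(in_core)) {
    matrix(labs == which.max(tabulate(in_core)), d[1], d[2])
  } else core
  list(mask = mask, scores = matrix(scores, d[1], d[2]), threshold = thr)
}

# trapezoid quadrature weights for an (irregular) axis
diff_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Average the spectra of the masked cell pixels
#'
#' @param cube [raman_hypercube()].
#' @param mask logical matrix matching the cube's spatial grid.
#' @param cell_id,label carried into the record.
#' @return tibble with one row: `cell_id`, `label`, `n_pixels` and the
#'   list-column `spectrum` (the arithmetic mean over masked pixels).
#' @export
average_cell_spectrum <- function(cube, mask, cell_id = NA_character_,
                                  label = NA_character_) {
  stopifnot(inherits(cube, "raman_hypercube"), is.logical(mask))
  d <- dim(cube$intensities)
  if (!all(dim(mask) == d[1:2])) {
    stop("mask dimensions do not match the hypercube grid")
  }
  if (!any(mask)) stop("mask selects no pixels")
  mat <- matrix(cube$intensities, d[1] * d[2], d[3])
  sel <- as.logical(mask)
  tibble::tibble(
    cell_id = cell_id, label = label,
    n_pixels = sum(sel),
    spectrum = list(colMeans(mat[sel, , drop = FALSE]))
  )
}

#' Band integral of a spectrum or hypercube
#'
#' Trapezoid integral of the intensity over the wavenumber window. For a
#' hypercube the result is a per-pixel image; with a mask, the masked sum of
#' that image is returned as well (the protein-content proxy uses the
#' phenylalanine + Amide I windows this way).
#'
#' @param x numeric spectrum or [raman_hypercube()].
#' @param axis wavenumber axis (required for a numeric spectrum).
#' @param lower,upper window bounds in cm^-1, or a one-row window from
#'   [default_band_windows()] via `window`.
#' @param window optional list/one-row data frame with `lower` and `upper`.
#' @param mask optional logical matrix (hypercube input only).
#' @return scalar for a spectrum; for a hypercube a list with `image` and
#'   (when masked) `masked_sum`.
#' @export
band_integral <- function(x, lower = NULL, upper = NULL, window = NULL,
                          axis = NULL, mask = NULL) {
  if (!is.null(window)) { lower <- window$lower; upper <- window$upper }
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  if (inherits(x, "raman_hypercube")) {
    ax <- x$axis
    sel <- ax >= lower & ax <= upper
    if (sum(sel) < 2L) stop("band window contains fewer than 2 axis samples")
    d <- dim(x$intensities)
    mat <- matrix(x$intensities, d[1] * d[2], d[3])
    img <- matrix(mat[, sel, drop = FALSE] %*% diff_weights(ax[sel]), d[1], d[2])
    if (is.null(mask)) return(list(image = img))
    stopifnot(all(dim(mask) == d[1:2]))
    return(list(image = img, masked_sum = sum(img[mask])))
  }
  if (is.null(axis)) stop("axis must be supplied for a numeric spectrum")
  stopifnot(length(axis) == length(x))
  sel <- axis >= lower & axis <= upper
  if (sum(sel) < 2L) stop("band window contains fewer than 2 axis samples")
  trapz(axis[sel], x[sel])
}

#' Protein-content proxy of a cell
#'
#' Sum of the phenylalanine (1002-1012 cm^-1) and Amide I (1640-1680 cm^-1)
#' band integrals of the cell-averaged spectrum, times the number of cell
#' pixels (i.e. the masked total, a semi-quantitative protein amount).
#'
#' @param spectrum cell-averaged spectrum.
#' @param axis wavenumber axis.
#' @param n_pixels number of cell pixels the average was taken over.
#' @return scalar protein proxy.
#' @export
protein_band_integral <- function(spectrum, axis, n_pixels = 1L) {
  wins <- default_band_windows()
  phe <- band_integral(spectrum, axis = axis,
                       window = wins[wins$name == "phenylalanine", ])
  ami <- band_integral(spectrum, axis = axis,
                       window = wins[wins$name == "amide_I", ])
  (phe + ami) * n_pixels
}

#' Extract per-cell records from a rendered cohort
#'
#' Runs preprocessing, PC1 segmentation and spectrum averaging on every
#' hypercube of a [generate_cohort()] result.
#'
#' @param cohort result of [generate_cohort()].
#' @param ... passed to [preprocess_map()].
#' @return tibble with columns `cell_id`, `label`, `n_pixels`, list-columns
#'   `spectrum` and `mask`, and `protein_integral`.
#' @export
extract_cell_records <- function(cohort, ...) {
  cells <- cohort$cells
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cube <- preprocess_map(cells$hypercube[[i]], ...)
    seg <- segment_cell_pixels(cube)
    rec <- average_cell_spectrum(cube, seg$mask,
                                 cell_id = cells$cell_id[i],
                                 label = cells$label[i])
    rec$mask <- list(seg$mask)
    rec$protein_integral <- protein_band_integral(rec$spectrum[[1]],
                                                  cube$axis, rec$n_pixels)
    out[[i]] <- rec
  }
  dplyr::bind_rows(out)
}
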