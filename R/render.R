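# Forward models: render one cell's Raman hypercube and RI tomogram from its
# geometry, chemistry and acquisition noise parameters.

#' Render a synthetic Raman hypercube for one cell
#'
#' Background pixels carry the quartz-substrate plus PBS-medium mixture; cell
#' pixels add the cellular component mixture scaled by the local projected
#' thickness of the ellipsoid, with the nucleic-acid component concentrated
#' in the nucleus sub-ellipsoid. A smooth positive polynomial baseline
#' (fluorescence), Gaussian spectral noise and Poisson-count single-pixel
#' cosmic spikes (at least 20x the local amplitude) are added on top.
#'
#' @param geometry [cell_geometry()] of the cell (um, field-of-view frame
#'   with the origin at the image centre).
#' @param params [phenotype_params()] supplying weights, baseline amplitude,
#'   noise and spike rate.
#' @param library [build_component_spectra()] output.
#' @param seed integer; identical (seed, arguments) give bit-identical cubes.
#' @param n_pixels image side in pixels.
#' @param pixel_pitch pixel size in um.
#' @param background_weights named weights of the background components.
#' @param confocal_depth axial extent (um) of the focal volume: the signal
#'   of a pixel saturates once the local cell thickness exceeds this depth,
#'   as it does for a high-NA confocal Raman probe. `Inf` makes the signal
#'   strictly proportional to the full projected thickness.
#' @param nucleus_enrichment concentration ratio of the nucleic-acid
#'   component inside vs outside the nucleus sub-ellipsoid (cell-total
#'   weight conserved).
#' @param weights optional named numeric of cellular component weights; when
#'   NULL they are drawn from `params` (the cohort generator passes the
#'   values it sampled so ground truth and rendering agree).
#' @return list with `cube` ([raman_hypercube()]), `mask` (logical matrix,
#'   ground-truth cell pixels), `weights` (named numeric used) and
#'   `n_spikes`.
#' @export
render_raman_hypercube <- function(geometry, params, library,
                                   seed,
                                   n_pixels = 50L,
                                   pixel_pitch = 0.8,
                                   background_weights = c(quartz_substrate = 3,
                                                          pbs_medium = 1.5),
                                   confocal_depth = 1.5,
                                   nucleus_enrichment = 3,
                                   weights = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(params, "phenotype_params"),
            inherits(library, "spectral_library"))
  set.seed(seed)
  axis <- library$axis
  n_w <- length(axis)
  half_fov <- n_pixels * pixel_pitch / 2
  a <- geometry$semi_axes[1]; b <- geometry$semi_axes[2]
  cc <- geometry$semi_axes[3]
  if (abs(geometry$center[1]) + a > half_fov ||
      abs(geometry$center[2]) + b > half_fov) {
    stop("cell geometry extends outside the field of view")
  }
  if (is.null(weights)) weights <- draw_component_weights(params)
  comp <- library$components
  need <- c("nucleus", "protein", "lipid", "cytoplasm",
            names(background_weights))
  missing <- setdiff(need, colnames(comp))
  if (length(missing)) stop("library lacks components: ",
                            paste(missing, collapse = ", "))

  xy <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_pitch
  u <- outer((xy - geometry$center[1])^2 / a^2,
             (xy - geometry$center[2])^2 / b^2, "+")
  thick <- matrix(0, n_pixels, n_pixels)
  inside <- u < 1
  thick[inside] <- 2 * cc * sqrt(1 - u[inside])
  f <- geometry$nucleus_fraction
  thick_nuc <- matrix(0, n_pixels, n_pixels)
  if (f > 0) {
    un <- u / f^2
    inn <- un < 1
    thick_nuc[inn] <- 2 * f * cc * sqrt(1 - un[inn])
  }

  bg_spec <- as.numeric(comp[, names(background_weights), drop = FALSE] %*%
                          background_weights)
  cyto_mix <- comp[, "protein"] * weights[["protein"]] +
    comp[, "lipid"] * weights[["lipid"]] +
    comp[, "cytoplasm"] * weights[["cytoplasm"]]
  # nucleic acid is enriched in the nucleus sub-ellipsoid (concentration
  # ratio `nucleus_enrichment` inside vs outside) with the cell-total weight
  # conserved; the confocal cap attenuates every column by the sampled
  # fraction of its thickness
  vf <- f^3
  d_out <- weights[["nucleus"]] / (1 + (nucleus_enrichment - 1) * vf)
  n_pix <- n_pixels * n_pixels
  thick_eff <- pmin(thick, confocal_depth)
  sampled_frac <- matrix(1, n_pixels, n_pixels)
  sampled_frac[inside] <- thick_eff[inside] / thick[inside]
  nuc_thick_eff <- thick_nuc * sampled_frac
  flat_thick <- as.numeric(thick_eff)
  flat_nuc <- d_out * (as.numeric(thick_eff) +
                         (nucleus_enrichment - 1) * as.numeric(nuc_thick_eff))
  signal <- outer(flat_thick, cyto_mix) + outer(flat_nuc, comp[, "nucleus"])
  signal <- sweep(signal, 2L, bg_spec, "+")

  # smooth positive fluorescence baseline, one random cubic per pixel
  if (params$baseline_amplitude > 0) {
    s <- seq(-1, 1, length.out = n_w)
    basis <- rbind(rep(1, n_w), s, s^2, s^3)
    coefs <- matrix(rnorm(n_pix * 4L), n_pix, 4L)
    base_raw <- coefs %*% basis
    base_raw <- base_raw - apply(base_raw, 1L, min) + 0.25
    signal <- signal + params$baseline_amplitude * base_raw
  }
  if (params$noise_sd > 0) {
    signal <- signal + rnorm(length(signal), sd = params$noise_sd)
  }
  n_spikes <- if (params$spike_rate > 0) rpois(1L, params$spike_rate) else 0L
  if (n_spikes > 0) {
    for (s_i in seq_len(n_spikes)) {
      px <- sample.int(n_pix, 1L)
      ch <- sample.int(n_w, 1L)
      local_amp <- max(abs(signal[px, ]), 1e-6)
      signal[px, ch] <- signal[px, ch] + local_amp * 20 * runif(1, 1, 3)
    }
  }
  signal[signal < 0] <- 0
  cube <- raman_hypercube(array(signal, c(n_pixels, n_pixels, n_w)),
                          axis = axis, pixel_pitch = pixel_pitch)
  list(cube = cube, mask = inside, weights = weights, n_spikes = n_spikes)
}

#' Render a synthetic RI tomogram for one cell
#'
#' Voxels inside the cell ellipsoid get RI = n0 + alpha * C with a positive
#' nucleus concentration offset arranged so the cell-mean concentration
#' equals `concentration`; Gaussian RI noise is added everywhere.
#'
#' @param geometry [cell_geometry()]; the cell is placed at the axial centre
#'   of the volume.
#' @param params [phenotype_params()] (supplies the dry-mass density
#'   distribution when `concentration` is NULL).
#' @param seed integer seed.
#' @param dims voxel grid (nx, ny, nz).
#' @param fov physical extent (um) of the three axes.
#' @param n0 background (medium) refractive index.
#' @param alpha refraction increment in ml/g.
#' @param concentration cell-mean dry-mass concentration in pg um^-3; drawn
#'   from `params` when NULL.
#' @param nucleus_dC positive concentration offset of the nucleus region.
#' @param ri_noise_sd additive Gaussian RI noise (dimensionless).
#' @return list with `tomogram` ([ri_tomogram()]), `mask` (logical 3D array,
#'   voxels of the noiseless cell above background), `concentration` used,
#'   and `low_contrast` flag (TRUE when part of the noiseless cell falls
#'   below the 1.345 segmentation threshold).
#' @export
render_tomogram <- function(geometry, params, seed,
                            dims = c(128L, 128L, 64L),
                            fov = c(40, 40, 40),
                            n0 = 1.3342, alpha = 0.19,
                            concentration = NULL,
                            nucleus_dC = 0.015,
                            ri_noise_sd = 5e-4) {
  stopifnot(inherits(geometry, "cell_geometry"), length(dims) == 3L,
            length(fov) == 3L, alpha > 0)
  set.seed(seed)
  voxel <- fov / dims
  if (is.null(concentration)) {
    m <- params$morphology_means[["D"]]
    s <- params$morphology_sds[["D"]]
    concentration <- max(rnorm(1L, m, s), 1e-3)
  }
  ax <- lapply(1:3, function(d) (seq_len(dims[d]) - (dims[d] + 1) / 2) * voxel[d])
  ctr <- geometry$center
  sa <- geometry$semi_axes
  if (any(abs(ctr[1:2]) + sa[1:2] > fov[1:2] / 2) || sa[3] > fov[3] / 2) {
    stop("cell geometry extends outside the tomogram volume")
  }
  ux <- (ax[[1]] - ctr[1])^2 / sa[1]^2
  uy <- (ax[[2]] - ctr[2])^2 / sa[2]^2
  uz <- (ax[[3]] - ctr[3])^2 / sa[3]^2
  u <- outer(outer(ux, uy, "+"), uz, "+")
  inside <- u < 1
  if (!any(inside)) {
    stop("no voxel centre falls inside the cell: the axial voxel size ",
         voxel[3], " um is too coarse for a cell of thickness ",
         2 * sa[3], " um")
  }
  f <- geometry$nucleus_fraction
  nucleus <- if (f > 0) u < f^2 else array(FALSE, dims)
  vf <- f^3
  C_nuc <- concentration + nucleus_dC * (1 - vf)
  C_cyt <- concentration - nucleus_dC * vf
  conc <- array(0, dims)
  conc[inside] <- C_cyt
  conc[nucleus] <- C_nuc
  ri_clean <- n0 + alpha * conc
  low_contrast <- FALSE
  if (min(ri_clean[inside]) < 1.345) {
    low_contrast <- TRUE
    warning("rendered cell RI falls below the 1.345 segmentation threshold; ",
            "flag recorded in the ground truth", call. = FALSE)
  }
  ri <- ri_clean
  if (ri_noise_sd > 0) ri <- ri + array(rnorm(length(ri), sd = ri_noise_sd), dims)
  ri[ri < 1] <- 1
  list(
    tomogram = ri_tomogram(ri, voxel_size = voxel, background_ri = n0),
    mask = inside,
    concentration = concentration,
    low_contrast = low_contrast
  )
}

# Draw one set of cellular component weights from the phenotype distributions
# (truncated at zero).
draw_component_weights <- function(params) {
  w <- rnorm(nrow(params$component_weights),
             params$component_weights$mean,
             params$component_weights$sd)
  w <- pmax(w, 0)
  setNames(w, params$component_weights$component)
}
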