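# Tomographic morphometry: RI-threshold segmentation and the eight per-cell
# indexes (mean RI, dry mass DM, dry-mass density D, sphericity, volume,
# surface area, footprint, thickness).

#' Segment cell voxels by an RI threshold
#'
#' Voxels with RI above `ri_threshold`; only the largest 26-connected
#' component is retained; holes are not filled.
#'
#' @param tomo [ri_tomogram()].
#' @param ri_threshold segmentation threshold (must exceed the background
#'   RI).
#' @return logical 3D array with attribute `threshold`.
#' @export
segment_cell_voxels <- function(tomo, ri_threshold = 1.345) {
  stopifnot(inherits(tomo, "ri_tomogram"))
  if (ri_threshold <= tomo$background_ri) {
    stop("ri_threshold must exceed the background RI (",
         tomo$background_ri, ")")
  }
  mask <- tomo$ri > ri_threshold
  if (!any(mask)) {
    stop("empty mask: no voxel exceeds the RI threshold ", ri_threshold)
  }
  mask <- largest_component(mask)
  attr(mask, "threshold") <- ri_threshold
  mask
}

#' Shape indexes of a 3D cell mask
#'
#' Volume V is the voxel count times the voxel volume; surface area S is a
#' triangulated isosurface area (marching tetrahedra at level 0.5 of a
#' lightly Gaussian-smoothed copy of the mask, sigma = (1, 1, 0.6) voxels);
#' footprint A is the number of XY columns containing at least one masked
#' voxel times the pixel area; thickness T = 1.5 V / A; sphericity
#' Phi = pi^(1/3) (6V)^(2/3) / S (Wadell).
#'
#' @param mask logical 3D array.
#' @param voxel_size numeric (dx, dy, dz) in um.
#' @param smooth_sigma smoothing (voxel units) applied before surface
#'   triangulation; 0 measures the raw staircase surface.
#' @return tibble with columns `V`, `S`, `A`, `T`, `phi`.
#' @export
compute_shape_indexes <- function(mask, voxel_size,
                                  smooth_sigma = c(1, 1, 0.6)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            length(voxel_size) == 3L, any(mask))
  vx <- prod(voxel_size)
  V <- sum(mask) * vx
  A <- sum(apply(mask, c(1, 2), any)) * voxel_size[1] * voxel_size[2]
  # pad by one empty layer per side so boundary-touching masks still close
  d <- dim(mask)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask + 0
  field <- smooth_gaussian_3d(padded, smooth_sigma)
  S <- cpp_mt_area(as.numeric(field), dim(field), voxel_size, 0.5)
  T_ <- 1.5 * V / A
  phi <- pi^(1 / 3) * (6 * V)^(2 / 3) / S
  tibble::tibble(V = V, S = S, A = A, T = T_, phi = phi)
}

#' Mass indexes of a masked tomogram
#'
#' Converts RI excess over the medium to dry-mass concentration through the
#' refraction increment, C = (RI - n0) / alpha, then integrates: dry mass
#' DM = sum(C) * voxel volume over the mask and density D = DM / V.
#' Negative concentrations (noise below background) are clipped to zero and
#' counted.
#'
#' @param tomo [ri_tomogram()].
#' @param mask logical 3D array of cell voxels.
#' @param alpha refraction increment in ml/g (0.19 for protein).
#' @param n0 medium refractive index.
#' @return list with `ri_mean`, `D` (pg um^-3), `DM` (pg), `concentration`
#'   (3D array, zero outside the mask) and `n_clipped`.
#' @export
compute_mass_indexes <- function(tomo, mask, alpha = 0.19, n0 = 1.3342) {
  stopifnot(inherits(tomo, "ri_tomogram"), alpha > 0,
            all(dim(mask) == dim(tomo$ri)), any(mask))
  ri_mean <- mean(tomo$ri[mask])
  conc <- array(0, dim(tomo$ri))
  cm <- (tomo$ri[mask] - n0) / alpha
  n_clipped <- sum(cm < 0)
  cm[cm < 0] <- 0
  conc[mask] <- cm
  vx <- prod(tomo$voxel_size)
  DM <- sum(cm) * vx
  V <- sum(mask) * vx
  list(ri_mean = ri_mean, D = DM / V, DM = DM, concentration = conc,
       n_clipped = n_clipped)
}

#' Full morphometry of one tomogram
#'
#' Segmentation plus the eight indexes in one row.
#'
#' @param tomo [ri_tomogram()].
#' @param ri_threshold segmentation threshold.
#' @param alpha refraction increment (ml/g).
#' @param n0 medium RI (defaults to the tomogram's background RI).
#' @param cell_id,label carried into the row.
#' @return one-row tibble: `cell_id`, `label`, `ri_mean`, `DM`, `D`, `phi`,
#'   `V`, `S`, `A`, `T`, `n_clipped`.
#' @export
morphology_summary <- function(tomo, ri_threshold = 1.345, alpha = 0.19,
                               n0 = NULL, cell_id = NA_character_,
                               label = NA_character_) {
  n0 <- n0 %||% tomo$background_ri
  if (ri_threshold > max(tomo$ri)) {
    stop("RI threshold ", ri_threshold, " exceeds the tomogram maximum")
  }
  mask <- segment_cell_voxels(tomo, ri_threshold)
  shape <- compute_shape_indexes(mask, tomo$voxel_size)
  mass <- compute_mass_indexes(tomo, mask, alpha = alpha, n0 = n0)
  tibble::tibble(
    cell_id = cell_id, label = label,
    ri_mean = mass$ri_mean, DM = mass$DM, D = mass$D,
    phi = shape$phi, V = shape$V, S = shape$S, A = shape$A, T = shape$T,
    n_clipped = mass$n_clipped
  )
}

#' Morphometry of every cell in a cohort
#'
#' @param cohort result of [generate_cohort()].
#' @param ... passed to [morphology_summary()].
#' @return tibble with one row per cell.
#' @export
cohort_morphology <- function(cohort, ...) {
  cells <- cohort$cells
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    morphology_summary(cells$tomogram[[i]], ...,
                       cell_id = cells$cell_id[i], label = cells$label[i])
  })
}

#' Predicted mean cell RI from a dry-mass density
#'
#' The linear RI-concentration relation n = n0 + alpha * D.
#'
#' @param density dry-mass density in pg um^-3.
#' @param n0 medium RI.
#' @param alpha refraction increment (ml/g).
#' @return predicted refractive index.
#' @export
ri_from_density <- function(density, n0 = 1.3342, alpha = 0.19) {
  n0 + alpha * density
}
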