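# Containers for the two imaging modalities.

#' Construct a Raman hypercube
#'
#' @param intensities numeric X x Y x Omega array (counts, arbitrary units).
#' @param axis wavenumber axis, length = third dimension.
#' @param pixel_pitch pixel size in um.
#' @param provenance character vector of processing steps already applied.
#' @return object of class `raman_hypercube`.
#' @export
raman_hypercube <- function(intensities, axis, pixel_pitch = 0.8,
                            provenance = character()) {
  stopifnot(
    is.array(intensities), length(dim(intensities)) == 3L,
    length(axis) == dim(intensities)[3],
    all(diff(axis) > 0),
    all(is.finite(intensities)),
    pixel_pitch > 0
  )
  structure(list(
    intensities = intensities,
    axis = as.numeric(axis),
    pixel_pitch = pixel_pitch,
    provenance = provenance
  ), class = "raman_hypercube")
}

#' @export
print.raman_hypercube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<raman_hypercube> %d x %d pixels (%.2g um pitch), %d wavenumbers [%g-%g cm^-1]\n",
              d[1], d[2], x$pixel_pitch, d[3], min(x$axis), max(x$axis)))
  if (length(x$provenance)) {
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Construct a refractive-index tomogram
#'
#' @param ri numeric X x Y x Z array of refractive indexes (all >= 1).
#' @param voxel_size numeric (dx, dy, dz) in um.
#' @param background_ri refractive index of the surrounding medium.
#' @return object of class `ri_tomogram`.
#' @export
ri_tomogram <- function(ri, voxel_size, background_ri = 1.3342) {
  stopifnot(
    is.array(ri), length(dim(ri)) == 3L,
    length(voxel_size) == 3L, all(voxel_size > 0),
    all(is.finite(ri)), min(ri) >= 1
  )
  structure(list(
    ri = ri,
    voxel_size = as.numeric(voxel_size),
    background_ri = background_ri
  ), class = "ri_tomogram")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf("<ri_tomogram> %d x %d x %d voxels (%.3g x %.3g x %.3g um), n0 = %.4f, RI range [%.4f, %.4f]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$background_ri, min(x$ri), max(x$ri)))
  invisible(x)
}
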