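# Disk formats: hypercubes and tomograms as multi-page 32-bit float TIFFs
# with plain-text/JSON sidecars, cohort manifests as CSV. TIFF float pages
# hold values in [0, 1], so arrays are stored as (value - offset) / scale
# with both recorded in the JSON sidecar.

#' Write a Raman hypercube
#'
#' One TIFF page per wavenumber plus `<stem>_wavenumbers.txt` (one shift per
#' line) and `<stem>.json` (pixel pitch, offset/scale, provenance).
#'
#' @param cube [raman_hypercube()].
#' @param path TIFF file path (sidecar names are derived from it).
#' @return `path`, invisibly.
#' @export
write_hypercube <- function(cube, path) {
  stopifnot(inherits(cube, "raman_hypercube"))
  rng <- range(cube$intensities)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  scaled <- (cube$intensities - offset) / scale
  pages <- lapply(seq_along(cube$axis), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  stem <- sub("\\.tiff?$", "", path)
  writeLines(format(cube$axis, digits = 12), paste0(stem, "_wavenumbers.txt"))
  jsonlite::write_json(list(
    pixel_pitch_um = cube$pixel_pitch,
    offset = offset, scale = scale,
    provenance = cube$provenance
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Raman hypercube written by [write_hypercube()]
#'
#' @param path TIFF file path.
#' @return [raman_hypercube()].
#' @export
read_hypercube <- function(path) {
  stem <- sub("\\.tiff?$", "", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  axis <- as.numeric(readLines(paste0(stem, "_wavenumbers.txt")))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- arr * meta$scale + meta$offset
  raman_hypercube(arr, axis, pixel_pitch = meta$pixel_pitch_um,
                  provenance = as.character(meta$provenance %||% character()))
}

#' Write an RI tomogram
#'
#' One TIFF page per Z slice plus a JSON sidecar with the voxel size,
#' background RI and offset/scale.
#'
#' @param tomo [ri_tomogram()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path) {
  stopifnot(inherits(tomo, "ri_tomogram"))
  rng <- range(tomo$ri)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  scaled <- (tomo$ri - offset) / scale
  pages <- lapply(seq_len(dim(tomo$ri)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  stem <- sub("\\.tiff?$", "", path)
  jsonlite::write_json(list(
    voxel_size_um = tomo$voxel_size,
    background_ri = tomo$background_ri,
    offset = offset, scale = scale
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RI tomogram written by [write_tomogram()]
#'
#' @param path TIFF file path.
#' @return [ri_tomogram()].
#' @export
read_tomogram <- function(path) {
  stem <- sub("\\.tiff?$", "", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- arr * meta$scale + meta$offset
  arr[arr < 1] <- 1 # guard float round-trip error at the lower bound
  ri_tomogram(arr, voxel_size = as.numeric(meta$voxel_size_um),
              background_ri = meta$background_ri)
}

#' Write a cohort to disk
#'
#' Per cell one hypercube and one tomogram (TIFF + sidecars) plus
#' `manifest.csv` (cell_id, label, hypercube_path, tomogram_path, seed) and
#' `ground_truth.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- cohort$cells
  manifest <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    hc <- file.path(out_dir, paste0(cells$cell_id[i], "_raman.tif"))
    tm <- file.path(out_dir, paste0(cells$cell_id[i], "_tomo.tif"))
    write_hypercube(cells$hypercube[[i]], hc)
    write_tomogram(cells$tomogram[[i]], tm)
    tibble::tibble(cell_id = cells$cell_id[i], label = cells$label[i],
                   hypercube_path = hc, tomogram_path = tm,
                   seed = cells$seed[i])
  })
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  gt <- dplyr::select(cohort$ground_truth, -dplyr::any_of("weights"))
  write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest and its images
#'
#' @param dir directory written by [write_cohort()].
#' @return tibble like the `cells` table of [generate_cohort()] (without
#'   ground-truth masks).
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(read.csv(file.path(dir, "manifest.csv"),
                                         stringsAsFactors = FALSE))
  manifest$hypercube <- purrr::map(manifest$hypercube_path, read_hypercube)
  manifest$tomogram <- purrr::map(manifest$tomogram_path, read_tomogram)
  manifest
}
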