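# Spectral component library: unit-area reference spectra for the molecular
# classes the simulator mixes (nucleic acids, proteins, lipids, cytoplasm,
# quartz substrate, PBS medium, water).

#' Default wavenumber axis
#'
#' The fingerprint region sampled the way the emulated instrument does:
#' 870 evenly spaced Raman shifts between 600 and 1800 cm^-1.
#'
#' @param n number of spectral samples.
#' @param from,to axis range in cm^-1.
#' @return numeric vector of class `wavenumber_axis`, strictly increasing.
#' @export
default_wavenumber_axis <- function(n = 870L, from = 600, to = 1800) {
  stopifnot(n >= 2L, from < to)
  structure(seq(from, to, length.out = n), class = "wavenumber_axis")
}

#' Default Raman peak table
#'
#' Line positions follow standard biomolecular band assignments in the
#' fingerprint region: pyrimidine ring breathing at 788 cm^-1 and backbone
#' modes for nucleic acids, phenylalanine at 1007 cm^-1 and the Amide I/III
#' bands for proteins, CH2/CH3 deformations near 1440-1460 cm^-1 for lipids,
#' a broad quartz substrate band centred near 800 cm^-1 and the PBS/water
#' bands. Widths are half-widths (Lorentzian gamma) in cm^-1; heights are
#' relative within a component (each component is later normalised to unit
#' area, so only the height ratios matter).
#'
#' @return tibble with columns `component`, `center`, `width`, `height`.
#' @export
default_peak_table <- function() {
  tibble::tribble(
    ~component, ~center, ~width, ~height,
    "nucleus",            788, 10,  1.00,
    "nucleus",            815,  8,  0.40,
    "nucleus",            828,  8,  0.35,
    "nucleus",           1095, 12,  0.45,
    "nucleus",           1240, 14,  0.60,
    "nucleus",           1340, 12,  0.35,
    "nucleus",           1578, 10,  0.50,
    "protein",            856,  9,  0.35,
    "protein",           1007,  6,  1.00,
    "protein",           1033,  8,  0.30,
    "protein",           1131,  9,  0.30,
    "protein",           1152,  9,  0.25,
    "protein",           1260, 16,  0.55,
    "protein",           1450, 12,  0.45,
    "protein",           1604,  8,  0.20,
    "protein",           1656, 14,  0.90,
    "lipid",              719,  8,  0.40,
    "lipid",             1085, 11,  0.40,
    "lipid",             1304, 11,  0.50,
    "lipid",             1440, 12,  1.00,
    "lipid",             1460, 10,  0.55,
    "lipid",             1656,  9,  0.25,
    "lipid",             1745,  9,  0.20,
    "cytoplasm",         1003,  8,  0.30,
    "cytoplasm",         1320, 18,  0.40,
    "cytoplasm",         1450, 15,  0.60,
    "cytoplasm",         1660, 18,  0.50,
    "quartz_substrate",   800, 60,  1.00,
    "quartz_substrate",  1060, 50,  0.25,
    "pbs_medium",         970, 12,  1.00,
    "pbs_medium",        1640, 50,  0.35,
    "water",             1640, 60,  1.00
  )
}

#' Build a library of unit-area component spectra
#'
#' Each component is a sum of Lorentzian lines evaluated on `axis` and
#' normalised to unit trapezoid area, so component weights downstream are
#' directly comparable across components.
#'
#' @param axis wavenumber axis (ascending numeric vector, cm^-1).
#' @param peak_table data frame with columns `component`, `center`, `width`,
#'   `height`; see [default_peak_table()].
#' @return object of class `spectral_library`: list with `axis` and
#'   `components`, a length(axis) x n_components matrix.
#' @examples
#' lib <- build_component_spectra(default_wavenumber_axis())
#' colnames(lib$components)
#' @export
build_component_spectra <- function(axis = default_wavenumber_axis(),
                                    peak_table = default_peak_table()) {
  stopifnot(is.numeric(axis), all(diff(axis) > 0))
  peak_table <- tibble::as_tibble(peak_table)
  required <- c("component", "center", "width", "height")
  if (!all(required %in% names(peak_table))) {
    stop("peak_table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(peak_table) == 0L) stop("peak_table is empty")
  if (any(peak_table$width <= 0)) stop("all peak widths must be > 0")
  out_of_range <- peak_table$center < min(axis) | peak_table$center > max(axis)
  if (any(out_of_range)) {
    bad <- peak_table[out_of_range, ]
    stop(sprintf(
      "peak centre(s) outside the axis range [%g, %g]: %s",
      min(axis), max(axis),
      paste(sprintf("%s@%g", bad$component, bad$center), collapse = ", ")
    ))
  }
  comps <- split(peak_table, peak_table$component)
  mat <- vapply(comps, function(tab) {
    y <- rep(0, length(axis))
    for (i in seq_len(nrow(tab))) {
      y <- y + tab$height[i] * lorentzian(axis, tab$center[i], tab$width[i])
    }
    area <- trapz(axis, y)
    if (area <= 0) stop("component '", tab$component[1], "' has zero area")
    y / area
  }, numeric(length(axis)))
  structure(list(axis = axis, components = mat), class = "spectral_library")
}

# Lorentzian line with half-width-at-half-maximum gamma, unit area on the
# real line (truncated on the axis, renormalised by the caller).
lorentzian <- function(x, center, gamma) {
  (gamma / pi) / ((x - center)^2 + gamma^2)
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", ncol(x$components), " components on ",
      length(x$axis), " wavenumbers [",
      min(x$axis), "-", max(x$axis), " cm^-1]\n", sep = "")
  cat("  components:", paste(colnames(x$components), collapse = ", "), "\n")
  invisible(x)
}
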