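# Per-phenotype simulation parameters. Defaults reproduce the reference
# colon-cancer cohort statistics (three lines: HT29, RKO, T84; n = 5 cells
# per line) that the downstream analysis is designed around.

#' Construct simulation parameters for one phenotype
#'
#' @param label phenotype name.
#' @param component_weights tibble with columns `component`, `mean`, `sd`:
#'   the mixing weight of each cellular spectral component (per micrometre of
#'   projected thickness; background components are configured globally, not
#'   here).
#' @param morphology_means named numeric: `D` dry-mass density (pg um^-3),
#'   `phi` sphericity (0-1), `T` thickness (um), `footprint_r` nominal
#'   footprint radius (um). Cell-level values of D, phi and T are drawn from
#'   Gaussians at these means; the footprint radius is then derived from
#'   (phi, T) through the exact oblate-spheroid surface area, so
#'   `footprint_r` only anchors the field-of-view check.
#' @param morphology_sds matching spreads (same names). The reference cohort
#'   reports standard errors with n = 5, so defaults use sd = SE * sqrt(5).
#' @param baseline_amplitude scalar amplitude of the smooth fluorescence
#'   baseline added to every pixel spectrum (same units as the spectra).
#' @param noise_sd standard deviation of additive Gaussian spectral noise.
#' @param spike_rate expected number of cosmic-ray spikes per hypercube
#'   (Poisson).
#' @return object of class `phenotype_params`.
#' @export
phenotype_params <- function(label,
                             component_weights,
                             morphology_means,
                             morphology_sds,
                             baseline_amplitude = 0.01,
                             noise_sd = 0.002,
                             spike_rate = 2) {
  component_weights <- tibble::as_tibble(component_weights)
  stopifnot(
    all(c("component", "mean", "sd") %in% names(component_weights)),
    all(component_weights$sd >= 0),
    all(c("D", "phi", "T") %in% names(morphology_means)),
    morphology_means[["D"]] > 0,
    morphology_means[["phi"]] > 0, morphology_means[["phi"]] <= 1,
    morphology_means[["T"]] > 0,
    all(morphology_sds >= 0),
    baseline_amplitude >= 0, noise_sd >= 0, spike_rate >= 0
  )
  structure(list(
    label = label,
    component_weights = component_weights,
    morphology_means = morphology_means,
    morphology_sds = morphology_sds,
    baseline_amplitude = baseline_amplitude,
    noise_sd = noise_sd,
    spike_rate = spike_rate
  ), class = "phenotype_params")
}

#' Default phenotype parameter set
#'
#' Three colorectal phenotypes. Morphology means and spreads follow the
#' reference cohort: dry-mass density D = 0.159/0.133/0.148 pg um^-3,
#' sphericity 0.685/0.572/0.566 and thickness 2.835/2.465/2.289 um for
#' HT29/RKO/T84, with sd = SE * sqrt(5) from the reported standard errors.
#' Chemistry encodes the qualitative contrasts the cohort shows: HT29 has an
#' elevated nucleic-acid weight, T84 a reduced protein and lipid weight;
#' magnitudes are configuration choices sized so the spectral contrast is
#' comparable to the between-cell variability.
#'
#' @return named list of [phenotype_params()] objects (HT29, RKO, T84).
#' @export
default_phenotype_params <- function() {
  base_weights <- function(nucleus, protein, lipid, cytoplasm, rel_sd = 0.08) {
    tibble::tibble(
      component = c("nucleus", "protein", "lipid", "cytoplasm"),
      mean = c(nucleus, protein, lipid, cytoplasm),
      sd = rel_sd * mean
    )
  }
  se <- sqrt(5)
  list(
    HT29 = phenotype_params(
      label = "HT29",
      component_weights = base_weights(1.25, 1.00, 0.50, 0.70),
      morphology_means = c(D = 0.159, phi = 0.685, T = 2.835, footprint_r = 5.9),
      morphology_sds = c(D = 0.003 * se, phi = 0.014 * se, T = 0.092 * se,
                         footprint_r = 0)
    ),
    RKO = phenotype_params(
      label = "RKO",
      component_weights = base_weights(0.85, 1.00, 0.50, 0.70),
      morphology_means = c(D = 0.133, phi = 0.572, T = 2.465, footprint_r = 7.1),
      morphology_sds = c(D = 0.004 * se, phi = 0.009 * se, T = 0.133 * se,
                         footprint_r = 0)
    ),
    T84 = phenotype_params(
      label = "T84",
      component_weights = base_weights(0.85, 0.72, 0.36, 0.70),
      morphology_means = c(D = 0.148, phi = 0.566, T = 2.289, footprint_r = 6.6),
      morphology_sds = c(D = 0.006 * se, phi = 0.052 * se, T = 0.220 * se,
                         footprint_r = 0)
    )
  )
}

#' Phenotype parameters with planted complementary separation
#'
#' A configuration in which the chemical and the morphological channel each
#' resolve a different pair of phenotypes: HT29 differs from the other two
#' only chemically (elevated nucleic-acid weight), RKO differs only
#' morphologically (reduced dry-mass density), and T84 matches HT29 in
#' morphology and RKO in chemistry. No single-channel model can separate
#' all three classes, while their combination can - the structure used to
#' exercise model selection on the combined reduced model.
#'
#' @param chem_gap nucleic-acid weight excess of HT29 over the others.
#' @param d_gap dry-mass density deficit (pg um^-3) of RKO below the others.
#' @return named list of [phenotype_params()] objects.
#' @export
planted_separation_params <- function(chem_gap = 0.3, d_gap = 0.03) {
  base <- default_phenotype_params()
  wts <- function(nucleus) {
    tibble::tibble(
      component = c("nucleus", "protein", "lipid", "cytoplasm"),
      mean = c(nucleus, 1.0, 0.5, 0.7),
      sd = c(0.08, 0.08, 0.04, 0.056)
    )
  }
  morph <- function(D) c(D = D, phi = 0.60, T = 2.5, footprint_r = 6.5)
  msds <- c(D = 0.008, phi = 0.03, T = 0.2, footprint_r = 0)
  base$HT29$component_weights <- wts(1.0 + chem_gap)
  base$RKO$component_weights <- wts(1.0)
  base$T84$component_weights <- wts(1.0)
  base$HT29$morphology_means <- morph(0.150)
  base$RKO$morphology_means <- morph(0.150 - d_gap)
  base$T84$morphology_means <- morph(0.150)
  base$HT29$morphology_sds <- msds
  base$RKO$morphology_sds <- msds
  base$T84$morphology_sds <- msds
  base
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params> ", x$label, "\n", sep = "")
  cat("  D =", x$morphology_means[["D"]], " phi =", x$morphology_means[["phi"]],
      " T =", x$morphology_means[["T"]], "um\n")
  cat("  components:", paste(sprintf("%s=%.2f", x$component_weights$component,
                                     x$component_weights$mean), collapse = " "), "\n")
  invisible(x)
}
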