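# Cohort generation: labelled synthetic cells with paired Raman hypercubes
# and RI tomograms, plus the analytic ground truth every downstream stage is
# tested against.

#' Generate a paired synthetic cohort
#'
#' Draws per-cell morphology (dry-mass density D, sphericity, thickness) and
#' chemistry (component weights) from the per-phenotype distributions,
#' derives each cell's oblate-spheroid geometry, and renders one Raman
#' hypercube and one RI tomogram per cell. Fully reproducible from
#' `(n_per_type, seed, params_by_type)`.
#'
#' @param n_per_type cells per phenotype (>= 2).
#' @param seed integer master seed; per-cell render seeds are derived from it.
#' @param params_by_type named list of [phenotype_params()]; at least two.
#' @param library spectral component library.
#' @param raman_pixels,raman_pitch Raman grid (pixels and um per pixel).
#' @param tomo_dims,tomo_fov tomogram grid and physical extent (um).
#' @param center_jitter sd (um) of the random lateral offset of each cell.
#' @param out_dir when not NULL, hypercubes/tomograms are written there as
#'   multi-page TIFFs with sidecars and a `manifest.csv` (see
#'   [write_hypercube()], [write_tomogram()]).
#' @return list with `cells` (tibble: cell_id, label, seed, and list-columns
#'   `hypercube`, `raman_mask`, `tomogram`, `tomo_mask`) and `ground_truth`
#'   (tibble of the analytic per-cell values: label, weights, D, DM, V, S, A,
#'   T, phi, low-contrast flag).
#' @export
generate_cohort <- function(n_per_type,
                            seed,
                            params_by_type = default_phenotype_params(),
                            library = build_component_spectra(),
                            raman_pixels = 50L,
                            raman_pitch = 0.8,
                            tomo_dims = c(128L, 128L, 64L),
                            tomo_fov = c(40, 40, 40),
                            center_jitter = 1.0,
                            out_dir = NULL) {
  stopifnot(n_per_type >= 2L)
  if (length(params_by_type) < 2L) {
    stop("at least two phenotypes must be configured")
  }
  draws <- draw_cohort_truth(n_per_type, seed, params_by_type,
                             center_jitter = center_jitter)
  cells <- vector("list", nrow(draws$truth))
  for (i in seq_len(nrow(draws$truth))) {
    gt <- draws$truth[i, ]
    geom <- draws$geometry[[i]]
    par_i <- params_by_type[[gt$label]]
    rr <- render_raman_hypercube(geom, par_i, library,
                                 seed = gt$seed,
                                 n_pixels = raman_pixels,
                                 pixel_pitch = raman_pitch,
                                 weights = draws$weights[[i]])
    tt <- render_tomogram(geom, par_i, seed = gt$seed + 1L,
                          dims = tomo_dims, fov = tomo_fov,
                          concentration = gt$D)
    cells[[i]] <- tibble::tibble(
      cell_id = gt$cell_id, label = gt$label, seed = gt$seed,
      hypercube = list(rr$cube), raman_mask = list(rr$mask),
      tomogram = list(tt$tomogram), tomo_mask = list(tt$mask),
      low_contrast = tt$low_contrast
    )
  }
  cells <- dplyr::bind_rows(cells)
  truth <- dplyr::left_join(draws$truth,
                            dplyr::select(cells, "cell_id", "low_contrast"),
                            by = "cell_id")
  out <- list(cells = cells, ground_truth = truth)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# Sample per-cell ground truth (morphology, weights, geometry) for a cohort.
draw_cohort_truth <- function(n_per_type, seed, params_by_type,
                              center_jitter = 1.0) {
  set.seed(seed)
  labels <- names(params_by_type)
  rows <- list(); geoms <- list(); wts <- list()
  k <- 0L
  cell_seeds <- sample.int(.Machine$integer.max %/% 4L,
                           n_per_type * length(labels))
  for (lab in labels) {
    par_i <- params_by_type[[lab]]
    mm <- par_i$morphology_means; ms <- par_i$morphology_sds
    # draws truncated symmetrically at +/- 2 sd (keeps the mean, avoids
    # physically implausible tail geometries), then clamped to valid ranges
    rtrunc <- function(mean, sd) {
      min(max(rnorm(1, mean, sd), mean - 2 * sd), mean + 2 * sd)
    }
    for (j in seq_len(n_per_type)) {
      k <- k + 1L
      D <- max(rtrunc(mm[["D"]], ms[["D"]]), 1e-3)
      phi <- min(max(rtrunc(mm[["phi"]], ms[["phi"]]), 0.2), 0.98)
      T_ <- max(rtrunc(mm[["T"]], ms[["T"]]), 0.5)
      r <- solve_footprint_radius(phi, T_)
      ctr <- c(rnorm(2, 0, center_jitter), 0)
      geom <- cell_geometry(c(r, r, T_ / 2), center = ctr)
      w <- draw_component_weights(par_i)
      geoms[[k]] <- geom
      wts[[k]] <- w
      rows[[k]] <- tibble::tibble(
        cell_id = sprintf("%s_%02d", lab, j), label = lab,
        seed = cell_seeds[k],
        D = D, phi = geom$sphericity, T = geom$thickness,
        footprint_r = r,
        V = geom$volume, S = geom$surface, A = geom$footprint,
        DM = D * geom$volume,
        weights = list(w)
      )
    }
  }
  list(truth = dplyr::bind_rows(rows), geometry = geoms, weights = wts)
}

#' Simulate cell-averaged spectra and morphology without image rendering
#'
#' The moment-level fast path of the generator: produces directly the
#' per-cell records the statistical stages consume (cell-averaged spectrum +
#' morphological indexes), using the same per-phenotype distributions as
#' [generate_cohort()] but skipping hypercube/tomogram rendering. The
#' cell-averaged spectrum is the background mixture plus the mean projected
#' thickness (V/A) times the cellular component mixture, with spectral noise
#' shrunk by the effective number of averaged pixels.
#'
#' @inheritParams generate_cohort
#' @param background_weights named background component weights.
#' @param confocal_depth axial focal extent (um) matching the renderer's.
#' @param n_pixels_averaged effective number of cell pixels an average
#'   spectrum results from (controls residual noise on the mean).
#' @return list with `records` (tibble: cell_id, label, morphology columns,
#'   list-column `spectrum`) and `ground_truth` (as in [generate_cohort()]).
#' @export
simulate_cell_spectra <- function(n_per_type,
                                  seed,
                                  params_by_type = default_phenotype_params(),
                                  library = build_component_spectra(),
                                  background_weights = c(quartz_substrate = 3,
                                                         pbs_medium = 1.5),
                                  confocal_depth = 1.5,
                                  n_pixels_averaged = 450) {
  stopifnot(n_per_type >= 2L)
  if (length(params_by_type) < 2L) {
    stop("at least two phenotypes must be configured")
  }
  draws <- draw_cohort_truth(n_per_type, seed, params_by_type)
  comp <- library$components
  bg_spec <- as.numeric(comp[, names(background_weights), drop = FALSE] %*%
                          background_weights)
  recs <- vector("list", nrow(draws$truth))
  for (i in seq_len(nrow(draws$truth))) {
    gt <- draws$truth[i, ]
    w <- draws$weights[[i]]
    par_i <- params_by_type[[gt$label]]
    geom_i <- cell_geometry(c(gt$footprint_r, gt$footprint_r, gt$T / 2))
    t_mean <- mean_sampled_thickness(geom_i, confocal_depth)
    mix <- comp[, "nucleus"] * w[["nucleus"]] +
      comp[, "protein"] * w[["protein"]] +
      comp[, "lipid"] * w[["lipid"]] +
      comp[, "cytoplasm"] * w[["cytoplasm"]]
    spec <- bg_spec + t_mean * mix
    if (par_i$noise_sd > 0) {
      spec <- spec + rnorm(length(spec),
                           sd = par_i$noise_sd / sqrt(n_pixels_averaged))
    }
    recs[[i]] <- tibble::tibble(
      cell_id = gt$cell_id, label = gt$label,
      D = gt$D, phi = gt$phi, T = gt$T, V = gt$V, S = gt$S, A = gt$A,
      DM = gt$DM, ri_mean = 1.3342 + 0.19 * gt$D,
      spectrum = list(spec)
    )
  }
  list(records = dplyr::bind_rows(recs), ground_truth = draws$truth,
       axis = library$axis)
}
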