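test_that("identical seeds give bit-identical hypercubes and tomograms", {
  lib <- test_library()
  geom <- test_geometry()
  par <- default_phenotype_params()$HT29
  r1 <- render_raman_hypercube(geom, par, lib, seed = 7, n_pixels = 30L)
  r2 <- render_raman_hypercube(geom, par, lib, seed = 7, n_pixels = 30L)
  expect_identical(r1$cube$intensities, r2$cube$intensities)
  t1 <- render_tomogram(geom, par, seed = 7, dims = c(48L, 48L, 24L))
  t2 <- render_tomogram(geom, par, seed = 7, dims = c(48L, 48L, 24L))
  expect_identical(t1$tomogram$ri, t2$tomogram$ri)
  r3 <- render_raman_hypercube(geom, par, lib, seed = 8, n_pixels = 30L)
  expect_false(identical(r1$cube$intensities, r3$cube$intensities))
})

test_that("noise-free rendering makes every background pixel identical", {
  lib <- test_library()
  rr <- render_raman_hypercube(test_geometry(), quiet_params(), lib,
                               seed = 1, n_pixels = 30L)
  d <- dim(rr$cube$intensities)
  mat <- matrix(rr$cube$intensities, d[1] * d[2], d[3])
  bg <- mat[!as.logical(rr$mask), ]
  expect_equal(max(apply(bg, 2L, function(col) diff(range(col)))), 0)
})

test_that("geometry outside the field of view is rejected", {
  lib <- test_library()
  par <- quiet_params()
  geom <- cell_geometry(c(6, 6, 1.4), center = c(12, 0, 0))
  expect_error(render_raman_hypercube(geom, par, lib, seed = 1,
                                      n_pixels = 30L, pixel_pitch = 1),
               "field of view")
  expect_error(render_tomogram(geom, par, seed = 1, dims = c(48L, 48L, 24L),
                               fov = c(30, 30, 30)),
               "volume")
})

test_that("cosmic-spike counts follow the configured Poisson rate", {
  lib <- test_library(120L)
  geom <- test_geometry()
  par <- quiet_params(noise_sd = 0.002, spikes = 5)
  counts <- vapply(1:100, function(s) {
    render_raman_hypercube(geom, par, lib, seed = s, n_pixels = 12L,
                           pixel_pitch = 2)$n_spikes
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 100))
})

test_that("noiseless tomogram interior equals n0 + alpha C", {
  geom <- test_geometry()
  par <- quiet_params()
  tt <- render_tomogram(geom, par, seed = 1, dims = c(64L, 64L, 32L),
                        concentration = 0.159, nucleus_dC = 0,
                        ri_noise_sd = 0)
  inside <- tt$mask
  expect_equal(unique(tt$tomogram$ri[inside]), 1.3342 + 0.19 * 0.159,
               tolerance = 1e-12)
  expect_equal(unique(tt$tomogram$ri[!inside]), 1.3342, tolerance = 1e-12)
})

test_that("zero concentration renders an interior indistinguishable from background", {
  tt <- suppressWarnings(
    render_tomogram(test_geometry(), quiet_params(), seed = 1,
                    dims = c(48L, 48L, 24L), concentration = 1e-9,
                    nucleus_dC = 0, ri_noise_sd = 0))
  expect_lt(diff(range(tt$tomogram$ri)), 1e-8)
})

test_that("a low-contrast cell triggers the threshold warning and flag", {
  expect_warning(
    tt <- render_tomogram(test_geometry(), quiet_params(), seed = 1,
                          dims = c(48L, 48L, 24L), concentration = 0.03,
                          nucleus_dC = 0),
    "1.345")
  expect_true(tt$low_contrast)
})

test_that("digitised sphere volume is within 2% of the analytic value", {
  tt <- render_tomogram(cell_geometry(c(8, 8, 8), nucleus_fraction = 0),
                        quiet_params(), seed = 1,
                        dims = c(128L, 128L, 64L), fov = c(40, 40, 40),
                        concentration = 0.159, ri_noise_sd = 0)
  v_count <- sum(tt$mask) * prod(tt$tomogram$voxel_size)
  expect_lt(abs(v_count / (4 / 3 * pi * 8^3) - 1), 0.02)
})

test_that("ground-truth 3D mask equals the voxels above background in the noiseless field", {
  tt <- render_tomogram(test_geometry(), quiet_params(), seed = 3,
                        dims = c(48L, 48L, 24L), concentration = 0.15,
                        ri_noise_sd = 0)
  expect_identical(tt$mask, tt$tomogram$ri > tt$tomogram$background_ri)
})

test_that("cohorts have the requested size, labels and reproducibility", {
  sim1 <- simulate_cell_spectra(5, seed = 3, library = test_library())
  sim2 <- simulate_cell_spectra(5, seed = 3, library = test_library())
  expect_equal(nrow(sim1$records), 15L)
  expect_equal(as.vector(table(sim1$records$label)), rep(5L, 3L))
  expect_identical(sim1$records$spectrum, sim2$records$spectrum)
  expect_error(generate_cohort(1, seed = 1), "n_per_type")
  expect_error(
    generate_cohort(2, seed = 1,
                    params_by_type = default_phenotype_params()["HT29"]),
    "two phenotypes")
})

test_that("zero-variance parameters reproduce the configured morphology exactly", {
  pp <- default_phenotype_params()
  for (nm in names(pp)) {
    pp[[nm]]$morphology_sds[] <- 0
    pp[[nm]]$component_weights$sd <- 0
  }
  sim <- simulate_cell_spectra(2, seed = 9, params_by_type = pp,
                               library = test_library())
  by_type <- split(sim$records, sim$records$label)
  for (nm in names(by_type)) {
    expect_equal(unique(by_type[[nm]]$D), pp[[nm]]$morphology_means[["D"]])
    expect_equal(unique(by_type[[nm]]$T), pp[[nm]]$morphology_means[["T"]])
    expect_equal(unique(by_type[[nm]]$phi), pp[[nm]]$morphology_means[["phi"]],
                 tolerance = 1e-6)
  }
})

test_that("sample moments of D, phi, T recover the configured means", {
  sim <- simulate_cell_spectra(200, seed = 11, library = test_library(60L))
  pp <- default_phenotype_params()
  by_type <- split(sim$ground_truth, sim$ground_truth$label)
  for (nm in names(by_type)) {
    mm <- pp[[nm]]$morphology_means
    ms <- pp[[nm]]$morphology_sds
    for (v in c("D", "phi", "T")) {
      se <- ms[[v]] / sqrt(200)
      expect_lt(abs(mean(by_type[[nm]][[v]]) - mm[[v]]), 3 * se)
    }
  }
})

test_that("analytic thickness of every generated ellipsoid equals 2c exactly", {
  draws <- morphospec:::draw_cohort_truth(10, seed = 5,
                                          default_phenotype_params())
  for (g in draws$geometry) {
    expect_equal(g$thickness, 2 * g$semi_axes[3], tolerance = 1e-12)
    expect_equal(1.5 * g$volume / g$footprint, g$thickness, tolerance = 1e-12)
  }
  expect_equal(draws$truth$DM, draws$truth$D * draws$truth$V, tolerance = 1e-12)
})
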