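test_that("axis calibration recovers quadratic and nested linear models", {
  px <- c(10, 400, 800)
  shifts <- 600 + 1.2 * px + 2e-4 * px^2
  ax <- calibrate_axis(px, shifts, n_samples = 100L)
  cf <- attr(ax, "coefficients")
  expect_equal(unname(cf), c(600, 1.2, 2e-4), tolerance = 1e-9)
  expect_equal(max(abs(attr(ax, "residuals"))), 0, tolerance = 1e-9)
  # linear references: fitted curvature collapses to zero
  px6 <- seq(50, 900, length.out = 6)
  ax_lin <- calibrate_axis(px6, 500 + 1.5 * px6)
  expect_lt(abs(attr(ax_lin, "coefficients")[["a2"]]), 1e-9)
})

test_that("calibration on noisy points matches a normal-equations oracle", {
  set.seed(4)
  px <- c(30, 150, 320, 500, 700, 950)
  shifts <- 580 + 1.3 * px + 1e-4 * px^2 + rnorm(6, sd = 0.5)
  X <- cbind(1, px, px^2)
  beta <- solve(t(X) %*% X, t(X) %*% shifts)
  cf <- attr(calibrate_axis(px, shifts), "coefficients")
  expect_equal(unname(cf), as.numeric(beta), tolerance = 1e-8)
})

test_that("calibration input contracts are enforced", {
  expect_error(calibrate_axis(c(1, 2), c(600, 700)), "at least 3")
  expect_error(calibrate_axis(c(1, 2, 2), c(600, 700, 800)), "distinct")
  # wildly non-monotone references give a non-increasing fitted axis
  expect_error(calibrate_axis(c(1, 500, 1000), c(1800, 600, 1700)),
               "strictly increasing")
})

test_that("spike removal is a no-op on clean data and fixes injected spikes", {
  # peaks must be broad relative to the 5-sample running median at the
  # instrument's sampling density, as real Raman bands are
  axis <- test_axis(870L)
  x <- as.numeric(axis)
  clean <- 0.1 + 0.05 * sin(x / 60) +
    0.2 * morphospec:::lorentzian(x, 1007, 10)
  cube <- raman_hypercube(array(rep(clean, each = 4), c(2, 2, 870L)), axis)
  out <- remove_cosmic_spikes(cube)
  expect_identical(out$intensities, cube$intensities)
  expect_identical(attr(out, "n_replaced"), 0L)

  # one 50-sigma single-sample spike
  set.seed(41)
  noisy <- clean + rnorm(870L, sd = 0.001)
  spiked <- noisy
  spiked[300] <- spiked[300] + 50 * 0.001 * 10
  cube2 <- raman_hypercube(array(spiked, c(1, 1, 870L)), axis)
  out2 <- remove_cosmic_spikes(cube2)
  expect_gt(attr(out2, "n_replaced"), 0L)
  expect_lt(max(abs(out2$intensities[1, 1, ] - noisy)), 3 * 0.001 * 8)
  # samples away from the spike are bit-unchanged
  expect_identical(out2$intensities[1, 1, -(298:302)], spiked[-(298:302)])
})

test_that("a spike at the first sample is corrected by the shrinking end rule", {
  axis <- test_axis(50L)
  y <- rep(1, 50L)
  y[1] <- 100
  cube <- raman_hypercube(array(y, c(1, 1, 50L)), axis)
  out <- remove_cosmic_spikes(cube)
  expect_equal(out$intensities[1, 1, 1], 1)
})

test_that("spike removal rejects spectra shorter than the window", {
  cube <- raman_hypercube(array(1, c(2, 2, 3)), c(600, 700, 800))
  expect_error(remove_cosmic_spikes(cube), "window")
})

test_that("asPLS returns zero baseline for zero input and flags non-convergence", {
  z <- subtract_baseline_aspls(rep(0, 100))
  expect_equal(z$baseline, rep(0, 100))
  expect_equal(z$corrected, rep(0, 100))
  x <- seq(0, 1, length.out = 400)
  expect_warning(subtract_baseline_aspls(1 + x^2, max_iter = 2L),
                 "converge")
})

test_that("asPLS recovers a peak-free sigmoid baseline to better than 1% RMS", {
  x <- seq(600, 1800, length.out = 870)
  base <- 0.2 / (1 + exp(-(x - 1100) / 300))
  fit <- suppressWarnings(subtract_baseline_aspls(base))
  rms <- sqrt(mean((fit$baseline - base)^2))
  expect_lt(rms, 0.01 * diff(range(base)))
})

test_that("asPLS preserves Lorentzian peak areas on a quadratic baseline", {
  x <- seq(600, 1800, length.out = 870)
  lor <- function(c0, g) (g / pi) / ((x - c0)^2 + g^2)
  base <- 0.15 + 1.5e-4 * (x - 600) - 6e-8 * (x - 600)^2
  amps <- c(0.30, 0.25, 0.40)
  centers <- c(900, 1250, 1600)
  g <- 5
  y <- base + amps[1] * lor(900, g) + amps[2] * lor(1250, g) +
    amps[3] * lor(1600, g)
  fit <- suppressWarnings(subtract_baseline_aspls(y))
  for (i in 1:3) {
    w <- centers[i] + c(-60, 60)
    truth <- amps[i] * (atan(60 / g) - atan(-60 / g)) / pi
    est <- band_integral(fit$corrected, axis = x, lower = w[1], upper = w[2])
    expect_lt(abs(est / truth - 1), 0.05)
  }
})

test_that("Savitzky-Golay reproduces quadratics, its kernel, and its noise gain", {
  x <- seq_len(101)
  quad <- 2 + 0.3 * x - 0.01 * x^2
  expect_equal(smooth_savitzky_golay(quad), quad, tolerance = 1e-10)
  # impulse response equals the SG kernel
  imp <- rep(0, 51); imp[26] <- 1
  kern <- smooth_savitzky_golay(imp)[23:29]
  sg <- signal::sgolay(p = 2, n = 7)
  expect_equal(kern, as.numeric(sg[4, ]), tolerance = 1e-10)
  # white-noise variance shrinks by the sum of squared coefficients
  set.seed(8)
  noise <- rnorm(1e4)
  gain <- var(smooth_savitzky_golay(noise)[100:9900])
  expect_lt(abs(gain / sum(sg[4, ]^2) - 1), 0.1)
  expect_error(smooth_savitzky_golay(x, window = 6L), "odd")
  expect_error(smooth_savitzky_golay(x, window = 3L, order = 4L), "odd")
})

test_that("Frobenius normalisation has the closed form, scale invariance and exact norm", {
  axis <- c(700, 900)
  cube <- raman_hypercube(array(1, c(2, 2, 2)), axis)
  out <- normalize_frobenius(cube)
  expect_equal(as.numeric(out$intensities), rep(1 / sqrt(8), 8))
  set.seed(2)
  for (i in 1:20) {
    arr <- array(runif(2 * 3 * 5), c(2, 3, 5))
    c1 <- normalize_frobenius(raman_hypercube(arr, seq(600, 1000, length.out = 5)))
    c7 <- normalize_frobenius(raman_hypercube(7 * arr, seq(600, 1000, length.out = 5)))
    expect_equal(c1$intensities, c7$intensities, tolerance = 1e-12)
    expect_equal(sqrt(sum(c1$intensities^2)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_frobenius(
    raman_hypercube(array(0, c(2, 2, 2)), axis)), "zero")
  # idempotence
  expect_equal(normalize_frobenius(out)$intensities, out$intensities,
               tolerance = 1e-12)
})

test_that("preprocess_map applies stages in the fixed order and records provenance", {
  lib <- test_library(120L)
  rr <- render_raman_hypercube(test_geometry(), quiet_params(noise_sd = 1e-3),
                               lib, seed = 3, n_pixels = 12L, pixel_pitch = 2)
  out <- preprocess_map(rr$cube)
  expect_identical(out$provenance, c("spikes", "aspls", "savgol", "frobenius"))
  ident <- preprocess_map(rr$cube, spike_z = NULL, aspls_lambda = NULL,
                          savgol_window = NULL, frobenius = FALSE)
  expect_identical(ident$intensities, rr$cube$intensities)
  expect_identical(ident$provenance, character())
})

test_that("preprocessed background matches the clean substrate mixture", {
  lib <- test_library()
  par <- quiet_params(noise_sd = 0.002, baseline = 0.01, spikes = 2)
  rr <- render_raman_hypercube(test_geometry(), par, lib, seed = 5,
                               n_pixels = 30L)
  cube <- preprocess_map(rr$cube)
  d <- dim(cube$intensities)
  mat <- matrix(cube$intensities, d[1] * d[2], d[3])
  bg_mean <- colMeans(mat[!as.logical(rr$mask), ])
  clean <- as.numeric(lib$components[, c("quartz_substrate", "pbs_medium")] %*%
                        c(3, 1.5))
  # the baseline stage removes the broad quartz pedestal from signal and
  # reference alike, so compare against the same filtering of the clean mix
  clean_corr <- smooth_savitzky_golay(
    suppressWarnings(subtract_baseline_aspls(clean))$corrected)
  expect_gt(stats::cor(bg_mean, clean_corr), 0.95)
})
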