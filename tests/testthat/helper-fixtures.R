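# Shared fixtures. Most tests run on a reduced spectral axis and small
# grids so the suite stays fast; full-size runs live in the acceptance
# tests.

test_axis <- function(n = 300L) default_wavenumber_axis(n)

test_library <- function(n = 300L) build_component_spectra(test_axis(n))

# A small, quiet phenotype parameter set for rendering tests.
quiet_params <- function(label = "HT29", noise_sd = 0, baseline = 0,
                         spikes = 0) {
  p <- default_phenotype_params()[[label]]
  p$noise_sd <- noise_sd
  p$baseline_amplitude <- baseline
  p$spike_rate <- spikes
  p
}

test_geometry <- function(a = 6, b = 6, c = 1.4, center = c(0, 0, 0)) {
  cell_geometry(c(a, b, c), center = center)
}

# Dice overlap of two logical masks.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Digitised ellipsoid mask on a voxel grid, centred.
digitize_ellipsoid <- function(semi_axes, voxel, pad = 3) {
  dims <- ceiling(2 * (semi_axes / voxel + pad))
  ax <- lapply(1:3, function(d) (seq_len(dims[d]) - (dims[d] + 1) / 2) * voxel[d])
  ux <- ax[[1]]^2 / semi_axes[1]^2
  uy <- ax[[2]]^2 / semi_axes[2]^2
  uz <- ax[[3]]^2 / semi_axes[3]^2
  outer(outer(ux, uy, "+"), uz, "+") < 1
}

# Thomsen approximate ellipsoid surface area (test-side reference for
# triaxial shapes; exact for spheres up to the approximation error < 1.1%).
thomsen_surface <- function(a, b, c) {
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

# Independent multinomial log-likelihood for an optimiser oracle:
# coefficient matrix beta is (G-1) x (p+1), reference class first.
mlor_loglik <- function(beta_vec, X, y_idx, G) {
  p1 <- ncol(X) + 1L
  beta <- matrix(beta_vec, G - 1L, p1)
  eta <- cbind(0, cbind(1, X) %*% t(beta))
  eta <- eta - apply(eta, 1L, max)
  logp <- eta - log(rowSums(exp(eta)))
  sum(logp[cbind(seq_along(y_idx), y_idx)])
}

# Decimal places of a number as printed in fixed notation (0.006 -> 3).
nchar_decimals <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  if (!grepl("\\.", s)) return(0L)
  nchar(sub(".*\\.", "", s))
}

# Cached small rendered cohort (built once per test run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # full 870-sample axis: at coarser spectral sampling the narrow
      # bands are indistinguishable from cosmic spikes
      cache <<- generate_cohort(
        2, seed = 42,
        tomo_dims = c(96L, 96L, 48L)
      )
    }
    cache
  }
})
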