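# Internal numeric helpers shared across modules.

#' Otsu threshold of a numeric vector
#'
#' Picks the cut that maximises between-class variance of the two groups it
#' induces, computed on a fixed-width histogram of the values. Used to split
#' PC1 scores into cell and background pixels.
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins.
#' @return the threshold value (a scalar between `min(x)` and `max(x)`).
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop("otsu_threshold(): input has no variation, cannot split into two classes")
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Label connected components of a logical mask
#'
#' 8-connectivity for matrices, 26-connectivity for 3D arrays.
#'
#' @param mask logical matrix or 3D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @keywords internal
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) %in% c(2L, 3L))
  cpp_label_components(as.logical(mask), as.integer(dim(mask)))
}

# Keep only the largest connected component of a logical mask.
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  keep <- which.max(tabulate(lab[lab > 0L]))
  array(lab == keep, dim = dim(mask))
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxel units.
# Replicate-padded at the borders (the kernel is renormalised there).
smooth_gaussian_3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L, length(sigma) == 3L)
  for (d in 1:3) {
    if (sigma[d] <= 0) next
    a <- convolve_along(a, gauss_kernel_1d(sigma[d]), d)
  }
  a
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_along <- function(a, k, dim) {
  d <- dim(a)
  n <- d[dim]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (j in seq_along(k)) K[i, idx[j]] <- K[i, idx[j]] + k[j]
  }
  perm <- c(dim, setdiff(1:3, dim))
  ap <- aperm(a, perm)
  out <- K %*% matrix(ap, nrow = n)
  aperm(array(out, d[perm]), order(perm))
}

# Running median with window 5; Tukey's end rule shrinks the window at the
# boundaries so first/last samples are still smoothed (replicate padding
# would copy an edge spike into its own reference).
running_median5 <- function(y) {
  n <- length(y)
  if (n < 5L) stop("running_median5(): spectrum shorter than the window")
  as.numeric(runmed(y, k = 5L, endrule = "median"))
}

# Trapezoid integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
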