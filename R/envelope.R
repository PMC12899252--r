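# Molecular-envelope reconstruction: Gaussian-weighted density averaging,
# solvent-content thresholding, and mask agreement scoring.

# fast core: smooth a density vector with a periodic Gaussian of sd sigma (A)
# via reciprocal space; s2g = per-coefficient |s|^2 vector.
smooth_core <- function(v, n, s2g, sigma) {
  K <- exp(-2 * pi^2 * sigma^2 * s2g)
  Re(stats::fft(array(stats::fft(array(v, n)) * K, n), inverse = TRUE)) / length(v)
}

#' Gaussian-weighted density average
#'
#' Convolves the map with a normalized periodic Gaussian kernel of standard
#' deviation `sigma` (Angstrom), implemented in reciprocal space (multiplying
#' coefficients by `exp(-2 pi^2 sigma^2 s^2)`) so periodicity is exact.
#' Constant maps are mapped to themselves.
#'
#' @param map A [density_map()].
#' @param sigma Kernel standard deviation in Angstrom (> 0).
#' @param ctx Optional [phasing_context()] supplying the cached `s^2` grid.
#' @return The smoothed [density_map()].
#' @export
gaussian_weights <- function(map, sigma, ctx = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  n <- dim(map$values)
  s2g <- if (!is.null(ctx)) ctx$s2g else as.vector(grid_s2(n, map$cell))
  # kernel far below the grid scale: indistinguishable from identity
  if (exp(-2 * pi^2 * sigma^2 * max(s2g)) > 1 - 1e-6) {
    warning("sigma is below the grid scale; returning the map unchanged")
    return(map)
  }
  density_map(array(smooth_core(as.vector(map$values), n, s2g, sigma), n), map$cell)
}

#' Envelope smoothing-width schedule
#'
#' Linear interpolation of the Gaussian envelope width from `sigma_start` at
#' iteration 0 to `sigma_end` at iteration `n_iter` (coarse-to-fine: locate
#' the envelope early, refine the boundary later).
#'
#' @param iter Current iteration (0-based).
#' @param n_iter Iteration at which `sigma_end` is reached.
#' @param sigma_start,sigma_end Schedule endpoints in Angstrom (defaults 4.0
#'   and 2.5).
#' @return Sigma in Angstrom.
#' @export
sigma_schedule <- function(iter, n_iter, sigma_start = 4.0, sigma_end = 2.5) {
  stopifnot(n_iter >= 1)
  f <- min(max(iter / n_iter, 0), 1)
  sigma_start + f * (sigma_end - sigma_start)
}

#' Threshold smoothed density into a protein mask
#'
#' Marks the `(1 - solvent_fraction)` fraction of voxels with the highest
#' smoothed density as protein; the threshold is the corresponding order
#' statistic, with ties broken deterministically by voxel index.
#'
#' @param w A [density_map()] of smoothed density (weights).
#' @param solvent_fraction Solvent fraction in (0, 1), e.g. from the
#'   Matthews coefficient.
#' @return A [density_mask()].
#' @export
mask_from_weights <- function(w, solvent_fraction) {
  stopifnot(solvent_fraction > 0, solvent_fraction < 1)
  v <- as.vector(w$values)
  k <- max(1L, round((1 - solvent_fraction) * length(v)))
  inside <- logical(length(v))
  inside[order(v, decreasing = TRUE, method = "radix")[seq_len(k)]] <- TRUE
  density_mask(array(inside, dim(w$values)), w$cell)
}

# fast core used by the engine: returns protein voxel indices
mask_core <- function(v, protein_count) {
  sort.int(order(v, decreasing = TRUE, method = "radix")[seq_len(protein_count)])
}

#' Intersection-over-union of two masks
#'
#' `|A and B| / |A or B|`; defined as 1 when both masks are empty.
#'
#' @param a,b [density_mask()] objects on the same grid.
#' @return A fraction in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a$inside) == dim(b$inside))) stop("mask grids differ")
  u <- sum(a$inside | b$inside)
  if (u == 0) return(1)
  sum(a$inside & b$inside) / u
}
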