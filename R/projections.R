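#' Reference protein density histogram
#'
#' An ordered set of quantiles sampling the cumulative distribution of
#' protein-region electron density at the working resolution. Protein-region
#' density histograms at a given resolution are remarkably similar across
#' unrelated proteins, so a histogram taken from any model at the right
#' resolution is an effective real-space constraint.
#'
#' @param quantiles Monotone non-decreasing numeric vector (length >= 2) of
#'   density values at levels `(i - 0.5) / length(quantiles)`.
#' @param resolution Resolution (Angstrom) the histogram corresponds to.
#' @return An object of class `histogram_ref`.
#' @export
histogram_ref <- function(quantiles, resolution = NA_real_) {
  q <- as.numeric(quantiles)
  if (length(q) < 2) stop("a histogram reference needs at least 2 quantiles")
  if (is.unsorted(q)) stop("histogram quantiles must be non-decreasing")
  structure(list(quantiles = q, resolution = resolution), class = "histogram_ref")
}

#' @export
print.histogram_ref <- function(x, ...) {
  cat(sprintf("<histogram_ref> %d quantiles in [%.4g, %.4g], resolution %.3g A\n",
              length(x$quantiles), min(x$quantiles), max(x$quantiles), x$resolution))
  invisible(x)
}

#' Build a reference histogram from a model map
#'
#' Extracts the quantiles of the protein-region density of a model map. The
#' quantile at level `p` is the linear interpolation of the sorted values at
#' rank `p * m + 0.5` (so for values 1..4 and two quantiles the result is the
#' lower and upper medians, 1.5 and 3.5).
#'
#' @param model_map A [density_map()] at the working resolution.
#' @param mask A [density_mask()]; quantiles are taken over `inside` voxels.
#' @param n_quantiles Number of quantiles (>= 2); use the protein voxel count
#'   for a lossless reference.
#' @param resolution Optional resolution label (Angstrom).
#' @return A [histogram_ref()].
#' @export
make_reference_histogram <- function(model_map, mask, n_quantiles = 512L,
                                     resolution = NA_real_) {
  if (n_quantiles < 2) stop("n_quantiles must be >= 2")
  v <- model_map$values[mask$inside]
  if (length(v) == 0) stop("empty protein region")
  histogram_ref(quantile_midrank(sort(v), (seq_len(n_quantiles) - 0.5) / n_quantiles),
                resolution)
}

# interpolated inverse empirical CDF on midpoint ranks:
# level (i-0.5)/m maps exactly to sorted[i]; clamped at the ends
quantile_midrank <- function(sorted, p) {
  m <- length(sorted)
  if (m == 1) return(rep(sorted, length(p)))
  stats::approx(x = (seq_len(m) - 0.5) / m, y = sorted, xout = p, rule = 2)$y
}

# sorted target values for a protein region of m voxels
href_targets <- function(href, m) {
  quantile_midrank(href$quantiles, (seq_len(m) - 0.5) / m)
}

#' Serialize a histogram reference
#'
#' Two-column whitespace-separated text: quantile index, density value.
#' @param href A [histogram_ref()].
#' @param path File path.
#' @export
write_histogram_ref <- function(href, path) {
  writeLines(c(sprintf("# hdmphase histogram v1 resolution %.10g", href$resolution),
               sprintf("%d %.17g", seq_along(href$quantiles), href$quantiles)), path)
  invisible(path)
}

#' @rdname write_histogram_ref
#' @export
read_histogram_ref <- function(path) {
  lines <- readLines(path)
  res <- NA_real_
  if (grepl("resolution", lines[1])) {
    res <- suppressWarnings(as.numeric(sub(".*resolution\\s+", "", lines[1])))
    lines <- lines[-1]
  }
  dat <- utils::read.table(text = paste(lines, collapse = "\n"))
  histogram_ref(dat[[2]][order(dat[[1]])], res)
}

# ---- PA: real-space projection ---------------------------------------------

# fast core: x numeric vector, pidx protein voxel indices, targets sorted values
pa_core <- function(x, pidx, targets) {
  out <- numeric(length(x))
  xv <- x[pidx]
  out[pidx[order(xv, method = "radix")]] <- targets
  out
}

#' Real-space projection PA: histogram matching and solvent flattening
#'
#' Sets every solvent voxel to exactly zero and rank-order remaps the protein
#' region onto the reference histogram: the voxel of rank r (ties broken by
#' voxel index) receives the reference quantile at level `(r - 0.5) / m`.
#' The operator is idempotent.
#'
#' @param map A [density_map()].
#' @param mask A [density_mask()] on the same grid.
#' @param href A [histogram_ref()].
#' @return The projected [density_map()].
#' @export
project_real <- function(map, mask, href) {
  stopifnot(all(dim(map$values) == dim(mask$inside)))
  pidx <- which(mask$inside)
  if (length(pidx) == 0) stop("empty protein region")
  out <- pa_core(as.vector(map$values), pidx, href_targets(href, length(pidx)))
  density_map(array(out, dim(map$values)), map$cell)
}

# ---- PB: Fourier-space projection ------------------------------------------

#' Amplitude scale factor
#'
#' The scale between observed and calculated amplitudes,
#' `lambda = sum(|Fobs|) / sum(|Fcal|)` over the work set.
#'
#' @param rs A [reflection_set()].
#' @param sf A [complex_sf()] aligned row-wise with `rs`.
#' @return The scalar scale factor.
#' @export
scale_factor <- function(rs, sf) {
  w <- rs$refl$status == "work"
  if (!any(w) || sum(rs$refl$f_obs[w]) <= 0)
    stop("scale factor needs at least one work reflection with f_obs > 0")
  den <- sum(sf$f[w])
  if (den <= 0) stop("degenerate input: all calculated work amplitudes are zero")
  sum(rs$refl$f_obs[w]) / den
}

#' Fill amplitudes of excluded reflections from calculated values
#'
#' Reflections that are missing, free, noisy or at very low resolution take
#' the amplitude `(sum |Fobs| / sum |Fcal|) * |Fcal(h)|`, with sums over the
#' work set: the calculated amplitude rescaled to the observed scale.
#'
#' @param rs A [reflection_set()].
#' @param sf A [complex_sf()] aligned row-wise with `rs`.
#' @return Numeric vector over all reflections: `f_obs` for work reflections,
#'   the filled amplitude for the rest.
#' @export
fill_missing <- function(rs, sf) {
  w <- rs$refl$status == "work"
  den <- sum(sf$f[w])
  if (!any(w) || den <= 0) stop("degenerate input: work-set amplitude sums must be positive")
  kappa <- sum(rs$refl$f_obs[w]) / den
  ifelse(w, rs$refl$f_obs, kappa * sf$f)
}

# fast PB core operating on the Fourier coefficients of the current map.
# F: complex fft array; w: per-reflection weights in [0,1].
# Only coefficients belonging to measured reflections (the whole symmetry
# orbit) are touched; everything else (F(000) included) passes through.
# Returns list(F = projected coefficients, amp = per-reflection |Fcal|).
pb_core <- function(F, ctx, w = NULL) {
  idx <- ctx$idx
  amp <- Mod(F[idx$rep_of])
  den <- sum(amp[ctx$work])
  if (den <= 0) stop("degenerate input: all calculated work amplitudes are zero")
  if (is.null(w)) w <- rep(1, idx$nrefl)
  lam_w <- sum(w[ctx$work] * ctx$f_obs[ctx$work]) / den
  target <- numeric(idx$nrefl)
  target[ctx$work] <- w[ctx$work] * ctx$f_obs[ctx$work] / lam_w
  # filled (non-work) reflections keep the calculated amplitude on the map
  # scale: this equals the observed-scale fill (sum|Fobs|/sum|Fcal|)·|Fcal|
  # divided by the same lambda at unit weights, and stays neutral under
  # resolution weighting (a weighted ratio here would feed back on itself)
  target[!ctx$work] <- amp[!ctx$work]
  z <- F[idx$coef]
  a <- Mod(z)
  tt <- target[idx$refl]
  ok <- a > 0
  z[ok] <- z[ok] * (tt[ok] / a[ok])
  z[!ok] <- tt[!ok]          # undefined phase: take phase 0 by convention
  F[idx$coef] <- z
  # F(000) and coefficients beyond the measured sphere pass through: they are
  # unmeasured, and the real-space constraints determine them
  list(F = F, amp = amp)
}

#' Fourier-space projection PB: amplitude replacement
#'
#' Replaces the calculated Fourier amplitudes of the map with the observed
#' diffraction amplitudes (optionally resolution-weighted), keeping the
#' calculated phases. Work reflections take `weights(h) * |Fobs(h)| / lambda`
#' where `lambda = sum(w |Fobs|) / sum(|Fcal|)` over the work set; free,
#' missing, large-error and low-resolution reflections are filled from
#' calculated values — on the map scale they simply keep their calculated
#' amplitude, which equals the observed-scale fill of [fill_missing()]
#' rescaled by the same lambda; `F(000)` and Fourier coefficients beyond the
#' measured resolution sphere are unmeasured and pass through unchanged —
#' the real-space constraints determine them. The operator is idempotent.
#'
#' @param map A [density_map()].
#' @param rs A [reflection_set()].
#' @param weights Optional per-reflection weights in `[0, 1]` (default 1).
#' @param ctx Optional [phasing_context()].
#' @return The projected [density_map()].
#' @export
project_fourier <- function(map, rs, weights = NULL, ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  stopifnot(all(dim(map$values) == ctx$n))
  if (!is.null(weights) && (any(weights < 0) || any(weights > 1)))
    stop("weights must lie in [0, 1]")
  pb <- pb_core(stats::fft(map$values), ctx, weights)
  density_map(array(Re(stats::fft(pb$F, inverse = TRUE)) / ctx$N, ctx$n), map$cell)
}
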