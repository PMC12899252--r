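#' Complex structure factors
#'
#' Per-reflection complex structure factors, stored as a tibble with columns
#' `h, k, l`, `f` (amplitude, >= 0) and `phi` (phase in degrees, `[0, 360)`),
#' in the same row order as the owning [reflection_set()].
#'
#' @param hkl Integer matrix of Miller indices (3 columns).
#' @param f Amplitudes.
#' @param phi Phases in degrees.
#' @return A tibble of class `complex_sf`.
#' @export
complex_sf <- function(hkl, f, phi) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  if (any(f < 0)) stop("structure-factor amplitudes must be >= 0")
  out <- tibble::tibble(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                        l = as.integer(hkl[, 3]),
                        f = as.numeric(f), phi = as.numeric(phi) %% 360)
  class(out) <- c("complex_sf", class(out))
  out
}

sf_complex_values <- function(sf) sf$f * exp(1i * sf$phi * pi / 180)

#' Precomputed phasing context
#'
#' Bundles everything that depends only on the reflection set and the grid:
#' the mapping from symmetry-unique reflections to Fourier-coefficient array
#' positions (whole orbit, Friedel mates included), the per-coefficient
#' reciprocal-space magnitudes, and the voxel permutations realising the
#' space-group operations. Building it once and passing it to
#' [fft_density_to_sf()], [project_fourier()] or the iterator steps avoids
#' repeated set-up work.
#'
#' @param rs A [reflection_set()].
#' @param grid Optional integer vector (nx, ny, nz); default from
#'   [grid_for_resolution()].
#' @param spacing Optional voxel spacing passed to [grid_for_resolution()].
#' @return An object of class `phasing_context`.
#' @export
phasing_context <- function(rs, grid = NULL, spacing = NULL) {
  if (is.null(grid)) grid <- grid_for_resolution(rs$cell, rs$d_min, spacing)
  grid <- as.integer(grid)
  H <- as.matrix(rs$refl[, c("h", "k", "l")])
  idx <- sf_index(H, rs$sg, grid)
  structure(list(
    cell = rs$cell, sg = rs$sg, n = grid, N = prod(grid),
    H = H, idx = idx,
    f_obs = rs$refl$f_obs,
    s = rs$refl$s,
    work = rs$refl$status == "work",
    s2g = as.vector(grid_s2(grid, rs$cell)),
    perms = sym_perms(rs$sg, grid)
  ), class = "phasing_context")
}

#' @export
print.phasing_context <- function(x, ...) {
  cat(sprintf("<phasing_context> grid %d x %d x %d, %d reflections (%d work), %s\n",
              x$n[1], x$n[2], x$n[3], x$idx$nrefl, sum(x$work), x$sg$symbol))
  invisible(x)
}

ctx_for <- function(rs, ctx, map = NULL) {
  if (!is.null(ctx)) return(ctx)
  phasing_context(rs, grid = if (!is.null(map)) dim(map$values) else NULL)
}

#' Fourier transforms between density maps and structure factors
#'
#' `fft_density_to_sf()` computes the structure factors of a map at the
#' reflections of `rs` (amplitude and phase at each symmetry-unique index);
#' `sf_to_density()` synthesizes the map from per-reflection structure
#' factors, filling the whole symmetry orbit (Friedel mates conjugated) and
#' leaving all other Fourier coefficients at zero.
#'
#' @param map A [density_map()].
#' @param rs A [reflection_set()].
#' @param sf A [complex_sf()] aligned row-wise with `rs`.
#' @param grid Grid dimensions for the synthesized map (defaults to the
#'   context grid).
#' @param ctx Optional [phasing_context()] (built on demand otherwise).
#' @return `fft_density_to_sf()` a [complex_sf()]; `sf_to_density()` a
#'   [density_map()].
#' @export
fft_density_to_sf <- function(map, rs, ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  stopifnot(all(dim(map$values) == ctx$n))
  F <- stats::fft(map$values)
  z <- F[ctx$idx$rep_of]
  complex_sf(ctx$H, Mod(z), Arg(z) * 180 / pi)
}

#' @rdname fft_density_to_sf
#' @export
sf_to_density <- function(sf, rs, grid = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- phasing_context(rs, grid = grid)
  stopifnot(nrow(sf) == ctx$idx$nrefl)
  A <- array(0i, ctx$n)
  z <- sf_complex_values(sf)
  v <- z[ctx$idx$refl]
  v[ctx$idx$cnj] <- Conj(v[ctx$idx$cnj])
  A[ctx$idx$coef] <- v * ctx$idx$fac
  density_map(array(Re(stats::fft(A, inverse = TRUE)) / ctx$N, ctx$n), ctx$cell)
}
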