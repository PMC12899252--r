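# Post-processing of converged runs: origin/hand alignment of independently
# converged maps, ensemble averaging, and final phase output.

#' Align one map onto another over the allowed origin shifts
#'
#' Transforms `mov` by the allowed origin translation (the whole grid where
#' the origin is continuous, as in P1) and, where the space group leaves the
#' hand ambiguous, inversion, maximizing the real-space correlation with
#' `ref`. The identity is always a candidate, so alignment never decreases
#' the correlation.
#'
#' @param ref,mov [density_map()]s on the same grid.
#' @param sg A [space_group()]; `NULL` treats the origin as continuous and
#'   the hand as ambiguous.
#' @return The aligned `mov` as a [density_map()], with attributes `shift`
#'   (voxels), `inverted` and `correlation`.
#' @export
align_pair <- function(ref, mov, sg = NULL) {
  stopifnot(all(dim(ref$values) == dim(mov$values)))
  n <- dim(ref$values)
  rv <- as.vector(ref$values)
  tr <- align_transform(rv, as.vector(mov$values), n, sg)
  out <- if (tr$inverted || any(tr$shift != 0)) {
    v <- apply_transform(tr$Fm, n, tr$shift, tr$inverted)
    if (!is.null(sg) && sg$order > 1) {
      # inversion may land outside the group's origin convention; re-symmetrize
      perms <- sym_perms(sg, n)
      if (tr$inverted && !is.null(perms)) {
        acc <- numeric(length(v)); for (p in perms) acc <- acc + v[p]
        v <- acc / length(perms)
      }
    }
    density_map(array(v, n), mov$cell)
  } else mov
  attr(out, "shift") <- tr$shift
  attr(out, "inverted") <- tr$inverted
  attr(out, "correlation") <- stats::cor(rv, as.vector(out$values))
  out
}

#' Average independently converged density maps
#'
#' Aligns every map onto the reference (by default the first; pass the index
#' of the best-R_free map for ensemble use) and returns the voxel-wise mean.
#' Averaging reduces the random component of the phase error; beyond about 20
#' maps the additional improvement is marginal, hence the default cap.
#'
#' @param maps Non-empty list of [density_map()]s on a common grid.
#' @param sg A [space_group()] (`NULL` = continuous origin, free hand).
#' @param ref_index Index of the reference map.
#' @param max_maps Use at most this many maps (including the reference).
#' @return The averaged [density_map()].
#' @export
average_maps <- function(maps, sg = NULL, ref_index = 1L, max_maps = 20L) {
  if (length(maps) == 0) stop("need at least one map to average")
  keep <- unique(c(ref_index, seq_along(maps)))[seq_len(min(length(maps), max_maps))]
  maps <- maps[keep]
  ref <- maps[[1]]
  acc <- as.vector(ref$values)
  if (length(maps) > 1) {
    for (m in maps[-1]) acc <- acc + as.vector(align_pair(ref, m, sg)$values)
  }
  density_map(array(acc / length(maps), dim(ref$values)), ref$cell)
}

#' Mean phase error of a map against known true phases
#'
#' Computes the structure-factor phases of `map` and the mean phase error
#' (degrees, work set) against `truth`, by default minimized over the allowed
#' origin shifts and, where ambiguous, inversion — the standard way to score
#' an ab initio solution whose origin and hand are arbitrary.
#'
#' @param map A [density_map()].
#' @param rs A [reflection_set()].
#' @param truth A [complex_sf()] of true structure factors.
#' @param align Minimize over allowed origin shifts / inversion (default).
#' @param ctx Optional [phasing_context()].
#' @return Mean phase error in degrees.
#' @export
map_phase_error <- function(map, rs, truth, align = TRUE, ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  F <- stats::fft(map$values)
  if (!align) {
    phi_cal <- Arg(F[ctx$idx$rep_of])
    w <- ctx$work
    return(dphi_core(truth$phi[w] * pi / 180, phi_cal[w]))
  }
  sh <- list(ctx = ctx, work = ctx$work, H = ctx$H,
             phi_true = truth$phi * pi / 180, align_idx = NULL)
  A <- array(0i, ctx$n)
  z <- sf_complex_values(truth)
  v <- z[ctx$idx$refl]
  v[ctx$idx$cnj] <- Conj(v[ctx$idx$cnj])
  A[ctx$idx$coef] <- v * ctx$idx$fac
  sh$Ftrue <- A
  if (is.matrix(ctx$sg$origin_shifts)) {
    tm <- ctx$sg$origin_shifts
    iv <- round(tm %*% diag(ctx$n)) %% matrix(ctx$n, nrow(tm), 3, byrow = TRUE)
    sh$align_idx <- as.integer(iv[, 1] + ctx$n[1] * (iv[, 2] + ctx$n[2] * iv[, 3]) + 1)
  }
  best_phase_error(F, sh)
}

#' Final phase output from a (possibly averaged) map
#'
#' Re-projects the map once through the Fourier amplitude constraint and
#' returns the resulting structure factors (observed-scale amplitudes with
#' the map's phases) — the final deliverable of a phasing run.
#'
#' @param map A [density_map()].
#' @param rs A [reflection_set()].
#' @param ctx Optional [phasing_context()].
#' @return A [complex_sf()].
#' @export
finalize_phases <- function(map, rs, ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  pb <- project_fourier(map, rs, ctx = ctx)
  fft_density_to_sf(pb, rs, ctx = ctx)
}
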