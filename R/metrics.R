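# Quantitative assessment of a phasing run: R factors, mean phase error,
# and the regional density deviations used as a truth-free convergence
# criterion. Envelope agreement (IoU) lives with the envelope code.

#' Crystallographic R factor
#'
#' `R = sum(||Fobs| - lambda |Fcal||) / sum(|Fobs|)` over the chosen subset.
#' The scale `lambda` always comes from the work set (also when scoring the
#' free set), see [scale_factor()].
#'
#' @param rs A [reflection_set()].
#' @param sf A [complex_sf()] aligned row-wise with `rs`.
#' @param subset `"work"` or `"free"`.
#' @return The R factor (>= 0).
#' @export
r_factor <- function(rs, sf, subset = c("work", "free")) {
  subset <- match.arg(subset)
  lam <- scale_factor(rs, sf)
  sel <- rs$refl$status == subset
  if (!any(sel)) stop("empty ", subset, " subset")
  sum(abs(rs$refl$f_obs[sel] - lam * sf$f[sel])) / sum(rs$refl$f_obs[sel])
}

#' Mean phase error
#'
#' `mean(arccos(cos(phi_true - phi_cal)))` over work reflections, in degrees;
#' the result lies in `[0, 180]` and is 90 on average for random phases.
#'
#' @param rs A [reflection_set()].
#' @param phi_true,phi_cal [complex_sf()] objects (or anything with a `phi`
#'   column in degrees) aligned row-wise with `rs`.
#' @return Mean phase error in degrees.
#' @export
mean_phase_error <- function(rs, phi_true, phi_cal) {
  w <- rs$refl$status == "work"
  if (!any(w)) stop("empty work subset")
  pt <- phi_true$phi[w]
  pc <- phi_cal$phi[w]
  if (anyNA(pt) || anyNA(pc)) stop("missing phases")
  mean(acos(cos((pt - pc) * pi / 180))) * 180 / pi
}

# fast core on radian vectors
dphi_core <- function(pt_rad, pc_rad) mean(acos(pmin(1, pmax(-1, cos(pt_rad - pc_rad))))) * 180 / pi

# per-algorithm protein-region residual term from the cached projections
dev_term <- function(algorithm, rho, pb, papb, pa) {
  switch(algorithm,
    hdm_f1 = , hdm_f2 = , diffmap = 2 * papb - pa - pb,
    hdm_f3 = , hdm_f4 = papb - pa,
    hdm_f5 = , hdm_f6 = papb - pb,
    hio = papb - rho,
    stop("unknown algorithm: ", algorithm))
}

#' Regional density deviations
#'
#' A truth-free convergence monitor: the mean absolute value of the update
#' rule's own protein-region residual term over the protein region, and of
#' the amplitude-projected density `PB rho` over the solvent region. Both
#' remain high while the iteration searches and drop sharply at convergence.
#' For the first hybrid formula the protein term is `(2 PA.PB - PA - PB) rho`;
#' the other update rules use their own bracketed terms.
#'
#' @param map A [density_map()] (the current iterate).
#' @param mask A [density_mask()] (current protein region).
#' @param rs A [reflection_set()].
#' @param href A [histogram_ref()].
#' @param algorithm Update-rule name, see [phasing_config()].
#' @param weights Optional per-reflection PB weights.
#' @param ctx Optional [phasing_context()].
#' @return Named numeric vector `c(dev_protein, dev_solvent)`.
#' @export
density_deviation <- function(map, mask, rs, href, algorithm = "hdm_f1",
                              weights = NULL, ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  rho <- as.vector(map$values)
  pidx <- which(mask$inside)
  if (length(pidx) == 0) stop("empty protein region")
  pb <- as.vector(project_fourier(map, rs, weights, ctx)$values)
  targets <- href_targets(href, length(pidx))
  papb <- pa_core(pb, pidx, targets)
  pa <- pa_core(rho, pidx, targets)
  term <- dev_term(algorithm, rho, pb, papb, pa)
  c(dev_protein = mean(abs(term[pidx])),
    dev_solvent = mean(abs(pb[-pidx])))
}
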