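# Synthetic toy crystals: Gaussian pseudo-atoms in a unit cell, with exact
# structure-factor amplitudes, known true phases, a true protein mask and a
# matching reference histogram. The truth is constructed to satisfy both
# phasing constraints exactly (solvent exactly zero, cell mean exactly zero,
# histogram identical to its own reference), so it is a genuine fixed point
# of every iterator.

#' Generate a toy crystal with known ground truth
#'
#' Emulates a small protein crystal: `n_blobs` Gaussian pseudo-atoms (seeded
#' random positions inside a molecular ball whose volume matches the protein
#' fraction, widths 0.8-1.2 Angstrom, random weights) ride on a smooth
#' envelope pedestal — the molecular envelope of a real protein is filled
#' with near-uniform density, which is what gives solvent flattening its
#' contrast. Blob density is synthesized in reciprocal space (exact
#' periodicity); the true protein mask is the top `(1 - solvent_fraction)`
#' fraction of the Gaussian-smoothed density; the solvent region is then
#' zeroed exactly. Observed amplitudes are the exact structure-factor moduli
#' of this true map; true phases are stored alongside (the unmeasured
#' F(000), the integral of the protein density, stays positive). For space groups beyond P1
#' the molecule sits at a general position and is expanded over the symmetry
#' operations.
#'
#' @param cell A [unit_cell()] (default 30 Angstrom cube).
#' @param sg A [space_group()] (`P1` default; `P212121` supported — blob
#'   positions are expanded over the symmetry operations).
#' @param n_blobs Number of pseudo-atoms per asymmetric unit (default 30).
#' @param solvent_fraction Requested solvent fraction in (0.05, 0.95).
#' @param d_min Resolution limit in Angstrom (default 2.0).
#' @param seed Integer seed.
#' @param complete If `TRUE`, generate reflections for every Fourier
#'   coefficient of an odd-dimension grid instead of the resolution sphere,
#'   making map and structure factors exactly inter-convertible (useful for
#'   self-consistency tests).
#' @return A list of class `toy_crystal` with elements `rs`
#'   ([reflection_set()]), `truth` ([complex_sf()]), `true_map`
#'   ([density_map()]), `true_mask` ([density_mask()]), `href`
#'   ([histogram_ref()]), and the achieved `protein_fraction`.
#' @export
make_toy_crystal <- function(cell = unit_cell(30), sg = space_group("P1"),
                             n_blobs = 30L, solvent_fraction = 0.7,
                             d_min = 2.0, seed = 1L, complete = FALSE,
                             width_range = c(0.8, 1.2), ped_fall = 3.0,
                             ped_height = 1.2, spacing = NULL) {
  if (!(solvent_fraction > 0.05 && solvent_fraction < 0.95))
    stop("infeasible solvent fraction: need 0.05 < solvent_fraction < 0.95")
  len <- c(cell$a, cell$b, cell$c)
  n <- if (complete) {
    m <- as.integer(ceiling(len / (d_min / 2)))
    m + (m + 1L) %% 2L                     # force odd: no Nyquist planes
  } else grid_for_resolution(cell, d_min, spacing)
  N <- prod(n)
  p_frac <- 1 - solvent_fraction
  r_ball <- min((3 * p_frac * cell$volume / (4 * pi * sg$order))^(1 / 3),
                0.45 * min(len))
  r_cent <- max(r_ball - 2.0, 0.4 * r_ball)
  # molecular centre: cell centre in P1, a general position otherwise
  c0 <- if (sg$order == 1) c(0.5, 0.5, 0.5) else c(0.27, 0.31, 0.22)

  blobs <- with_seed(split_seed(seed, 0L, "toy_blobs"), {
    # uniform draws inside a ball of radius r_cent (Cartesian) around c0
    u <- stats::runif(n_blobs)^(1 / 3) * r_cent
    z <- stats::runif(n_blobs, -1, 1)
    phi <- stats::runif(n_blobs, 0, 2 * pi)
    sq <- sqrt(1 - z^2)
    xyz <- cbind(u * sq * cos(phi), u * sq * sin(phi), u * z)
    list(centre = sweep(xyz, 2, c0 * len, "+"),  # Cartesian offsets from c0
         width = stats::runif(n_blobs, width_range[1], width_range[2]),
         weight = stats::runif(n_blobs, 0.5, 1.5))
  })
  # fractional centres; expand over the symmetry operations
  cf <- sweep(blobs$centre, 2, len, "/")
  centres <- cf; widths <- blobs$width; weights <- blobs$weight
  mol_centres <- matrix(c0, 1, 3)
  if (sg$order > 1) {
    centres <- do.call(rbind, lapply(sg$symops, function(op)
      (cf %*% t(op$R) + matrix(op$t, nrow(cf), 3, byrow = TRUE)) %% 1))
    widths <- rep(blobs$width, sg$order)
    weights <- rep(blobs$weight, sg$order)
    mol_centres <- do.call(rbind, lapply(sg$symops, function(op)
      (as.numeric(op$R %*% c0) + op$t) %% 1))
  }

  # reciprocal-space synthesis: F(h) = sum_i w_i s_i^3 exp(-2 pi^2 s_i^2 s^2)
  #                                    * exp(-2 pi i h.c_i)
  h1 <- index_to_miller(seq_len(n[1]), n[1])
  h2 <- index_to_miller(seq_len(n[2]), n[2])
  h3 <- index_to_miller(seq_len(n[3]), n[3])
  H1 <- array(h1, n)
  H2 <- array(rep(h2, each = n[1]), n)
  H3 <- array(rep(h3, each = n[1] * n[2]), n)
  s2g <- grid_s2(n, cell)
  F <- array(0i, n)
  for (i in seq_along(widths)) {
    ph <- H1 * centres[i, 1] + H2 * centres[i, 2] + H3 * centres[i, 3]
    F <- F + (weights[i] * widths[i]^3) *
      exp(-2 * pi^2 * widths[i]^2 * s2g - 2i * pi * ph)
  }
  # zero Nyquist-plane coefficients (h = +n/2 aliases -n/2 on even grids and
  # would break the map's exact symmetry; they lie beyond the data sphere)
  F[H1 == n[1] / 2 | H2 == n[2] / 2 | H3 == n[3] / 2] <- 0
  rho <- Re(stats::fft(F, inverse = TRUE)) / N

  # envelope pedestal: near-uniform density filling the molecular ball(s),
  # plateau height tied to the mean blob density inside the envelope
  fr1 <- (seq_len(n[1]) - 1) / n[1]
  fr2 <- (seq_len(n[2]) - 1) / n[2]
  fr3 <- (seq_len(n[3]) - 1) / n[3]
  X1 <- array(fr1, n)
  X2 <- array(rep(fr2, each = n[1]), n)
  X3 <- array(rep(fr3, each = n[1] * n[2]), n)
  G <- cell$metric
  fall <- ped_fall                           # falloff width (Angstrom)
  ped_shape <- array(0, n)
  d2min <- array(Inf, n)
  for (j in seq_len(nrow(mol_centres))) {
    u1 <- X1 - mol_centres[j, 1]; u1 <- u1 - round(u1)
    u2 <- X2 - mol_centres[j, 2]; u2 <- u2 - round(u2)
    u3 <- X3 - mol_centres[j, 3]; u3 <- u3 - round(u3)
    d2 <- G[1, 1] * u1 * u1 + G[2, 2] * u2 * u2 + G[3, 3] * u3 * u3 +
      2 * (G[1, 2] * u1 * u2 + G[1, 3] * u1 * u3 + G[2, 3] * u2 * u3)
    d2min <- pmin(d2min, d2)
  }
  d <- sqrt(d2min)
  core <- d <= r_ball
  edge <- d > r_ball & d < r_ball + fall
  ped_shape[core] <- 1
  ped_shape[edge] <- cos((d[edge] - r_ball) / fall * pi / 2)^2
  h_ped <- ped_height * mean(pmax(rho[core], 0))
  rho <- rho + h_ped * ped_shape

  # true mask from the smoothed density; exact protein fraction by count.
  # Iterate flatten -> re-derive mask until the mask is a fixed point of the
  # envelope operator, so that a perfectly phased map reproduces the true
  # mask exactly (no envelope-error floor on the attainable phase error).
  m_protein <- max(2L, round(p_frac * N))
  s2v <- as.vector(s2g)
  rho_v <- as.vector(rho)
  perms <- sym_perms(sg, n)
  # close the voxel set under the group action so the flattened map keeps the
  # space-group symmetry exactly (the threshold may split a symmetry orbit)
  sym_close <- function(pidx) {
    if (is.null(perms)) return(pidx)
    ins <- logical(N); ins[pidx] <- TRUE
    for (p in perms) ins <- ins | ins[p]
    which(ins)
  }
  pidx <- sym_close(mask_core(smooth_core(rho_v, n, s2v, 2.5), m_protein))
  for (pass in 1:20) {
    v <- rho_v
    v[-pidx] <- 0
    pidx_new <- sym_close(mask_core(smooth_core(v, n, s2v, 2.5), m_protein))
    if (identical(pidx_new, pidx)) break
    pidx <- pidx_new
  }
  inside <- array(FALSE, n); inside[pidx] <- TRUE
  v <- rho_v
  v[-pidx] <- 0                # solvent exactly flat at zero
  true_map <- density_map(array(v, n), cell)
  true_mask <- density_mask(inside, cell)
  href <- histogram_ref(sort(v[pidx]), resolution = d_min)

  H <- if (complete) {
    hb <- expand.grid(h = h1[order(h1)], k = h2[order(h2)], l = h3[order(h3)])
    Hm <- as.matrix(hb)
    Hm <- Hm[rowSums(abs(Hm)) > 0, , drop = FALSE]
    keep <- (Hm[, 1] > 0) | (Hm[, 1] == 0 & Hm[, 2] > 0) |
      (Hm[, 1] == 0 & Hm[, 2] == 0 & Hm[, 3] > 0)
    storage.mode(Hm) <- "integer"
    Hm[keep, , drop = FALSE]
  } else unique_hkl(cell, sg, d_min)

  Ft <- stats::fft(true_map$values)
  z <- Ft[hkl_to_linear(H, n)]
  truth <- complex_sf(H, Mod(z), Arg(z) * 180 / pi)
  rs <- reflection_set(H, Mod(z), cell, sg,
                       d_min = if (complete) NULL else d_min, reduce = FALSE)
  structure(list(rs = rs, truth = truth, true_map = true_map,
                 true_mask = true_mask, href = href,
                 protein_fraction = length(pidx) / N,
                 grid = n, seed = seed), class = "toy_crystal")
}

#' @export
print.toy_crystal <- function(x, ...) {
  cat(sprintf("<toy_crystal> %s, %d reflections to %.3g A, grid %s, protein fraction %.3f\n",
              x$rs$sg$symbol, nrow(x$rs$refl), x$rs$d_min,
              paste(x$grid, collapse = "x"), x$protein_fraction))
  invisible(x)
}

#' Add relative Gaussian noise to observed amplitudes
#'
#' Perturbs each amplitude by Gaussian noise with standard deviation
#' `rel_sigma * f_obs` (clipped at zero) and records `sig_f = rel_sigma *
#' f_obs`, emulating measurement error.
#'
#' @param rs A [reflection_set()].
#' @param rel_sigma Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return The perturbed [reflection_set()].
#' @export
add_noise <- function(rs, rel_sigma, seed = 1L) {
  stopifnot(rel_sigma >= 0)
  if (rel_sigma == 0) return(rs)
  f0 <- rs$refl$f_obs
  rs$refl$f_obs <- with_seed(split_seed(seed, 0L, "noise"),
                             pmax(0, f0 + stats::rnorm(length(f0), 0, rel_sigma * f0)))
  rs$refl$sig_f <- rel_sigma * f0
  rs
}
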