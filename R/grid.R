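#' Electron-density map on a unit-cell grid
#'
#' A real-valued voxel grid covering one unit cell. Voxel `(i, j, k)`
#' (1-based) sits at fractional coordinates `((i-1)/nx, (j-1)/ny, (k-1)/nz)`.
#'
#' @param values Numeric 3-d array of density values (all finite).
#' @param cell A [unit_cell()].
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, cell) {
  stopifnot(is.array(values), length(dim(values)) == 3, inherits(cell, "unit_cell"))
  if (!all(is.finite(values))) stop("density map values must all be finite")
  structure(list(values = values, cell = cell), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Protein/solvent mask on a unit-cell grid
#'
#' @param inside Logical 3-d array, `TRUE` for protein-region voxels.
#' @param cell A [unit_cell()].
#' @return An object of class `density_mask` with a `protein_fraction` field.
#' @export
density_mask <- function(inside, cell) {
  stopifnot(is.array(inside), length(dim(inside)) == 3, is.logical(inside))
  structure(list(inside = inside, cell = cell,
                 protein_fraction = mean(inside)), class = "density_mask")
}

#' @export
print.density_mask <- function(x, ...) {
  d <- dim(x$inside)
  cat(sprintf("<density_mask> %d x %d x %d voxels, protein fraction %.3f\n",
              d[1], d[2], d[3], x$protein_fraction))
  invisible(x)
}

# smallest integer >= m that is even and 7-smooth (efficient FFT length)
good_fft_size <- function(m) {
  n <- max(2L, as.integer(ceiling(m)))
  if (n %% 2 == 1) n <- n + 1L
  repeat {
    k <- n
    for (p in c(2L, 3L, 5L, 7L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(n)
    n <- n + 2L
  }
}

#' Choose a grid for phasing at a given resolution
#'
#' Picks per-axis voxel counts for a unit-cell grid with spacing at most
#' `spacing` (default `d_min/2`, the Nyquist bound for data extending to
#' `d_min`), large enough that no Miller index inside the resolution sphere
#' aliases onto another, and even/7-smooth for fast FFTs.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @param spacing Target voxel spacing in Angstrom; default `d_min/2`.
#' @return Integer vector of length 3 (nx, ny, nz).
#' @export
grid_for_resolution <- function(cell, d_min, spacing = NULL) {
  stopifnot(d_min > 0)
  if (is.null(spacing)) spacing <- d_min / 2
  if (spacing > d_min / 2 + 1e-9)
    stop("grid too coarse for d_min: spacing must be <= d_min/2")
  len <- c(cell$a, cell$b, cell$c)
  hmax <- floor(len / d_min)          # largest index on each axis within the sphere
  n <- pmax(ceiling(len / spacing), 2 * hmax + 2)
  vapply(n, good_fft_size, integer(1))
}

# ---- internal index plumbing ------------------------------------------------

# wrap 1-based fft array index -> signed Miller index
index_to_miller <- function(idx, n) ifelse(idx - 1 <= n %/% 2, idx - 1, idx - 1 - n)

# Miller index matrix -> 1-based linear index into an fft array of dim n
hkl_to_linear <- function(H, n) {
  i1 <- (H[, 1] %% n[1]) + 1L
  i2 <- (H[, 2] %% n[2]) + 1L
  i3 <- (H[, 3] %% n[3]) + 1L
  as.integer(i1 + n[1] * (i2 - 1L + n[2] * (i3 - 1L)))
}

# s^2 = |s|^2 (1/A^2) for every coefficient of an fft array
grid_s2 <- function(n, cell) {
  h1 <- index_to_miller(seq_len(n[1]), n[1])
  h2 <- index_to_miller(seq_len(n[2]), n[2])
  h3 <- index_to_miller(seq_len(n[3]), n[3])
  Gi <- cell$metric_inv
  H1 <- array(h1, n)
  H2 <- array(rep(h2, each = n[1]), n)
  H3 <- array(rep(h3, each = n[1] * n[2]), n)
  Gi[1, 1] * H1 * H1 + Gi[2, 2] * H2 * H2 + Gi[3, 3] * H3 * H3 +
    2 * (Gi[1, 2] * H1 * H2 + Gi[1, 3] * H1 * H3 + Gi[2, 3] * H2 * H3)
}

# Per-reflection orbit expansion onto fft-array coefficients.
# For a map with symmetry rho(Rx+t) = rho(x): F(h R) = exp(+2i pi h.t) F(h)
# (h a row vector), and Friedel mates are conjugate.
# Returns parallel vectors over all orbit members of all reflections:
#   coef   - linear fft-array index
#   refl   - owning reflection row
#   fac    - complex factor; F[coef] = fac * F_rep (cnj FALSE)
#                            F[coef] = fac * Conj(F_rep) (cnj TRUE)
#   rep_of - for each reflection, the linear index of its representative (+h)
sf_index <- function(H, sg, n) {
  nr <- nrow(H)
  if (sg$order == 1) {
    # P1 fast path: orbit is {h, -h}
    ip <- hkl_to_linear(H, n)
    im <- hkl_to_linear(-H, n)
    if (any(ip == im) || anyDuplicated(c(ip, im)))
      stop("grid too coarse: reflections alias onto shared Fourier coefficients")
    return(list(coef = c(ip, im), refl = rep.int(seq_len(nr), 2),
                fac = rep(1 + 0i, 2 * nr),
                cnj = rep(c(FALSE, TRUE), each = nr),
                rep_of = ip, n = n, nrefl = nr))
  }
  coefs <- vector("list", nr)
  facs <- vector("list", nr)
  cnjs <- vector("list", nr)
  for (i in seq_len(nr)) {
    h <- H[i, , drop = FALSE]
    ent_idx <- integer(0); ent_fac <- complex(0); ent_cnj <- logical(0)
    for (op in sg$symops) {
      h1 <- as.integer(h %*% op$R)
      f1 <- exp(2i * pi * sum(h * op$t))
      ent_idx <- c(ent_idx, hkl_to_linear(matrix(h1, 1), n),
                   hkl_to_linear(matrix(-h1, 1), n))
      ent_fac <- c(ent_fac, f1, Conj(f1))
      ent_cnj <- c(ent_cnj, FALSE, TRUE)
    }
    keep <- !duplicated(ent_idx)
    coefs[[i]] <- ent_idx[keep]
    facs[[i]] <- ent_fac[keep]
    cnjs[[i]] <- ent_cnj[keep]
  }
  coef <- unlist(coefs)
  refl <- rep.int(seq_len(nr), lengths(coefs))
  if (anyDuplicated(coef)) {
    bad <- refl[duplicated(coef) | duplicated(coef, fromLast = TRUE)]
    stop("grid too coarse: reflections alias onto shared Fourier coefficients (rows ",
         paste(utils::head(unique(bad), 4), collapse = ", "), " ...)")
  }
  list(coef = coef, refl = refl, fac = unlist(facs), cnj = unlist(cnjs),
       rep_of = hkl_to_linear(H, n), n = n, nrefl = nr)
}

# precomputed voxel permutations realising each symop on the grid (or NULL for P1)
sym_perms <- function(sg, n) {
  if (sg$order == 1) return(NULL)
  i1 <- rep(seq_len(n[1]) - 1L, times = n[2] * n[3])
  i2 <- rep(rep(seq_len(n[2]) - 1L, each = n[1]), times = n[3])
  i3 <- rep(seq_len(n[3]) - 1L, each = n[1] * n[2])
  lapply(sg$symops, function(op) {
    # voxel x_i -> R x_i + t, expressed in grid units of each axis
    ja <- op$R[1, 1] * i1 * (n[1] / n[1]) + op$R[1, 2] * i2 * (n[1] / n[2]) +
      op$R[1, 3] * i3 * (n[1] / n[3]) + op$t[1] * n[1]
    jb <- op$R[2, 1] * i1 * (n[2] / n[1]) + op$R[2, 2] * i2 * (n[2] / n[2]) +
      op$R[2, 3] * i3 * (n[2] / n[3]) + op$t[2] * n[2]
    jc <- op$R[3, 1] * i1 * (n[3] / n[1]) + op$R[3, 2] * i2 * (n[3] / n[2]) +
      op$R[3, 3] * i3 * (n[3] / n[3]) + op$t[3] * n[3]
    if (max(abs(ja - round(ja)), abs(jb - round(jb)), abs(jc - round(jc))) > 1e-6)
      stop("grid dimensions do not admit the space-group symmetry exactly")
    ja <- as.integer(round(ja)) %% n[1]
    jb <- as.integer(round(jb)) %% n[2]
    jc <- as.integer(round(jc)) %% n[3]
    ja + n[1] * (jb + n[2] * jc) + 1L
  })
}

#' Symmetrize a density map under a space group
#'
#' Averages the map over all symmetry operations so that
#' `rho(R x + t) = rho(x)` holds exactly on the grid.
#'
#' @param map A [density_map()].
#' @param sg A [space_group()].
#' @return A [density_map()].
#' @export
symmetrize_map <- function(map, sg) {
  perms <- sym_perms(sg, dim(map$values))
  if (is.null(perms)) return(map)
  v <- map$values
  acc <- numeric(length(v))
  for (p in perms) acc <- acc + v[p]
  density_map(array(acc / length(perms), dim(v)), map$cell)
}
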