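#' Unit cell
#'
#' Constructs a crystallographic unit cell from edge lengths (in Angstrom) and
#' inter-axial angles (in degrees).
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with the cell parameters, the cell
#'   volume, and cached direct/reciprocal metric tensors.
#' @examples
#' uc <- unit_cell(30, 30, 30)
#' uc$volume
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  # direct-space metric tensor G (Angstrom^2)
  G <- matrix(c(
    a * a,        a * b * ca[3], a * c * ca[2],
    a * b * ca[3], b * b,        b * c * ca[1],
    a * c * ca[2], b * c * ca[1], c * c
  ), 3, 3, byrow = TRUE)
  vol2 <- det(G)
  if (!is.finite(vol2) || vol2 <= 0) stop("degenerate unit cell (volume^2 <= 0)")
  cell <- structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    volume = sqrt(vol2),
    metric = G,
    metric_inv = solve(G)   # reciprocal metric tensor G* (Angstrom^-2)
  ), class = "unit_cell")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g  V=%.6g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Reciprocal-space magnitude and resolution of Miller indices
#'
#' `recip_s()` returns |s| = 1/d (in 1/Angstrom) for each Miller index row;
#' `d_spacing()` returns the resolution d (in Angstrom).
#'
#' @param hkl Integer matrix with three columns (h, k, l), or a length-3 vector.
#' @param cell A [unit_cell()].
#' @return Numeric vector of |s| values (or d values).
#' @export
recip_s <- function(hkl, cell) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  stopifnot(ncol(hkl) == 3, inherits(cell, "unit_cell"))
  H <- as.matrix(hkl)
  s2 <- rowSums((H %*% cell$metric_inv) * H)
  sqrt(pmax(s2, 0))
}

#' @rdname recip_s
#' @export
d_spacing <- function(hkl, cell) {
  s <- recip_s(hkl, cell)
  ifelse(s > 0, 1 / s, Inf)
}
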