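#' Space-group description
#'
#' A light-weight space-group container holding the symmetry operations as
#' (rotation, translation) pairs acting on fractional coordinates, the allowed
#' origin shifts (equivalent descriptions of the same structure), and whether
#' the group leaves an enantiomorph (density inversion) ambiguity.
#'
#' Built-in symbols: `"P1"`, `"P-1"`, `"P21"` (b-unique) and `"P212121"`.
#' Arbitrary groups can be constructed by passing `symops` explicitly; the
#' operation list is checked for closure (modulo lattice translations) and for
#' the identity.
#'
#' @param symbol Hermann-Mauguin symbol (used for the built-in table, and kept
#'   as a label for custom groups).
#' @param symops Optional list of `list(R = <3x3 integer matrix>, t = <length-3
#'   fractional translation>)`. If `NULL` the built-in table is used.
#' @param origin_shifts Allowed origin shifts: either the string `"continuous"`
#'   (any translation relates equivalent descriptions, as in P1), or a matrix
#'   with 3 columns of fractional shifts.
#' @param inversion_ambiguity Logical; `TRUE` when inverting the density
#'   through the origin yields an equally valid solution (non-centrosymmetric
#'   groups).
#' @return An object of class `space_group`.
#' @examples
#' sg <- space_group("P212121")
#' length(sg$symops)
#' @export
space_group <- function(symbol = "P1", symops = NULL, origin_shifts = NULL,
                        inversion_ambiguity = NULL) {
  if (is.null(symops)) {
    builtin <- sg_builtin(symbol)
    if (is.null(builtin)) stop("unknown space group symbol: ", symbol)
    symops <- builtin$symops
    if (is.null(origin_shifts)) origin_shifts <- builtin$origin_shifts
    if (is.null(inversion_ambiguity)) inversion_ambiguity <- builtin$inversion_ambiguity
  }
  symops <- lapply(symops, function(op) {
    R <- matrix(as.numeric(op$R), 3, 3)
    if (max(abs(R - round(R))) > 1e-9) stop("symop rotation must be integral")
    list(R = round(R), t = as.numeric(op$t) %% 1)
  })
  check_symop_group(symops)
  if (is.null(origin_shifts)) origin_shifts <- matrix(0, 1, 3)
  if (is.null(inversion_ambiguity)) inversion_ambiguity <- TRUE
  structure(list(
    symbol = symbol,
    symops = symops,
    origin_shifts = origin_shifts,
    inversion_ambiguity = isTRUE(inversion_ambiguity),
    order = length(symops)
  ), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group> %s  (%d symmetry operation%s)\n",
              x$symbol, x$order, if (x$order == 1) "" else "s"))
  invisible(x)
}

sg_builtin <- function(symbol) {
  I3 <- diag(3)
  key <- gsub("[ _]", "", toupper(symbol))
  half <- as.matrix(expand.grid(c(0, .5), c(0, .5), c(0, .5)))
  colnames(half) <- NULL
  switch(key,
    "P1" = list(
      symops = list(list(R = I3, t = c(0, 0, 0))),
      origin_shifts = "continuous",
      inversion_ambiguity = TRUE),
    "P-1" = list(
      symops = list(list(R = I3, t = c(0, 0, 0)),
                    list(R = -I3, t = c(0, 0, 0))),
      origin_shifts = half,
      inversion_ambiguity = FALSE),
    "P21" = list(  # b-unique: (x,y,z), (-x, y+1/2, -z)
      symops = list(list(R = I3, t = c(0, 0, 0)),
                    list(R = diag(c(-1, 1, -1)), t = c(0, .5, 0))),
      origin_shifts = "continuous",  # origin free along b; x,z shifts of 0/1/2 also allowed
      inversion_ambiguity = TRUE),
    "P212121" = list(
      symops = list(
        list(R = I3,                 t = c(0, 0, 0)),
        list(R = diag(c(1, -1, -1)), t = c(.5, .5, 0)),
        list(R = diag(c(-1, 1, -1)), t = c(0, .5, .5)),
        list(R = diag(c(-1, -1, 1)), t = c(.5, 0, .5))),
      origin_shifts = half,
      inversion_ambiguity = TRUE),
    NULL)
}

# closure (mod lattice) + identity check
check_symop_group <- function(symops) {
  key <- function(R, t) paste(c(as.integer(R), round(t * 24) %% 24), collapse = ",")
  have <- vapply(symops, function(op) key(op$R, op$t), "")
  if (anyDuplicated(have)) stop("duplicate symmetry operations")
  id <- key(diag(3), c(0, 0, 0))
  if (!id %in% have) stop("symmetry operations must include the identity")
  for (a in symops) for (b in symops) {
    R <- a$R %*% b$R
    t <- (a$R %*% b$t + a$t) %% 1
    if (!key(R, t) %in% have)
      stop("symmetry operations are not closed under composition")
  }
  invisible(TRUE)
}

#' Centric reflections
#'
#' A reflection h is centric when some symmetry rotation maps h to -h; its
#' phase is then restricted to one of two values.
#'
#' @param hkl Integer matrix (3 columns) or length-3 vector of Miller indices.
#' @param sg A [space_group()].
#' @return Logical vector.
#' @export
is_centric <- function(hkl, sg) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  H <- as.matrix(hkl)
  out <- rep(FALSE, nrow(H))
  for (op in sg$symops) {
    out <- out | (rowSums(abs(H %*% op$R + H)) == 0)
  }
  out
}

# All reciprocal-space equivalents of each row of H (point group x Friedel),
# returned for one index as a matrix. Equivalents of h are h %*% R (and their
# Friedel mates).
hkl_orbit <- function(h, sg, friedel = TRUE) {
  eq <- do.call(rbind, lapply(sg$symops, function(op) as.integer(h %*% op$R)))
  if (friedel) eq <- rbind(eq, -eq)
  unique(eq)
}

#' Reduce Miller indices to symmetry-unique representatives
#'
#' Maps each index to the lexicographically greatest member of its orbit under
#' the space-group rotations and Friedel symmetry, giving a deterministic
#' reciprocal-space asymmetric unit.
#'
#' @param hkl Integer matrix (3 columns) or length-3 vector.
#' @param sg A [space_group()].
#' @return Integer matrix of the same shape with reduced indices.
#' @export
asu_reduce <- function(hkl, sg) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  H <- as.matrix(hkl)
  if (sg$order == 1) {
    # Friedel only: keep whichever of {h, -h} is lexicographically greater
    pos <- (H[, 1] > 0) | (H[, 1] == 0 & H[, 2] > 0) |
      (H[, 1] == 0 & H[, 2] == 0 & H[, 3] > 0)
    out <- H
    out[!pos, ] <- -H[!pos, , drop = FALSE]
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- H
  for (i in seq_len(nrow(H))) {
    eq <- hkl_orbit(H[i, ], sg)
    o <- order(eq[, 1], eq[, 2], eq[, 3], decreasing = TRUE)
    out[i, ] <- eq[o[1], ]
  }
  storage.mode(out) <- "integer"
  out
}
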