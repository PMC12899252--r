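#' Reflection set
#'
#' A set of symmetry-unique reflections with observed amplitudes. Reflections
#' are stored as a tibble with columns `h, k, l` (Miller indices reduced to
#' the reciprocal-space asymmetric unit), `f_obs` (amplitude, arbitrary
#' experimental scale), `sig_f` (amplitude standard deviation), `d`
#' (resolution, Angstrom), `s` (= 1/d, 1/Angstrom) and `status` (one of
#' `work`, `free`, `missing`, `large_error`, `low_res`).
#'
#' @param hkl Integer matrix with 3 columns of Miller indices.
#' @param f_obs Numeric vector of observed amplitudes (>= 0).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param sig_f Numeric vector of amplitude sigmas (>= 0); default 0.
#' @param d_min Resolution limit; default the finest d present.
#' @param status Character vector of statuses; default `"work"`.
#' @param reduce If `TRUE` (default) indices are reduced to the asymmetric
#'   unit first; duplicates after reduction are an error.
#' @return An object of class `reflection_set`.
#' @export
reflection_set <- function(hkl, f_obs, cell, sg = space_group("P1"),
                           sig_f = NULL, d_min = NULL, status = NULL,
                           reduce = TRUE) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  H <- as.matrix(hkl); storage.mode(H) <- "integer"
  nr <- nrow(H)
  stopifnot(length(f_obs) == nr)
  if (any(f_obs < 0)) stop("f_obs must be >= 0")
  if (is.null(sig_f)) sig_f <- rep(0, nr)
  if (is.null(status)) status <- rep("work", nr)
  if (any(rowSums(abs(H)) == 0)) stop("the (0,0,0) reflection is not allowed")
  if (reduce) H <- asu_reduce(H, sg)
  key <- paste(H[, 1], H[, 2], H[, 3])
  if (anyDuplicated(key)) {
    d1 <- which(duplicated(key))[1]
    d0 <- which(key == key[d1])[1]
    stop(sprintf("duplicate reflection after reduction to the asymmetric unit: rows %d and %d both map to (%d %d %d)",
                 d0, d1, H[d1, 1], H[d1, 2], H[d1, 3]))
  }
  d <- d_spacing(H, cell)
  if (is.null(d_min)) d_min <- min(d)
  if (any(d < d_min - 1e-9)) stop("reflections beyond the stated d_min")
  refl <- tibble::tibble(
    h = H[, 1], k = H[, 2], l = H[, 3],
    f_obs = as.numeric(f_obs), sig_f = as.numeric(sig_f),
    d = d, s = 1 / d,
    status = factor(status, levels = refl_status_levels))
  if (anyNA(refl$status)) stop("invalid reflection status")
  structure(list(cell = cell, sg = sg, d_min = d_min, refl = refl),
            class = "reflection_set")
}

refl_status_levels <- c("work", "free", "missing", "large_error", "low_res")

#' @export
print.reflection_set <- function(x, ...) {
  tab <- table(x$refl$status)
  cat(sprintf("<reflection_set> %d unique reflections, %s, d_min %.3g A\n",
              nrow(x$refl), x$sg$symbol, x$d_min))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

# systematically absent reflections: some symop fixes h (h R == h) with a
# non-integral phase shift h.t, forcing F(h) = 0
is_absent <- function(H, sg) {
  out <- rep(FALSE, nrow(H))
  for (op in sg$symops) {
    fixed <- rowSums(H %*% op$R == H) == 3
    ph <- (H %*% op$t) %% 1
    out <- out | (fixed & pmin(ph, 1 - ph) > 1e-9)
  }
  out
}

#' Enumerate symmetry-unique Miller indices to a resolution limit
#'
#' Systematically absent reflections (forced to zero by screw axes or glide
#' planes) are excluded.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param d_min Resolution limit in Angstrom.
#' @return Integer matrix of unique indices with `d >= d_min`.
#' @export
unique_hkl <- function(cell, sg, d_min) {
  len <- c(cell$a, cell$b, cell$c)
  hmax <- floor(len / d_min)
  G <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = -hmax[3]:hmax[3])
  H <- as.matrix(G)
  H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
  s <- recip_s(H, cell)
  H <- H[s <= 1 / d_min + 1e-12, , drop = FALSE]
  if (sg$order == 1) {
    keep <- (H[, 1] > 0) | (H[, 1] == 0 & H[, 2] > 0) |
      (H[, 1] == 0 & H[, 2] == 0 & H[, 3] > 0)
    H <- H[keep, , drop = FALSE]
  } else {
    R <- asu_reduce(H, sg)
    keep <- rowSums(R == H) == 3
    H <- unique(H[keep, , drop = FALSE])
    H <- H[!is_absent(H, sg), , drop = FALSE]
  }
  storage.mode(H) <- "integer"
  H[order(-H[, 1], -H[, 2], -H[, 3]), , drop = FALSE]
}

#' Assign reflection status flags
#'
#' Flags reflections with large measurement errors (`sig_f > sig_ratio *
#' f_obs`), very low resolution (`d > d_low_cut`), and a random free set of
#' approximately `free_frac` of the remaining work reflections (seeded,
#' reproducible). Precedence: `large_error` > `low_res` > `free`. Flagged
#' reflections are excluded from the Fourier amplitude constraint and have
#' their amplitudes filled from calculated values during phasing.
#'
#' @param rs A [reflection_set()].
#' @param free_frac Fraction of work reflections to hold out; default 0.01.
#' @param sig_ratio Large-error threshold as a multiple of `f_obs`; default 2.
#' @param d_low_cut Low-resolution cutoff in Angstrom; default 15.
#' @param seed Integer seed for the free-set draw.
#' @return The reflection set with updated statuses.
#' @export
assign_flags <- function(rs, free_frac = 0.01, sig_ratio = 2.0,
                         d_low_cut = 15.0, seed = 1L) {
  stopifnot(free_frac >= 0, free_frac < 1)
  st <- rep("work", nrow(rs$refl))
  keep_missing <- rs$refl$status == "missing"
  st[keep_missing] <- "missing"
  st[st == "work" & rs$refl$sig_f > sig_ratio * rs$refl$f_obs] <- "large_error"
  st[st == "work" & rs$refl$d > d_low_cut] <- "low_res"
  work_idx <- which(st == "work")
  n_free <- round(free_frac * length(work_idx))
  if (n_free > 0) {
    pick <- with_seed(split_seed(seed, 0L, "free_flags"),
                      sample(work_idx, n_free))
    st[pick] <- "free"
  }
  rs$refl$status <- factor(st, levels = refl_status_levels)
  rs
}

#' Read and write reflections in the package's text dialect
#'
#' The dialect is whitespace-separated with comment/header lines:
#' \preformatted{
#'   # hdmphase reflections v1
#'   cell 30 30 30 90 90 90
#'   spacegroup P1
#'   d_min 2.0
#'   h k l f_obs sig_f status
#'   15 0 0 12.34 0.0 work
#'   ...
#' }
#' The `status` column is optional on input (defaults to `work`).
#'
#' @param path File path.
#' @param dialect Only `"text"` is supported.
#' @return `read_reflections()` returns a [reflection_set()];
#'   `write_reflections()` returns `path` invisibly.
#' @export
read_reflections <- function(path, dialect = "text") {
  if (dialect != "text") stop("only the 'text' dialect is supported")
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- list()
  body_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (tolower(tok[1]) %in% c("cell", "spacegroup", "d_min")) {
      hdr[[tolower(tok[1])]] <- tok[-1]
    } else { body_at <- i; break }
  }
  if (is.null(hdr$cell) || is.null(hdr$spacegroup))
    stop("reflection file must declare 'cell' and 'spacegroup' before the data")
  cv <- as.numeric(hdr$cell)
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  sg <- space_group(hdr$spacegroup[1])
  cols <- strsplit(lines[body_at], "[[:space:]]+")[[1]]
  if (!all(c("h", "k", "l", "f_obs") %in% cols))
    stop("reflection table must have columns h k l f_obs")
  dat <- utils::read.table(text = paste(lines[-seq_len(body_at)], collapse = "\n"),
                           col.names = cols, stringsAsFactors = FALSE)
  reflection_set(
    as.matrix(dat[, c("h", "k", "l")]), dat$f_obs, cell, sg,
    sig_f = if ("sig_f" %in% cols) dat$sig_f else NULL,
    d_min = if (!is.null(hdr$d_min)) as.numeric(hdr$d_min[1]) else NULL,
    status = if ("status" %in% cols) dat$status else NULL,
    reduce = TRUE)
}

#' @rdname read_reflections
#' @param rs A [reflection_set()] to write.
#' @export
write_reflections <- function(rs, path, dialect = "text") {
  if (dialect != "text") stop("only the 'text' dialect is supported")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# hdmphase reflections v1",
    sprintf("cell %.10g %.10g %.10g %.10g %.10g %.10g",
            rs$cell$a, rs$cell$b, rs$cell$c,
            rs$cell$alpha, rs$cell$beta, rs$cell$gamma),
    paste("spacegroup", rs$sg$symbol),
    sprintf("d_min %.10g", rs$d_min),
    "h k l f_obs sig_f status"), con)
  r <- rs$refl
  writeLines(sprintf("%d %d %d %.17g %.17g %s",
                     r$h, r$k, r$l, r$f_obs, r$sig_f, as.character(r$status)), con)
  invisible(path)
}
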