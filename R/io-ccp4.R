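# Minimal CCP4/MRC map I/O (mode 2, 32-bit float, one full unit cell,
# axis order X Y Z). Enough to exchange maps and masks with standard
# crystallographic viewers.

#' Write a density map (or mask) as a CCP4/MRC map file
#'
#' @param map A [density_map()] or [density_mask()] (masks are written as
#'   0/1 densities).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(map, path) {
  if (inherits(map, "density_mask"))
    map <- density_map(array(as.numeric(map$inside), dim(map$inside)), map$cell)
  v <- as.vector(map$values)
  n <- dim(map$values)
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                                   # NC NR NS
  wi(2)                                   # MODE 2: float32
  wi(c(0, 0, 0))                          # start
  wi(n)                                   # intervals MX MY MZ
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))          # DMIN DMAX DMEAN
  wi(1)                                   # ISPG (P1 grid; symmetry lives in the data)
  wi(0)                                   # NSYMBT
  wi(rep(0, 25))                          # extra
  wf(c(0, 0, 0))                          # ORIGIN (MRC)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))                        # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC map file written by [write_ccp4()]
#'
#' @param path File path.
#' @return A [density_map()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) CCP4 maps are supported")
  ri(3); mx <- ri(3)
  cl <- rf(6)
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) stop("only X,Y,Z axis order is supported")
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(n))
  density_map(array(v, n), unit_cell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]))
}

#' Write and read per-reflection phases in the text dialect
#'
#' Columns `h k l f phi` after the same `cell` / `spacegroup` header as the
#' reflection dialect; phases in degrees.
#'
#' @param sf A [complex_sf()].
#' @param rs The owning [reflection_set()] (for the header).
#' @param path File path.
#' @return `path` (write) or a [complex_sf()] (read).
#' @export
write_phases <- function(sf, rs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# hdmphase phases v1",
    sprintf("cell %.10g %.10g %.10g %.10g %.10g %.10g",
            rs$cell$a, rs$cell$b, rs$cell$c,
            rs$cell$alpha, rs$cell$beta, rs$cell$gamma),
    paste("spacegroup", rs$sg$symbol),
    "h k l f phi"), con)
  writeLines(sprintf("%d %d %d %.17g %.17g", sf$h, sf$k, sf$l, sf$f, sf$phi), con)
  invisible(path)
}

#' @rdname write_phases
#' @export
read_phases <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  skip <- grep("^h\\s", lines)[1]
  dat <- utils::read.table(text = paste(lines[-seq_len(skip)], collapse = "\n"),
                           col.names = strsplit(lines[skip], "[[:space:]]+")[[1]])
  complex_sf(as.matrix(dat[, c("h", "k", "l")]), dat$f, dat$phi)
}
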