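# Fourier plumbing: DFT conventions against a brute-force oracle, Parseval,
# round trips, grid choice, and space-group symmetrization.

test_that("structure factors match the brute-force DFT oracle", {
  uc <- unit_cell(8)
  sg <- space_group("P1")
  H <- unique_hkl(uc, sg, 2.1)
  rs <- reflection_set(H, rep(1, nrow(H)), uc, sg, reduce = FALSE)
  ctx <- phasing_context(rs, grid = c(8L, 8L, 8L))
  set.seed(4)
  v <- array(rnorm(8^3), c(8, 8, 8))
  sf <- fft_density_to_sf(density_map(v, uc), rs, ctx)
  D <- slow_dft(v)
  z <- D[hkl_to_linear_test(H, c(8, 8, 8))]
  expect_equal(sf$f, Mod(z), tolerance = 1e-10)
  expect_equal(cos(sf$phi * pi / 180 - Arg(z)), rep(1, nrow(H)), tolerance = 1e-10)
})

test_that("discrete Parseval identity holds to 1e-10", {
  set.seed(8)
  v <- array(rnorm(16^3), c(16, 16, 16))
  F <- fft(v)
  expect_equal(sum(Mod(F)^2) / length(v), sum(v^2), tolerance = 1e-10)
})

test_that("degenerate spectra: constant map and single impulse", {
  toy <- rs_16()
  rs <- toy$rs
  n <- dim(toy$true_map$values)
  const <- density_map(array(3.7, n), rs$cell)
  expect_lt(max(fft_density_to_sf(const, rs)$f), 1e-9)
  imp <- array(0, n); imp[1, 1, 1] <- 1
  sf <- fft_density_to_sf(density_map(imp, rs$cell), rs)
  expect_equal(sf$f, rep(1, nrow(sf)), tolerance = 1e-12)
})

test_that("synthesis/analysis round trip through the reflection set", {
  # complete toy: reflections cover every Fourier coefficient, so the map and
  # its structure factors are exactly inter-convertible
  toy <- cached("toy_complete",
    make_toy_crystal(cell = unit_cell(12), n_blobs = 6, solvent_fraction = 0.6,
                     d_min = 2.4, seed = 11, complete = TRUE))
  m <- sf_to_density(toy$truth, toy$rs, grid = toy$grid)
  # reflections carry everything except the unmeasured F(000): synthesis
  # reproduces the true map up to its mean
  expect_lt(max(abs((m$values + mean(toy$true_map$values)) - toy$true_map$values)), 1e-8)
  sf <- fft_density_to_sf(m, toy$rs)
  expect_equal(sf$f, toy$truth$f, tolerance = 1e-10)
  # sphere-truncated toy: re-synthesis reproduces the in-sphere component
  toy2 <- toy_small()
  m2 <- sf_to_density(toy2$truth, toy2$rs, grid = dim(toy2$true_map$values))
  sf2 <- fft_density_to_sf(m2, toy2$rs)
  expect_equal(sf2$f, toy2$truth$f, tolerance = 1e-8)
  expect_equal(cos((sf2$phi - toy2$truth$phi) * pi / 180),
               rep(1, nrow(sf2)), tolerance = 1e-8)
})

test_that("grid selection respects Nyquist and aliasing limits", {
  uc <- unit_cell(30)
  expect_true(all(grid_for_resolution(uc, 2.0) >= 32))
  expect_error(grid_for_resolution(uc, 2.0, spacing = 1.5), "grid too coarse")
  # aliasing guard: an undersized explicit grid is rejected
  toy <- toy_small()
  expect_error(phasing_context(toy$rs, grid = c(8L, 8L, 8L)), "alias")
})

test_that("symmetrized maps have symmetry-equal amplitudes and exact voxel maps", {
  sg <- space_group("P212121")
  uc <- unit_cell(24)
  set.seed(5)
  m <- symmetrize_map(density_map(array(runif(24^3), c(24, 24, 24)), uc), sg)
  expect_equal(symmetrize_map(m, sg)$values, m$values)  # idempotent
  H <- unique_hkl(uc, sg, 2.2)
  rs <- reflection_set(H, rep(1, nrow(H)), uc, sg, reduce = FALSE)
  ctx <- phasing_context(rs, grid = c(24L, 24L, 24L))
  F <- fft(m$values)
  amps <- split(Mod(F[ctx$idx$coef]), ctx$idx$refl)
  spread <- vapply(amps, function(a) diff(range(a)) / max(max(a), 1e-12), 0)
  big <- vapply(amps, max, 0) > 1e-6 * max(Mod(F))
  expect_lt(max(spread[big]), 1e-8)
  # odd grids cannot represent the half-cell translations
  expect_error(sym_perms_test(sg, c(23L, 24L, 24L)), "admit")
})

test_that("CCP4 map I/O round-trips within float32 precision", {
  toy <- toy_small()
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(toy$true_map, path)
  back <- read_ccp4(path)
  expect_equal(dim(back$values), dim(toy$true_map$values))
  expect_equal(back$cell$a, toy$true_map$cell$a, tolerance = 1e-6)
  expect_equal(back$values, toy$true_map$values, tolerance = 1e-6)
})
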