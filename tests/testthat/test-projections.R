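# The two projection operators and their supporting pieces.

test_that("scale factor and amplitude fills follow the ratio-of-sums rules", {
  uc <- unit_cell(20)
  H <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5), c(3, 3, 0), c(1, 2, 3))
  rs <- reflection_set(H, c(10, 20, 30, 25, 15), uc, reduce = FALSE)
  sf_eq <- complex_sf(H, c(10, 20, 30, 25, 15), rep(0, 5))
  expect_equal(scale_factor(rs, sf_eq), 1)
  sf_2x <- complex_sf(H, 2 * c(10, 20, 30, 25, 15), rep(0, 5))
  expect_equal(scale_factor(rs, sf_2x), 0.5)
  # hand arithmetic on an arbitrary table
  sf <- complex_sf(H, c(4, 9, 28, 40, 2), rep(0, 5))
  expect_equal(scale_factor(rs, sf), 100 / 83)
  # fills: ratio 1 keeps calculated amplitudes
  rs$refl$status[c(2, 5)] <- "free"
  sfw <- complex_sf(H, c(10, 7, 30, 25, 3), rep(0, 5))
  expect_equal(scale_factor(rs, sfw), 1)  # work rows agree
  expect_equal(fill_missing(rs, sfw)[c(2, 5)], c(7, 3))
  # work sums 100 and 50 with |Fcal(h)| = 3 -> fill 6
  rs2 <- reflection_set(H, c(40, 60, 5, 0, 0), uc, reduce = FALSE)
  rs2$refl$status[3:5] <- "missing"
  sf2 <- complex_sf(H, c(20, 30, 3, 1, 1), rep(0, 5))
  expect_equal(fill_missing(rs2, sf2)[3], 6)
  # scale equivariance: c * Fobs -> c * fills
  rs3 <- rs2
  rs3$refl$f_obs <- 3 * rs2$refl$f_obs
  expect_equal(fill_missing(rs3, sf2)[3:5], 3 * fill_missing(rs2, sf2)[3:5])
  expect_error(scale_factor(rs, complex_sf(H, rep(0, 5), rep(0, 5))), "degenerate")
})

test_that("reference histograms use the midpoint-rank quantile rule", {
  uc <- unit_cell(4)
  m <- density_map(array(c(4, 2, 1, 3, rep(0, 4)), c(2, 2, 2)), uc)
  msk <- density_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)), uc)
  hr <- make_reference_histogram(m, msk, n_quantiles = 2)
  expect_equal(hr$quantiles, c(1.5, 3.5))   # lower and upper medians of 1..4
  hc <- make_reference_histogram(density_map(array(2.5, c(2, 2, 2)), uc), msk, 8)
  expect_equal(hc$quantiles, rep(2.5, 8))
  expect_error(make_reference_histogram(m, msk, n_quantiles = 1), "n_quantiles")
  # serialization round trip
  path <- withr::local_tempfile()
  write_histogram_ref(hr, path)
  expect_equal(read_histogram_ref(path)$quantiles, hr$quantiles)
})

test_that("PA flattens the solvent, matches the reference ranks, idempotent", {
  uc <- unit_cell(4)
  vals <- array(runif(27), c(3, 3, 3))
  msk <- density_mask(array(rep(c(TRUE, FALSE, FALSE), 9), c(3, 3, 3)), uc)
  # 8-voxel oracle: rank r maps to quantile level (r - 0.5) / m
  m8 <- density_map(array(c(0.9, 0.1, 0.5, 0.3, 1.2, -0.4, 0.7, 0.2, rep(9, 19)), c(3, 3, 3)), uc)
  msk8 <- density_mask(array(c(rep(TRUE, 8), rep(FALSE, 19)), c(3, 3, 3)), uc)
  href_u <- histogram_ref(((1:8) - 0.5) / 8)
  out <- project_real(m8, msk8, href_u)
  expect_equal(out$values[1:8][order(m8$values[1:8])], ((1:8) - 0.5) / 8)
  expect_equal(out$values[9:27], rep(0, 19))
  # idempotence on random maps
  toy <- rs_16()
  r <- random_map_like(toy, 21)
  p1 <- project_real(r, toy$true_mask, toy$href)
  p2 <- project_real(p1, toy$true_mask, toy$href)
  expect_lt(max(abs(p2$values - p1$values)), 1e-12)
  # protein-region histogram equals the reference
  prot <- sort(p1$values[toy$true_mask$inside])
  expect_equal(prot, toy$href$quantiles, tolerance = 1e-12)
  expect_error(project_real(r, density_mask(array(FALSE, dim(r$values)), uc), toy$href),
               "empty protein")
})

test_that("PB replaces amplitudes, keeps phases, passes unmeasured terms, idempotent", {
  toy <- rs_16()
  rs <- assign_flags(toy$rs, free_frac = 0.05, seed = 2)
  ctx <- phasing_context(rs)
  r <- random_map_like(toy, 33)
  sf_before <- fft_density_to_sf(r, rs, ctx)
  p1 <- project_fourier(r, rs, ctx = ctx)
  sf_after <- fft_density_to_sf(p1, rs, ctx)
  work <- rs$refl$status == "work"
  lam <- sum(rs$refl$f_obs[work]) / sum(sf_before$f[work])
  # work amplitudes replaced at the internal scale, phases kept exactly
  expect_equal(sf_after$f[work], rs$refl$f_obs[work] / lam, tolerance = 1e-10)
  expect_equal(cos((sf_after$phi - sf_before$phi) * pi / 180)[work],
               rep(1, sum(work)), tolerance = 1e-10)
  # non-work amplitudes filled from calculated values (ratio kappa = lambda)
  expect_equal(sf_after$f[!work], sf_before$f[!work], tolerance = 1e-10)
  # idempotent
  p2 <- project_fourier(p1, rs, ctx = ctx)
  expect_lt(max(abs(p2$values - p1$values)) / max(abs(p1$values)), 1e-10)
  # fixed point: a map already satisfying the data is unchanged
  pt <- project_fourier(toy$true_map, toy$rs, ctx = phasing_context(toy$rs))
  expect_lt(max(abs(pt$values - toy$true_map$values)), 1e-10)
  expect_error(project_fourier(density_map(array(0, dim(r$values)), rs$cell), rs, ctx = ctx),
               "degenerate")
  expect_error(project_fourier(r, rs, weights = rep(2, nrow(rs$refl)), ctx = ctx),
               "weights")
})

test_that("PB agrees with a brute-force DFT oracle coefficient by coefficient", {
  uc <- unit_cell(8)
  sg <- space_group("P1")
  H <- unique_hkl(uc, sg, 2.5)
  set.seed(14)
  fobs <- runif(nrow(H), 1, 5)
  rs <- reflection_set(H, fobs, uc, sg, reduce = FALSE)
  n <- c(8L, 8L, 8L)
  ctx <- phasing_context(rs, grid = n)
  v <- array(rnorm(prod(n)), n)
  got <- project_fourier(density_map(v, uc), rs, ctx = ctx)$values
  # oracle: full DFT, replace amplitudes on the orbit, inverse DFT
  D <- slow_dft(v)
  lam <- sum(fobs) / sum(Mod(D[hkl_to_linear_test(H, n)]))
  for (i in seq_len(nrow(H))) for (s in c(1, -1)) {
    j <- hkl_to_linear_test(matrix(s * H[i, ], 1), n)
    D[j] <- D[j] / Mod(D[j]) * fobs[i] / lam
  }
  oracle <- Re(fft(D, inverse = TRUE)) / prod(n)
  expect_equal(got, array(oracle, n), tolerance = 1e-10)
})

test_that("engine kernels match the reference projector implementations", {
  toy <- toy_small()
  rs <- assign_flags(toy$rs, seed = 5)
  ctx <- phasing_context(rs)
  set.seed(6)
  n <- dim(toy$true_map$values)
  v <- array(runif(prod(n)), n)
  FR <- fft(v)
  ref <- pb_core_test(FR, ctx)
  FC <- fft(v)
  hdmphase:::pb_kernel(FC, ctx$idx$coef, ctx$idx$refl, ctx$idx$rep_of, ctx$work,
                       rs$refl$status == "free", ctx$f_obs, numeric(0))
  expect_lt(max(Mod(FC - ref$F)), 1e-10)
  pidx <- which(toy$true_mask$inside)
  targ <- href_targets_test(toy$href, length(pidx))
  xv <- as.vector(v)
  expect_identical(hdmphase:::pa_kernel(xv, pidx, targ), pa_core_test(xv, pidx, targ))
  # ties broken identically
  xt <- round(xv, 2)
  expect_identical(hdmphase:::pa_kernel(xt, pidx, targ), pa_core_test(xt, pidx, targ))
})
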