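# Unit cell, space groups, reflection bookkeeping, status flags, text I/O.

test_that("unit cell geometry: volume, d-spacings, validation", {
  uc <- unit_cell(10, 10, 10)
  expect_equal(uc$volume, 1000)
  # closed-form d for an orthogonal cell: 1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2
  H <- rbind(c(1, 0, 0), c(1, 1, 0), c(2, 3, 6))
  expect_equal(d_spacing(H, uc),
               1 / sqrt(rowSums(sweep(H^2, 2, c(100, 100, 100), "/"))))
  # triclinic volume: a b c sqrt(1 - cos^2 terms + 2 cos product)
  tc <- unit_cell(10, 12, 14, 80, 95, 100)
  ca <- cos(c(80, 95, 100) * pi / 180)
  expect_equal(tc$volume,
               10 * 12 * 14 * sqrt(1 - sum(ca^2) + 2 * prod(ca)))
  expect_error(unit_cell(-1, 10, 10), "lengths")
  expect_error(unit_cell(10, 10, 10, alpha = 200), "angles")
})

test_that("space group table: closure, centric zones, asu reduction", {
  sg <- space_group("P212121")
  expect_equal(sg$order, 4)
  # principal zones are centric in 222, general reflections are not
  expect_true(all(is_centric(rbind(c(0, 2, 3), c(2, 0, 3), c(2, 3, 0)), sg)))
  expect_false(any(is_centric(rbind(c(1, 2, 3), c(-4, 1, 2)), sg)))
  expect_error(space_group("XYZ"), "unknown space group")
  # a non-closed op list is rejected
  expect_error(space_group("bad", symops = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3), t = c(0, 0, 0)))),
    "not closed")
  # every orbit member reduces to the same representative
  p1 <- space_group("P1")
  h <- c(2, -3, 1)
  expect_equal(asu_reduce(rbind(h, -h), p1)[1, ], asu_reduce(rbind(h, -h), p1)[2, ])
  for (op in sg$symops) {
    hm <- as.integer(h %*% op$R)
    expect_equal(asu_reduce(matrix(hm, 1), sg), asu_reduce(matrix(h, 1), sg))
  }
})

test_that("status flags: counts, thresholds, precedence, purity", {
  uc <- unit_cell(60)
  sg <- space_group("P1")
  H <- unique_hkl(uc, sg, 3.4)
  rs <- reflection_set(H[seq_len(1000), ], rep(10, 1000), uc, sg, reduce = FALSE)
  fl <- assign_flags(rs, free_frac = 0.01, seed = 7)
  expect_equal(sum(fl$refl$status == "free"), 10)  # exactly round(1000 * 0.01)
  # purity: same inputs, same flags
  expect_identical(assign_flags(rs, free_frac = 0.01, seed = 7)$refl$status,
                   fl$refl$status)
  expect_false(identical(assign_flags(rs, free_frac = 0.01, seed = 8)$refl$status,
                         fl$refl$status))
  # large-error and low-res thresholds, with precedence over free
  rs2 <- rs
  rs2$refl$sig_f[1] <- 30          # sig_f = 3 f_obs > 2 f_obs
  fl2 <- assign_flags(rs2, free_frac = 0, sig_ratio = 2, d_low_cut = 15, seed = 1)
  expect_equal(as.character(fl2$refl$status[1]), "large_error")
  expect_true(all((fl2$refl$d > 15) == (fl2$refl$status == "low_res") |
                    fl2$refl$status == "large_error"))
  # free_frac 0 leaves the set unchanged apart from threshold flags
  fl3 <- assign_flags(rs, free_frac = 0, seed = 1)
  expect_equal(sum(fl3$refl$status == "free"), 0)
})

test_that("reflection text dialect round-trips bit-exactly and validates", {
  toy <- toy_small()
  rs <- assign_flags(add_noise(toy$rs, 0.05, seed = 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_reflections(rs, path)
  back <- read_reflections(path)
  expect_identical(back$refl$h, rs$refl$h)
  expect_identical(back$refl$f_obs, rs$refl$f_obs)
  expect_identical(back$refl$sig_f, rs$refl$sig_f)
  expect_identical(as.character(back$refl$status), as.character(rs$refl$status))
  expect_equal(back$cell$a, rs$cell$a)
  expect_equal(back$d_min, rs$d_min)
  # duplicates after reduction are rejected: (1,0,0) and its Friedel mate
  lines <- c("cell 10 10 10 90 90 90", "spacegroup P212121", "h k l f_obs",
             "1 0 0 5.0", "-1 0 0 5.0")
  p2 <- withr::local_tempfile(fileext = ".hkl")
  writeLines(lines, p2)
  expect_error(read_reflections(p2), "duplicate")
  expect_error(read_reflections({
    p3 <- withr::local_tempfile(); writeLines(c("cell 10 10 10 90 90 90",
      "spacegroup NOPE", "h k l f_obs", "1 0 0 1"), p3); p3
  }), "unknown space group")
})

test_that("systematic absences are excluded from generated reflection sets", {
  sg <- space_group("P212121")
  H <- unique_hkl(unit_cell(24), sg, 2.2)
  odd_axial <- (H[, 2] == 0 & H[, 3] == 0 & H[, 1] %% 2 == 1) |
    (H[, 1] == 0 & H[, 3] == 0 & H[, 2] %% 2 == 1) |
    (H[, 1] == 0 & H[, 2] == 0 & H[, 3] %% 2 == 1)
  expect_equal(sum(odd_axial), 0)
})

test_that("seed splitting is deterministic and purpose/trial sensitive", {
  expect_identical(split_seed(42, 3, "init"), split_seed(42, 3, "init"))
  expect_false(split_seed(42, 3, "init") == split_seed(42, 4, "init"))
  expect_false(split_seed(42, 3, "init") == split_seed(42, 3, "mask"))
  s <- vapply(1:200, function(t) split_seed(1, t, "x"), integer(1))
  expect_false(anyDuplicated(s) > 0)
})
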