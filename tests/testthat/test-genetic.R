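# Genetic-evolution components: fitness, selection, crossover, mutation,
# population alignment, and the one-generation operator.

test_that("dynamic fitness follows the adaptive threshold rule", {
  expect_equal(ga_fitness(0.4, r_avg = 0.5, r_min = 0.4), 1)     # at the minimum
  expect_equal(ga_fitness(0.6, r_avg = 0.5, r_min = 0.4), 0)     # at the threshold
  expect_equal(ga_fitness(0.7, r_avg = 0.5, r_min = 0.4), 0)     # beyond: clamped
  expect_equal(ga_fitness(0.5, r_avg = 0.5, r_min = 0.4), 0.5)   # plug-in
  # uniform population: everyone gets fitness 1
  expect_equal(ga_fitness(rep(0.3, 4), 0.3, 0.3), rep(1, 4))
  # invariance under a common shift of all R values
  r <- c(0.42, 0.5, 0.61, 0.38)
  expect_equal(ga_fitness(r, mean(r), min(r)),
               ga_fitness(r + 0.2, mean(r) + 0.2, min(r) + 0.2))
})

test_that("roulette selection is proportional, with a uniform fallback", {
  # single fit individual is always chosen
  expect_true(all(ga_select(c(0, 1, 0), n = 50, seed = 1) == 2))
  # 2:1 fitness ratio reproduced over many draws (5 sigma binomial band)
  draws <- ga_select(c(2e-6, 1e-6), n = 10000, seed = 7)
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 2 / 3), 5 * sqrt(2 / 9 / 10000))
  # all-zero fitness: uniform
  u <- ga_select(c(0, 0, 0, 0), n = 8000, seed = 3)
  expect_gt(min(table(factor(u, levels = 1:4))), 8000 / 4 - 5 * sqrt(8000 * 3 / 16))
  expect_error(ga_select(c(-1, 1)), "fitness")
})

test_that("crossover swaps about half the grid through five boxes", {
  toy <- toy_small()
  a <- random_map_like(toy, 61)
  b <- random_map_like(toy, 62)
  for (s in 1:5) {
    cx <- ga_crossover(a, b, seed = s)
    expect_gte(cx$fraction, 0.48)
    expect_lte(cx$fraction, 0.52)
    # exchange conserves the combined multiset of voxel values
    expect_equal(sort(c(cx$a$values, cx$b$values)), sort(c(a$values, b$values)))
    # outside the swap region offspring equal the parents
    same_a <- cx$a$values == a$values
    expect_equal(mean(same_a), 1 - cx$fraction, tolerance = 0.02)
  }
  # identical parents: both offspring equal the parent
  cx0 <- ga_crossover(a, a, seed = 1)
  expect_identical(cx0$a$values, a$values)
  expect_identical(cx0$b$values, a$values)
  # disabled: identity
  expect_identical(ga_crossover(a, b, segments = 0)$a$values, a$values)
})

test_that("mutation hits the expected voxel count with values in [0, 1]", {
  uc <- unit_cell(20)
  n <- c(40L, 40L, 40L)  # 64000 voxels
  m <- density_map(array(5, n), uc)
  expect_identical(ga_mutate(m, 0)$values, m$values)
  mm <- ga_mutate(m, 0.01, seed = 4)
  hit <- mm$values != 5
  expect_lt(abs(sum(hit) - 640), 5 * sqrt(64000 * 0.01 * 0.99))
  expect_true(all(mm$values[hit] >= 0 & mm$values[hit] <= 1))
  expect_identical(ga_mutate(m, 0.01, seed = 4)$values, mm$values)  # seeded
})

test_that("population alignment recovers origin shifts and never hurts overlap", {
  toy <- toy_small()
  tm <- toy$true_map
  n <- dim(tm$values)
  # shifted copy: alignment must recover it exactly (P1, FFT correlation)
  sh <- tm$values[c(5:n[1], 1:4), c(9:n[2], 1:8), c(2:n[3], 1)]
  maps <- list(tm, density_map(sh, tm$cell))
  al <- ga_align_population(maps, fittest = 1, sg = toy$rs$sg,
                            solvent_fraction = 1 - toy$protein_fraction)
  expect_identical(al[[1]]$values, tm$values)   # fittest untouched
  expect_lt(max(abs(al[[2]]$values - tm$values)) / max(abs(tm$values)), 1e-8)
  # alignment never decreases mask IoU with the fittest
  r <- random_map_like(toy, 71)
  sf <- 1 - toy$protein_fraction
  al2 <- ga_align_population(list(tm, r), fittest = 1, sg = toy$rs$sg,
                             solvent_fraction = sf)
  mask_of <- function(m) mask_from_weights(gaussian_weights(m, 2.5), sf)
  expect_gte(mask_iou(mask_of(al2[[2]]), mask_of(tm)) + 1e-9,
             mask_iou(mask_of(r), mask_of(tm)))
})

test_that("evolve preserves size, copies elites bitwise, flags early stop", {
  toy <- toy_small()
  set.seed(9)
  maps <- lapply(1:6, function(i) random_map_like(toy, 80 + i))
  rw <- c(0.2, 0.45, 0.5, 0.55, 0.6, 0.35)
  cfg <- phasing_config(solvent_fraction = 1 - toy$protein_fraction,
                        elite = 2L, population = 6L, seed = 5)
  pop <- ga_population(maps, rw, sg = toy$rs$sg,
                       solvent_fraction = 1 - toy$protein_fraction)
  nxt <- evolve(pop, cfg)
  expect_equal(length(nxt$maps), 6)
  expect_equal(nxt$generation, 1L)
  expect_false(attr(nxt, "early_stop"))
  expect_equal(attr(nxt, "r_thres"), mean(rw) + (mean(rw) - min(rw)))
  # the two fitness elites are carried over bit-identically
  expect_identical(nxt$maps[[1]]$values, maps[[1]]$values)
  expect_identical(nxt$maps[[6]]$values, maps[[6]]$values)
  # something outside the elite was refreshed
  expect_true(any(vapply(2:5, function(i)
    !identical(nxt$maps[[i]]$values, maps[[i]]$values), TRUE)))
  # all converged: unchanged population, early stop fires
  pop2 <- ga_population(maps, rw, converged = rep(TRUE, 6), sg = toy$rs$sg,
                        solvent_fraction = 1 - toy$protein_fraction)
  nxt2 <- evolve(pop2, cfg)
  expect_true(attr(nxt2, "early_stop"))
  for (i in 1:6) expect_identical(nxt2$maps[[i]]$values, maps[[i]]$values)
  # crossover and mutation disabled: population passes through unchanged
  cfg0 <- phasing_config(solvent_fraction = 1 - toy$protein_fraction,
                         crossover_segments = 0L, mutation_rate = 0, seed = 5)
  nxt3 <- evolve(pop, cfg0)
  for (i in 1:6) expect_identical(nxt3$maps[[i]]$values, maps[[i]]$values)
})

test_that("with genetic operators disabled the scheme equals independent runs", {
  toy <- toy_small()
  rs <- assign_flags(toy$rs, seed = 6)
  sf <- 1 - toy$protein_fraction
  cfg_ga <- phasing_config(algorithm = "hdm_f2", beta = 0.75, gamma = 0.75,
                           scheme = "genetic", population = 3L, cadence = 20L,
                           crossover_segments = 0L, mutation_rate = 0,
                           sigma_w_start = 0, n_iter = 60L, n_finish = 10L,
                           solvent_fraction = sf, seed = 31)
  ga <- run_phasing_genetic(rs, toy$href, cfg_ga, truth = toy$truth)
  cfg_c <- phasing_config(algorithm = "hdm_f2", beta = 0.75, gamma = 0.75,
                          n_iter = 60L, n_finish = 10L,
                          solvent_fraction = sf, seed = 31)
  for (t in 1:3) {
    solo <- run_phasing(rs, toy$href, cfg_c, truth = toy$truth, trial = t)
    expect_identical(ga$results[[t]]$trace, solo$trace)
    expect_identical(ga$results[[t]]$map$values, solo$map$values)
  }
})
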