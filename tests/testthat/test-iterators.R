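# Update-rule algebra, fixed points, and the run loop.

test_that("hybrid steps match hand-composed cached projections on random states", {
  toy <- toy_small()
  rs <- toy$rs
  ctx <- ctx_small()
  r <- random_map_like(toy, 12)
  rho <- as.vector(r$values)
  pidx <- which(toy$true_mask$inside)
  targ <- href_targets_test(toy$href, length(pidx))
  pb <- as.vector(project_fourier(r, rs, ctx = ctx)$values)
  papb <- pa_core_test(pb, pidx, targ)
  pa <- pa_core_test(rho, pidx, targ)
  beta <- 0.6; gamma <- 0.8
  protein <- list(
    f1 = papb + (2 * papb - pa - pb),
    f2 = papb + beta * (2 * papb - pa - pb),
    f3 = papb + (papb - pa),
    f4 = papb + beta * (papb - pa),
    f5 = papb + (papb - pb),
    f6 = papb + beta * (papb - pb))
  for (f in names(protein)) {
    g <- if (f %in% c("f1", "f3", "f5")) 1 else gamma
    want <- rho - g * pb
    want[pidx] <- protein[[f]][pidx]
    got <- step_hdm(r, toy$true_mask, rs, toy$href, f, beta = beta, gamma = gamma, ctx = ctx)
    expect_equal(as.vector(got$values), want, tolerance = 1e-12, label = f)
  }
  # HIO: protein PAPB, solvent negative feedback
  hio <- step_hio(r, toy$true_mask, rs, toy$href, gamma = gamma, ctx = ctx)
  want <- rho - gamma * pb
  want[pidx] <- papb[pidx]
  expect_equal(as.vector(hio$values), want, tolerance = 1e-12)
  expect_error(step_hdm(r, toy$true_mask, rs, toy$href, "f7", ctx = ctx), "unknown")
})

test_that("the parameterized rules reduce to the parameter-free ones", {
  toy <- toy_small()
  ctx <- ctx_small()
  for (s in 1:5) {
    r <- random_map_like(toy, 100 + s)
    a <- step_hdm(r, toy$true_mask, toy$rs, toy$href, "f2", beta = 1, gamma = 1, ctx = ctx)
    b <- step_hdm(r, toy$true_mask, toy$rs, toy$href, "f1", ctx = ctx)
    expect_identical(a$values, b$values)
  }
})

test_that("DiffMap at beta0 = 1 equals the global and partitioned simplified forms", {
  toy <- toy_small()
  rs <- toy$rs
  ctx <- ctx_small()
  r <- random_map_like(toy, 44)
  rho <- as.vector(r$values)
  pidx <- which(toy$true_mask$inside)
  targ <- href_targets_test(toy$href, length(pidx))
  pb <- as.vector(project_fourier(r, rs, ctx = ctx)$values)
  papb <- pa_core_test(pb, pidx, targ)
  pa <- pa_core_test(rho, pidx, targ)
  got <- as.vector(step_diffmap(r, toy$true_mask, rs, toy$href, beta0 = 1, ctx = ctx)$values)
  global_form <- rho + 2 * papb - pa - pb        # rho + (2 PA.PB - PA - PB) rho
  part <- rho - pb                               # solvent rows
  part[pidx] <- rho[pidx] + 2 * papb[pidx] - pa[pidx] - pb[pidx]
  expect_equal(got, global_form, tolerance = 1e-12)
  expect_equal(got, part, tolerance = 1e-12)
  # fixed point of the general update: rho_A = rho_B implies no change
  t2 <- step_diffmap(toy$true_map, toy$true_mask, rs, toy$href, beta0 = 0.7, ctx = ctx)
  expect_lt(max(abs(t2$values - toy$true_map$values)), 1e-10)
  # literal (unexpanded) composition differs through the nonlinear PA
  lit <- step_diffmap(r, toy$true_mask, rs, toy$href, beta0 = 1, ctx = ctx,
                      expand_pa = FALSE)
  expect_gt(max(abs(as.vector(lit$values) - got)), 1e-8)
  expect_error(step_diffmap(r, toy$true_mask, rs, toy$href, beta0 = 0, ctx = ctx), "beta0")
})

test_that("every update rule fixes the toy crystal's exact solution", {
  for (toy in list(toy_small(), toy_p212121())) {
    ctx <- phasing_context(toy$rs)
    tm <- toy$true_map
    scale <- max(abs(tm$values))
    for (f in paste0("f", 1:6)) {
      s <- step_hdm(tm, toy$true_mask, toy$rs, toy$href, f, beta = 0.75, gamma = 0.75, ctx = ctx)
      expect_lt(max(abs(s$values - tm$values)) / scale, 1e-8)
    }
    s <- step_hio(tm, toy$true_mask, toy$rs, toy$href, gamma = 0.75, ctx = ctx)
    expect_lt(max(abs(s$values - tm$values)) / scale, 1e-8)
    s <- step_diffmap(tm, toy$true_mask, toy$rs, toy$href, beta0 = 0.9, ctx = ctx)
    expect_lt(max(abs(s$values - tm$values)) / scale, 1e-8)
  }
})

test_that("run_phasing: baseline 90-degree start, determinism, degenerate schedule", {
  toy <- toy_small()
  rs <- assign_flags(toy$rs, seed = 6)
  cfg <- phasing_config(algorithm = "hdm_f2", beta = 0.75, gamma = 0.75,
                        n_iter = 40, n_finish = 10,
                        solvent_fraction = 1 - toy$protein_fraction, seed = 17)
  r1 <- run_phasing(rs, toy$href, cfg, truth = toy$truth, true_mask = toy$true_mask, trial = 2)
  # random start: phase error of iteration 1 is near 90 degrees
  expect_lt(abs(r1$trace$phase_error[1] - 90), 6)  # ~540 reflections, sd ~2.3
  expect_equal(nrow(r1$trace), 40)
  expect_true(all(r1$trace$r_work > 0))
  expect_true(all(is.finite(r1$trace$dev_protein)))
  # same seed, bit-identical trace; different trial differs
  r2 <- run_phasing(rs, toy$href, cfg, truth = toy$truth, true_mask = toy$true_mask, trial = 2)
  expect_identical(r1$trace, r2$trace)
  r3 <- run_phasing(rs, toy$href, cfg, truth = toy$truth, true_mask = toy$true_mask, trial = 3)
  expect_false(identical(r1$trace$r_work, r3$trace$r_work))
  # n_iter == n_finish + 1: almost pure PA.PB alternation runs without error
  cfg2 <- phasing_config(n_iter = 12L, n_finish = 11L,
                         solvent_fraction = 1 - toy$protein_fraction, seed = 1)
  r4 <- run_phasing(rs, toy$href, cfg2, trial = 1)
  expect_equal(r4$n_iter_run, 12)
  expect_false(r4$failed)
})

test_that("warm starts near the solution stay converged through the full loop", {
  toy <- toy_small()
  rs <- assign_flags(toy$rs, seed = 6)
  tm <- toy$true_map
  init <- with_seed(42, density_map(
    tm$values + array(rnorm(length(tm$values), 0, 0.03 * stats::sd(tm$values)),
                      dim(tm$values)), tm$cell))
  cfg <- phasing_config(algorithm = "hdm_f2", beta = 0.75, gamma = 0.75,
                        n_iter = 120, n_finish = 40,
                        solvent_fraction = 1 - toy$protein_fraction, seed = 3)
  res <- run_phasing(rs, toy$href, cfg, truth = toy$truth, true_mask = toy$true_mask,
                     trial = 1, init_map = init)
  # stays in the solution's neighbourhood, far from the 90-degree random
  # level (individual trajectories are chaotic, so the bound is generous)
  expect_lt(res$final$phase_error, 45)
  expect_lt(res$final$r_work, 0.1)
})

test_that("tidiers and autoplot work on results and ensembles", {
  toy <- toy_small()
  rs <- assign_flags(toy$rs, seed = 6)
  cfg <- phasing_config(n_iter = 25, n_finish = 5,
                        solvent_fraction = 1 - toy$protein_fraction, seed = 2)
  tri <- run_trials(rs, toy$href, cfg, n_trials = 2, truth = toy$truth)
  expect_s3_class(tidy(tri$results[[1]]), "tbl_df")
  expect_equal(nrow(glance(tri$results[[1]])), 1)
  expect_equal(nrow(tidy(tri)), 2)
  expect_equal(glance(tri)$n_trials, 2)
  expect_s3_class(autoplot(tri$results[[1]]), "ggplot")
  expect_s3_class(autoplot(tri, metric = "r_work"), "ggplot")
})
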