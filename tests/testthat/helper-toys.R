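# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small fast toy: 14^3 grid, ~540 reflections
toy_small <- function() cached("toy_small",
  make_toy_crystal(cell = unit_cell(15), n_blobs = 8, solvent_fraction = 0.65,
                   d_min = 2.5, seed = 3))

ctx_small <- function() cached("ctx_small", phasing_context(toy_small()$rs))

# orthorhombic toy with screw axes, for the symmetry code paths
toy_p212121 <- function() cached("toy_p212121",
  make_toy_crystal(cell = unit_cell(24), sg = space_group("P212121"),
                   n_blobs = 10, solvent_fraction = 0.65, d_min = 2.2, seed = 5))

# 16^3 reflection set for projector-law checks (cell 14 A, d_min 2 A)
rs_16 <- function() cached("rs_16", {
  toy <- make_toy_crystal(cell = unit_cell(14), n_blobs = 8,
                          solvent_fraction = 0.6, d_min = 2.0, seed = 9)
  toy
})

random_map_like <- function(toy, seed = 1) {
  n <- dim(toy$true_map$values)
  with_seed(split_seed(seed, 0L, "testmap"),
            density_map(array(stats::runif(prod(n)), n), toy$true_map$cell))
}

# aliases for internal helpers exercised in tests
hkl_to_linear_test <- function(H, n) hdmphase:::hkl_to_linear(H, n)
sym_perms_test <- function(sg, n) hdmphase:::sym_perms(sg, n)
pa_core_test <- function(x, pidx, targets) hdmphase:::pa_core(x, pidx, targets)
pb_core_test <- function(F, ctx, w = NULL) hdmphase:::pb_core(F, ctx, w)
href_targets_test <- function(href, m) hdmphase:::href_targets(href, m)

# brute-force DFT oracle: F(h) = sum_x rho(x) exp(-2 pi i h.x/n), tiny grids only
slow_dft <- function(v) {
  n <- dim(v)
  idx <- list(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1))
  out <- array(0i, n)
  for (i3 in idx[[3]]) for (i2 in idx[[2]]) for (i1 in idx[[1]]) {
    ph <- outer(idx[[1]] * i1 / n[1],
                outer(idx[[2]] * i2 / n[2], idx[[3]] * i3 / n[3], "+"), "+")
    out[i1 + 1, i2 + 1, i3 + 1] <- sum(v * exp(-2i * pi * ph))
  }
  out
}
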