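# Population-based evolutionary phasing: dynamic fitness on R_work, roulette
# selection, multi-segment box crossover, per-voxel mutation, origin/hand
# alignment to the fittest individual, a similarity penalty, elitism, and
# collective early termination.

#' Dynamic fitness from R_work
#'
#' `f = (Rthres - Rwork) / (Rthres - Rmin)` clamped to `[0, 1]`, with the
#' adaptive threshold `Rthres = Ravg + (Ravg - Rmin)`; individuals at or above
#' the threshold get fitness 0. When the population is fully uniform
#' (`Rthres == Rmin`) all fitnesses are 1.
#'
#' @param r_work Numeric vector (or scalar) of per-individual R_work values.
#' @param r_avg,r_min Population mean and minimum R_work (`r_min <= r_avg`).
#' @return Fitness values in `[0, 1]`.
#' @export
ga_fitness <- function(r_work, r_avg, r_min) {
  stopifnot(r_min <= r_avg + 1e-12)
  r_thres <- r_avg + (r_avg - r_min)
  if (r_thres - r_min <= .Machine$double.eps) return(rep(1, length(r_work)))
  f <- (r_thres - r_work) / (r_thres - r_min)
  pmin(1, pmax(0, f))
}

#' Roulette-wheel parent selection
#'
#' Samples indices with probability proportional to fitness; when every
#' fitness is zero the draw is uniform.
#'
#' @param fitness Numeric vector of (possibly penalized) fitness values.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Integer vector of selected indices.
#' @export
ga_select <- function(fitness, n = 1L, seed = 1L) {
  stopifnot(all(fitness >= 0))
  p <- if (sum(fitness) > 0) fitness / sum(fitness) else
    rep(1 / length(fitness), length(fitness))
  with_seed(split_seed(seed, 0L, "ga_select"),
            sample.int(length(fitness), n, replace = TRUE, prob = p))
}

# sample a 5-box swap region covering coverage +/- tol of the grid (periodic
# wrap allowed); returns a logical array
crossover_region <- function(n, segments, coverage = 0.5, tol = 0.02,
                             max_tries = 200L) {
  best <- NULL; best_err <- Inf
  for (tries in seq_len(max_tries)) {
    sel <- array(FALSE, n)
    for (s in seq_len(segments)) {
      len <- pmax(1L, pmin(n, round(n * stats::runif(3, 0.34, 0.67))))
      st <- vapply(n, function(m) sample.int(m, 1L), integer(1))
      ix <- lapply(1:3, function(a) ((st[a] - 1L + seq_len(len[a]) - 1L) %% n[a]) + 1L)
      sel[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
    }
    err <- abs(mean(sel) - coverage)
    if (err < best_err) { best <- sel; best_err <- err }
    if (err <= tol) break
  }
  best
}

#' Multi-segment crossover of two density chromosomes
#'
#' Selects `segments` random axis-aligned boxes (periodic wrap allowed) whose
#' union covers about half of the grid points and exchanges the density
#' values inside them between the two parents. With `segments = 0` the
#' offspring equal the parents.
#'
#' @param a,b Parent [density_map()]s on the same grid.
#' @param segments Number of boxes (default 5).
#' @param coverage Target swapped fraction (default 0.5, tolerance `tol`).
#' @param tol Acceptance half-width on the swapped fraction.
#' @param seed Integer seed.
#' @return `list(a, b, fraction)`: the two offspring and the swapped fraction.
#' @export
ga_crossover <- function(a, b, segments = 5L, coverage = 0.5, tol = 0.02,
                         seed = 1L) {
  stopifnot(all(dim(a$values) == dim(b$values)))
  if (segments == 0) return(list(a = a, b = b, fraction = 0))
  sel <- with_seed(split_seed(seed, 0L, "ga_cross"),
                   crossover_region(dim(a$values), segments, coverage, tol))
  va <- a$values; vb <- b$values
  tmp <- va[sel]; va[sel] <- vb[sel]; vb[sel] <- tmp
  list(a = density_map(va, a$cell), b = density_map(vb, b$cell),
       fraction = mean(sel))
}

#' Per-voxel mutation
#'
#' Each voxel is independently replaced with a Uniform[0, 1] draw with
#' probability `rate`.
#'
#' @param ind A [density_map()] chromosome.
#' @param rate Mutation probability per voxel (default 0.01).
#' @param seed Integer seed.
#' @return The mutated [density_map()].
#' @export
ga_mutate <- function(ind, rate = 0.01, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(ind)
  v <- as.vector(ind$values)
  v <- with_seed(split_seed(seed, 0L, "ga_mutate"), {
    hit <- which(stats::runif(length(v)) < rate)
    v[hit] <- stats::runif(length(hit))
    v
  })
  density_map(array(v, dim(ind$values)), ind$cell)
}

# ---- alignment --------------------------------------------------------------

# best (translation, inversion) overlaying mov onto ref by cross-correlation.
# ref_vec/mov_vec are plain numeric vectors over a grid n. For discrete
# allowed origin shifts the translation search is restricted to them for the
# direct branch; the inversion branch searches the full grid.
align_transform <- function(ref_vec, mov_vec, n, sg = NULL) {
  Fr <- stats::fft(array(ref_vec, n))
  Fm <- stats::fft(array(mov_vec, n))
  cand <- NULL
  if (!is.null(sg) && is.matrix(sg$origin_shifts)) {
    tm <- sg$origin_shifts
    iv <- round(tm %*% diag(n)) %% matrix(n, nrow(tm), 3, byrow = TRUE)
    cand <- as.integer(iv[, 1] + n[1] * (iv[, 2] + n[2] * iv[, 3]) + 1)
  }
  pick <- function(FA, cand) {
    D <- Re(stats::fft(FA * Conj(Fr), inverse = TRUE))
    j <- if (is.null(cand)) which.max(D) else cand[which.max(D[cand])]
    list(val = D[j], j = j)
  }
  s1 <- pick(Fm, cand)
  inv <- FALSE; best <- s1
  if (is.null(sg) || sg$inversion_ambiguity) {
    s2 <- pick(Conj(Fm), NULL)
    if (s2$val > s1$val) { best <- s2; inv <- TRUE }
  }
  j0 <- best$j - 1L
  list(shift = c(j0 %% n[1], (j0 %/% n[1]) %% n[2], j0 %/% (n[1] * n[2])),
       inverted = inv, score = best$val, Fm = Fm)
}

# apply (inversion, then shift by t voxels) to the coefficients of mov:
# aligned(x) = mov(+/- (x + t))
apply_transform <- function(Fm, n, shift, inverted) {
  if (inverted) Fm <- Conj(Fm)
  ph1 <- exp(2i * pi * index_to_miller(seq_len(n[1]), n[1]) * shift[1] / n[1])
  ph2 <- exp(2i * pi * index_to_miller(seq_len(n[2]), n[2]) * shift[2] / n[2])
  ph3 <- exp(2i * pi * index_to_miller(seq_len(n[3]), n[3]) * shift[3] / n[3])
  P <- array(ph1, n) * array(rep(ph2, each = n[1]), n) *
    array(rep(ph3, each = n[1] * n[2]), n)
  Re(stats::fft(Fm * P, inverse = TRUE)) / prod(n)
}

#' Align population chromosomes to the fittest individual
#'
#' Each individual's density is transformed by the translation (over the
#' allowed origin shifts, or the whole grid where the origin is continuous)
#' and, where the space group leaves the hand ambiguous, inversion that
#' maximize the overlap of its protein mask with that of the fittest
#' individual. The fittest individual is unchanged, and the overlap of an
#' aligned mask never decreases (the identity transform is a candidate).
#'
#' @param maps List of [density_map()] chromosomes.
#' @param fittest Index of the fittest individual.
#' @param sg A [space_group()] (`NULL` = continuous origin + inversion).
#' @param masks Optional list of logical arrays/vectors (protein masks). By
#'   default masks are derived from each map with [gaussian_weights()] at
#'   2.5 Angstrom and [mask_from_weights()] at `solvent_fraction`.
#' @param solvent_fraction Used when `masks` is `NULL`.
#' @return List of aligned [density_map()]s.
#' @export
ga_align_population <- function(maps, fittest, sg = NULL, masks = NULL,
                                solvent_fraction = 0.7) {
  n <- dim(maps[[fittest]]$values)
  if (is.null(masks)) {
    masks <- lapply(maps, function(m)
      mask_from_weights(gaussian_weights(m, 2.5), solvent_fraction)$inside)
  } else {
    masks <- lapply(masks, function(m) if (is.list(m)) m$inside else m)
  }
  ref <- as.numeric(as.vector(masks[[fittest]]))
  out <- maps
  for (i in seq_along(maps)) {
    if (i == fittest) next
    tr <- align_transform(ref, as.numeric(as.vector(masks[[i]])), n, sg)
    if (tr$inverted || any(tr$shift != 0)) {
      Fm <- stats::fft(maps[[i]]$values)
      out[[i]] <- density_map(array(apply_transform(Fm, n, tr$shift, tr$inverted), n),
                              maps[[i]]$cell)
    }
  }
  out
}

# ---- one generation ---------------------------------------------------------

# internal core over plain vectors; returns new chromosome vectors.
# age = generations since each slot was last replaced; slots younger than
# offspring_grace generations are immune, so crossed offspring get time to
# mature before they risk replacement.
evolve_core <- function(rho_list, mask_list, r_work, converged, n, sg, cfg, gen,
                        age = NULL) {
  P <- length(rho_list)
  if (is.null(age)) age <- rep(Inf, P)
  early_stop <- all(converged)
  if (early_stop || (cfg$crossover_segments == 0 && cfg$mutation_rate == 0)) {
    return(list(rho = rho_list, early_stop = early_stop, fitness = rep(NA_real_, P),
                changed = rep(FALSE, P)))
  }
  r_avg <- mean(r_work); r_min <- min(r_work)
  fit <- ga_fitness(r_work, r_avg, r_min)
  elite_n <- min(cfg$elite, P)
  # converged individuals are always retained alongside the fitness elite
  elite <- union(order(-fit, seq_len(P))[seq_len(elite_n)], which(converged))
  # similarity penalty: near-duplicates of a fitter individual lose fitness
  pen <- fit
  if (P > 1 && cfg$similarity_penalty < 1) {
    M <- matrix(unlist(rho_list), ncol = P)
    cm <- suppressWarnings(stats::cor(M))
    cm[!is.finite(cm)] <- 0
    for (i in seq_len(P)) {
      if (i %in% elite) next
      dup <- any(cm[i, -i] > cfg$similarity_cut & fit[-i] >= fit[i])
      if (dup) pen[i] <- pen[i] * cfg$similarity_penalty
    }
  }
  fittest <- order(-fit, seq_len(P))[1]
  # align everyone to the fittest by protein-mask overlap
  ref <- as.numeric(mask_list[[fittest]])
  aligned <- rho_list
  for (i in seq_len(P)) {
    if (i == fittest) next
    tr <- align_transform(ref, as.numeric(mask_list[[i]]), n, sg)
    if (tr$inverted || any(tr$shift != 0))
      aligned[[i]] <- apply_transform(tr$Fm, n, tr$shift, tr$inverted)
  }
  # steady-state replacement: refresh only the weaker half of the mature
  # non-elite slots each generation
  pool <- setdiff(seq_len(P), elite)
  pool <- pool[age[pool] >= cfg$offspring_grace]
  pool <- pool[order(fit[pool], pool)]
  slots <- pool[seq_len(ceiling(length(pool) / 2))]
  if (length(pool) == 0) slots <- integer(0)
  out <- rho_list
  changed <- rep(FALSE, P)
  if (length(slots) > 0 && cfg$crossover_segments > 0) {
    k <- 0L
    while (k < length(slots)) {
      sd_pair <- split_seed(cfg$seed, gen * 1000L + k, "ga_gen")
      par <- ga_select(pen, 2L, seed = sd_pair)
      sel <- with_seed(split_seed(sd_pair, 1L, "ga_cross"),
                       crossover_region(n, cfg$crossover_segments))
      ca <- aligned[[par[1]]]; cb <- aligned[[par[2]]]
      tmp <- ca[sel]; ca[sel] <- cb[sel]; cb[sel] <- tmp
      for (child in list(ca, cb)) {
        k <- k + 1L
        if (k > length(slots)) break
        v <- child
        if (cfg$mutation_rate > 0) {
          v <- with_seed(split_seed(sd_pair, k, "ga_mut"), {
            hit <- which(stats::runif(length(v)) < cfg$mutation_rate)
            v[hit] <- stats::runif(length(hit))
            v
          })
        }
        out[[slots[k]]] <- v
        changed[slots[k]] <- TRUE
      }
    }
  }
  list(rho = out, early_stop = FALSE, fitness = pen, changed = changed,
       r_avg = r_avg, r_min = r_min, r_thres = r_avg + (r_avg - r_min))
}

#' A population of density chromosomes
#'
#' @param maps List of [density_map()] chromosomes.
#' @param r_work Per-individual R_work values.
#' @param converged Per-individual convergence flags (default all `FALSE`).
#' @param sg A [space_group()].
#' @param solvent_fraction Solvent fraction used to derive masks.
#' @param generation Generation counter.
#' @return An object of class `ga_population`.
#' @export
ga_population <- function(maps, r_work, converged = NULL,
                          sg = space_group("P1"), solvent_fraction = 0.7,
                          generation = 0L) {
  stopifnot(length(maps) == length(r_work))
  if (is.null(converged)) converged <- rep(FALSE, length(maps))
  structure(list(maps = maps, r_work = as.numeric(r_work),
                 converged = converged, sg = sg,
                 solvent_fraction = solvent_fraction,
                 generation = as.integer(generation)),
            class = "ga_population")
}

#' Advance a population by one generation
#'
#' Recomputes fitness (with the similarity penalty), copies the elite
#' unchanged, aligns all chromosomes to the fittest, and fills the remaining
#' slots with offspring produced by roulette selection, multi-segment
#' crossover and mutation. Population size is preserved. When every
#' individual has converged, or when both crossover and mutation are
#' disabled, the population is returned unchanged (with the `early_stop`
#' attribute set accordingly) so that the genetic scheme degenerates to
#' independent runs.
#'
#' @param pop A [ga_population()].
#' @param cfg A [phasing_config()] (GA fields: `elite`, `mutation_rate`,
#'   `crossover_segments`, `similarity_cut`, `similarity_penalty`, `seed`).
#' @return The next [ga_population()], with attributes `early_stop`,
#'   `fitness`, `r_avg`, `r_min`, `r_thres`.
#' @export
evolve <- function(pop, cfg) {
  n <- dim(pop$maps[[1]]$values)
  masks <- lapply(pop$maps, function(m)
    mask_from_weights(gaussian_weights(m, 2.5), pop$solvent_fraction)$inside)
  res <- evolve_core(lapply(pop$maps, function(m) as.vector(m$values)),
                     masks, pop$r_work, pop$converged, n, pop$sg, cfg,
                     pop$generation)
  new <- pop
  new$maps <- lapply(res$rho, function(v) density_map(array(v, n), pop$maps[[1]]$cell))
  new$generation <- pop$generation + 1L
  attr(new, "early_stop") <- res$early_stop
  attr(new, "fitness") <- res$fitness
  attr(new, "r_avg") <- res$r_avg
  attr(new, "r_min") <- res$r_min
  attr(new, "r_thres") <- res$r_thres
  new
}

#' Run the genetic-evolution phasing scheme
#'
#' Maintains a population of phasing trials that advance independently
#' between cadence points (every `cfg$cadence` iterations, which also forms
#' the initial population) and exchange information through genetic
#' operations at each cadence boundary. Once every individual satisfies the
#' truth-free convergence verdict the evolution terminates early and all
#' individuals run the finishing protocol (solvent flattening).
#'
#' @inheritParams run_phasing
#' @return A `phasing_trials` object (see [run_trials()]) with extra fields
#'   `generations`, `early_stop` and `first_converged_iter`.
#' @export
run_phasing_genetic <- function(rs, href, cfg, truth = NULL, true_mask = NULL) {
  sh <- engine_shared(rs, href, cfg, truth, true_mask)
  P <- cfg$population
  engines <- lapply(seq_len(P), function(t) phasing_engine(sh, trial = t))
  for (e in engines) e$advance(cfg$cadence)
  early <- FALSE
  gen <- 0L
  first_conv <- NA_integer_
  age <- rep(Inf, P)
  repeat {
    conv_iters <- vapply(engines, function(e) {
      ci <- e$conv_check(); if (is.na(ci)) NA_integer_ else as.integer(ci)
    }, integer(1))
    converged <- !is.na(conv_iters)
    if (is.na(first_conv) && any(converged))
      first_conv <- min(conv_iters, na.rm = TRUE)
    if (all(converged)) { early <- TRUE; break }
    if (engines[[1]]$get_iter() >= sh$n_pre) break
    gen <- gen + 1L
    age <- age + 1
    res <- evolve_core(lapply(engines, function(e) e$get_rho()),
                       lapply(engines, function(e) e$get_mask()),
                       vapply(engines, function(e) e$last_r_work(), 0),
                       converged, sh$ctx$n, sh$ctx$sg, cfg, gen, age = age)
    for (i in seq_len(P)) if (res$changed[i]) {
      engines[[i]]$set_rho(res$rho[[i]])
      age[i] <- 0
    }
    for (e in engines) e$advance(cfg$cadence)
  }
  for (e in engines) e$finish()
  results <- lapply(engines, function(e) e$result())
  out <- summarize_trials(results, cfg, has_truth = !is.null(truth))
  out$generations <- gen
  out$early_stop <- early
  out$first_converged_iter <- first_conv
  out
}
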