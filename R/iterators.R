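# Per-iteration update rules (DiffMap, HIO, and the six hybrid formulas) and
# the phasing run loop with envelope updates, schedules and the finishing
# protocol. All rules share a single PA implementation (pa_core) and a single
# PB implementation (pb_core); each step evaluates PB on the iterate once and
# PA at most twice (on PB.rho and, where the formula needs it, on rho).

hdm_needs_pa <- c(hdm_f1 = TRUE, hdm_f2 = TRUE, hdm_f3 = TRUE, hdm_f4 = TRUE,
                  hdm_f5 = FALSE, hdm_f6 = FALSE)

# protein-region update of the hybrid formulas from cached projections
hdm_protein <- function(formula, beta_eff, papb, pa, pb, pidx) {
  switch(formula,
    hdm_f1 = , hdm_f2 = papb[pidx] + beta_eff * (2 * papb[pidx] - pa[pidx] - pb[pidx]),
    hdm_f3 = , hdm_f4 = papb[pidx] + beta_eff * (papb[pidx] - pa[pidx]),
    hdm_f5 = , hdm_f6 = papb[pidx] + beta_eff * (papb[pidx] - pb[pidx]),
    stop("unknown hybrid formula: ", formula))
}

#' One iteration of the hybrid difference-map update rules
#'
#' Applies one step of formula `f1` ... `f6`. In the protein region the
#' update combines the doubly-projected density `PA.PB rho` with a
#' DiffMap-style relaxation term (`f1/f2`: `(2 PA.PB - PA - PB) rho`;
#' `f3/f4`: `(PA.PB - PA) rho`; `f5/f6`: `(PA.PB - PB) rho`); in the solvent
#' region all formulas use the negative-feedback update `rho - gamma PB rho`.
#' `f1/f3/f5` are the parameter-free variants (`beta = gamma = 1`).
#'
#' @param map Current iterate, a [density_map()].
#' @param mask Current protein [density_mask()].
#' @param rs A [reflection_set()].
#' @param href A [histogram_ref()].
#' @param formula One of `"f1"` ... `"f6"` (or the full `"hdm_f1"` form).
#' @param beta,gamma Relaxation and negative-feedback factors (ignored for
#'   `f1/f3/f5`, which fix both at 1).
#' @param weights Optional per-reflection PB weights.
#' @param ctx Optional [phasing_context()].
#' @return The next iterate, a [density_map()].
#' @export
step_hdm <- function(map, mask, rs, href, formula = "f1", beta = 0.75,
                     gamma = 0.75, weights = NULL, ctx = NULL) {
  formula <- if (grepl("^hdm_", formula)) formula else paste0("hdm_", formula)
  if (!formula %in% names(hdm_needs_pa)) stop("unknown formula id: ", formula)
  if (formula %in% c("hdm_f1", "hdm_f3", "hdm_f5")) beta <- gamma <- 1
  ctx <- ctx_for(rs, ctx, map)
  rho <- as.vector(map$values)
  pidx <- which(mask$inside)
  if (length(pidx) == 0) stop("empty protein region")
  targets <- href_targets(href, length(pidx))
  pb <- as.vector(project_fourier(map, rs, weights, ctx)$values)
  papb <- pa_core(pb, pidx, targets)
  pa <- if (hdm_needs_pa[[formula]]) pa_core(rho, pidx, targets) else NULL
  new <- rho - gamma * pb
  new[pidx] <- hdm_protein(formula, beta, papb, pa, pb, pidx)
  density_map(array(new, dim(map$values)), map$cell)
}

#' One iteration of the hybrid input-output (HIO) update
#'
#' Protein voxels take the doubly-projected density `PA.PB rho`; solvent
#' voxels take the negative-feedback update `rho - gamma PB rho`.
#'
#' @inheritParams step_hdm
#' @param gamma Negative-feedback factor, typically in (0.5, 1.0).
#' @return The next iterate, a [density_map()].
#' @export
step_hio <- function(map, mask, rs, href, gamma = 0.75, weights = NULL,
                     ctx = NULL) {
  ctx <- ctx_for(rs, ctx, map)
  rho <- as.vector(map$values)
  pidx <- which(mask$inside)
  if (length(pidx) == 0) stop("empty protein region")
  pb <- as.vector(project_fourier(map, rs, weights, ctx)$values)
  papb <- pa_core(pb, pidx, href_targets(href, length(pidx)))
  new <- rho - gamma * pb
  new[pidx] <- papb[pidx]
  density_map(array(new, dim(map$values)), map$cell)
}

#' One iteration of the difference-map (DiffMap) update
#'
#' Builds the two candidate solutions
#' `rho_A = PA[(1 + 1/beta0) PB rho - (1/beta0) rho]` and
#' `rho_B = PB[(1 - 1/beta0) PA rho + (1/beta0) rho]` and returns
#' `rho + beta0 (rho_A - rho_B)`. By default the PA bracket of `rho_A` is
#' expanded over the cached projections
#' (`(1 + 1/beta0) PA.PB rho - (1/beta0) PA rho`), the form under which the
#' beta0 = 1 special case reduces exactly to the global update
#' `rho + (2 PA.PB - PA - PB) rho`; set `expand_pa = FALSE` for the literal
#' composition through the nonlinear histogram-matching operator.
#'
#' @inheritParams step_hdm
#' @param beta0 Relaxation factor (nonzero), typically in (0.5, 1.0].
#' @param expand_pa Expand the PA bracket over cached projections (default).
#' @return The next iterate, a [density_map()].
#' @export
step_diffmap <- function(map, mask, rs, href, beta0 = 1.0, weights = NULL,
                         ctx = NULL, expand_pa = TRUE) {
  if (beta0 == 0) stop("beta0 must be nonzero")
  ctx <- ctx_for(rs, ctx, map)
  rho <- as.vector(map$values)
  pidx <- which(mask$inside)
  if (length(pidx) == 0) stop("empty protein region")
  targets <- href_targets(href, length(pidx))
  pb <- as.vector(project_fourier(map, rs, weights, ctx)$values)
  pa <- pa_core(rho, pidx, targets)
  rho_a <- if (expand_pa) {
    (1 + 1 / beta0) * pa_core(pb, pidx, targets) - (1 / beta0) * pa
  } else {
    pa_core((1 + 1 / beta0) * pb - (1 / beta0) * rho, pidx, targets)
  }
  y <- density_map(array((1 - 1 / beta0) * pa + (1 / beta0) * rho, dim(map$values)),
                   map$cell)
  rho_b <- as.vector(project_fourier(y, rs, weights, ctx)$values)
  density_map(array(rho + beta0 * (rho_a - rho_b), dim(map$values)), map$cell)
}

# ---- run loop ---------------------------------------------------------------

# everything shared between trials of one study: context, truth, schedules
engine_shared <- function(rs, href, cfg, truth = NULL, true_mask = NULL,
                          ctx = NULL) {
  if (is.null(ctx)) ctx <- phasing_context(rs, spacing = cfg$grid_spacing)
  sh <- list(
    ctx = ctx, cfg = cfg, href = href,
    work = ctx$work, free = rs$refl$status == "free",
    f_obs = ctx$f_obs, s = ctx$s, H = ctx$H,
    n_pre = cfg$n_iter - cfg$n_finish,
    m_protein = max(1L, round((1 - cfg$solvent_fraction) * ctx$N)),
    phi_true = NULL, Ftrue = NULL, true_in = NULL, align_idx = NULL)
  sh$sumF_work <- sum(sh$f_obs[sh$work])
  if (!is.null(truth)) {
    stopifnot(nrow(truth) == ctx$idx$nrefl)
    sh$phi_true <- truth$phi * pi / 180
    A <- array(0i, ctx$n)
    z <- sf_complex_values(truth)
    v <- z[ctx$idx$refl]
    v[ctx$idx$cnj] <- Conj(v[ctx$idx$cnj])
    A[ctx$idx$coef] <- v * ctx$idx$fac
    sh$Ftrue <- A
    if (is.matrix(ctx$sg$origin_shifts)) {
      tmat <- ctx$sg$origin_shifts
      iv <- round(tmat %*% diag(ctx$n)) %% matrix(ctx$n, nrow(tmat), 3, byrow = TRUE)
      sh$align_idx <- as.integer(iv[, 1] + ctx$n[1] * (iv[, 2] + ctx$n[2] * iv[, 3]) + 1)
    }
  }
  if (!is.null(true_mask)) sh$true_in <- as.vector(true_mask$inside)
  sh
}

# mean phase error (deg, work set) of coefficients F against the shared truth,
# minimized over the allowed origin shifts (and inversion when ambiguous)
best_phase_error <- function(F, sh) {
  ctx <- sh$ctx
  score <- function(Fm) {
    D <- Re(stats::fft(Fm * Conj(sh$Ftrue), inverse = TRUE))
    if (!is.null(sh$align_idx)) {
      j <- sh$align_idx[which.max(D[sh$align_idx])]
    } else j <- which.max(D)
    list(val = D[j], j = j)
  }
  s1 <- score(F)
  inv <- FALSE
  best <- s1
  if (ctx$sg$inversion_ambiguity) {
    s2 <- score(Conj(F))
    if (s2$val > s1$val) { best <- s2; inv <- TRUE }
  }
  j0 <- best$j - 1L
  t3 <- c(j0 %% ctx$n[1],
          (j0 %/% ctx$n[1]) %% ctx$n[2],
          j0 %/% (ctx$n[1] * ctx$n[2])) / ctx$n
  phi_cal <- Arg(F[ctx$idx$rep_of])
  if (inv) phi_cal <- -phi_cal
  phi_al <- phi_cal + 2 * pi * as.vector(sh$H %*% t3)
  dphi_core(sh$phi_true[sh$work], phi_al[sh$work])
}

# running truth-free convergence verdict: first pre-finishing iteration at
# which r_free has stayed below the threshold for conv_sustain iterations AND
# both density deviations sit below conv_dev_drop of their trailing-window
# median. Returns NA when never satisfied.
convergence_iteration <- function(r_conv, dev_p, dev_s, jmax, cfg) {
  su <- cfg$conv_sustain
  if (jmax < su) return(NA_integer_)
  for (j in seq.int(su, jmax)) {
    if (all(r_conv[(j - su + 1):j] < cfg$conv_r_free, na.rm = FALSE)) {
      lo <- max(1L, j - cfg$conv_window + 1L)
      if (dev_p[j] < cfg$conv_dev_drop * stats::median(dev_p[lo:j]) &&
          dev_s[j] < cfg$conv_dev_drop * stats::median(dev_s[lo:j]))
        return(j)
    }
  }
  NA_integer_
}

# A mutable phasing engine for one trial. Returns a list of closures over a
# local environment so the genetic scheme can interleave generations with
# ordinary iterations.
phasing_engine <- function(sh, trial = 0L, init_map = NULL) {
  ctx <- sh$ctx; cfg <- sh$cfg
  n <- ctx$n; N <- ctx$N
  n_pre <- sh$n_pre
  use_w <- cfg$scheme %in% c("res_weighted", "genetic") && cfg$sigma_w_start > 0
  alg <- cfg$algorithm
  fixed_par <- alg %in% c("hdm_f1", "hdm_f3", "hdm_f5")
  beta <- if (fixed_par) 1 else cfg$beta
  gamma <- if (alg %in% c("hdm_f1", "hdm_f3", "hdm_f5")) 1 else cfg$gamma
  need_pa <- if (alg %in% names(hdm_needs_pa)) hdm_needs_pa[[alg]] else alg == "diffmap"

  rho <- if (!is.null(init_map)) as.vector(init_map$values) else
    with_seed(split_seed(cfg$seed, trial, "init"), stats::runif(N))
  if (!is.null(ctx$perms)) {
    acc <- numeric(N); for (p in ctx$perms) acc <- acc + rho[p]
    rho <- acc / length(ctx$perms)
  }
  dim(rho) <- n

  cap <- cfg$n_iter
  tr_rw <- rep(NA_real_, cap); tr_rf <- rep(NA_real_, cap)
  tr_dp <- rep(NA_real_, cap); tr_ds <- rep(NA_real_, cap)
  tr_pe <- rep(NA_real_, cap); tr_io <- rep(NA_real_, cap)
  i <- 0L                     # completed iterations
  pidx <- NULL; sidx <- NULL; in_vec <- NULL; targets <- NULL
  w <- NULL; last_sigw <- -1
  failed <- FALSE
  last_pe <- NA_real_; last_io <- NA_real_
  any_free <- any(sh$free)
  sumF_free <- if (any_free) sum(sh$f_obs[sh$free]) else NA_real_

  # The envelope is reconstructed from the current density ESTIMATE (the
  # amplitude-projected map PB.rho), not from the raw feedback iterate: the
  # iterate's solvent region carries the accumulated negative-feedback
  # search signal, which would drown the envelope contrast.
  update_mask <- function(sigma, src) {
    wv <- smooth_core(src, n, ctx$s2g, sigma)
    pidx <<- mask_core(wv, sh$m_protein)
    iv <- logical(N); iv[pidx] <- TRUE
    in_vec <<- iv
    sidx <<- which(!iv)
    targets <<- href_targets(sh$href, length(pidx))
    if (!is.null(sh$true_in)) {
      last_io <<- sum(iv & sh$true_in) / sum(iv | sh$true_in)
    }
  }

  alg_code <- switch(alg, hdm_f1 = , hdm_f2 = 1L, hdm_f3 = , hdm_f4 = 2L,
                     hdm_f5 = , hdm_f6 = 3L, hio = 4L, diffmap = 1L)
  no_w <- numeric(0)
  idx <- ctx$idx

  one_iter <- function(finishing, u) {
    i <<- i + 1L
    if (use_w) {
      sigw <- sigma_w_schedule(i - 1L, cfg$n_ramp, cfg$sigma_w_start)
      if (sigw != last_sigw) {
        w <<- if (sigw > 0) exp(-2 * (pi * sigw * sh$s)^2) else NULL
        last_sigw <<- sigw
      }
    }
    F <- stats::fft(rho)
    # in-place amplitude projection + R factors (F freshly allocated above)
    st <- pb_kernel(F, idx$coef, idx$refl, idx$rep_of, sh$work, sh$free,
                    sh$f_obs, if (is.null(w)) no_w else w)
    tr_rw[i] <<- st[1]; tr_rf[i] <<- st[2]
    if (!is.null(sh$phi_true) &&
        ((i - 1L) %% cfg$envelope_every == 0L || i == cfg$n_iter))
      last_pe <<- best_phase_error(F, sh)
    pbr <- Re(stats::fft(F, inverse = TRUE)) / N
    if (!finishing && (i - 1L) %% cfg$envelope_every == 0L)
      update_mask(sigma_schedule(i - 1L, max(n_pre, 1L), cfg$sigma_start, cfg$sigma_end),
                  pbr)
    tr_pe[i] <<- last_pe; tr_io[i] <<- last_io
    papb <- pa_kernel(pbr, pidx, targets)
    pa <- if (need_pa) pa_kernel(rho, pidx, targets) else no_w
    cm <- combine_kernel(rho, pbr, papb, pa, pidx, alg_code,
                         u * beta, u * gamma)
    tr_dp[i] <<- cm$dev_p; tr_ds[i] <<- cm$dev_s
    new <- if (alg == "diffmap") {
      rho_a <- (1 + 1 / cfg$beta0) * papb - (1 / cfg$beta0) * pa
      Fy <- stats::fft(array((1 - 1 / cfg$beta0) * pa + (1 / cfg$beta0) * rho, n))
      pb_kernel(Fy, idx$coef, idx$refl, idx$rep_of, sh$work, sh$free,
                sh$f_obs, if (is.null(w)) no_w else w)
      rho_b <- Re(stats::fft(Fy, inverse = TRUE)) / N
      rho + (u * cfg$beta0) * (rho_a - rho_b)
    } else cm$out
    if (finishing) {
      F2 <- stats::fft(array(new, n))
      pb_kernel(F2, idx$coef, idx$refl, idx$rep_of, sh$work, sh$free,
                sh$f_obs, if (is.null(w)) no_w else w)
      new <- pa_kernel(Re(stats::fft(F2, inverse = TRUE)) / N, pidx, targets)
    }
    if (!is.null(ctx$perms)) {
      acc <- numeric(N); for (p in ctx$perms) acc <- acc + new[p]
      new <- acc / length(ctx$perms)
    }
    if (!all(is.finite(range(new)))) {
      failed <<- TRUE
    } else {
      dim(new) <- n
      rho <<- new
    }
    invisible(NULL)
  }

  advance <- function(k) {
    k <- min(k, n_pre - i)
    if (k <= 0 || failed) return(invisible(i))
    for (jj in seq_len(k)) {
      one_iter(FALSE, 1)
      if (failed) break
    }
    invisible(i)
  }

  finish <- function() {
    if (failed) return(invisible(i))
    nf <- min(cfg$n_finish, cap - i)
    for (jj in seq_len(nf)) {
      one_iter(TRUE, 1 - jj / cfg$n_finish)
      if (failed) break
    }
    invisible(i)
  }

  conv_check <- function() {
    jmax <- min(i, n_pre)
    r_conv <- if (any_free) tr_rf else tr_rw
    convergence_iteration(r_conv, tr_dp, tr_ds, jmax, cfg)
  }

  result <- function() {
    F <- stats::fft(array(rho, n))
    z <- F[ctx$idx$rep_of]
    sf <- complex_sf(sh$H, Mod(z), Arg(z) * 180 / pi)
    amp <- Mod(z)
    lam <- sh$sumF_work / max(sum(amp[sh$work]), .Machine$double.eps)
    rw <- sum(abs(sh$f_obs[sh$work] - lam * amp[sh$work])) / sh$sumF_work
    rf <- if (any_free)
      sum(abs(sh$f_obs[sh$free] - lam * amp[sh$free])) / sumF_free else NA_real_
    pe <- if (!is.null(sh$phi_true) && !failed) best_phase_error(F, sh) else NA_real_
    cj <- conv_check()
    ii <- seq_len(i)
    trace <- tibble::tibble(iter = ii, r_work = tr_rw[ii], r_free = tr_rf[ii],
                            phase_error = tr_pe[ii], iou = tr_io[ii],
                            dev_protein = tr_dp[ii], dev_solvent = tr_ds[ii])
    map <- structure(list(values = array(rho, n), cell = ctx$cell),
                     class = "density_map")
    structure(list(
      map = map, sf = sf, trace = trace,
      converged = !failed && !is.na(cj), converged_iter = cj, failed = failed,
      final = list(r_work = rw, r_free = rf, phase_error = pe, iou = last_io),
      success = if (!is.null(sh$phi_true)) !failed && !is.na(pe) && pe < cfg$success_dphi else NA,
      n_iter_run = i, trial = trial, cfg = cfg), class = "phasing_result")
  }

  list(advance = advance, finish = finish, result = result,
       conv_check = conv_check,
       get_rho = function() rho,
       set_rho = function(v) {
         if (!is.null(ctx$perms)) {
           acc <- numeric(N); for (p in ctx$perms) acc <- acc + v[p]
           v <- acc / length(ctx$perms)
         }
         dim(v) <- n
         rho <<- v
       },
       get_mask = function() in_vec,
       get_iter = function() i,
       last_r_work = function() if (i > 0) tr_rw[i] else NA_real_,
       has_failed = function() failed)
}

#' Run one phasing trial
#'
#' Executes a full phasing run: seeded random-density start, iterative
#' projection with periodic envelope updates, and the finishing protocol
#' (update rule linearly ramped off over the last `n_finish` iterations while
#' each iterate is re-projected through plain solvent flattening + amplitude
#' projection). Metrics are recorded every iteration; the mean phase error
#' (when `truth` is supplied) and envelope IoU (when `true_mask` is supplied)
#' are refreshed at the envelope cadence.
#'
#' A trial whose density diverges to non-finite values is marked `failed`
#' rather than raising an error.
#'
#' @param rs A [reflection_set()] (statuses set, e.g. via [assign_flags()]).
#' @param href A [histogram_ref()].
#' @param cfg A [phasing_config()].
#' @param truth Optional [complex_sf()] of true structure factors for
#'   benchmark metrics.
#' @param true_mask Optional true protein [density_mask()] for the IoU trace.
#' @param trial Trial index used in seed splitting.
#' @param init_map Optional starting [density_map()] (default: seeded uniform
#'   random density in `[0, 1)`, symmetrized).
#' @return A `phasing_result`: final map, structure factors (`sf`), a trace
#'   tibble (`iter, r_work, r_free, phase_error, iou, dev_protein,
#'   dev_solvent`), a truth-free `converged` verdict with `converged_iter`,
#'   and final summary metrics (phase error minimized over allowed origin
#'   shifts and, where ambiguous, inversion).
#' @export
run_phasing <- function(rs, href, cfg, truth = NULL, true_mask = NULL,
                        trial = 0L, init_map = NULL) {
  sh <- engine_shared(rs, href, cfg, truth, true_mask)
  eng <- phasing_engine(sh, trial, init_map)
  eng$advance(sh$n_pre)
  eng$finish()
  eng$result()
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("<phasing_result> %s/%s trial %d: %d iterations, R_work %.3f, R_free %s, converged %s\n",
              x$cfg$algorithm, x$cfg$scheme, x$trial, x$n_iter_run,
              x$final$r_work,
              ifelse(is.na(x$final$r_free), "NA", sprintf("%.3f", x$final$r_free)),
              x$converged))
  if (!is.na(x$final$phase_error))
    cat(sprintf("  mean phase error %.1f deg (aligned)\n", x$final$phase_error))
  invisible(x)
}
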