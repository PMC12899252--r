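# Multi-trial orchestration and ensemble summaries.

summarize_trials <- function(results, cfg, has_truth) {
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      trial = r$trial,
      converged = r$converged,
      converged_iter = if (is.na(r$converged_iter)) NA_integer_ else as.integer(r$converged_iter),
      failed = r$failed,
      r_work = r$final$r_work,
      r_free = r$final$r_free,
      phase_error = r$final$phase_error,
      iou = r$final$iou,
      success = if (has_truth) isTRUE(r$success) else r$converged,
      # benchmark solution: truth-free verdict plus phase error under 60 deg
      benchmark = if (has_truth) r$converged && !is.na(r$final$phase_error) &&
        r$final$phase_error < 60 else r$converged)
  }))
  succ <- summary$success
  # median iterations to convergence over the benchmark (converged) trials
  keep <- summary$benchmark & !is.na(summary$converged_iter)
  med <- stats::median(summary$converged_iter[keep])
  structure(list(
    results = results,
    summary = summary,
    success_rate = mean(succ),
    median_iterations = med,
    n_trials = length(results),
    has_truth = has_truth,
    cfg = cfg), class = "phasing_trials")
}

#' Run independent phasing trials (or one genetic population)
#'
#' For the `conventional` and `res_weighted` schemes, runs `n_trials`
#' independent seeded trials (trial `t` derives its randomness from
#' `split_seed(cfg$seed, t, ...)`). For the `genetic` scheme, runs one
#' population of `cfg$population` individuals via [run_phasing_genetic()].
#'
#' @inheritParams run_phasing
#' @param n_trials Number of independent trials (ignored for the genetic
#'   scheme).
#' @return A `phasing_trials` object: per-trial `results`, a `summary`
#'   tibble, the `success_rate` (fraction of trials with aligned mean phase
#'   error below `cfg$success_dphi` when truth is known, otherwise the
#'   truth-free convergence verdict), and `median_iterations` to convergence
#'   over the benchmark trials (convergence verdict met with phase error
#'   below 60 degrees when truth is known).
#' @export
run_trials <- function(rs, href, cfg, n_trials = 10L, truth = NULL,
                       true_mask = NULL) {
  if (cfg$scheme == "genetic")
    return(run_phasing_genetic(rs, href, cfg, truth, true_mask))
  sh <- engine_shared(rs, href, cfg, truth, true_mask)
  results <- lapply(seq_len(n_trials), function(t) {
    eng <- phasing_engine(sh, trial = t)
    eng$advance(sh$n_pre)
    eng$finish()
    eng$result()
  })
  summarize_trials(results, cfg, has_truth = !is.null(truth))
}

#' @export
print.phasing_trials <- function(x, ...) {
  cat(sprintf("<phasing_trials> %s/%s: %d trials, success rate %.0f%%, median iterations to convergence %s\n",
              x$cfg$algorithm, x$cfg$scheme, x$n_trials, 100 * x$success_rate,
              ifelse(is.na(x$median_iterations), "NA", format(x$median_iterations))))
  invisible(x)
}

#' Average the successful solutions of an ensemble
#'
#' Selects the successful trials, orders them by R_free (best first), aligns
#' all maps to the best one, and averages (capped at `max_maps`). The
#' averaged map is re-projected once through the amplitude constraint to
#' produce final phases.
#'
#' @param trials A `phasing_trials` object from [run_trials()].
#' @param rs The [reflection_set()] the trials were run on.
#' @param max_maps Cap on the number of maps averaged (default 20).
#' @return A list with the averaged `map` ([density_map()]), final `sf`
#'   ([complex_sf()]), `n_used`, and the `used` trial indices.
#' @export
average_ensemble <- function(trials, rs, max_maps = 20L) {
  ok <- which(trials$summary$success & !trials$summary$failed)
  if (length(ok) == 0) stop("no successful trials to average")
  ord <- ok[order(trials$summary$r_free[ok], na.last = TRUE)]
  maps <- lapply(trials$results[ord], function(r) r$map)
  avg <- average_maps(maps, sg = rs$sg, ref_index = 1L, max_maps = max_maps)
  list(map = avg, sf = finalize_phases(avg, rs),
       n_used = min(length(maps), max_maps),
       used = ord[seq_len(min(length(maps), max_maps))])
}
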