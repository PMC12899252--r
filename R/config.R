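#' Phasing run configuration
#'
#' Collects every tunable of a phasing run. Defaults follow the recommended
#' operating ranges: relaxation and negative-feedback factors of 0.75 for the
#' parameterized update rules, an envelope-smoothing width ramped linearly
#' from 4.0 to 2.5 Angstrom, and a resolution-weighting filter radius ramped
#' from 0.8 Angstrom to 0 over the first 30% of the run.
#'
#' @param algorithm One of `"diffmap"`, `"hio"`, `"hdm_f1"` ... `"hdm_f6"`.
#' @param scheme Phasing strategy: `"conventional"`, `"res_weighted"` or
#'   `"genetic"`.
#' @param n_iter Total iterations per trial (finishing included).
#' @param n_finish Finishing iterations during which the update rule is
#'   linearly ramped off and each iterate is re-projected through plain
#'   PA.PB (solvent flattening + amplitude projection); must be < `n_iter`.
#' @param solvent_fraction Estimated solvent fraction of the cell, in (0,1).
#' @param beta0 DiffMap relaxation factor (nonzero).
#' @param beta,gamma Relaxation / negative-feedback factors of the
#'   parameterized update rules (`hdm_f2/f4/f6`, and `gamma` for `hio`).
#' @param grid_spacing Voxel spacing in Angstrom; `NULL` chooses `d_min/2`.
#' @param seed Master seed; all randomness derives from it via [split_seed()].
#' @param sigma_start,sigma_end Envelope smoothing width schedule (Angstrom).
#' @param envelope_every Envelope update cadence in iterations.
#' @param sigma_w_start Initial resolution-weighting filter radius (Angstrom);
#'   only used by the `res_weighted` and `genetic` schemes.
#' @param n_ramp Iterations over which `sigma_w` falls to 0; `NULL` chooses
#'   `round(0.3 * n_iter)`.
#' @param free_frac,sig_ratio,d_low_cut Status-flag parameters, see
#'   [assign_flags()].
#' @param conv_r_free R-free level that must be sustained for convergence.
#' @param conv_sustain Number of trailing pre-finishing iterations over which
#'   `conv_r_free` must be sustained.
#' @param conv_dev_drop Fraction of the trailing-median density deviation the
#'   current deviations must fall below.
#' @param conv_window Trailing window (iterations) for the deviation median.
#' @param success_dphi Mean phase error (degrees, after origin alignment)
#'   below which a trial is counted a success when true phases are known.
#' @param population,cadence,elite,mutation_rate,crossover_segments,
#'   offspring_grace GA controls (see [evolve()] and
#'   [run_phasing_genetic()]); `offspring_grace` is the number of generations
#'   a freshly crossed offspring is immune from replacement.
#' @param similarity_cut,similarity_penalty GA diversity penalty: individuals
#'   whose map correlation with a fitter individual exceeds `similarity_cut`
#'   have fitness multiplied by `similarity_penalty`.
#' @return An object of class `phasing_config` (a named list).
#' @export
phasing_config <- function(algorithm = "hdm_f1",
                           scheme = "conventional",
                           n_iter = 2000L,
                           n_finish = 500L,
                           solvent_fraction = 0.7,
                           beta0 = 1.0,
                           beta = 0.75,
                           gamma = 0.75,
                           grid_spacing = NULL,
                           seed = 1L,
                           sigma_start = 4.0,
                           sigma_end = 2.5,
                           envelope_every = 10L,
                           sigma_w_start = 0.8,
                           n_ramp = NULL,
                           free_frac = 0.01,
                           sig_ratio = 2.0,
                           d_low_cut = 15.0,
                           conv_r_free = 0.35,
                           conv_sustain = 200L,
                           conv_dev_drop = 0.5,
                           conv_window = 1000L,
                           success_dphi = 30,
                           population = 100L,
                           cadence = 100L,
                           elite = 5L,
                           mutation_rate = 0.01,
                           crossover_segments = 5L,
                           similarity_cut = 0.98,
                           similarity_penalty = 0.5,
                           offspring_grace = 4L) {
  algorithm <- match.arg(algorithm,
                         c("diffmap", "hio", paste0("hdm_f", 1:6)))
  scheme <- match.arg(scheme, c("conventional", "res_weighted", "genetic"))
  if (!(solvent_fraction > 0 && solvent_fraction < 1))
    stop("solvent_fraction must be in (0, 1)")
  if (n_finish >= n_iter) stop("n_finish must be < n_iter")
  if (algorithm == "diffmap" && beta0 == 0) stop("beta0 must be nonzero")
  if (is.null(n_ramp)) n_ramp <- max(1L, round(0.3 * n_iter))
  cfg <- as.list(environment())
  class(cfg) <- "phasing_config"
  cfg
}

#' @export
print.phasing_config <- function(x, ...) {
  cat(sprintf("<phasing_config> %s / %s, %d iterations (%d finishing), solvent %.2f, seed %d\n",
              x$algorithm, x$scheme, x$n_iter, x$n_finish, x$solvent_fraction, x$seed))
  invisible(x)
}
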