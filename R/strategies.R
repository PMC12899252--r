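# Phasing strategies: resolution weighting (Gaussian low-pass filtering of
# the observed amplitudes) and its ramp schedule. The conventional
# full-resolution scheme is the special case sigma_w = 0 (all weights 1).

#' Resolution-dependent amplitude weights
#'
#' Gaussian low-pass filter applied to the observed amplitudes:
#' `w(h) = exp(-2 (pi sigma_w s_h)^2)` with `s_h = 1/d_h`. Early in a run a
#' large `sigma_w` suppresses high-resolution data so the overall molecular
#' shape is located first; as `sigma_w` decreases, finer detail enters.
#'
#' @param rs A [reflection_set()].
#' @param sigma_w Filter radius in Angstrom (>= 0); 0 gives unit weights.
#' @return Numeric vector of weights in `(0, 1]`, one per reflection.
#' @export
resolution_weights <- function(rs, sigma_w) {
  stopifnot(sigma_w >= 0)
  exp(-2 * (pi * sigma_w * rs$refl$s)^2)
}

#' Resolution-weighting ramp schedule
#'
#' Linear decrease of the filter radius from `sigma_w_start` at iteration 0
#' to 0 at iteration `n_ramp`, and 0 thereafter.
#'
#' @param iter Current iteration (0-based).
#' @param n_ramp Iterations over which the radius falls to zero.
#' @param sigma_w_start Initial filter radius in Angstrom (< 1.0 recommended).
#' @return Sigma_w in Angstrom.
#' @export
sigma_w_schedule <- function(iter, n_ramp, sigma_w_start = 0.8) {
  stopifnot(n_ramp >= 1)
  max(0, sigma_w_start * (1 - iter / n_ramp))
}
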