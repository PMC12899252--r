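# Deterministic seed splitting: every source of randomness in the package
# derives a child seed from (master seed, trial index, purpose tag) so that
# independent trials are reproducible in isolation.

MOD31 <- 2147483629  # large prime < 2^31

#' Derive a child seed from a master seed
#'
#' Counter-based splitting rule: a child seed is a deterministic hash of the
#' master seed, a trial index and a purpose tag. All randomness in the package
#' flows through this function, so any trial of any run can be reproduced
#' independently.
#'
#' @param seed Master seed (integer).
#' @param trial Trial/individual counter (non-negative integer).
#' @param purpose Short string naming the consumer (e.g. `"init"`).
#' @return An integer seed in `[1, 2^31)`.
#' @export
split_seed <- function(seed, trial = 0L, purpose = "") {
  s <- as.numeric(seed) %% MOD31
  for (code in utf8ToInt(purpose)) s <- (s * 31 + code) %% MOD31
  s <- (s * 69069 + as.numeric(trial) * 1103515245 + 12345) %% MOD31
  as.integer(s + 1)
}

# evaluate expr with a local, seeded RNG; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
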