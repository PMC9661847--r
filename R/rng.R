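#' Derive an operation-specific seed from the global run seed
#'
#' All stochastic stages draw their randomness from one global integer seed,
#' keyed by the operation name, so that re-running a single stage does not
#' perturb the random streams of the others.
#'
#' @param seed global integer seed.
#' @param op character scalar naming the operation (e.g. `"sourcetrack"`).
#' @return An integer seed in `[0, 2^31 - 1)`, deterministic in `(seed, op)`.
#' @export
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  # small multiplicative string hash, kept within 32-bit integer range
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Evaluate an expression under a locally-seeded RNG
#'
#' Sets the RNG to a seed derived from `seed` and `op`, runs `expr`, and
#' restores the caller's RNG state afterwards.
#'
#' @param seed global seed; `op` operation key; `expr` expression.
#' @return Value of `expr`.
#' @keywords internal
with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, op))
  expr
}
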