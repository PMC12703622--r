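#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (case generation, training, per-episode action sampling, ...),
#' so that components are independently reproducible: regenerating a case
#' never perturbs a training run and vice versa.
#'
#' @param seed integer root seed.
#' @param stream character substream name, e.g. `"case"`, `"train"`,
#'   `"episode"`.
#' @param index non-negative integer, distinguishes repeated draws from the
#'   same substream (case number, repeat number, ...).
#' @return an integer seed in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stream)
  stream_id <- sum(chars * seq_along(chars))
  # multiplicative-congruential style mix kept in double precision;
  # 2147483647 = 2^31 - 1 keeps the result a valid 32-bit R integer
  x <- (abs(as.double(seed)) * 48271 + stream_id * 9973 + as.double(index) * 131071) %%
    2147483647
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so that library code never disturbs a caller's
#' random stream.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
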