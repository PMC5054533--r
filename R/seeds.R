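#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from a
#' single master seed through this counter-based splitter, so each stage is
#' reproducible in isolation (re-running one stage with the same master seed
#' and counter gives the same stream regardless of what ran before it).
#'
#' Uses a Lehmer-style multiplicative congruence modulo the Mersenne prime
#' 2^31 - 1; all intermediate products stay below 2^53 so the arithmetic is
#' exact in doubles.
#'
#' @param master integer master seed (any non-negative integer < 2^31).
#' @param counter integer stream counter distinguishing the consumer.
#' @return an integer seed in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
split_seed <- function(master, counter) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  out <- ((s + 1) * 48271 + (as.numeric(counter) %% m) * 16807) %% m
  as.integer(if (out == 0) 1 else out)
}
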