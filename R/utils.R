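#' Derive a child seed from a run seed
#'
#' Every stochastic stage takes an explicit integer seed. A single run seed is
#' expanded into per-iteration / per-stage seeds with one fixed rule (a Lehmer
#' step modulo 2^31 - 1) so that end-to-end runs are reproducible and stages
#' can be re-run in isolation.
#'
#' @param seed integer run seed.
#' @param k integer offset (stage or iteration index).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m) * 48271 + as.double(k)
  as.integer(1 + (s %% (m - 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats predict pbinom pnorm psignrank rnorm runif sd setNames t.test
#' @importFrom utils head
NULL
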