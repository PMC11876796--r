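#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames quantile sd cor
#' @importFrom utils read.csv write.csv head tail
#' @importFrom data.table data.table
#' @importFrom Rcpp evalCpp
#' @useDynLib stcausal, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Set every random stream used by the package
#'
#' Seeds R's RNG (which drives simulation, masking, parameter initialisation
#' and Gumbel draws alike) and returns a small record suitable for embedding
#' in an output manifest.
#'
#' @param seed Integer seed.
#' @return A list with the seed, RNG kind and timestamp.
#' @export
set_global_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stopf("seed must be an integer")
  set.seed(seed)
  list(seed = seed, rng_kind = RNGkind()[1], set_at = format(Sys.time(), tz = "UTC"))
}

## Deterministic child seed so that independent stages (simulate / init /
## masking) can be re-seeded without coupling their streams.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483587L
}
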