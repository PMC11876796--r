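#' Build a sensor-graph adjacency with a thresholded Gaussian kernel
#'
#' The standard distance-based construction for sensor networks: the edge
#' weight between sensors i and j is `exp(-D[i,j]^2 / sigma^2)`, zeroed when
#' it falls below the cutoff `kappa`.  Zero self-distance gives `A[i,i] = 1`
#' for any `kappa <= 1`, so every node is always in its own attention
#' neighbourhood.
#'
#' The cutoff is applied to the kernel *weight* (not the raw distance), which
#' makes `kappa` scale-free: `kappa = 0.1` keeps edges within roughly
#' `1.52 * sigma` regardless of the distance units.
#'
#' @param D Nonnegative symmetric matrix of pairwise distances (zero diagonal).
#' @param sigma Positive kernel bandwidth, in the units of `D`.
#' @param kappa Weight threshold in `[0, 1]`; weights below it become 0.
#' @return N x N adjacency matrix.
#' @examples
#' D <- as.matrix(dist(cbind(runif(5), runif(5))))
#' A <- build_adjacency(D, sigma = 0.5, kappa = 0.1)
#' @export
build_adjacency <- function(D, sigma, kappa = 0.1) {
  D <- as.matrix(D)
  if (any(D < 0)) stopf("distances must be nonnegative")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) stopf("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stopf("distance matrix must have a zero diagonal")
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be positive")
  if (kappa < 0 || kappa > 1) stopf("kappa must be in [0, 1]")
  A <- exp(-(D^2) / sigma^2)
  A[A < kappa] <- 0
  A
}
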