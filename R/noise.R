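#' Poisson photon-noise model for sinograms
#'
#' Simulates transmission photon statistics: for a clean line integral p,
#' the expected photon count behind the object is lambda = I0 * exp(-p);
#' a Poisson count N is drawn and converted back to a noisy integral
#' -log(max(N, 1) / I0). Zero counts are clamped to one photon so the log
#' stays finite. For lambda above 1e7 the Poisson draw uses its Gaussian
#' limit (rounded, floored at 0), which keeps the simulation exact to well
#' below the shot-noise scale while avoiding integer overflow.
#'
#' @param sino a \linkS4class{Sinogram} of nonnegative line integrals.
#' @param photonCount I0, expected unattenuated photons per detector bin.
#' @param seed integer seed; draws are reproducible.
#' @return A \linkS4class{Sinogram} with noisy line integrals.
#' @export
#' @examples
#' geom <- makeEquiangularGeometry("parallel", nAngles = 2, nDetectors = 4)
#' s <- sinogram(matrix(1, 2, 4), geom)
#' applyPoisson(s, photonCount = 1e4, seed = 1)
applyPoisson <- function(sino, photonCount, seed = 1L) {
  if (photonCount <= 0) stop("photonCount must be positive")
  p <- sino@values
  if (any(p < 0))
    stop("sinogram must contain nonnegative line integrals")
  set.seed(as.integer(seed))
  lam <- photonCount * exp(-p)
  big <- lam > 1e7
  counts <- numeric(length(lam))
  if (any(!big))
    counts[!big] <- stats::rpois(sum(!big), lam[!big])
  if (any(big))
    counts[big] <- pmax(0, round(lam[big] +
      sqrt(lam[big]) * stats::rnorm(sum(big))))
  noisy <- -log(pmax(counts, 1) / photonCount)
  sinogram(matrix(noisy, nrow(p), ncol(p)), sino@geometry)
}

#' Independent noisy replicates of a sinogram
#'
#' Draws \code{nReps} independent noisy datasets from sequential seeds
#' derived from \code{seed} (replicate i uses \code{seed + i - 1}), as
#' used to average RNMP over noise realisations.
#'
#' @inheritParams applyPoisson
#' @param nReps number of replicates (>= 1).
#' @return List of \linkS4class{Sinogram}s.
#' @export
noisyReplicates <- function(sino, photonCount, nReps, seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1")
  lapply(seq_len(nReps), function(i)
    applyPoisson(sino, photonCount, seed = as.integer(seed) + i - 1L))
}
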