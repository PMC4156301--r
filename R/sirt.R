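#' SIRT reconstruction with optional fixed-pixel mask
#'
#' Runs the Simultaneous Iterative Reconstruction Technique
#' \deqn{x \leftarrow x + C W^T R (p - W x)}
#' where R and C are diagonal matrices holding the reciprocals of the ray
#' and pixel weight sums of W (reciprocals of zero sums are set to 0).
#' When \code{mask} is supplied only the listed (non-fixed) pixels are
#' updated; all other pixels keep their exact input values, but still
#' contribute to the residual \code{p - W x} through the forward
#' projection.
#'
#' @param initial a \linkS4class{TomoImage}, the starting iterate.
#' @param sino a \linkS4class{Sinogram}.
#' @param nIters number of iterations (>= 0; 0 returns \code{initial}).
#' @param mask optional integer vector of column-major pixel indices to
#'   update (the non-fixed set). \code{NULL} updates every pixel; an empty
#'   vector freezes the whole image.
#' @param relaxation step-size multiplier on the update (default 1, the
#'   plain scheme).
#' @param operator optional prebuilt \linkS4class{TomoOperator}; pass one
#'   when calling repeatedly on the same grid and geometry.
#' @param workCounter internal environment counting operator applications
#'   (used by the budgeted benchmark runs); leave NULL otherwise.
#' @return A \linkS4class{TomoImage} with the updated iterate.
#' @export
#' @examples
#' grid <- imageGrid(16)
#' geom <- makeEquiangularGeometry("parallel", nAngles = 12, nDetectors = 16)
#' truth <- diskWithHoles(16, diskRadius = 6, holeRadius = 2, nHoles = 0)
#' p <- forwardProject(truth, geom)
#' rec <- sirtRun(tomoImage(0, grid), p, nIters = 50)
sirtRun <- function(initial, sino, nIters, mask = NULL, relaxation = 1,
                    operator = NULL, workCounter = NULL) {
  if (nIters < 0) stop("nIters must be >= 0")
  op <- if (is.null(operator)) tomoOperator(initial@grid, sino@geometry)
        else operator
  if (!identical(dim(initial@values), c(op@grid@nRows, op@grid@nCols)))
    stop("initial image shape does not match the operator grid")
  x <- as.vector(initial@values)
  p <- .sinoToVec(sino@values)
  if (length(p) != nrow(op@W))
    stop("sinogram shape does not match the operator geometry")
  if (!is.null(mask) && length(mask) > 0L &&
      (min(mask) < 1L || max(mask) > length(x)))
    stop("mask indices outside the grid")
  rInv <- safeReciprocal(raySums(op))
  cInv <- safeReciprocal(pixelSums(op))
  emptyMask <- !is.null(mask) && length(mask) == 0L
  for (k in seq_len(nIters)) {
    if (emptyMask) break          # all pixels fixed: nothing can change
    res <- p - .opForward(op, x, workCounter)
    upd <- relaxation * cInv * .opAdjoint(op, rInv * res, workCounter)
    if (any(!is.finite(upd)))
      stop("non-finite SIRT update at iteration ", k)
    if (is.null(mask)) x <- x + upd
    else x[mask] <- x[mask] + upd[mask]
  }
  tomoImage(matrix(x, op@grid@nRows, op@grid@nCols), op@grid)
}

#' Projection distance of a reconstruction
#'
#' The Euclidean norm of the residual, \eqn{\|W x - p\|_2}: the data
#' fidelity of image \code{x} with respect to the measured sinogram
#' \code{p}. Used both as a convergence diagnostic and as the quantity
#' whose stalling triggers DART termination.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param sino a \linkS4class{Sinogram}.
#' @param operator optional prebuilt \linkS4class{TomoOperator}.
#' @param workCounter internal work ledger (see \code{\link{sirtRun}}).
#' @return A nonnegative number.
#' @export
projectionDistance <- function(image, sino, operator = NULL,
                               workCounter = NULL) {
  op <- if (is.null(operator)) tomoOperator(image@grid, sino@geometry)
        else operator
  res <- .sinoToVec(sino@values) -
    .opForward(op, as.vector(image@values), workCounter)
  sqrt(sum(res^2))
}
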