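## Joseph ray-driven projector.
##
## For each ray the dominant axis is found; the ray is sampled once per
## pixel row/column along that axis and the two pixel centres adjacent to
## the crossing point on the minor axis are weighted by linear
## interpolation. Each sample carries a path-length factor
## pixelSize * sqrt(1 + slope^2) so sinogram entries are physical line
## integrals. Interpolation weights falling outside the grid are dropped;
## rays that miss the grid entirely get an all-zero row.

## ray bundle for one geometry: origin points P0 and directions D,
## one row per (angle, bin) in angle-major order
.rayBundle <- function(geometry) {
  th <- geometry@angles
  nd <- geometry@nDetectors
  t_j <- (seq_len(nd) - (nd + 1) / 2) * geometry@detectorPixelSize
  nA <- length(th)
  ct <- cos(th); st <- sin(th)
  if (identical(geometry@beam, "parallel")) {
    ## detector axis u = (cos, sin); rays run along (-sin, cos)
    p0x <- rep(ct, each = nd) * rep(t_j, times = nA)
    p0y <- rep(st, each = nd) * rep(t_j, times = nA)
    dx <- rep(-st, each = nd)
    dy <- rep(ct, each = nd)
  } else {
    dso <- geometry@sourceObjectDistance
    dsd <- geometry@sourceDetectorDistance
    sx <- rep(-dso * ct, each = nd)
    sy <- rep(-dso * st, each = nd)
    ## detector centre = source + dsd * beam axis; bins offset along u
    bx <- sx + dsd * rep(ct, each = nd) - rep(st, each = nd) * rep(t_j, nA)
    by <- sy + dsd * rep(st, each = nd) + rep(ct, each = nd) * rep(t_j, nA)
    p0x <- sx; p0y <- sy
    dx <- bx - sx
    dy <- by - sy
  }
  list(p0x = p0x, p0y = p0y, dx = dx, dy = dy, nRays = nA * nd)
}

## sparse Joseph weights for one bundle half (dominant axis given);
## returns triplets (ray index, pixel linear index, weight)
.josephHalf <- function(rays, raySel, n, s) {
  if (length(raySel) == 0L)
    return(list(i = integer(), j = integer(), x = numeric()))
  p0x <- rays$p0x[raySel]; p0y <- rays$p0y[raySel]
  dx <- rays$dx[raySel]; dy <- rays$dy[raySel]
  xdom <- abs(dx) >= abs(dy)
  cent <- (seq_len(n) - (n + 1) / 2) * s   # x of column c; y of row r is -cent[r]

  build <- function(idx, major_is_x) {
    if (length(idx) == 0L)
      return(list(i = integer(), j = integer(), x = numeric()))
    k <- length(idx)
    if (major_is_x) {
      m <- dy[idx] / dx[idx]
      ## y at each column centre; continuous row coordinate
      Y <- p0y[idx] + m * outer(rep(1, k), cent) -
        m * p0x[idx]  # k x n: p0y + m*(x_c - p0x)
      rr <- (n + 1) / 2 - Y / s
      i0 <- floor(rr)
      fr <- rr - i0
      fac <- s * sqrt(1 + m^2)
      majorPix <- function(minorIdx) {
        # pixel linear index for row=minorIdx matrix, col = column index
        colIdx <- matrix(rep(seq_len(n), each = k), k, n)
        minorIdx + (colIdx - 1L) * n
      }
    } else {
      m <- dx[idx] / dy[idx]
      ## x at each row centre y_r = -cent[r]; continuous column coordinate
      X <- p0x[idx] + m * outer(rep(1, k), -cent) - m * p0y[idx]
      rr <- X / s + (n + 1) / 2
      i0 <- floor(rr)
      fr <- rr - i0
      fac <- s * sqrt(1 + m^2)
      majorPix <- function(minorIdx) {
        rowIdx <- matrix(rep(seq_len(n), each = k), k, n)
        rowIdx + (minorIdx - 1L) * n
      }
    }
    rayIdx <- matrix(rep(raySel[idx], times = n), k, n)
    out_i <- integer(); out_j <- integer(); out_x <- numeric()
    ## two interpolation taps: minor index i0 (weight 1-fr) and i0+1 (fr)
    for (tap in 1:2) {
      minor <- if (tap == 1L) i0 else i0 + 1
      w <- if (tap == 1L) (1 - fr) else fr
      keep <- minor >= 1 & minor <= n & w > 0
      if (any(keep)) {
        out_i <- c(out_i, rayIdx[keep])
        out_j <- c(out_j, as.integer(majorPix(minor)[keep]))
        out_x <- c(out_x, (w * fac)[keep])
      }
    }
    list(i = out_i, j = out_j, x = out_x)
  }

  a <- build(which(xdom), TRUE)
  b <- build(which(!xdom), FALSE)
  list(i = c(a$i, b$i), j = c(a$j, b$j), x = c(a$x, b$x))
}

#' Build the Joseph projection operator for a grid and geometry
#'
#' Assembles the sparse system matrix W whose entry w_ij is the Joseph
#' interpolation weight of pixel j on ray i (in physical length units).
#' Forward and back projection are then sparse matrix-vector products, and
#' the row/column sums needed by SIRT come directly from W.
#'
#' @param grid reconstruction \linkS4class{ImageGrid}.
#' @param geometry \linkS4class{ProjectionGeometry}; for fan beam the
#'   source must lie outside the grid.
#' @return A \linkS4class{TomoOperator}.
#' @export
#' @examples
#' op <- tomoOperator(imageGrid(16), makeEquiangularGeometry("parallel",
#'   nAngles = 8, nDetectors = 16))
tomoOperator <- function(grid, geometry) {
  n <- grid@nCols
  s <- grid@pixelSize
  .checkCoverage(grid, geometry)
  rays <- .rayBundle(geometry)
  tr <- .josephHalf(rays, seq_len(rays$nRays), n, s)
  W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(rays$nRays, n * n))
  new("TomoOperator", grid = grid, geometry = geometry, W = W)
}

## warn when the detector cannot see the grid's inscribed circle
.checkCoverage <- function(grid, geometry) {
  halfDet <- geometry@nDetectors * geometry@detectorPixelSize / 2
  radius <- grid@nCols * grid@pixelSize / 2
  mag <- if (identical(geometry@beam, "fan"))
    geometry@sourceDetectorDistance / geometry@sourceObjectDistance else 1
  if (halfDet < 0.999 * mag * radius)
    warning("detector (half-width ", halfDet,
            ") does not cover the grid's inscribed circle (radius ",
            radius, " at magnification ", signif(mag, 4), ")")
  invisible(TRUE)
}

## internal work ledger: operator applications are counted in pixel units
## so one application on a grid coarsened k times costs 4^-k of a
## target-grid application (see the benchmark budget semantics)
.newWorkCounter <- function() {
  env <- new.env(parent = emptyenv())
  env$applications <- 0L
  env$pixelWork <- 0
  env
}
.chargeWork <- function(counter, op) {
  if (!is.null(counter)) {
    counter$applications <- counter$applications + 1L
    counter$pixelWork <- counter$pixelWork + ncol(op@W)
  }
  invisible(NULL)
}

#' Forward projection (W x)
#'
#' Computes the sinogram of an image under a projection geometry using
#' Joseph's method: each sinogram entry is the interpolated line integral
#' of the image along the corresponding ray, in physical length units.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param geometry a \linkS4class{ProjectionGeometry}, or a prebuilt
#'   \linkS4class{TomoOperator} (preferred inside iterative loops so W is
#'   assembled once).
#' @return A \linkS4class{Sinogram}.
#' @export
forwardProject <- function(image, geometry) {
  op <- if (is(geometry, "TomoOperator")) geometry
        else tomoOperator(image@grid, geometry)
  if (!identical(dim(image@values), c(op@grid@nRows, op@grid@nCols)))
    stop("image shape does not match the operator grid")
  if (any(!is.finite(image@values)))
    stop("image contains non-finite values")
  p <- .opForward(op, as.vector(image@values))
  sinogram(matrix(p, nrow = length(op@geometry@angles),
                  ncol = op@geometry@nDetectors, byrow = TRUE),
           op@geometry)
}

## raw vector forms used by the solvers (rays in angle-major order)
.opForward <- function(op, xvec, counter = NULL) {
  .chargeWork(counter, op)
  as.vector(op@W %*% xvec)
}
.opAdjoint <- function(op, pvec, counter = NULL) {
  .chargeWork(counter, op)
  as.vector(Matrix::crossprod(op@W, pvec))
}
.sinoToVec <- function(values) as.vector(t(values))
.vecToSino <- function(p, geometry)
  matrix(p, nrow = length(geometry@angles), ncol = geometry@nDetectors,
         byrow = TRUE)

#' Back projection (W^T p)
#'
#' Applies the exact transpose of the Joseph forward projector: the same
#' interpolation weights, accumulated from rays into pixels. Together with
#' \code{\link{forwardProject}} this satisfies the adjoint identity
#' <W x, y> == <x, W^T y>.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param grid the reconstruction \linkS4class{ImageGrid}, or a prebuilt
#'   \linkS4class{TomoOperator}.
#' @return A \linkS4class{TomoImage}.
#' @export
backProject <- function(sino, grid) {
  op <- if (is(grid, "TomoOperator")) grid
        else tomoOperator(grid, sino@geometry)
  if (any(!is.finite(sino@values)))
    stop("sinogram contains non-finite values")
  x <- .opAdjoint(op, .sinoToVec(sino@values))
  tomoImage(matrix(x, op@grid@nRows, op@grid@nCols), op@grid)
}

#' Ray and pixel weight sums of the operator
#'
#' \code{raySums} returns, per ray, the total Joseph weight (identical to
#' forward-projecting an all-ones image); \code{pixelSums} returns, per
#' pixel, the total weight over all rays (identical to back-projecting an
#' all-ones sinogram). These are the diagonal normalisations of SIRT.
#' Zero sums (rays missing the grid, unseen pixels) are reciprocated to 0
#' by \code{\link{safeReciprocal}}.
#'
#' @param op a \linkS4class{TomoOperator}.
#' @return Numeric vector of length n_rays (\code{raySums}, angle-major
#'   order) or n_pixels (\code{pixelSums}, column-major order).
#' @export
raySums <- function(op) Matrix::rowSums(op@W)

#' @rdname raySums
#' @export
pixelSums <- function(op) Matrix::colSums(op@W)

#' Reciprocal with the zero convention
#'
#' Elementwise 1/x with 0 mapped to 0, so rays that miss the grid and
#' pixels seen by no ray stay inert in the SIRT update.
#'
#' @param x nonnegative numeric vector.
#' @return Numeric vector of the same length.
#' @export
safeReciprocal <- function(x) ifelse(x > 0, 1 / x, 0)

#' Materialise the system matrix densely (small grids only)
#'
#' Debug/testing path: returns W as a plain dense matrix. Refused for
#' grids larger than 16 x 16, where a dense W would be wastefully large.
#'
#' @param op a \linkS4class{TomoOperator}.
#' @param maxSide largest grid side for which densification is allowed.
#' @return A dense numeric matrix, n_rays x n_pixels.
#' @export
denseSystemMatrix <- function(op, maxSide = 16L) {
  if (op@grid@nCols > maxSide)
    stop("dense system matrix is only available for grids up to ",
         maxSide, " x ", maxSide)
  as.matrix(op@W)
}

#' Brute-force line integral oracle
#'
#' Independent check of the projector: approximates the line integral of
#' an image along one ray by a Riemann sum with nearest-pixel lookup. The
#' ray is clipped to the grid's bounding square and sampled at midpoints
#' of consecutive steps. Converges to the integral of the
#' piecewise-constant image as \code{step} shrinks.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param ray list with elements \code{point} (c(x, y) on the ray) and
#'   \code{direction} (c(dx, dy), not both zero).
#' @param step sampling step along the ray; must be positive and should be
#'   well below the pixel size.
#' @return The approximate line integral (0 for rays missing the grid).
#' @export
oracleLineIntegral <- function(image, ray, step) {
  if (step <= 0) stop("step must be positive")
  n <- image@grid@nCols
  s <- image@grid@pixelSize
  half <- n * s / 2
  d <- ray$direction / sqrt(sum(ray$direction^2))
  p0 <- ray$point
  ## slab clipping against the bounding square [-half, half]^2
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    if (abs(d[ax]) < 1e-14) {
      if (abs(p0[ax]) > half) return(0)
    } else {
      t1 <- (-half - p0[ax]) / d[ax]
      t2 <- (half - p0[ax]) / d[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) return(0)
  tt <- seq(tmin + step / 2, tmax, by = step)
  if (length(tt) == 0L) return(0)
  x <- p0[1] + tt * d[1]
  y <- p0[2] + tt * d[2]
  col <- round(x / s + (n + 1) / 2)
  row <- round((n + 1) / 2 - y / s)
  ok <- row >= 1 & row <= n & col >= 1 & col <= n
  if (!any(ok)) return(0)
  sum(image@values[cbind(row[ok], col[ok])]) * step
}

#' Rays of a geometry, for use with the line-integral oracle
#'
#' Returns the ray (point, direction) for each (angle, detector bin) pair,
#' matching the rays the Joseph operator integrates along.
#'
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @return A list of \code{list(point=, direction=)} entries in
#'   angle-major order (all bins of angle 1, then angle 2, ...).
#' @export
geometryRays <- function(geometry) {
  b <- .rayBundle(geometry)
  lapply(seq_len(b$nRays), function(i)
    list(point = c(b$p0x[i], b$p0y[i]), direction = c(b$dx[i], b$dy[i])))
}
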