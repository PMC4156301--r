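#' Termination rule for DART iterations
#'
#' Three rules are supported: a fixed number of iterations
#' (\code{"max_iterations"}), the relative number of modified pixels
#' dropping below a threshold (\code{"modified_pixels"}), and the change
#' in projection distance between consecutive iterations dropping below a
#' threshold (\code{"projection_distance_delta"}). The two thresholded
#' rules fire only after holding for \code{patience} consecutive
#' iterations (default 3).
#'
#' @slot kind one of the three rule names.
#' @slot threshold rule threshold (iteration count, pixel fraction, or
#'   distance delta respectively).
#' @slot patience number of consecutive iterations the condition must hold.
#' @export
setClass("TerminationSpec",
  representation(kind = "character", threshold = "numeric",
                 patience = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("max_iterations", "modified_pixels",
                            "projection_distance_delta"))
      msg <- c(msg, "unknown termination kind")
    if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
    if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param kind,threshold,patience see the slot descriptions.
#' @rdname TerminationSpec-class
#' @return \code{terminationSpec} returns a \linkS4class{TerminationSpec}.
#' @export
#' @examples
#' terminationSpec("projection_distance_delta", 1e-3, patience = 3)
terminationSpec <- function(kind = c("projection_distance_delta",
                                     "max_iterations", "modified_pixels"),
                            threshold, patience = 3L) {
  new("TerminationSpec", kind = match.arg(kind),
      threshold = as.numeric(threshold), patience = as.integer(patience))
}

#' DART parameter set
#'
#' @slot initialArmIters SIRT iterations for the initial reconstruction
#'   (used when no initial image is supplied).
#' @slot innerArmIters masked SIRT iterations per DART iteration.
#' @slot fixProbability probability with which each non-boundary pixel is
#'   freed (added to the non-fixed set) at every DART iteration.
#' @slot smoothingBlend blend weight b of the 3x3 neighbourhood-mean
#'   smoothing applied between DART iterations.
#' @slot termination a \linkS4class{TerminationSpec}.
#' @slot rngSeed integer seed making the random pixel freeing reproducible.
#' @slot connectivity 4 or 8; neighbourhood used for boundary detection.
#' @slot relaxation SIRT relaxation factor.
#' @export
setClass("DARTConfig",
  representation(initialArmIters = "integer", innerArmIters = "integer",
                 fixProbability = "numeric", smoothingBlend = "numeric",
                 termination = "TerminationSpec", rngSeed = "integer",
                 connectivity = "integer", relaxation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@initialArmIters < 0L || object@innerArmIters < 0L)
      msg <- c(msg, "iteration counts must be >= 0")
    if (object@fixProbability < 0 || object@fixProbability > 1)
      msg <- c(msg, "fixProbability must be in [0, 1]")
    if (object@smoothingBlend < 0 || object@smoothingBlend > 1)
      msg <- c(msg, "smoothingBlend must be in [0, 1]")
    if (!object@connectivity %in% c(4L, 8L))
      msg <- c(msg, "connectivity must be 4 or 8")
    if (length(msg)) msg else TRUE
  })

#' @param initialArmIters,innerArmIters,fixProbability,smoothingBlend
#'   see the slot descriptions.
#' @param termination a \linkS4class{TerminationSpec}.
#' @param rngSeed,connectivity,relaxation see the slot descriptions.
#' @rdname DARTConfig-class
#' @return \code{dartConfig} returns a \linkS4class{DARTConfig}.
#' @export
#' @examples
#' dartConfig(rngSeed = 7, termination = terminationSpec("max_iterations", 30))
dartConfig <- function(initialArmIters = 200L, innerArmIters = 10L,
                       fixProbability = 0.15, smoothingBlend = 0.1,
                       termination = terminationSpec(
                         "projection_distance_delta", 1e-3, 3L),
                       rngSeed = 1L, connectivity = 8L, relaxation = 1) {
  new("DARTConfig", initialArmIters = as.integer(initialArmIters),
      innerArmIters = as.integer(innerArmIters),
      fixProbability = as.numeric(fixProbability),
      smoothingBlend = as.numeric(smoothingBlend),
      termination = termination, rngSeed = as.integer(rngSeed),
      connectivity = as.integer(connectivity),
      relaxation = as.numeric(relaxation))
}

#' Global-threshold segmentation
#'
#' Maps every pixel to the grey value of its threshold interval: values in
#' (tau_{i-1}, tau_i] map to rho_i, values at or below the first threshold
#' to rho_1, values above the last threshold to rho_L. Ties at a threshold
#' go to the lower class (half-open intervals).
#'
#' @param image a \linkS4class{TomoImage}.
#' @param model a \linkS4class{GreyLevelModel}.
#' @return A \linkS4class{TomoImage} whose values all belong to
#'   \code{greyValues(model)}.
#' @export
#' @examples
#' m <- greyLevelModel(c(0, 0.5, 1), thresholds = c(0.25, 0.75))
#' values(segmentImage(tomoImage(matrix(0.3, 1, 1)), m))  # 0.5
segmentImage <- function(image, model) {
  v <- image@values
  idx <- matrix(1L, nrow(v), ncol(v))
  for (tau in model@thresholds)
    idx <- idx + (v > tau)
  tomoImage(matrix(model@greyValues[idx], nrow(v), ncol(v)), image@grid)
}

## logical matrix marking pixels with a differing neighbour
.boundaryMask <- function(v, connectivity) {
  n <- nrow(v); m <- ncol(v)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  b <- matrix(FALSE, n, m)
  for (sh in shifts) {
    r <- seq_len(n); r <- r[r + sh[1L] >= 1L & r + sh[1L] <= n]
    cc <- seq_len(m); cc <- cc[cc + sh[2L] >= 1L & cc + sh[2L] <= m]
    b[r, cc] <- b[r, cc] | (v[r, cc] != v[r + sh[1L], cc + sh[2L]])
  }
  b
}

#' Boundary pixels of a segmented image
#'
#' A pixel is a boundary pixel when at least one adjacent pixel (under
#' 4- or 8-connectivity; image borders use only in-grid neighbours) has a
#' different grey level. These pixels always enter DART's non-fixed set.
#'
#' @param segmented a segmented \linkS4class{TomoImage}.
#' @param connectivity 4 or 8 (default).
#' @return Sorted integer vector of column-major pixel indices.
#' @export
boundaryPixels <- function(segmented, connectivity = 8L) {
  which(.boundaryMask(segmented@values, as.integer(connectivity)))
}

#' Partition pixels into DART's fixed and non-fixed sets
#'
#' The non-fixed set U is the boundary of the segmentation plus each
#' non-boundary pixel independently with probability \code{p} (drawn from
#' the current RNG stream, so results are reproducible under
#' \code{set.seed}); the fixed set F is the complement.
#'
#' @param segmented a segmented \linkS4class{TomoImage}.
#' @param p probability in [0, 1] of freeing a non-boundary pixel.
#' @param connectivity 4 or 8 (default).
#' @return A \linkS4class{PixelPartition}.
#' @export
makePartition <- function(segmented, p, connectivity = 8L) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  bmask <- .boundaryMask(segmented@values, as.integer(connectivity))
  nPix <- length(bmask)
  boundary <- which(bmask)
  nonB <- which(!bmask)
  freed <- if (p > 0 && length(nonB) > 0L)
    nonB[stats::runif(length(nonB)) < p] else integer()
  nonFixed <- sort(c(boundary, freed))
  new("PixelPartition", nonFixed = as.integer(nonFixed),
      fixed = setdiff(seq_len(nPix), nonFixed),
      boundary = as.integer(boundary), nPixels = as.integer(nPix))
}

#' Neighbourhood-mean smoothing
#'
#' Blends every pixel with the mean of its 3x3 in-grid neighbourhood
#' (centre excluded): \code{x <- (1 - b) x + b mean(neighbours)}. Applied
#' to the entire image between DART iterations to regularise the
#' continuous iterate.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param b blend weight in [0, 1]; 0 is the identity.
#' @return A \linkS4class{TomoImage}.
#' @export
smoothImage <- function(image, b) {
  if (b < 0 || b > 1) stop("blend weight must be in [0, 1]")
  if (b == 0) return(image)
  v <- image@values
  n <- nrow(v); m <- ncol(v)
  acc <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r <- seq_len(n); r <- r[r + dr >= 1L & r + dr <= n]
    cc <- seq_len(m); cc <- cc[cc + dc >= 1L & cc + dc <= m]
    acc[r, cc] <- acc[r, cc] + v[r + dr, cc + dc]
    cnt[r, cc] <- cnt[r, cc] + 1
  }
  tomoImage((1 - b) * v + b * acc / cnt, image@grid)
}

#' Evaluate a termination rule on a reconstruction trace
#'
#' @param trace data frame with one row per completed DART iteration,
#'   carrying at least \code{iteration}, \code{proj_distance},
#'   \code{modified_pixels} and \code{n_pixels} columns (as produced by
#'   \code{\link{dartReconstruct}}).
#' @param spec a \linkS4class{TerminationSpec}.
#' @return \code{TRUE} when the rule fires.
#' @export
checkTermination <- function(trace, spec) {
  if (nrow(trace) == 0L) stop("trace is empty")
  k <- nrow(trace)
  pat <- spec@patience
  switch(spec@kind,
    max_iterations = trace$iteration[k] >= spec@threshold,
    modified_pixels = {
      if (k < pat) return(FALSE)
      frac <- trace$modified_pixels / trace$n_pixels
      all(frac[(k - pat + 1L):k] < spec@threshold)
    },
    projection_distance_delta = {
      if (k < pat + 1L) return(FALSE)
      deltas <- abs(diff(trace$proj_distance))
      all(deltas[(k - pat):(k - 1L)] < spec@threshold)
    },
    stop("unknown termination kind: ", spec@kind))
}

## one trace row; time is wall clock since t0
.traceRow <- function(iteration, level, t0, projDist, modified, nPixels,
                      counter, rnmpVal) {
  data.frame(iteration = iteration, level = level,
             time_s = as.numeric(proc.time()["elapsed"]) - t0,
             proj_distance = projDist, modified_pixels = modified,
             n_pixels = nPixels, pixel_work = counter$pixelWork,
             operator_applications = counter$applications,
             rnmp = rnmpVal)
}

.budgetExhausted <- function(budget, counter, t0) {
  if (is.null(budget)) return(FALSE)
  if (!is.null(budget$pixelWork) && counter$pixelWork >= budget$pixelWork)
    return(TRUE)
  if (!is.null(budget$seconds) &&
      (as.numeric(proc.time()["elapsed"]) - t0) >= budget$seconds)
    return(TRUE)
  FALSE
}

#' DART: discrete algebraic reconstruction
#'
#' Reconstructs an image known to contain only the grey values of
#' \code{model} from few-view projection data. Starting from an initial
#' SIRT reconstruction, each DART iteration (i) segments the current
#' iterate with the global thresholds, (ii) partitions pixels into a
#' fixed set (kept at their segmented grey values) and a non-fixed set
#' (segmentation boundary plus a random fraction of the rest), (iii) runs
#' masked SIRT on the non-fixed pixels, (iv) checks termination, and
#' (v) smooths the entire iterate before the next round. Smoothing is
#' skipped after the terminating iteration, so the returned continuous
#' image is the un-smoothed post-SIRT iterate.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param grid the reconstruction \linkS4class{ImageGrid}.
#' @param model a \linkS4class{GreyLevelModel} with the object's grey
#'   values and thresholds.
#' @param config a \linkS4class{DARTConfig}; the run is deterministic
#'   given \code{rngSeed}.
#' @param initial optional \linkS4class{TomoImage} starting iterate; when
#'   omitted, \code{initialArmIters} unmasked SIRT iterations from zero
#'   are used.
#' @param budget optional list with elements \code{pixelWork} (operator
#'   applications weighted by grid pixel count) and/or \code{seconds}
#'   (wall time); checked between DART iterations only.
#' @param groundTruth optional phantom \linkS4class{TomoImage}; when
#'   given, each trace row carries the RNMP of the current segmentation.
#' @param operator optional prebuilt \linkS4class{TomoOperator}.
#' @param level grid level tag recorded in the trace (used by MDART).
#' @param workCounter,startTime internal: shared work ledger and start
#'   time for multi-level runs.
#' @return A list with elements \code{continuous} (final iterate),
#'   \code{segmented} (its segmentation) and \code{trace} (data frame with
#'   iteration, level, time_s, proj_distance, modified_pixels, n_pixels,
#'   pixel_work, operator_applications, rnmp).
#' @export
#' @examples
#' ph <- diskWithHoles(32, diskRadius = 12, holeRadius = 3, nHoles = 2,
#'                     seed = 4)
#' geom <- makeEquiangularGeometry("parallel", nAngles = 20, nDetectors = 32)
#' p <- forwardProject(ph, geom)
#' cfg <- dartConfig(initialArmIters = 50, innerArmIters = 5,
#'                   termination = terminationSpec("max_iterations", 10))
#' res <- dartReconstruct(p, imageGridOf(ph), greyLevelModel(c(0, 1)), cfg)
dartReconstruct <- function(sino, grid, model, config = dartConfig(),
                            initial = NULL, budget = NULL,
                            groundTruth = NULL, operator = NULL,
                            level = 0L, workCounter = NULL,
                            startTime = NULL) {
  op <- if (is.null(operator)) tomoOperator(grid, sino@geometry) else operator
  counter <- if (is.null(workCounter)) .newWorkCounter() else workCounter
  t0 <- if (is.null(startTime)) as.numeric(proc.time()["elapsed"]) else startTime
  set.seed(config@rngSeed)
  if (!is.null(budget) && !is.null(budget$seconds) && budget$seconds <= 0)
    stop("budget must be positive")
  if (is.null(initial)) {
    initial <- sirtRun(tomoImage(0, grid), sino, config@initialArmIters,
                       relaxation = config@relaxation, operator = op,
                       workCounter = counter)
  } else if (!identical(dim(initial@values), c(grid@nRows, grid@nCols))) {
    stop("initial image does not match the reconstruction grid")
  }
  x <- initial
  nPix <- grid@nRows * grid@nCols
  trace <- NULL
  iter <- 0L
  maxIterGuard <- 100000L
  repeat {
    if (.budgetExhausted(budget, counter, t0)) break
    iter <- iter + 1L
    seg <- segmentImage(x, model)
    part <- makePartition(seg, config@fixProbability, config@connectivity)
    ## fixed pixels take their segmented grey values; non-fixed keep the
    ## continuous iterate
    xv <- x@values
    xv[part@fixed] <- seg@values[part@fixed]
    x <- sirtRun(tomoImage(xv, grid), sino, config@innerArmIters,
                 mask = part@nonFixed, relaxation = config@relaxation,
                 operator = op, workCounter = counter)
    newSeg <- segmentImage(x, model)
    modified <- sum(newSeg@values != seg@values)
    d <- projectionDistance(x, sino, operator = op, workCounter = counter)
    rn <- if (is.null(groundTruth)) NA_real_
          else rnmp(groundTruth, newSeg, model)
    trace <- rbind(trace, .traceRow(iter, level, t0, d, modified, nPix,
                                    counter, rn))
    if (checkTermination(trace, config@termination)) break
    if (iter >= maxIterGuard) break
    if (.budgetExhausted(budget, counter, t0)) break
    x <- smoothImage(x, config@smoothingBlend)
  }
  if (is.null(trace))
    trace <- .traceRow(0L, level, t0,
                       projectionDistance(x, sino, operator = op,
                                          workCounter = counter),
                       0L, nPix, counter, NA_real_)[0, ]
  list(continuous = x, segmented = segmentImage(x, model), trace = trace)
}
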