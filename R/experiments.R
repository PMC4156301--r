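#' Segmented SIRT (SSIRT) baseline
#'
#' Plain unmasked SIRT run until an iteration count or budget is
#' exhausted, followed by one global-threshold segmentation. This is the
#' non-discrete baseline every DART variant is compared against.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param grid reconstruction \linkS4class{ImageGrid}.
#' @param model \linkS4class{GreyLevelModel} used for the final
#'   segmentation.
#' @param nIters maximum SIRT iterations (default effectively unlimited;
#'   give a budget instead for time-parity comparisons).
#' @param budget optional list with \code{pixelWork} and/or \code{seconds},
#'   checked before every iteration.
#' @param groundTruth optional phantom for per-iteration RNMP tracing.
#' @param operator optional prebuilt \linkS4class{TomoOperator}.
#' @return As \code{\link{dartReconstruct}}: list with \code{continuous},
#'   \code{segmented}, \code{trace}.
#' @export
ssirtReconstruct <- function(sino, grid, model, nIters = 100000L,
                             budget = NULL, groundTruth = NULL,
                             operator = NULL) {
  op <- if (is.null(operator)) tomoOperator(grid, sino@geometry) else operator
  counter <- .newWorkCounter()
  t0 <- as.numeric(proc.time()["elapsed"])
  x <- tomoImage(0, grid)
  prevSeg <- segmentImage(x, model)
  nPix <- grid@nRows * grid@nCols
  trace <- NULL
  iter <- 0L
  while (iter < nIters) {
    if (.budgetExhausted(budget, counter, t0)) break
    iter <- iter + 1L
    x <- sirtRun(x, sino, 1L, operator = op, workCounter = counter)
    seg <- segmentImage(x, model)
    modified <- sum(seg@values != prevSeg@values)
    prevSeg <- seg
    d <- projectionDistance(x, sino, operator = op, workCounter = counter)
    rn <- if (is.null(groundTruth)) NA_real_ else rnmp(groundTruth, seg, model)
    trace <- rbind(trace, .traceRow(iter, 0L, t0, d, modified, nPix,
                                    counter, rn))
  }
  if (is.null(trace))
    trace <- .traceRow(0L, 0L, t0, NA_real_, 0L, nPix, counter,
                       NA_real_)[0, ]
  list(continuous = x, segmented = segmentImage(x, model), trace = trace)
}

## reconstruct one dataset with a named algorithm; "mdartN" selects an
## N-level multiresolution run
.runAlgorithm <- function(algorithm, sino, grid, model, config, budget,
                          seed) {
  cfg <- dartConfig(initialArmIters = config@initialArmIters,
                    innerArmIters = config@innerArmIters,
                    fixProbability = config@fixProbability,
                    smoothingBlend = config@smoothingBlend,
                    termination = config@termination,
                    rngSeed = seed, connectivity = config@connectivity,
                    relaxation = config@relaxation)
  if (identical(algorithm, "ssirt"))
    return(ssirtReconstruct(sino, grid, model, budget = budget))
  if (identical(algorithm, "dart"))
    return(dartReconstruct(sino, grid, model, cfg, budget = budget))
  if (grepl("^mdart[0-9]+$", algorithm)) {
    levels <- as.integer(sub("^mdart", "", algorithm))
    return(mdartReconstruct(sino, mdartConfig(grid, levels, cfg), model,
                            budget = budget))
  }
  stop("unknown algorithm: ", algorithm)
}

#' Run a benchmark sweep
#'
#' Executes the full cross-product of phantoms, projection counts,
#' missing wedges, photon counts, algorithms and seeds under one shared
#' budget, reconstructing each dataset and scoring it with RNMP. This is
#' the engine behind the projection-count, hole-radius/missing-wedge and
#' photon-count sweep protocols.
#'
#' @param spec a list with fields:
#'   \describe{
#'     \item{phantoms}{named list of ground-truth
#'       \linkS4class{TomoImage}s.}
#'     \item{reconGrid}{\linkS4class{ImageGrid} for all reconstructions.}
#'     \item{model}{\linkS4class{GreyLevelModel}.}
#'     \item{beam}{"parallel" or "fan".}
#'     \item{nAnglesList}{integer vector of projection counts.}
#'     \item{angularRange}{degrees (default 360 for fan, 180 parallel).}
#'     \item{missingWedges}{numeric vector of wedge widths in degrees
#'       (default 0).}
#'     \item{nDetectors, detectorPixelSize}{detector layout.}
#'     \item{sourceObjectDistance, sourceDetectorDistance}{fan distances.}
#'     \item{photonCounts}{optional photon counts; \code{NA} entries mean
#'       noiseless (default).}
#'     \item{algorithms}{character vector from "ssirt", "dart",
#'       "mdart<N>".}
#'     \item{config}{base \linkS4class{DARTConfig}; the per-run seed
#'       replaces its \code{rngSeed}.}
#'     \item{budget}{list with \code{pixelWork} and/or \code{seconds}.}
#'     \item{seeds}{integer vector of replicate seeds.}
#'   }
#' @return A data frame with one row per completed run: phantom id,
#'   algorithm, seed, n_angles, missing_wedge, photon_count, final RNMP,
#'   iterations, pixel_work and an error message for failed runs (their
#'   rnmp is NA; the sweep continues).
#' @export
runBenchmark <- function(spec) {
  stopifnot(length(spec$phantoms) >= 1L, length(spec$algorithms) >= 1L)
  beam <- if (is.null(spec$beam)) "fan" else spec$beam
  angularRange <- if (is.null(spec$angularRange))
    (if (beam == "fan") 360 else 180) else spec$angularRange
  wedges <- if (is.null(spec$missingWedges)) 0 else spec$missingWedges
  photons <- if (is.null(spec$photonCounts)) NA_real_ else spec$photonCounts
  seeds <- if (is.null(spec$seeds)) 1L else spec$seeds
  config <- if (is.null(spec$config)) dartConfig() else spec$config
  rows <- list()
  for (phName in names(spec$phantoms)) {
    phantom <- spec$phantoms[[phName]]
    for (nAng in spec$nAnglesList) for (wedge in wedges) {
      geom <- makeEquiangularGeometry(beam, nAngles = nAng,
        angularRange = angularRange, missingWedge = wedge,
        nDetectors = spec$nDetectors,
        detectorPixelSize = spec$detectorPixelSize,
        sourceObjectDistance = spec$sourceObjectDistance,
        sourceDetectorDistance = spec$sourceDetectorDistance)
      clean <- forwardProject(phantom, geom)
      for (I0 in photons) for (seed in seeds) {
        sino <- if (is.na(I0)) clean else applyPoisson(clean, I0, seed)
        for (alg in spec$algorithms) {
          res <- tryCatch(
            .runAlgorithm(alg, sino, spec$reconGrid, spec$model, config,
                          spec$budget, seed),
            error = function(e) e)
          if (inherits(res, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              phantom = phName, algorithm = alg, seed = seed,
              n_angles = nAng, missing_wedge = wedge, photon_count = I0,
              rnmp = NA_real_, iterations = NA_integer_,
              pixel_work = NA_real_, error = conditionMessage(res))
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            phantom = phName, algorithm = alg, seed = seed,
            n_angles = nAng, missing_wedge = wedge, photon_count = I0,
            rnmp = rnmp(phantom, res$segmented),
            iterations = nrow(res$trace),
            pixel_work = if (nrow(res$trace)) utils::tail(
              res$trace$pixel_work, 1L) else 0,
            error = NA_character_)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark replicates
#'
#' Averages RNMP over replicates (phantoms and/or seeds) within each
#' combination of the grouping columns, reporting the mean and its
#' standard error (sd / sqrt(n)).
#'
#' @param table a result table from \code{\link{runBenchmark}}.
#' @param by character vector of grouping column names (default:
#'   algorithm, n_angles, missing_wedge, photon_count).
#' @return Data frame with the grouping columns plus \code{mean_rnmp},
#'   \code{se_rnmp} and \code{n}.
#' @export
#' @examples
#' t <- data.frame(algorithm = "dart", n_angles = 10, missing_wedge = 0,
#'                 photon_count = NA, rnmp = c(0.1, 0.2, 0.3))
#' aggregateRnmp(t)   # mean 0.2, se 0.0577
aggregateRnmp <- function(table,
                          by = c("algorithm", "n_angles", "missing_wedge",
                                 "photon_count")) {
  by <- intersect(by, names(table))
  keyCols <- lapply(table[by], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "<none>"   # NA photon count means noiseless
    x
  })
  key <- interaction(keyCols, drop = TRUE)
  parts <- split(table, key)
  out <- lapply(parts, function(d) {
    v <- d$rnmp[!is.na(d$rnmp)]
    cbind(d[1L, by, drop = FALSE],
          data.frame(mean_rnmp = mean(v),
                     se_rnmp = if (length(v) > 1L)
                       stats::sd(v) / sqrt(length(v)) else NA_real_,
                     n = length(v)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
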