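#' Multiresolution DART configuration
#'
#' Describes an n-level coarse-to-fine run: level k (k = nLevels-1, ..., 0)
#' reconstructs on the target grid coarsened k times (pixel size
#' 2^k x target, same physical field of view). The target side must be
#' divisible by 2^(nLevels-1). Unless per-level overrides are given, all
#' levels share one DART parameter set.
#'
#' @slot nLevels number of grids (1 reproduces plain DART).
#' @slot targetGrid the finest (output) \linkS4class{ImageGrid}.
#' @slot interpolation inter-level resampling; only \code{"bilinear"}.
#' @slot configs list of \linkS4class{DARTConfig}, coarsest level first.
#' @export
setClass("MDARTConfig",
  representation(nLevels = "integer", targetGrid = "ImageGrid",
                 interpolation = "character", configs = "list"),
  validity = function(object) {
    msg <- character()
    if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
    if (!identical(object@interpolation, "bilinear"))
      msg <- c(msg, "only bilinear interpolation is supported")
    if (length(object@configs) != object@nLevels)
      msg <- c(msg, "need one DARTConfig per level")
    f <- 2L^(object@nLevels - 1L)
    if (object@targetGrid@nCols %% f != 0L)
      msg <- c(msg, "target grid side must be divisible by 2^(nLevels-1)")
    if (length(msg)) msg else TRUE
  })

#' @param targetGrid,nLevels see the slot descriptions.
#' @param config the \linkS4class{DARTConfig} shared by all levels.
#' @param perLevel optional list of per-level \linkS4class{DARTConfig}
#'   overrides, coarsest level first; \code{NULL} entries fall back to
#'   \code{config}.
#' @rdname MDARTConfig-class
#' @return \code{mdartConfig} returns an \linkS4class{MDARTConfig}.
#' @export
#' @examples
#' mdartConfig(imageGrid(64), nLevels = 2, config = dartConfig(rngSeed = 3))
mdartConfig <- function(targetGrid, nLevels, config = dartConfig(),
                        perLevel = NULL) {
  nLevels <- as.integer(nLevels)
  configs <- rep(list(config), nLevels)
  if (!is.null(perLevel)) {
    for (i in seq_along(perLevel))
      if (!is.null(perLevel[[i]])) configs[[i]] <- perLevel[[i]]
  }
  new("MDARTConfig", nLevels = nLevels, targetGrid = targetGrid,
      interpolation = "bilinear", configs = configs)
}

#' Dyadic bilinear upsampling
#'
#' Doubles the grid side and halves the pixel size, preserving the
#' physical field of view. Pixel values are treated as samples at pixel
#' centres and interpolated bilinearly; target centres outside the range
#' of source centres (a half source pixel at each edge) replicate the edge
#' value. This is the carrier that moves an MDART iterate from one grid
#' level to the next finer one.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param factor only 2 is supported (dyadic level ratio).
#' @return A \linkS4class{TomoImage} on the doubled grid.
#' @export
#' @examples
#' v <- matrix(c(0, 0, 1, 1), 2, 2)   # rows [0, 1]
#' values(upsampleImage(tomoImage(v)))[1, ]  # 0 0.25 0.75 1
upsampleImage <- function(image, factor = 2L) {
  if (factor != 2L) stop("only factor-2 upsampling is supported")
  interpAxis <- function(M) {
    ## output sample j sits at source coordinate j/2 + 1/4 (centre-aligned)
    n <- nrow(M)
    u <- seq_len(2L * n) / 2 + 0.25
    i0 <- floor(u)
    fr <- u - i0
    lo <- pmin(pmax(i0, 1), n)
    hi <- pmin(i0 + 1, n)
    (1 - fr) * M[lo, , drop = FALSE] + fr * M[hi, , drop = FALSE]
  }
  out <- t(interpAxis(t(interpAxis(image@values))))
  tomoImage(out, imageGrid(2L * image@grid@nCols, image@grid@pixelSize / 2))
}

#' MDART: multiresolution DART reconstruction
#'
#' Runs DART on a hierarchy of grids sharing one physical field of view
#' and one (untouched) projection dataset. The coarsest level starts from
#' its own SIRT initial reconstruction; every finer level is initialised
#' by bilinear upsampling of the previous level's continuous iterate, and
#' the pixel size halves at each switch. With \code{nLevels = 1} the run
#' is identical to \code{\link{dartReconstruct}} under the same seed and
#' configuration. Coarse grids make the few-view problem less
#' underdetermined, so early levels converge quickly and cheaply; the
#' final level refines detail at the target resolution.
#'
#' @param sino a \linkS4class{Sinogram}; the same data are used at every
#'   level.
#' @param config an \linkS4class{MDARTConfig}.
#' @param model a \linkS4class{GreyLevelModel}.
#' @param budget optional global budget (list with \code{pixelWork} and/or
#'   \code{seconds}) shared across levels; levels simply run until their
#'   own termination or until the budget is exhausted, whichever first.
#' @param groundTruth optional phantom for per-iteration RNMP tracing.
#' @return As \code{\link{dartReconstruct}}: list with \code{continuous},
#'   \code{segmented} and \code{trace}; the trace's \code{level} column
#'   records the grid level of each iteration (nLevels-1 down to 0) and
#'   \code{level_switch} marks the first iteration after each grid switch.
#' @export
#' @examples
#' ph <- diskWithHoles(64, diskRadius = 24, holeRadius = 6, nHoles = 2,
#'                     seed = 1)
#' geom <- makeEquiangularGeometry("parallel", nAngles = 16, nDetectors = 64)
#' p <- forwardProject(ph, geom)
#' cfg <- mdartConfig(imageGrid(64), nLevels = 2,
#'   config = dartConfig(initialArmIters = 40, innerArmIters = 5,
#'     termination = terminationSpec("max_iterations", 8)))
#' res <- mdartReconstruct(p, cfg, greyLevelModel(c(0, 1)))
mdartReconstruct <- function(sino, config, model, budget = NULL,
                             groundTruth = NULL) {
  n <- config@nLevels
  counter <- .newWorkCounter()
  t0 <- as.numeric(proc.time()["elapsed"])
  x <- NULL
  traces <- vector("list", n)
  res <- NULL
  for (k in seq(n - 1L, 0L)) {
    grid_k <- coarsenGrid(config@targetGrid, k)
    cfg <- config@configs[[n - k]]
    res <- dartReconstruct(sino, grid_k, model, cfg, initial = x,
                           budget = budget, groundTruth = groundTruth,
                           level = k, workCounter = counter,
                           startTime = t0)
    tr <- res$trace
    if (nrow(tr) > 0L)
      tr$level_switch <- c(k < n - 1L, rep(FALSE, nrow(tr) - 1L))
    else
      tr$level_switch <- logical(0)
    traces[[n - k]] <- tr
    if (k > 0L) x <- upsampleImage(res$continuous)
  }
  list(continuous = res$continuous, segmented = res$segmented,
       trace = do.call(rbind, traces))
}
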