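#' Create a square reconstruction grid
#'
#' The grid is centred on the rotation axis; pixel (r, c) has its centre at
#' world coordinates x = (c - (n+1)/2) * pixelSize,
#' y = ((n+1)/2 - r) * pixelSize (x to the right, y up, rows downward).
#'
#' @param side number of pixels per side (grids are square).
#' @param pixelSize physical size of one pixel (length units).
#' @return An \linkS4class{ImageGrid}.
#' @export
#' @examples
#' imageGrid(64, pixelSize = 1)
imageGrid <- function(side, pixelSize = 1) {
  if (length(side) == 2L) {
    if (side[1L] != side[2L])
      stop("non-square grids are not supported (got ", side[1L], " x ",
           side[2L], ")")
    side <- side[1L]
  }
  new("ImageGrid", nRows = as.integer(side), nCols = as.integer(side),
      pixelSize = as.numeric(pixelSize))
}

#' Create an image on a grid
#'
#' @param values numeric matrix of pixel values (rows x cols), or a single
#'   number recycled over the grid.
#' @param grid an \linkS4class{ImageGrid}; defaults to a grid matching
#'   \code{values} with unit pixels.
#' @return A \linkS4class{TomoImage}.
#' @export
#' @examples
#' tomoImage(matrix(0, 16, 16))
tomoImage <- function(values, grid = NULL) {
  if (is.matrix(values) && is.null(grid))
    grid <- imageGrid(dim(values))
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("TomoImage", grid = grid, values = values)
}

## world coordinates of pixel centres, as used by the projector and the
## resampling routines
.pixelCentres <- function(grid) {
  n <- grid@nCols
  s <- grid@pixelSize
  x <- (seq_len(n) - (n + 1) / 2) * s
  list(x = x, y = rev(x))   # y of row r is ((n+1)/2 - r) * s
}

#' Equiangular projection geometry with optional missing wedge
#'
#' Builds \code{nAngles} projection angles uniformly spaced over the
#' half-open interval [0, angularRange - missingWedge) degrees; the missing
#' wedge is carved out of the top of the range. For fan beam, the source
#' and detector distances must both be supplied.
#'
#' @param beam \code{"parallel"} or \code{"fan"}.
#' @param nAngles number of projections (>= 1).
#' @param angularRange total nominal angular range in degrees (180 for
#'   parallel, 360 for fan, typically).
#' @param missingWedge width of the unobserved wedge in degrees
#'   (0 <= wedge < range).
#' @param nDetectors number of detector bins.
#' @param detectorPixelSize width of one detector bin (length units).
#' @param sourceObjectDistance,sourceDetectorDistance fan-beam distances
#'   from the source to the rotation axis and to the detector.
#' @return A \linkS4class{ProjectionGeometry}.
#' @export
#' @examples
#' makeEquiangularGeometry("parallel", nAngles = 4, angularRange = 180,
#'                         nDetectors = 32)
makeEquiangularGeometry <- function(beam = c("parallel", "fan"),
                                    nAngles,
                                    angularRange = if (beam == "fan") 360 else 180,
                                    missingWedge = 0,
                                    nDetectors,
                                    detectorPixelSize = 1,
                                    sourceObjectDistance = NA_real_,
                                    sourceDetectorDistance = NA_real_) {
  beam <- match.arg(beam)
  if (nAngles < 1L) stop("nAngles must be >= 1")
  if (missingWedge < 0 || missingWedge >= angularRange)
    stop("invalid geometry: missing wedge must satisfy 0 <= wedge < angular range")
  if (beam == "fan" &&
      (is.na(sourceObjectDistance) || is.na(sourceDetectorDistance)))
    stop("fan-beam geometry requires sourceObjectDistance and sourceDetectorDistance")
  covered <- angularRange - missingWedge
  ang <- (seq_len(nAngles) - 1L) / nAngles * covered * pi / 180
  new("ProjectionGeometry", beam = beam, angles = ang,
      nDetectors = as.integer(nDetectors),
      detectorPixelSize = as.numeric(detectorPixelSize),
      sourceObjectDistance = as.numeric(sourceObjectDistance),
      sourceDetectorDistance = as.numeric(sourceDetectorDistance),
      angularRange = as.numeric(angularRange),
      missingWedge = as.numeric(missingWedge))
}

#' Create a sinogram
#'
#' @param values numeric matrix, one row per angle, one column per
#'   detector bin.
#' @param geometry the \linkS4class{ProjectionGeometry} the data live on.
#' @return A \linkS4class{Sinogram}.
#' @export
sinogram <- function(values, geometry) {
  storage.mode(values) <- "double"
  new("Sinogram", geometry = geometry, values = values)
}

#' Coarsen a grid by dyadic factors
#'
#' Returns the grid with side divided by 2^k and pixel size multiplied by
#' 2^k: same physical field of view, fewer and larger pixels. This is the
#' grid hierarchy multiresolution DART descends through.
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param k non-negative integer number of halvings.
#' @return An \linkS4class{ImageGrid}.
#' @export
#' @examples
#' coarsenGrid(imageGrid(256, 1), 2)  # 64 pixels of size 4
coarsenGrid <- function(grid, k) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  if (k == 0L) return(grid)
  f <- 2L^k
  if (grid@nCols %% f != 0L)
    stop("grid side ", grid@nCols, " is not divisible by 2^", k)
  imageGrid(grid@nCols %/% f, grid@pixelSize * f)
}

#' Default grey-level model
#'
#' @param greyValues strictly increasing grey values (>= 2 of them).
#' @param thresholds segmentation thresholds; defaults to the midpoints of
#'   consecutive grey values (the global threshold used throughout).
#' @return A \linkS4class{GreyLevelModel}.
#' @export
#' @examples
#' greyLevelModel(c(0, 1))            # binary, threshold 0.5
#' greyLevelModel(c(0, 0.5, 1), thresholds = c(0.25, 0.75))
greyLevelModel <- function(greyValues, thresholds = NULL) {
  greyValues <- sort(as.numeric(greyValues))
  if (is.null(thresholds))
    thresholds <- (greyValues[-1L] + greyValues[-length(greyValues)]) / 2
  new("GreyLevelModel", greyValues = greyValues,
      thresholds = as.numeric(thresholds))
}
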