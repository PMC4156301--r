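#' Nearest-neighbour resampling between grids
#'
#' Maps an image onto a target grid covering the same physical field of
#' view: each target pixel takes the value of the source pixel whose
#' centre is nearest to the target pixel centre. No new values are
#' created, so segmented (label) images stay label images. This is the
#' resampling used before counting misclassified pixels.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param targetGrid an \linkS4class{ImageGrid} with the same field of
#'   view as the image's grid.
#' @return A \linkS4class{TomoImage} on \code{targetGrid}.
#' @export
resampleNearest <- function(image, targetGrid) {
  srcGrid <- image@grid
  fovS <- srcGrid@nCols * srcGrid@pixelSize
  fovT <- targetGrid@nCols * targetGrid@pixelSize
  if (abs(fovS - fovT) > 1e-9 * max(fovS, fovT))
    stop("source and target grids cover different fields of view")
  if (identical(srcGrid@nCols, targetGrid@nCols) &&
      isTRUE(all.equal(srcGrid@pixelSize, targetGrid@pixelSize)))
    return(tomoImage(image@values, targetGrid))
  ratio <- targetGrid@pixelSize / srcGrid@pixelSize
  idx <- round((seq_len(targetGrid@nCols) - 0.5) * ratio + 0.5)
  idx <- pmin(pmax(idx, 1L), srcGrid@nCols)
  tomoImage(image@values[idx, idx, drop = FALSE], targetGrid)
}

#' Relative number of misclassified pixels (RNMP)
#'
#' The segmentation error of a reconstruction against a phantom: the
#' reconstruction is resampled onto the phantom's grid by
#' nearest-neighbour interpolation, the pixels whose grey value differs
#' from the phantom are counted, and the count is divided by the number of
#' phantom pixels with nonzero grey value (the object size). Both images
#' must already be segmented; pass the reconstruction through
#' \code{\link{segmentImage}} first if needed.
#'
#' @param phantom ground-truth \linkS4class{TomoImage} (segmented values).
#' @param reconstruction segmented \linkS4class{TomoImage}, any grid with
#'   the same field of view.
#' @param model optional \linkS4class{GreyLevelModel}; when supplied, both
#'   inputs are checked to contain only model grey values.
#' @return Nonnegative number (0 = perfect, 1 = as bad as an all-background
#'   reconstruction of a binary phantom).
#' @export
#' @examples
#' ph <- diskWithHoles(32, diskRadius = 10, oversample = 1)
#' rnmp(ph, ph)   # 0
rnmp <- function(phantom, reconstruction, model = NULL) {
  if (!is.null(model)) {
    ok <- function(v) all(v %in% model@greyValues)
    if (!ok(phantom@values) || !ok(reconstruction@values))
      stop("inputs must contain only model grey values; segment first")
  }
  rec <- resampleNearest(reconstruction, phantom@grid)
  nObject <- sum(phantom@values != 0)
  if (nObject == 0L)
    stop("undefined RNMP: phantom has no nonzero pixels")
  sum(rec@values != phantom@values) / nObject
}

#' Classification error image
#'
#' Compares a segmented reconstruction with a phantom pixel by pixel
#' (after nearest-neighbour resampling onto the phantom grid) and returns
#' a 4-category map: 0 correctly classified background, 1 correctly
#' classified object, 2 misclassified background (phantom background,
#' wrong in the reconstruction), 3 misclassified object (phantom object,
#' wrong grey value in the reconstruction). "Object" means any nonzero
#' grey value. The conventional display palette is black, yellow, red,
#' green for categories 0-3.
#'
#' @inheritParams rnmp
#' @return A \linkS4class{TomoImage} with integer category codes 0-3.
#' @export
errorImage <- function(phantom, reconstruction) {
  rec <- resampleNearest(reconstruction, phantom@grid)
  obj <- phantom@values != 0
  wrong <- rec@values != phantom@values
  code <- matrix(0, nrow(obj), ncol(obj))
  code[obj & !wrong] <- 1
  code[!obj & wrong] <- 2
  code[obj & wrong] <- 3
  tomoImage(code, phantom@grid)
}
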