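## Phantom generators.
##
## All generators share one pixelation rule: a pixel belongs to a shape iff
## its centre is inside the shape, so phantoms are exactly discrete (no
## anti-aliasing) and the grey-level prior holds exactly. Shape parameters
## are given in base-grid pixel units; the `oversample` factor (default 2)
## renders the phantom on a finer grid with the same physical field of
## view, so projections of the phantom are less affected by pixelation
## than the (coarser) reconstruction grid.

## pixel-centre coordinates of the rendered grid, in base-grid units,
## origin at the lower-left corner of the field of view
.phantomFrame <- function(size, oversample, pixelSize) {
  n <- as.integer(round(size * oversample))
  x <- (seq_len(n) - 0.5) / oversample         # column -> x (right)
  y <- (n - seq_len(n) + 0.5) / oversample     # row -> y (up)
  list(n = n, x = x, y = y,
       grid = imageGrid(n, pixelSize / oversample))
}

## squared distance of every pixel centre to (cx, cy)
.dist2 <- function(frame, cx, cy) {
  outer((frame$y - cy)^2, (frame$x - cx)^2, `+`)
}

#' Disk phantom with randomly placed circular holes
#'
#' A binary disk (value \code{greyValue}, background 0) centred in the
#' field of view, with \code{nHoles} non-overlapping circular holes placed
#' uniformly at random, each lying entirely inside the disk. Hole centres
#' are drawn by rejection sampling; if a feasible packing is not found in
#' 10000 attempts the generator fails with a packing error.
#'
#' @param size side of the base grid, in pixels; all radii are in the same
#'   units.
#' @param diskRadius disk radius (default 0.4 * size).
#' @param holeRadius hole radius.
#' @param nHoles number of holes (0 for a plain disk).
#' @param seed integer seed making hole placement reproducible.
#' @param greyValue foreground attenuation value (default 1).
#' @param oversample rendering factor: the image is rendered on a grid
#'   \code{oversample} times finer with the same physical extent.
#' @param pixelSize physical size of one base-grid pixel.
#' @return A binary \linkS4class{TomoImage}.
#' @export
#' @examples
#' ph <- diskWithHoles(64, holeRadius = 5, nHoles = 3, seed = 11)
diskWithHoles <- function(size, diskRadius = 0.4 * size, holeRadius = 0,
                          nHoles = 0L, seed = 1L, greyValue = 1,
                          oversample = 2L, pixelSize = 1) {
  if (diskRadius <= 0 || (nHoles > 0L && holeRadius <= 0))
    stop("radii must be positive")
  if (diskRadius > size / 2)
    stop("disk does not fit inside the grid")
  fr <- .phantomFrame(size, oversample, pixelSize)
  cx <- size / 2; cy <- size / 2
  v <- matrix(0, fr$n, fr$n)
  v[.dist2(fr, cx, cy) <= diskRadius^2] <- greyValue
  if (nHoles > 0L) {
    if (holeRadius >= diskRadius)
      stop("packing failure: hole radius must be below the disk radius")
    centres <- matrix(numeric(), 0L, 2L)
    maxR <- diskRadius - holeRadius      # hole must not cross the edge
    set.seed(as.integer(seed))
    attempts <- 0L
    while (nrow(centres) < nHoles) {
      attempts <- attempts + 1L
      if (attempts > 10000L)
        stop("packing failure: could not place ", nHoles,
             " holes of radius ", holeRadius, " after 10000 attempts")
      cand <- stats::runif(2, -maxR, maxR)
      if (sum(cand^2) > maxR^2) next
      if (nrow(centres) > 0L &&
          any((centres[, 1L] - cand[1L])^2 + (centres[, 2L] - cand[2L])^2 <
              (2 * holeRadius)^2)) next
      centres <- rbind(centres, cand)
    }
    for (i in seq_len(nrow(centres)))
      v[.dist2(fr, cx + centres[i, 1L], cy + centres[i, 2L]) <=
          holeRadius^2] <- 0
  }
  tomoImage(v, fr$grid)
}

#' Siemens star phantom
#'
#' A binary star of alternating angular sectors between an inner and an
#' outer radius: \code{nSpokes} sectors of equal angular width, every
#' other one set to \code{greyValue}. With an even spoke count the pattern
#' has 2-fold rotational symmetry. Resolution targets of this kind probe
#' how finely an algorithm separates converging wedges.
#'
#' @param size base grid side in pixels.
#' @param nSpokes even number of sectors.
#' @param innerRadius,outerRadius sector radii, 0 <= inner < outer.
#' @inheritParams diskWithHoles
#' @return A binary \linkS4class{TomoImage}.
#' @export
#' @examples
#' siemensStar(64, nSpokes = 8, innerRadius = 4, outerRadius = 26)
siemensStar <- function(size, nSpokes, innerRadius, outerRadius,
                        greyValue = 1, oversample = 2L, pixelSize = 1) {
  if (nSpokes %% 2L != 0L || nSpokes < 2L)
    stop("nSpokes must be a positive even number")
  if (innerRadius < 0 || outerRadius <= innerRadius)
    stop("need 0 <= innerRadius < outerRadius")
  if (outerRadius > size / 2)
    stop("star does not fit inside the grid")
  fr <- .phantomFrame(size, oversample, pixelSize)
  cx <- size / 2; cy <- size / 2
  X <- outer(rep(1, fr$n), fr$x - cx)
  Y <- outer(fr$y - cy, rep(1, fr$n))
  r2 <- X^2 + Y^2
  phi <- atan2(Y, X) %% (2 * pi)
  sector <- floor(phi / (2 * pi / nSpokes))
  v <- matrix(0, fr$n, fr$n)
  keep <- (sector %% 2 == 0) & r2 >= innerRadius^2 & r2 <= outerRadius^2
  v[keep] <- greyValue
  tomoImage(v, fr$grid)
}

#' Multi-grey phantom composed of ellipses
#'
#' Paints a list of (possibly rotated, possibly intersecting) ellipses
#' onto a zero background; later ellipses overwrite earlier ones where
#' they overlap. Each ellipse is
#' \code{list(center = c(x, y), semiAxes = c(a, b), rotation = degrees,
#' value = grey)}, all lengths in base-grid pixels with the origin at the
#' lower-left corner of the field of view.
#'
#' @param size base grid side in pixels.
#' @param ellipses list of ellipse descriptions; the default is a
#'   three-grey composite (background 0 plus two grey levels) of
#'   intersecting ellipses.
#' @inheritParams diskWithHoles
#' @return A \linkS4class{TomoImage} whose distinct values are a subset of
#'   0 and the listed grey values.
#' @export
#' @examples
#' ph <- ellipsesPhantom(64)
#' sort(unique(as.vector(values(ph))))   # 0, 0.5, 1
ellipsesPhantom <- function(size, ellipses = NULL, oversample = 2L,
                            pixelSize = 1) {
  if (is.null(ellipses))
    ellipses <- list(
      list(center = c(0.50, 0.48) * size, semiAxes = c(0.34, 0.26) * size,
           rotation = 20, value = 0.5),
      list(center = c(0.40, 0.55) * size, semiAxes = c(0.16, 0.10) * size,
           rotation = -30, value = 1),
      list(center = c(0.62, 0.40) * size, semiAxes = c(0.12, 0.18) * size,
           rotation = 65, value = 1),
      list(center = c(0.55, 0.60) * size, semiAxes = c(0.07, 0.05) * size,
           rotation = 0, value = 0.5))
  fr <- .phantomFrame(size, oversample, pixelSize)
  v <- matrix(0, fr$n, fr$n)
  X <- outer(rep(1, fr$n), fr$x)
  Y <- outer(fr$y, rep(1, fr$n))
  for (e in ellipses) {
    a <- e$semiAxes[1L]; b <- e$semiAxes[2L]
    if (any(e$center + max(a, b) > size) || any(e$center - max(a, b) < 0))
      stop("ellipse extends outside the grid")
    th <- e$rotation * pi / 180
    dx <- X - e$center[1L]; dy <- Y - e$center[2L]
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    v[(xr / a)^2 + (yr / b)^2 <= 1] <- e$value
  }
  tomoImage(v, fr$grid)
}

#' Structured binary phantom from geometric primitives
#'
#' Composes rectangles, disks, annuli and randomly placed hole batches
#' into a binary object by sequential add/subtract operations. This is a
#' parametric stand-in, synthetic by construction, for machined binary
#' objects with fine structured features (slots, bores, thin walls); the
#' default composition is a disk carrying an annular wall, radial slots
#' and a seeded batch of small holes.
#'
#' Primitive forms (lengths in base-grid pixels, origin lower-left):
#' \itemize{
#'   \item \code{list(kind = "rect", xlim =, ylim =, op =)}
#'   \item \code{list(kind = "disk", center =, radius =, op =)}
#'   \item \code{list(kind = "annulus", center =, inner =, outer =, op =)}
#'   \item \code{list(kind = "random_disks", n =, radius =, region_radius =,
#'     op =)} — n disks placed uniformly in a central region using the
#'     generator seed.
#' }
#' \code{op} is \code{"add"} (default) or \code{"subtract"}.
#'
#' @param size base grid side in pixels.
#' @param primitives list of primitives; \code{NULL} selects the default
#'   composition.
#' @inheritParams diskWithHoles
#' @return A binary \linkS4class{TomoImage}.
#' @export
#' @examples
#' ph <- structuredBinary(64, seed = 2)
structuredBinary <- function(size, primitives = NULL, seed = 1L,
                             greyValue = 1, oversample = 2L,
                             pixelSize = 1) {
  if (is.null(primitives))
    primitives <- list(
      list(kind = "disk", center = c(0.5, 0.5) * size,
           radius = 0.42 * size, op = "add"),
      list(kind = "annulus", center = c(0.5, 0.5) * size,
           inner = 0.30 * size, outer = 0.34 * size, op = "subtract"),
      list(kind = "rect", xlim = c(0.47, 0.53) * size,
           ylim = c(0.12, 0.88) * size, op = "subtract"),
      list(kind = "rect", xlim = c(0.12, 0.88) * size,
           ylim = c(0.47, 0.53) * size, op = "subtract"),
      list(kind = "random_disks", n = 6L, radius = 0.03 * size,
           region_radius = 0.24 * size, op = "subtract"))
  if (length(primitives) == 0L)
    stop("empty composition")
  fr <- .phantomFrame(size, oversample, pixelSize)
  mask <- matrix(FALSE, fr$n, fr$n)
  set.seed(as.integer(seed))
  for (pr in primitives) {
    op <- if (is.null(pr$op)) "add" else pr$op
    m <- switch(pr$kind,
      rect = outer(fr$y >= pr$ylim[1L] & fr$y <= pr$ylim[2L],
                   fr$x >= pr$xlim[1L] & fr$x <= pr$xlim[2L], `&`),
      disk = .dist2(fr, pr$center[1L], pr$center[2L]) <= pr$radius^2,
      annulus = {
        d2 <- .dist2(fr, pr$center[1L], pr$center[2L])
        d2 >= pr$inner^2 & d2 <= pr$outer^2
      },
      random_disks = {
        m2 <- matrix(FALSE, fr$n, fr$n)
        for (i in seq_len(pr$n)) {
          repeat {
            cand <- stats::runif(2, -pr$region_radius, pr$region_radius)
            if (sum(cand^2) <= pr$region_radius^2) break
          }
          m2 <- m2 | (.dist2(fr, size / 2 + cand[1L], size / 2 + cand[2L])
                      <= pr$radius^2)
        }
        m2
      },
      stop("unknown primitive kind: ", pr$kind))
    mask <- if (identical(op, "subtract")) mask & !m else mask | m
  }
  tomoImage(matrix(as.numeric(mask) * greyValue, fr$n, fr$n), fr$grid)
}

#' Batch of disk-with-holes phantoms over a hole-radius sweep
#'
#' Generates \code{nPerRadius} independent phantoms (distinct seeds
#' derived from \code{baseSeed}) for each requested hole radius, as used
#' by the hole-size and missing-wedge sweep protocols.
#'
#' @param size,diskRadius,nHoles,greyValue,oversample,pixelSize passed to
#'   \code{\link{diskWithHoles}}.
#' @param holeRadii numeric vector of hole radii.
#' @param nPerRadius phantoms per radius (>= 3 in the sweep protocol).
#' @param baseSeed integer; phantom (r, i) uses seed
#'   \code{baseSeed + 1000 * r_index + i}.
#' @return Named list (one entry per radius) of lists of
#'   \linkS4class{TomoImage}s.
#' @export
phantomBatch <- function(size, diskRadius = 0.4 * size, holeRadii,
                         nHoles = 3L, nPerRadius = 3L, baseSeed = 1L,
                         greyValue = 1, oversample = 2L, pixelSize = 1) {
  out <- lapply(seq_along(holeRadii), function(ri) {
    lapply(seq_len(nPerRadius), function(i)
      diskWithHoles(size, diskRadius, holeRadii[ri], nHoles,
                    seed = baseSeed + 1000L * ri + i,
                    greyValue = greyValue, oversample = oversample,
                    pixelSize = pixelSize))
  })
  names(out) <- as.character(holeRadii)
  out
}
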