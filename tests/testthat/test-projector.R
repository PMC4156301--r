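test_that("simple analytic projections are exact", {
  # zero image -> zero sinogram
  g <- parallelGeom(4, 16)
  expect_true(all(values(forwardProject(tomoImage(0, imageGrid(16)), g)) == 0))

  # one pixel of value v, ray through its centre at 0 degrees: v * pixelSize
  img1 <- tomoImage(matrix(3, 1, 1), imageGrid(1, pixelSize = 2))
  g1 <- makeEquiangularGeometry("parallel", nAngles = 1, angularRange = 180,
                                nDetectors = 1, detectorPixelSize = 2)
  expect_equal(as.vector(values(forwardProject(img1, g1))), 6)

  # uniform disk: central parallel ray is about one diameter long
  dsk <- diskWithHoles(32, diskRadius = 12, oversample = 1)
  gd <- parallelGeom(1, 33)
  central <- values(forwardProject(dsk, gd))[1, 17]
  oracle <- oracleLineIntegral(dsk, list(point = c(0, 0),
                                         direction = c(0, 1)),
                               step = 1 / 200)
  expect_lt(abs(central - 24) / 24, 0.05)
  expect_lt(abs(central - oracle) / oracle, 0.005)
})

test_that("Joseph projections match the line-sampling oracle on smooth images", {
  img <- smoothRandomImage(16)

  # parallel beam, detector matched to the grid: every ray agrees
  geomP <- parallelGeom(8, 16)
  p <- as.vector(t(values(forwardProject(img, geomP))))
  orc <- vapply(geometryRays(geomP),
                function(r) oracleLineIntegral(img, r, step = 1 / 50), 0)
  expect_lt(max(abs(p - orc) / orc), 0.01)

  # fan beam: rays through the inscribed circle agree; rays grazing the
  # grid edge tangentially are excluded, since linear interpolation and
  # nearest-pixel lookup treat the outer half-pixel band differently
  geomF <- fanGeom(6, fov = 16)
  rays <- geometryRays(geomF)
  pf <- as.vector(t(values(forwardProject(img, geomF))))
  orcF <- vapply(rays, function(r) oracleLineIntegral(img, r, step = 1 / 50),
                 0)
  impact <- vapply(rays, function(r) {
    d <- r$direction / sqrt(sum(r$direction^2))
    abs(r$point[1] * d[2] - r$point[2] * d[1])
  }, 0)
  sel <- impact < 0.8 * 8
  expect_gt(sum(sel), 300)
  expect_lt(max(abs(pf - orcF)[sel] / orcF[sel]), 0.02)
})

test_that("operator is linear and exactly adjoint", {
  grid <- imageGrid(12)
  op <- tomoOperator(grid, parallelGeom(7, 14))
  set.seed(3)
  for (i in 1:20) {
    x <- tomoImage(matrix(rnorm(144), 12, 12), grid)
    y <- tomoImage(matrix(rnorm(144), 12, 12), grid)
    a <- rnorm(1); b <- rnorm(1)
    lin <- forwardProject(tomoImage(a * values(x) + b * values(y), grid), op)
    expect_equal(values(lin),
                 a * values(forwardProject(x, op)) +
                 b * values(forwardProject(y, op)), tolerance = 1e-12)
    s <- sinogram(matrix(rnorm(7 * 14), 7, 14), geometryOf(op))
    lhs <- sum(values(forwardProject(x, op)) * values(s))
    rhs <- sum(values(x) * values(backProject(s, op)))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  }
})

test_that("back projection of a one-hot sinogram is the matching W row", {
  grid <- imageGrid(8)
  geom <- parallelGeom(5, 8)
  op <- tomoOperator(grid, geom)
  W <- denseSystemMatrix(op)
  rayIdx <- 17L  # angle 3, bin 1 in angle-major order
  oneHot <- matrix(0, 5, 8)
  oneHot[3, 1] <- 1
  bp <- backProject(sinogram(oneHot, geom), op)
  expect_equal(as.vector(values(bp)), W[rayIdx, ])
  expect_error(denseSystemMatrix(tomoOperator(imageGrid(32),
                                              parallelGeom(4, 32))),
               "only available")
})

test_that("row and column sums equal one-vector projections", {
  grid <- imageGrid(10)
  geom <- fanGeom(5, fov = 10)
  op <- tomoOperator(grid, geom)
  ones <- tomoImage(1, grid)
  expect_equal(raySums(op), as.vector(t(values(forwardProject(ones, op)))))
  onesSino <- sinogram(matrix(1, 5, 96), geom)
  expect_equal(pixelSums(op), as.vector(values(backProject(onesSino, op))))

  # corner pixels are crossed by less total weight than the centre
  ps <- matrix(pixelSums(tomoOperator(imageGrid(9), parallelGeom(12, 13))),
               9, 9)
  expect_lt(ps[1, 1], ps[5, 5])
})

test_that("rays missing the grid contribute zero and invert to zero", {
  # detector much wider than the grid: outer rays miss entirely
  g <- makeEquiangularGeometry("parallel", nAngles = 2, angularRange = 180,
                               nDetectors = 41, detectorPixelSize = 1)
  op <- tomoOperator(imageGrid(8), g)
  rs <- raySums(op)
  expect_true(any(rs == 0))
  expect_true(all(safeReciprocal(rs)[rs == 0] == 0))
  expect_equal(safeReciprocal(c(2, 0, 4)), c(0.5, 0, 0.25))

  ray <- list(point = c(0, 100), direction = c(1, 0))
  expect_equal(oracleLineIntegral(tomoImage(1, imageGrid(8)), ray, 0.01), 0)
})

test_that("oracle integrates a constant image to the crossing length", {
  img <- tomoImage(1, imageGrid(16, pixelSize = 0.5))  # width 8
  ray <- list(point = c(0, 0), direction = c(1, 0))
  expect_equal(oracleLineIntegral(img, ray, step = 0.001), 8,
               tolerance = 1e-3)
  expect_error(oracleLineIntegral(img, ray, step = 0), "positive")
})

test_that("rotational symmetry and pixel-size scaling hold", {
  # radially symmetric smooth blob: every angle sees the same profile
  n <- 32
  cent <- (seq_len(n) - (n + 1) / 2)
  blob <- tomoImage(exp(-outer(cent^2, cent^2, `+`) / (2 * 6^2)),
                    imageGrid(n))
  p <- values(forwardProject(blob, parallelGeom(12, n)))
  ref <- p[1, ]
  for (a in 2:12)
    expect_lt(max(abs(p[a, ] - ref)) / max(ref), 0.02)

  # doubling pixel size doubles the integrals (same pixel values)
  img <- smoothRandomImage(12, seed = 9)
  big <- tomoImage(values(img), imageGrid(12, pixelSize = 2))
  g1 <- parallelGeom(4, 12)
  g2 <- makeEquiangularGeometry("parallel", nAngles = 4, angularRange = 180,
                                nDetectors = 12, detectorPixelSize = 2)
  expect_equal(values(forwardProject(big, g2)),
               2 * values(forwardProject(img, g1)), tolerance = 1e-10)
})

test_that("inconsistent inputs are rejected", {
  op <- tomoOperator(imageGrid(8), parallelGeom(4, 8))
  expect_error(forwardProject(tomoImage(0, imageGrid(9)), op), "shape")
  expect_warning(tomoOperator(imageGrid(32), parallelGeom(4, 8)),
                 "does not cover")
})
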