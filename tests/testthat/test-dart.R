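test_that("segmentation maps threshold intervals to grey values", {
  m3 <- greyLevelModel(c(0, 0.5, 1), thresholds = c(0.25, 0.75))
  seg <- function(v, m) vapply(v, function(x) values(segmentImage(
    tomoImage(matrix(x, 1, 1)), m))[1, 1], 0)
  expect_equal(seg(c(0, 0.5, 1), m3), c(0, 0.5, 1))     # exact grey values
  expect_equal(seg(0.3, m3), 0.5)                        # interval lookup
  expect_equal(seg(0.7, binaryModel), 1)
  # ties at a threshold go to the lower class; extremes clamp
  expect_equal(seg(c(0.25, 0.75, -5, 5), m3), c(0, 0.5, 0, 1))
})

test_that("boundary pixels are exactly those with a differing neighbour", {
  expect_length(boundaryPixels(tomoImage(matrix(1, 6, 6))), 0)

  # single foreground pixel: itself plus its 8 neighbours
  v <- matrix(0, 5, 5); v[3, 3] <- 1
  b8 <- boundaryPixels(tomoImage(v), 8)
  expect_length(b8, 9)
  expect_true(all(b8 %in% which(matrix(abs(row(v) - 3) <= 1 &
                                       abs(col(v) - 3) <= 1, 5, 5))))

  # vertical half-plane edge, 4-connectivity: the two adjacent columns
  h <- matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4)
  b4 <- boundaryPixels(tomoImage(h), 4)
  expect_setequal(b4, which(col(h) %in% c(2, 3)))
})

test_that("the partition obeys p = 0 / p = 1 and binomial statistics", {
  seg <- tomoImage(matrix(1, 100, 100))
  set.seed(1)
  p0 <- makePartition(seg, 0)
  expect_length(p0@nonFixed, 0)        # constant image: no boundary
  p1 <- makePartition(seg, 1)
  expect_length(p1@fixed, 0)
  expect_length(p1@nonFixed, 10000L)

  # with an edge, p = 0 gives exactly the boundary
  v <- matrix(0, 20, 20); v[, 11:20] <- 1
  sp <- makePartition(tomoImage(v), 0)
  expect_setequal(sp@nonFixed, boundaryPixels(tomoImage(v), 8))

  # |U| ~ Binomial(10000, 0.15): each draw within 4 sigma of the mean
  sizes <- vapply(1:5, function(s) {
    set.seed(s)
    length(makePartition(seg, 0.15)@nonFixed)
  }, 0L)
  sigma <- sqrt(10000 * 0.15 * 0.85)
  expect_true(all(abs(sizes - 1500) < 4 * sigma))
})

test_that("neighbourhood-mean smoothing matches hand computation", {
  img <- smoothRandomImage(9, seed = 3)
  expect_identical(values(smoothImage(img, 0)), values(img))
  flat <- tomoImage(matrix(2.5, 7, 7))
  expect_equal(values(smoothImage(flat, 0.7)), values(flat))

  v <- matrix(0, 5, 5); v[3, 3] <- 1
  sm <- values(smoothImage(tomoImage(v), 0.5))
  expect_equal(sm[3, 3], 0.5)
  expect_equal(sm[2, 2], 0.5 * 1 / 8)
  expect_equal(sm[2, 3], 0.5 * 1 / 8)
  expect_equal(sm[1, 1], 0)  # beyond the 3x3 neighbourhood
})

test_that("termination rules fire on the documented patterns", {
  tr <- function(d) data.frame(iteration = seq_along(d), proj_distance = d,
                               modified_pixels = 0, n_pixels = 100)
  expect_true(checkTermination(tr(rep(1, 10)),
                               terminationSpec("max_iterations", 10)))
  expect_false(checkTermination(tr(rep(1, 9)),
                                terminationSpec("max_iterations", 10)))

  spec <- terminationSpec("projection_distance_delta", 1e-3, 3)
  d <- cumsum(c(5, -1, -1e-4, -1e-4, -1e-4))
  expect_true(checkTermination(tr(d), spec))
  dBroken <- cumsum(c(5, -1e-4, -5, -1e-4))
  expect_false(checkTermination(tr(dBroken), spec))

  mp <- data.frame(iteration = 1:4, proj_distance = 1,
                   modified_pixels = c(50, 2, 1, 0), n_pixels = 1000)
  expect_true(checkTermination(mp, terminationSpec("modified_pixels",
                                                   0.01, 3)))
  expect_error(checkTermination(mp[0, ], terminationSpec("max_iterations", 1)),
               "empty")
})

test_that("DART is deterministic and conserves the fixed interior", {
  ph <- diskWithHoles(32, diskRadius = 12, holeRadius = 3, nHoles = 2,
                      seed = 8, oversample = 1)
  geom <- fanGeom(12, fov = 32)
  p <- forwardProject(ph, geom)
  cfg <- dartConfig(initialArmIters = 40, innerArmIters = 5, rngSeed = 21,
                    termination = terminationSpec("max_iterations", 6))
  a <- dartReconstruct(p, imageGridOf(ph), binaryModel, cfg)
  b <- dartReconstruct(p, imageGridOf(ph), binaryModel, cfg)
  expect_identical(values(a$continuous), values(b$continuous))
  expect_identical(a$trace$proj_distance, b$trace$proj_distance)
  expect_identical(a$trace$modified_pixels, b$trace$modified_pixels)

  # segmented output only contains model grey values
  expect_true(all(values(a$segmented) %in% greyValues(binaryModel)))

  # p = 0 and no smoothing: pixels far from any boundary stay at their
  # first segmented value through the whole run
  cfg0 <- dartConfig(initialArmIters = 60, innerArmIters = 4,
                     fixProbability = 0, smoothingBlend = 0, rngSeed = 1,
                     termination = terminationSpec("max_iterations", 5))
  init <- sirtRun(tomoImage(0, imageGridOf(ph)), p, 60)
  seg0 <- segmentImage(init, binaryModel)
  b0 <- boundaryPixels(seg0, 8)
  # pixels at Chebyshev distance > 5 from every initial boundary pixel
  br <- (b0 - 1) %% 32 + 1; bc <- (b0 - 1) %/% 32 + 1
  far <- which(vapply(seq_len(32 * 32), function(i) {
    r <- (i - 1) %% 32 + 1; cc <- (i - 1) %/% 32 + 1
    min(pmax(abs(br - r), abs(bc - cc))) > 5
  }, TRUE))
  out <- dartReconstruct(p, imageGridOf(ph), binaryModel, cfg0,
                         initial = init)
  expect_identical(values(out$continuous)[far], values(seg0)[far])
})

test_that("a zero-work budget returns the initial reconstruction", {
  ph <- diskWithHoles(16, diskRadius = 6, oversample = 1)
  geom <- parallelGeom(8, 16)
  p <- forwardProject(ph, geom)
  res <- dartReconstruct(p, imageGridOf(ph), binaryModel, dartConfig(),
                         initial = ph, budget = list(pixelWork = 0))
  expect_identical(values(res$continuous), values(ph))
  expect_identical(nrow(res$trace), 0L)
})

test_that("DART recovers a binary object exactly from many projections", {
  ph <- diskWithHoles(32, diskRadius = 12, holeRadius = 4, nHoles = 2,
                      seed = 4, oversample = 1)
  geom <- parallelGeom(30, 32)
  p <- forwardProject(ph, geom)
  cfg <- dartConfig(initialArmIters = 100, innerArmIters = 10, rngSeed = 2,
                    termination = terminationSpec("max_iterations", 30))
  res <- dartReconstruct(p, imageGridOf(ph), binaryModel, cfg,
                         groundTruth = ph)
  expect_identical(rnmp(ph, res$segmented, binaryModel), 0)
  expect_identical(utils::tail(res$trace$rnmp, 1), 0)
})
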