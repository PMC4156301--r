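test_that("RNMP counts mismatches over the phantom object size", {
  ph <- diskWithHoles(32, diskRadius = 11.3, oversample = 1)
  expect_identical(rnmp(ph, ph), 0)

  # construct exactly 400 object pixels and flip exactly 20 of them
  v <- matrix(0, 32, 32); v[9:28, 9:28] <- 1
  phantom <- tomoImage(v)
  rec <- v; rec[9:10, 9:18] <- 0
  expect_identical(rnmp(phantom, tomoImage(rec)), 20 / 400)

  # all-background reconstruction of a binary phantom scores 1
  expect_identical(rnmp(phantom, tomoImage(0, imageGridOf(phantom))), 1)
  expect_error(rnmp(tomoImage(0, imageGrid(8)), tomoImage(0, imageGrid(8))),
               "no nonzero")
  expect_error(rnmp(phantom, tomoImage(matrix(0.4, 32, 32)), binaryModel),
               "segment first")
})

test_that("nearest-neighbour resampling replicates and preserves labels", {
  v <- matrix(c(1, 3, 2, 4), 2, 2)
  img <- tomoImage(v, imageGrid(2, 2))
  same <- resampleNearest(img, imageGrid(2, 2))
  expect_identical(values(same), v)
  fine <- resampleNearest(img, imageGrid(4, 1))
  expect_identical(values(fine),
                   v[rep(1:2, each = 2), rep(1:2, each = 2)])
  expect_setequal(unique(as.vector(values(fine))), c(1, 2, 3, 4))
  # downsampling creates no new values either
  coarse <- resampleNearest(fine, imageGrid(2, 2))
  expect_true(all(values(coarse) %in% v))
  expect_error(resampleNearest(img, imageGrid(5, 3)), "fields of view")
})

test_that("error images give the four classification categories", {
  v <- matrix(0, 8, 8); v[3:6, 3:6] <- 1
  ph <- tomoImage(v)
  same <- errorImage(ph, ph)
  expect_setequal(unique(as.vector(values(same))), c(0, 1))

  rec <- v; rec[3, 3] <- 0; rec[1, 1] <- 1
  em <- values(errorImage(ph, tomoImage(rec)))
  expect_identical(em[3, 3], 3)   # misclassified object
  expect_identical(em[1, 1], 2)   # misclassified background
  expect_identical(sum(table(em)), 64L)
})

test_that("SSIRT reconstructs well from many angles and is deterministic", {
  ph <- diskWithHoles(64, diskRadius = 24, holeRadius = 5, nHoles = 2,
                      seed = 2, oversample = 1)
  geom <- parallelGeom(60, 64)
  p <- forwardProject(ph, geom)
  res <- ssirtReconstruct(p, imageGrid(64), binaryModel, nIters = 80)
  expect_lt(rnmp(ph, res$segmented), 0.02)
  res2 <- ssirtReconstruct(p, imageGrid(64), binaryModel, nIters = 80)
  expect_identical(values(res$continuous), values(res2$continuous))
  expect_identical(res$trace$proj_distance, res2$trace$proj_distance)

  # zero budget: segmentation of the zero image, RNMP 1 on binary phantoms
  none <- ssirtReconstruct(p, imageGrid(64), binaryModel,
                           budget = list(pixelWork = 0))
  expect_identical(rnmp(ph, none$segmented), 1)
})

test_that("the benchmark runner sweeps, aggregates and reproduces", {
  ph <- diskWithHoles(32, diskRadius = 12, holeRadius = 3, nHoles = 2,
                      seed = 5, oversample = 2)
  spec <- list(
    phantoms = list(disk = ph),
    reconGrid = imageGrid(32),
    model = binaryModel,
    beam = "parallel", nAnglesList = 12L, angularRange = 180,
    nDetectors = 32L, detectorPixelSize = 1,
    algorithms = c("ssirt", "dart"),
    config = dartConfig(initialArmIters = 20, innerArmIters = 4,
                        termination = terminationSpec("max_iterations", 5)),
    budget = list(pixelWork = 300 * 32^2),
    seeds = 1L)
  tab <- runBenchmark(spec)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$algorithm, c("ssirt", "dart"))
  expect_true(all(tab$rnmp >= 0))
  tab2 <- runBenchmark(spec)
  expect_identical(tab$rnmp, tab2$rnmp)

  agg <- aggregateRnmp(data.frame(algorithm = "dart", n_angles = 10,
                                  missing_wedge = 0, photon_count = NA,
                                  rnmp = c(0.1, 0.2, 0.3)))
  expect_equal(agg$mean_rnmp, 0.2)
  expect_equal(agg$se_rnmp, 0.0577, tolerance = 1e-3)
  expect_identical(agg$n, 3L)
})
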