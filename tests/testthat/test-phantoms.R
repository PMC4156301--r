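test_that("disk phantom has the right area and hole placement", {
  ph <- diskWithHoles(64, diskRadius = 20, oversample = 1)
  expect_lt(abs(sum(values(ph)) - pi * 20^2) / (pi * 20^2), 0.02)

  # oversampled rendering keeps the field of view, scales the pixel count
  ph2 <- diskWithHoles(64, diskRadius = 20, oversample = 2)
  expect_identical(nCols(ph2), 128L)
  expect_equal(nCols(ph2) * pixelSize(ph2), 64)
  expect_lt(abs(sum(values(ph2)) / 4 - pi * 20^2) / (pi * 20^2), 0.02)

  # holes stay inside the disk: removing them restores a plain disk
  phh <- diskWithHoles(64, diskRadius = 20, holeRadius = 4, nHoles = 3,
                       seed = 9, oversample = 1)
  plain <- values(diskWithHoles(64, diskRadius = 20, oversample = 1))
  expect_true(all(plain[values(phh) != plain] == 1))  # holes only in disk
  expect_true(all(values(phh) %in% c(0, 1)))

  expect_identical(values(diskWithHoles(64, 20, 4, 3, seed = 9)),
                   values(diskWithHoles(64, 20, 4, 3, seed = 9)))
  expect_error(diskWithHoles(64, diskRadius = 20, holeRadius = 12,
                             nHoles = 5, seed = 1),
               "packing failure")
})

test_that("Siemens star alternates sectors with rotational symmetry", {
  st <- siemensStar(64, nSpokes = 4, innerRadius = 4, outerRadius = 28,
                    oversample = 1)
  v <- values(st)
  expect_true(all(v %in% c(0, 1)))
  # one sector period for 4 spokes is 180 deg; half period is a quarter
  # turn, which swaps foreground and background rings; a full period (two
  # quarter turns) maps foreground to foreground
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_lt(mean(rot90(rot90(v)) != v), 0.01)

  # analytic membership: mid-sector, mid-radius pixel is foreground
  # first sector spans [0, 90) deg; take 45 deg at radius 16
  r <- 16 / sqrt(2)
  colIdx <- round(32 + r); rowIdx <- round(32 - r) # centre at (32, 32)
  expect_identical(v[rowIdx, colIdx], 1)
  expect_error(siemensStar(64, nSpokes = 3, innerRadius = 2,
                           outerRadius = 20), "even")
  expect_error(siemensStar(64, nSpokes = 4, innerRadius = 20,
                           outerRadius = 10), "innerRadius")
})

test_that("ellipse composites paint the declared grey values", {
  e1 <- list(center = c(32, 32), semiAxes = c(12, 8), rotation = 0,
             value = 1)
  ph <- ellipsesPhantom(64, list(e1), oversample = 1)
  expect_lt(abs(sum(values(ph)) - pi * 12 * 8) / (pi * 12 * 8), 0.02)

  expect_true(all(values(ellipsesPhantom(64, list(), oversample = 1)) == 0))

  two <- list(
    list(center = c(20, 20), semiAxes = c(6, 4), rotation = 30, value = 0.5),
    list(center = c(44, 44), semiAxes = c(5, 7), rotation = 0, value = 1))
  expect_identical(sort(unique(as.vector(values(
    ellipsesPhantom(64, two, oversample = 1))))), c(0, 0.5, 1))

  # default composite has exactly three grey levels
  expect_identical(sort(unique(as.vector(values(ellipsesPhantom(64))))),
                   c(0, 0.5, 1))
  bad <- list(list(center = c(2, 2), semiAxes = c(6, 4), rotation = 0,
                   value = 1))
  expect_error(ellipsesPhantom(64, bad), "outside the grid")
})

test_that("structured binary composition is exact and reproducible", {
  rect <- list(list(kind = "rect", xlim = c(10, 20), ylim = c(5, 30)))
  ph <- structuredBinary(64, rect, oversample = 1)
  # centre-inclusion: 10 columns x 25 rows of unit pixels
  expect_identical(sum(values(ph)), 10 * 25)

  ann <- list(list(kind = "disk", center = c(32, 32), radius = 20),
              list(kind = "disk", center = c(32, 32), radius = 10,
                   op = "subtract"))
  area <- sum(values(structuredBinary(64, ann, oversample = 1)))
  expect_lt(abs(area - pi * (20^2 - 10^2)) / (pi * 300), 0.02)

  expect_identical(values(structuredBinary(64, seed = 5)),
                   values(structuredBinary(64, seed = 5)))
  expect_false(identical(values(structuredBinary(64, seed = 5)),
                         values(structuredBinary(64, seed = 6))))
  expect_error(structuredBinary(64, list()), "empty composition")
})

test_that("phantom batches give independent phantoms per hole radius", {
  batch <- phantomBatch(32, diskRadius = 12, holeRadii = c(2, 3),
                        nHoles = 2, nPerRadius = 3, baseSeed = 7,
                        oversample = 1)
  expect_named(batch, c("2", "3"))
  expect_length(batch[["2"]], 3)
  expect_false(identical(values(batch[["2"]][[1]]),
                         values(batch[["2"]][[2]])))
  # regenerating with the same base seed reproduces the batch
  again <- phantomBatch(32, diskRadius = 12, holeRadii = c(2, 3),
                        nHoles = 2, nPerRadius = 3, baseSeed = 7,
                        oversample = 1)
  expect_identical(values(batch[["3"]][[2]]), values(again[["3"]][[2]]))
})
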