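# shared small fixtures; everything is generated in code

binaryModel <- greyLevelModel(c(0, 1))

# smooth strictly positive random image (several neighbourhood-mean passes
# kill the high frequencies so interpolating and nearest-pixel line
# integrals of the same field agree closely)
smoothRandomImage <- function(side, seed = 42, passes = 5) {
  set.seed(seed)
  img <- tomoImage(matrix(runif(side^2, 0.5, 1.5), side, side))
  for (i in seq_len(passes)) img <- smoothImage(img, 1)
  img
}

parallelGeom <- function(nAngles, nDetectors, wedge = 0,
                         detectorPixelSize = 1)
  makeEquiangularGeometry("parallel", nAngles = nAngles, angularRange = 180,
                          missingWedge = wedge, nDetectors = nDetectors,
                          detectorPixelSize = detectorPixelSize)

# fan geometry whose detector covers a field of view of `fov` length units
fanGeom <- function(nAngles, fov, wedge = 0) {
  makeEquiangularGeometry("fan", nAngles = nAngles, angularRange = 360,
                          missingWedge = wedge, nDetectors = 96L,
                          detectorPixelSize = 1.5 * fov / 64,
                          sourceObjectDistance = 3 * fov,
                          sourceDetectorDistance = 6 * fov)
}
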