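test_that("phantom generation is deterministic and well-formed", {
  ph <- tinyPhantom()
  ph2 <- makeSpinePhantom(3L, c(48L, 64L, 48L), c(2.5, 2.5, 2.5), seed = 7L)
  expect_identical(imgData(ph2@background), imgData(ph@background))
  expect_identical(lapply(ph2@vertebrae, function(v) v@vol@data),
                   lapply(ph@vertebrae, function(v) v@vol@data))
  expect_identical(vertebraLabels(ph), c("T12", "L1", "L2"))
  expect_identical(centeredLabel(ph), "L1")
  ## different seed changes the phantom
  ph3 <- makeSpinePhantom(3L, c(48L, 64L, 48L), c(2.5, 2.5, 2.5), seed = 8L)
  expect_false(identical(imgData(ph3@background), imgData(ph@background)))
})

test_that("vertebra masks are pairwise disjoint in world space", {
  ph <- makeSpinePhantom(5L, c(96L, 96L, 96L), c(1.5, 1.5, 1.5), seed = 2L)
  expect_length(ph@vertebrae, 5L)
  ## masks live on cropped grids; disjointness = y-extents cannot overlap
  yRanges <- t(vapply(ph@vertebrae, function(v) {
    bb <- fluororeg:::maskBBoxWorld(v@mask, v@vol@spacing, v@vol@origin)
    c(bb$lo[2], bb$hi[2])
  }, numeric(2)))
  ord <- order(-yRanges[, 1])          # cranio-caudal storage order
  expect_identical(ord, seq_len(5L))
  for (i in 1:4) expect_gt(yRanges[i, 1], yRanges[i + 1, 2])
})

test_that("body-center landmark matches the body sub-mask centroid", {
  for (v in tinyPhantom()@vertebrae) {
    idx <- which(v@bodyMask, arr.ind = TRUE)
    centroid <- v@vol@origin + (colMeans(idx) - 1) * v@vol@spacing
    expect_lt(max(abs(centroid - v@bodyCenter)), max(v@vol@spacing))
    ## left pedicle on the +x (patient-left) side of the body center
    expect_gt(v@leftPedicle[1], v@bodyCenter[1])
  }
})

test_that("a volume too small for the requested spine errors", {
  expect_error(makeSpinePhantom(5L, c(48L, 40L, 48L), c(1, 1, 1), seed = 1L),
               "too small")
})

test_that("perturbation honours its ranges and defaults", {
  ph <- tinyPhantom()
  ## zero ranges -> identity poses
  ph0 <- perturbSpine(ph, perturbRanges(tz = 0, rx = 0), seed = 3L)
  for (v in ph0@vertebrae)
    expect_equal(unname(poseVector(v@truePose)), rep(0, 6))
  ## defaults bound wx by 5 deg and tz by 2 mm, all else zero
  phd <- perturbSpine(ph, seed = 5L)
  for (v in phd@vertebrae) {
    q <- poseVector(v@truePose)
    expect_lte(abs(q["wx"]), 5)
    expect_lte(abs(q["tz"]), 2)
    expect_equal(unname(q[c("tx", "ty", "wy", "wz")]), rep(0, 4))
    expect_equal(v@truePose@center, v@bodyCenter)
  }
  ## same seed reproduces identical poses; different seed does not
  phd2 <- perturbSpine(ph, seed = 5L)
  expect_identical(lapply(phd2@vertebrae, function(v) poseVector(v@truePose)),
                   lapply(phd@vertebrae, function(v) poseVector(v@truePose)))
  phd3 <- perturbSpine(ph, seed = 6L)
  expect_false(identical(poseVector(phd3@vertebrae[[1]]@truePose),
                         poseVector(phd@vertebrae[[1]]@truePose)))
})

test_that("markers stay in the frame, apart, and need at least five", {
  ph <- tinyPhantom()
  mk <- placeMarkers(ph, 9L, seed = 4L)
  expect_identical(nrow(mk@centers), 9L)
  ## pairwise separation beyond one diameter
  expect_gt(min(dist(mk@centers)), 2 * mk@radius)
  ## inside the 150 mm frame centered over the centered vertebra
  mid <- getVertebra(ph, centeredLabel(ph))
  expect_true(all(abs(mk@centers[, 1]) <= 75))
  expect_true(all(abs(mk@centers[, 2] - mid@bodyCenter[2]) <= 75))
  ## dorsal side of the torso
  expect_true(all(mk@centers[, 3] > 0))
  expect_error(placeMarkers(ph, 4L), "minimum of five")
  ## determinism
  expect_identical(placeMarkers(ph, 7L, seed = 9L)@centers,
                   placeMarkers(ph, 7L, seed = 9L)@centers)
})

test_that("slice-thickness resampling preserves content and counts", {
  set.seed(10)
  v <- volumeImage(array(runif(20 * 60 * 20), c(20L, 60L, 20L)),
                   c(1.5, 0.67, 1.5))
  ## resampling at the native thickness is the identity
  r <- resampleSliceThickness(v, 0.67)
  expect_lt(max(abs(imgData(r) - imgData(v))), 1e-6)
  expect_equal(voxelSpacing(r), voxelSpacing(v))
  ## 0.67 -> 5.0 mm reduces the slice count by the spacing ratio (+-1)
  r5 <- resampleSliceThickness(v, 5.0)
  expect_lte(abs(dim(imgData(r5))[2] - round(60 * 0.67 / 5)), 1)
  expect_equal(voxelSpacing(r5)[2], 5.0)
  ## volume center is preserved
  expect_equal(volumeCenter(r5), volumeCenter(v), tolerance = 1e-9)
  ## slab averaging preserves the mean where slabs tile the volume
  expect_equal(mean(imgData(r5)), mean(imgData(v)), tolerance = 0.02)
  expect_error(resampleSliceThickness(v, -1), "thickness")
  expect_error(resampleSliceThickness(v, 0.3), ">=")
})

test_that("degrading a phantom keeps landmarks and shrinks slices", {
  ph <- tinyPhantom()
  d <- degradePhantom(ph, 5.0)
  expect_equal(voxelSpacing(d@background)[2], 5.0)
  for (i in seq_along(ph@vertebrae)) {
    expect_identical(d@vertebrae[[i]]@bodyCenter, ph@vertebrae[[i]]@bodyCenter)
    expect_identical(d@vertebrae[[i]]@leftPedicle,
                     ph@vertebrae[[i]]@leftPedicle)
    expect_lt(dim(d@vertebrae[[i]]@vol@data)[2],
              dim(ph@vertebrae[[i]]@vol@data)[2])
  }
})

test_that("test cases bundle consistently and deterministically", {
  tc <- tinyCase()
  expect_equal(tc@rad, 90)
  ## same config + seed -> bit-identical images and poses
  tc2 <- makeTestCase(tinyConfig(), seed = 11L)
  expect_identical(tc2@fluoro1@data, tc@fluoro1@data)
  expect_identical(tc2@fluoro2@data, tc@fluoro2@data)
  expect_identical(poseVector(getVertebra(tc2@phantom, "L1")@truePose),
                   poseVector(getVertebra(tc@phantom, "L1")@truePose))
  ## nominal RAD bookkeeping for other pairs
  tc40 <- makeTestCase(tinyConfig(angulations = c(-20, 20)), seed = 3L)
  expect_equal(tc40@rad, 40)
  ## true RAD includes the angulation jitter, within its band
  expect_lt(abs(rad(trueRelativePose(tc40)) - 40),
            2 * tinyConfig()$angulationJitter + 1e-9)
})

test_that("configuration validation is strict", {
  expect_error(caseConfig(markerCount = 4), "minimum of five")
  expect_error(caseConfig(angulations = c(-50, 20)), "within")
  cfg <- tinyConfig()
  cfg$typo <- 1
  expect_error(validateConfig(cfg), "unknown configuration keys")
  cfg2 <- tinyConfig()
  cfg2$noise <- NULL
  expect_error(validateConfig(cfg2), "missing")
})

test_that("every vertebra projects fully inside both default detectors", {
  tc <- makeTestCase(caseConfig(), seed = 21L)
  g1 <- tc@fluoro1@geometry; g2 <- tc@fluoro2@geometry
  for (v in tc@phantom@vertebrae)
    expect_true(checkCapture(v, v@truePose, g1, g2))
})
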