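test_that("line integrals match the homogeneous-sphere chord length", {
  vol <- sphereVolume(radius = 20, mu = 0.02, sp = 0.5)
  g <- makeCArmGeometry(0, sdd = 1000, sod = 600, pixelPitch = 1,
                        detDim = c(64L, 64L))
  drr <- forwardProject(vol, g, step = 0.25)
  ## central chord = 2 * r * mu = 0.8, within 1%
  expect_lt(abs(max(imgData(drr)) - 0.8) / 0.8, 0.01)
  ## all-zero volume projects to an all-zero DRR
  zero <- volumeImage(array(0, c(8, 8, 8)), c(5, 5, 5))
  expect_true(all(imgData(forwardProject(zero, g)) == 0))
  ## non-negative line integrals
  expect_true(all(imgData(drr) >= 0))
})

test_that("projection is linear and step-size converged", {
  vol <- sphereVolume(sp = 0.5)
  g <- makeCArmGeometry(0, pixelPitch = 1, detDim = c(64L, 64L))
  d1 <- imgData(forwardProject(vol, g, step = 0.25))
  v2 <- volumeImage(2 * imgData(vol), voxelSpacing(vol), imgOrigin(vol))
  expect_lt(max(abs(imgData(forwardProject(v2, g, step = 0.25)) - 2 * d1)),
            1e-6)
  ## halving the step changes the sphere integral by well under 0.5%
  dh <- imgData(forwardProject(vol, g, step = 0.125))
  expect_lt(max(abs(dh - d1)) / max(d1), 0.005)
})

test_that("masked projections add up to the full projection", {
  ph <- tinyPhantom()
  g <- makeCArmGeometry(-20, sod = 700, pixelPitch = 2.4,
                        detDim = c(128L, 128L))
  base <- baselineVolume(ph)
  ## split the baseline into per-vertebra masks and the remainder
  remainder <- array(TRUE, dim(imgData(base)))
  acc <- 0
  for (v in ph@vertebrae) {
    fullMask <- array(FALSE, dim(imgData(base)))
    il <- round((v@vol@origin - base@origin) / base@spacing) + 1
    ih <- il + dim(v@mask) - 1
    fullMask[il[1]:ih[1], il[2]:ih[2], il[3]:ih[3]] <- v@mask
    remainder <- remainder & !fullMask
    acc <- acc + imgData(forwardProject(base, g, mask = fullMask, step = 1))
  }
  acc <- acc + imgData(forwardProject(base, g, mask = remainder, step = 1))
  full <- imgData(forwardProject(base, g, step = 1))
  expect_lt(max(abs(acc - full)), 1e-6)
})

test_that("translating the volume moves the projected peak accordingly", {
  vol <- sphereVolume(radius = 10, mu = 0.05, sp = 0.5, n = 61L)
  g <- makeCArmGeometry(0, pixelPitch = 1, detDim = c(128L, 128L))
  pose <- rigidPose(c(14, -9, 0))
  drr <- imgData(forwardProject(vol, g, pose = pose, step = 0.25))
  peak <- which(drr == max(drr), arr.ind = TRUE)[1, ] - 1 # 0-based
  predicted <- projectPoints(g, applyPose(pose, c(0, 0, 0)))
  expect_lt(max(abs(peak - predicted)), 0.51)
})

test_that("a source inside the volume is refused", {
  vol <- volumeImage(array(0.01, c(50, 50, 50)), c(20, 20, 20))
  g <- makeCArmGeometry(0, sdd = 1000, sod = 400, pixelPitch = 1,
                        detDim = c(32L, 32L))
  expect_error(forwardProject(vol, g), "inside the volume")
})

test_that("marker rendering is analytic and peak-accurate", {
  ph <- tinyPhantom()
  mk <- placeMarkers(ph, 9L, seed = 6L)
  g <- makeCArmGeometry(-45, sod = 700, pixelPitch = 1.2,
                        detDim = c(256L, 256L))
  img <- imgData(renderMarkers(g, mk))
  ## peak value bounded by the central chord 2 * mu * r
  expect_lte(max(img), 2 * mk@attenuation * mk@radius + 1e-12)
  ## every marker's local intensity peak sits at its projected center
  tru <- projectPoints(g, mk@centers)
  for (k in seq_len(nrow(tru))) {
    rows <- round(tru[k, 1]) + (-3:3) + 1
    cols <- round(tru[k, 2]) + (-3:3) + 1
    win <- img[rows, cols]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    pk0 <- c(rows[peak[1]], cols[peak[2]]) - 1
    expect_lt(max(abs(pk0 - tru[k, ])), 0.51)
  }
  ## rays missing every sphere contribute exactly zero
  expect_identical(img[1, 1], 0)
  ## nine markers produce nine local maxima at the projected centers
  det <- detectMarkers2d(img)
  expect_identical(nrow(det), 9L)
})

test_that("fluoro simulation composes, seeds and scales as configured", {
  ph <- perturbSpine(tinyPhantom(), seed = 2L)
  mk <- placeMarkers(ph, 7L, seed = 3L)
  g <- makeCArmGeometry(-20, sod = 700, pixelPitch = 2.4,
                        detDim = c(128L, 128L))
  ## zero noise and identity intensity map reproduce the composite DRR
  clean <- simulateFluoro(ph, mk, g, noiseFree(), seed = 1L)
  comp <- imgData(forwardProject(ph@background, g))
  for (v in ph@vertebrae) {
    roi <- fluororeg:::vertebraROI(v, v@truePose, g, marginPx = 3L)
    comp[(roi[1]:roi[2]) + 1, (roi[3]:roi[4]) + 1] <-
      comp[(roi[1]:roi[2]) + 1, (roi[3]:roi[4]) + 1] +
      forwardProject(v@vol, g, pose = v@truePose, roi = roi)
  }
  comp <- comp + imgData(renderMarkers(g, mk))
  expect_equal(clean@data, comp, tolerance = 1e-12)
  ## same seed -> identical image; different seed -> different noise
  n1 <- simulateFluoro(ph, mk, g, noiseModel(), seed = 9L)
  n2 <- simulateFluoro(ph, mk, g, noiseModel(), seed = 9L)
  n3 <- simulateFluoro(ph, mk, g, noiseModel(), seed = 10L)
  expect_identical(n1@data, n2@data)
  expect_false(identical(n1@data, n3@data))
  ## an applied intensity scale is recovered by the similarity scale
  ## estimator (round trip through the affine detector response)
  sc <- simulateFluoro(ph, mk, g, noiseModel(gain = 0, gaussianSd = 0,
                                             scale = 2, offset = 0.3),
                       seed = 1L)
  s <- estimateScale(gradientImages(sc@data), gradientImages(clean@data))
  expect_equal(as.numeric(s), 2, tolerance = 1e-9)
})
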