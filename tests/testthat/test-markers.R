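## Shared two-view marker scene: 9 markers, +/-45 deg views at the
## default fine-pitch intrinsics, a nominal relative pose 4 deg off per
## view.
markerScene <- function() memo("markerScene", function() {
  ph <- makeSpinePhantom(5L, c(96L, 96L, 96L), c(1.5, 1.5, 1.5), seed = 1L)
  mk <- placeMarkers(ph, 9L, seed = 3L)
  g1 <- makeCArmGeometry(-45, sod = 742)
  g2 <- makeCArmGeometry(45, sod = 742)
  nomA <- makeCArmGeometry(-41, sod = 742)
  nomB <- makeCArmGeometry(41, sod = 742)
  list(ph = ph, mk = mk, g1 = g1, g2 = g2,
       g2nom = applyRelativePose(relativeAngulation(nomA, nomB), g1),
       trueRel = relativeAngulation(g1, g2))
})

test_that("blob detection finds rendered markers to subpixel accuracy", {
  sc <- markerScene()
  g <- makeCArmGeometry(-45, sod = 742, pixelPitch = 1.2,
                        detDim = c(256L, 256L))
  for (count in c(7L, 9L)) {
    mk <- placeMarkers(sc$ph, count, seed = 13L)
    det <- detectMarkers2d(renderMarkers(g, mk))
    expect_identical(nrow(det), count)
    tru <- projectPoints(g, mk@centers)
    for (i in seq_len(nrow(det))) {
      err <- min(sqrt((tru[, 1] - det$row[i])^2 + (tru[, 2] - det$col[i])^2))
      expect_lt(err, 0.5)
    }
  }
  ## a blank image yields no detections
  blank <- matrix(0, 128, 128)
  expect_identical(nrow(detectMarkers2d(blank)), 0L)
})

test_that("matching recovers the true bijection and ignores order", {
  sc <- markerScene()
  d1 <- syntheticDetections(sc$g1, sc$mk@centers)
  d2 <- syntheticDetections(sc$g2, sc$mk@centers)
  ## under the true geometries the assignment is exact with tiny residual
  m <- matchMarkers(d1, d2, sc$g1, sc$g2)
  expect_identical(m$i1, m$i2)
  expect_lt(mean(m$residual), 0.1)
  ## under the 4-deg-off nominal geometry the bijection still comes out
  mn <- matchMarkers(d1, d2, sc$g1, sc$g2nom)
  expect_identical(mn$i1, mn$i2)
  ## shuffling detection order permutes indices but not the pairing
  set.seed(5)
  perm <- sample(9)
  ms <- matchMarkers(d1[perm, ], d2, sc$g1, sc$g2nom)
  expect_identical(ms$i2[order(perm[ms$i1])], mn$i2)
  ## fewer than five detections is an error
  expect_error(matchMarkers(d1[1:4, ], d2, sc$g1, sc$g2nom),
               "minimum of five")
})

test_that("noise-free relative pose recovery is essentially exact", {
  sc <- markerScene()
  d1 <- syntheticDetections(sc$g1, sc$mk@centers)
  d2 <- syntheticDetections(sc$g2, sc$mk@centers)
  m <- matchMarkers(d1, d2, sc$g1, sc$g2nom)
  rel <- estimateRelativePose(d1, d2, m, sc$g1, sc$g2nom)
  expect_lt(abs(rad(rel) - rad(sc$trueRel)), 0.2)
  expect_lt(attr(rel, "residual"), 1e-6)
  ## refined geometry reproduces the true view-2 camera
  g2est <- attr(rel, "geometry2")
  expect_lt(max(abs(g2est@source - sc$g2@source)), 1e-6)
  ## identical detections and geometries give the identity
  mi <- matchMarkers(d1, d1, sc$g1, sc$g1)
  expect_equal(rad(estimateRelativePose(d1, d1, mi, sc$g1, sc$g1)), 0,
               tolerance = 1e-9)
  expect_error(estimateRelativePose(d1, d2, m[1:4, ], sc$g1, sc$g2nom),
               "minimum of five")
})

test_that("self-consistency: triangulated markers reproject onto detections", {
  sc <- markerScene()
  sdNoise <- 0.5
  d1 <- syntheticDetections(sc$g1, sc$mk@centers, sd = sdNoise, seed = 31L)
  d2 <- syntheticDetections(sc$g2, sc$mk@centers, sd = sdNoise, seed = 32L)
  m <- matchMarkers(d1, d2, sc$g1, sc$g2nom)
  rel <- estimateRelativePose(d1, d2, m, sc$g1, sc$g2nom)
  X <- attr(rel, "points")
  used <- attr(rel, "used")
  r1 <- projectPoints(sc$g1, X)
  r2 <- projectPoints(attr(rel, "geometry2"), X)
  e1 <- sqrt(rowSums((r1 - cbind(d1$row[m$i1], d1$col[m$i1])[used, ])^2))
  e2 <- sqrt(rowSums((r2 - cbind(d2$row[m$i2], d2$col[m$i2])[used, ])^2))
  expect_lt(max(c(e1, e2)), 2 * sdNoise * 2)
})

test_that("more markers never hurt noise-free RAD recovery", {
  sc <- markerScene()
  errByCount <- vapply(c(5L, 7L, 9L), function(count) {
    errs <- vapply(1:5, function(s) {
      mk <- placeMarkers(sc$ph, count, seed = 40L + s)
      d1 <- syntheticDetections(sc$g1, mk@centers)
      d2 <- syntheticDetections(sc$g2, mk@centers)
      m <- matchMarkers(d1, d2, sc$g1, sc$g2nom)
      abs(rad(estimateRelativePose(d1, d2, m, sc$g1, sc$g2nom)) -
            rad(sc$trueRel))
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(errByCount) <= 1e-6))
})

test_that("the full image chain estimates the relative pose on noisy views", {
  tc <- tinyCase()
  g1 <- tc@fluoro1@geometry
  cfgA <- tc@config$angulations
  nomA <- makeCArmGeometry(cfgA[1], sdd = g1@sdd, sod = g1@sod,
                           pixelPitch = g1@pixelPitch, detDim = g1@detDim)
  nomB <- makeCArmGeometry(cfgA[2], sdd = g1@sdd, sod = g1@sod,
                           pixelPitch = g1@pixelPitch, detDim = g1@detDim)
  g2nom <- applyRelativePose(relativeAngulation(nomA, nomB), g1)
  rel <- markerRelativePose(tc@fluoro1, tc@fluoro2, g1, g2nom)
  ## the estimate must beat the +-3 deg jittered nominal
  expect_lt(rotErrDeg(rel, trueRelativePose(tc)), 3)
})
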