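## Registration driver tests run on the reduced tinyCase (3 vertebrae,
## 128^2 detector, 2.5 mm voxels) with a small optimizer budget: they
## exercise the plumbing contracts; accuracy at the full study sizes is
## covered by the acceptance suite.

test_that("capture detection distinguishes in-view from off-view poses", {
  tc <- tinyCase()
  v <- getVertebra(tc@phantom, "L1")
  g1 <- tc@fluoro1@geometry; g2 <- tc@fluoro2@geometry
  expect_true(checkCapture(v, v@truePose, g1, g2))
  ## 200 mm caudal translation leaves the detector
  far <- composePose(recenterPose(v@truePose, v@bodyCenter),
                     rigidPose(c(0, -200, 0), center = v@bodyCenter))
  expect_false(checkCapture(v, far, g1, g2))
})

test_that("an uncaptured vertebra is skipped without a pose", {
  tc <- tinyCase()
  v <- getVertebra(tc@phantom, "L1")
  g1 <- tc@fluoro1@geometry
  rel <- trueRelativePose(tc)
  attr(rel, "geometry2") <- tc@fluoro2@geometry
  init <- composePose(recenterPose(v@truePose, v@bodyCenter),
                      rigidPose(c(0, -200, 0), center = v@bodyCenter))
  res <- stage2Vertebra(v, tc@fluoro1, tc@fluoro2, g1, rel, init,
                        cfg = tinyRegConfig(), seed = 1L)
  expect_false(res@captured)
  expect_false(res@converged)
  expect_true(is.na(res@similarity))
})

## Full-size case whose vertebrae share one rigid ground-truth pose (the
## patient repositioning), so the coarse shared pose has a well-defined
## truth. Stage 1 uses a single view: the in-plane components are
## constrained, the depth along the view axis is not.
sharedTruthCase <- function() memo("sharedTruthCase", function()
  makeTestCase(caseConfig(perturb = perturbRanges(tz = 0, rx = 0)),
               seed = 31L))

inPlaneErr <- function(est, truth, target, g) {
  d <- applyPose(est, target) - applyPose(truth, target)
  w <- (g@detCenter - g@source) / g@sdd
  sqrt(sum((d - sum(d * w) * w)^2))
}

test_that("stage 1 refines the in-plane coarse pose from a single view", {
  tc <- sharedTruthCase()
  labs <- vertebraLabels(tc@phantom)
  pair <- list(getVertebra(tc@phantom, labs[2]),
               getVertebra(tc@phantom, labs[3]))
  ctr <- volumeCenter(tc@phantom@background)
  g1 <- tc@fluoro1@geometry
  st1 <- stage1Coarse(pair, tc@fluoro1, g1, ctr,
                      cfg = registrationConfig(), seed = 5L)
  v <- getVertebra(tc@phantom, labs[3])
  ## in-plane error within ~1 voxel; total error inside the stage-2
  ## search bounds so stage 2 can take over
  expect_lt(inPlaneErr(st1$pose, v@truePose, v@bodyCenter, g1), 2)
  expect_lt(computeTre(st1$pose, v@truePose, v@bodyCenter), 10)
  expect_error(stage1Coarse(pair[1], tc@fluoro1, g1, ctr),
               "exactly two")
})

test_that("stage 2 recovers the true pose from the true-pose start", {
  tc <- memo("cleanTinyCase", function()
    makeTestCase(tinyConfig(noise = noiseFree(), angulationJitter = 0),
                 seed = 23L))
  v <- getVertebra(tc@phantom, "L1")
  rel <- trueRelativePose(tc)
  attr(rel, "geometry2") <- tc@fluoro2@geometry
  res <- stage2Vertebra(v, tc@fluoro1, tc@fluoro2, tc@fluoro1@geometry,
                        rel, init = v@truePose,
                        cfg = registrationConfig(budget = 500L), seed = 2L)
  expect_true(res@captured)
  expect_lt(computeTre(res@pose, v@truePose, v@bodyCenter), 0.2)
})

test_that("register_case runs end to end, reproducibly, order-independently", {
  tc <- tinyCase()
  cfg <- tinyRegConfig(useTrueRelativePose = TRUE)
  runA <- registerCase(tc, cfg, seed = 3L)
  expect_identical(sort(names(runA$results)), sort(vertebraLabels(tc@phantom)))
  expect_identical(nrow(runA$skips), 0L)
  ## bit-stable rerun
  runB <- registerCase(tc, cfg, seed = 3L)
  expect_identical(lapply(runA$results, function(r) poseVector(r@pose)),
                   lapply(runB$results, function(r) poseVector(r@pose)))
  ## registering a subset in a different order changes nothing
  runC <- registerCase(tc, cfg, seed = 3L, labels = c("L2", "T12"))
  for (lab in c("T12", "L2"))
    expect_identical(poseVector(runC$results[[lab]]@pose),
                     poseVector(runA$results[[lab]]@pose))
})

test_that("vertebrae flagged non-registrable are reported as skips", {
  tc <- memo("exclCase", function()
    makeTestCase(tinyConfig(excludeLabels = "L2"), seed = 11L))
  run <- registerCase(tc, tinyRegConfig(useTrueRelativePose = TRUE),
                      seed = 3L)
  expect_identical(names(run$results), c("T12", "L1"))
  expect_identical(run$skips$label, "L2")
  expect_match(run$skips$reason, "not registrable")
})

test_that("an off-detector vertebra yields one skip and N-1 results", {
  ## narrow the detector so the cranial vertebra projects off its edge
  tc0 <- tinyCase()
  g1 <- tc0@fluoro1@geometry
  tc <- memo("offDetCase", function() {
    cfgOff <- tinyConfig(detDim = c(76L, 128L))
    makeTestCase(cfgOff, seed = 11L)
  })
  stopifnot(!checkCapture(getVertebra(tc@phantom, "T12"),
                          getVertebra(tc@phantom, "T12")@truePose,
                          tc@fluoro1@geometry, tc@fluoro2@geometry))
  run <- registerCase(tc, tinyRegConfig(useTrueRelativePose = TRUE),
                      seed = 3L)
  expect_identical(length(run$results), 2L)
  expect_identical(run$skips$label, "T12")
  expect_match(run$skips$reason, "not fully captured")
})

test_that("marker-estimated relative pose is as good as truth, noise-free", {
  tc <- memo("cleanMarkerCase", function()
    makeTestCase(caseConfig(noise = noiseFree()), seed = 29L))
  cfg <- registrationConfig()
  cfgTrue <- cfg; cfgTrue$useTrueRelativePose <- TRUE
  runEst <- registerCase(tc, cfg, seed = 4L, labels = "L1")
  runTrue <- registerCase(tc, cfgTrue, seed = 4L, labels = "L1")
  v <- getVertebra(tc@phantom, "L1")
  treEst <- computeTre(runEst$results[["L1"]]@pose, v@truePose, v@bodyCenter)
  treTrue <- computeTre(runTrue$results[["L1"]]@pose, v@truePose,
                        v@bodyCenter)
  expect_lt(abs(treEst - treTrue), 0.2)
  ## the estimate itself reproduces the true RAD on clean images
  expect_lt(abs(runEst$radEstimate - rad(trueRelativePose(tc))), 0.5)
})

test_that("stage 1 before stage 2 widens the capture range", {
  ## from a 10 mm coarse offset, stage 2 preceded by stage 1 converges to
  ## the truth; stage 2 alone from the same offset succeeds less often
  tc <- sharedTruthCase()
  g1 <- tc@fluoro1@geometry
  rel <- trueRelativePose(tc)
  attr(rel, "geometry2") <- tc@fluoro2@geometry
  labs <- vertebraLabels(tc@phantom)
  mid <- ceiling(length(labs) / 2)
  pair <- list(getVertebra(tc@phantom, labs[mid - 1L]),
               getVertebra(tc@phantom, labs[mid]))
  ctr <- volumeCenter(tc@phantom@background)
  v <- getVertebra(tc@phantom, labs[mid])
  cfg <- registrationConfig()
  okWith <- okWithout <- 0L
  nSeeds <- 6L
  for (s in seq_len(nSeeds)) {
    set.seed(s)
    u <- runif(3, -1, 1); u <- 10 * u / sqrt(sum(u^2))
    init <- rigidPose(u, center = ctr)
    st1 <- stage1Coarse(pair, tc@fluoro1, g1, ctr, cfg,
                        seed = 50L + s, init = init)
    rWith <- stage2Vertebra(v, tc@fluoro1, tc@fluoro2, g1, rel,
                            init = st1$pose, cfg = cfg, seed = 60L + s)
    rAlone <- stage2Vertebra(v, tc@fluoro1, tc@fluoro2, g1, rel,
                             init = init, cfg = cfg, seed = 60L + s)
    okWith <- okWith +
      (computeTre(rWith@pose, v@truePose, v@bodyCenter) < 1.5)
    okWithout <- okWithout +
      (computeTre(rAlone@pose, v@truePose, v@bodyCenter) < 1.5)
  }
  expect_gte(okWith, ceiling(0.9 * nSeeds))
  expect_lte(okWithout, okWith)
})
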