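test_that("TRE is the Euclidean landmark distance between poses", {
  truth <- randomPose(1, center = c(2, 2, 2))
  expect_equal(computeTre(truth, truth, c(10, -5, 3)), 0)
  ## a pure extra translation (1,2,2) gives TRE 3
  shifted <- composePose(rigidPose(c(1, 2, 2), center = truth@center),
                         recenterPose(truth, truth@center))
  expect_equal(computeTre(shifted, truth, c(10, -5, 3)), 3,
               tolerance = 1e-12)
  ## 90 deg about the target's own center at 10 mm lever arm: 10 * sqrt(2)
  ctr <- c(4, 4, 4)
  rot <- rigidPose(angles = c(0, 0, 90), center = ctr)
  expect_equal(computeTre(rot, identityPose(), ctr + c(10, 0, 0)),
               10 * sqrt(2), tolerance = 1e-12)
})

test_that("axis decomposition is signed and Pythagorean", {
  truth <- identityPose()
  est <- rigidPose(c(0, 0, 0.4))
  expect_equal(axisDecomposition(est, truth, c(1, 2, 3)),
               c(x = 0, y = 0, z = 0.4))
  for (s in 1:20) {
    est <- randomPose(s, tmax = 3, rmax = 4)
    target <- rnorm(3, sd = 30)
    ax <- axisDecomposition(est, truth, target)
    expect_equal(sqrt(sum(ax^2)), computeTre(est, truth, target),
                 tolerance = 1e-9)
  }
})

test_that("the rotational-error indicator separates rotation from shift", {
  body <- c(0, 0, 0); ped <- c(7, 0, 11)
  truth <- identityPose()
  ## pure translation: both landmarks move equally, indicator 0
  trans <- rigidPose(c(1, -2, 0.5))
  expect_equal(rotationalErrorIndicator(trans, truth, body, ped), 0,
               tolerance = 1e-12)
  ## pure rotation about the body center: body TRE 0, pedicle TRE > 0
  rot <- rigidPose(angles = c(4, 0, 0), center = body)
  expect_gt(rotationalErrorIndicator(rot, truth, body, ped), 0)
  expect_equal(rotationalErrorIndicator(truth, truth, body, ped), 0)
})

test_that("cohort summaries follow the quartile-fence outlier rule", {
  ## hand-checked case: quartiles 2 and 4, fences -1 and 7, one outlier
  s <- summarizeTre(c(1, 2, 3, 4, 100))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(unname(s$fences), c(-1, 7))
  expect_identical(s$outliers, 100)
  expect_identical(s$outlierIdx, 5L)
  expect_equal(s$max, 100)
  ## equal values: IQR zero, nothing flagged
  s0 <- summarizeTre(rep(0.4, 8))
  expect_equal(s0$iqr, 0)
  expect_length(s0$outliers, 0)
  expect_error(summarizeTre(numeric(0)), "no values")
  ## stratified summaries carry one row per stratum
  s2 <- summarizeTre(c(1, 2, 3, 10, 20, 30), strata = rep(c("a", "b"), 3))
  expect_identical(sort(s2$byStratum$stratum), c("a", "b"))
  expect_identical(s2$byStratum$n, c(3L, 3L))
})

test_that("evaluateCase joins results with ground truth per vertebra", {
  tc <- tinyCase()
  run <- registerCase(tc, tinyRegConfig(useTrueRelativePose = TRUE),
                      seed = 3L)
  tab <- evaluateCase(tc, run)
  expect_identical(sort(tab$label), sort(vertebraLabels(tc@phantom)))
  reg <- tab[tab$status == "registered", ]
  expect_true(all(is.finite(reg$tre)))
  expect_equal(reg$tre, sqrt(reg$ex^2 + reg$ey^2 + reg$ez^2),
               tolerance = 1e-9)
  expect_equal(reg$rotIndicator, reg$trePedicle - reg$tre, tolerance = 1e-12)
})

test_that("TRE is invariant to a shared rigid frame change", {
  frame <- randomPose(9, tmax = 30, rmax = 40)
  for (s in 1:10) {
    est <- randomPose(s, tmax = 2, rmax = 3)
    truth <- randomPose(s + 50, tmax = 2, rmax = 3)
    target <- rnorm(3, sd = 25)
    base <- computeTre(est, truth, target)
    moved <- computeTre(composePose(frame, recenterPose(est, frame@center)),
                        composePose(frame, recenterPose(truth, frame@center)),
                        target)
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("a single-replicate sweep is deterministic and well-shaped", {
  cfgCase <- tinyConfig()
  cfgReg <- tinyRegConfig(useTrueRelativePose = TRUE)
  swA <- radSweep(cfgCase, rads = c(40, 90), replicates = 1L, seed = 8L,
                  cfg = cfgReg, labels = "L1")
  swB <- radSweep(cfgCase, rads = c(40, 90), replicates = 1L, seed = 8L,
                  cfg = cfgReg, labels = "L1")
  expect_identical(swA$perVertebra, swB$perVertebra)
  expect_identical(sort(unique(swA$perVertebra$rad)), c(40, 90))
  ## summaries cover only converged registrations, so at this plumbing
  ## budget a stratum may be absent; what there is must be well-formed
  expect_true(all(swA$summary$rad %in% c(40, 90)))
  if (nrow(swA$summary))
    expect_true(all(c("medianTre", "q1", "q3", "medianAbsZ") %in%
                      names(swA$summary)))
})
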