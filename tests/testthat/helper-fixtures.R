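## Shared fixtures. Everything is generated in code; heavier objects are
## built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

## Small phantom + markers used by most module tests.
tinyPhantom <- function() memo("tinyPhantom", function()
  makeSpinePhantom(3L, c(48L, 64L, 48L), c(2.5, 2.5, 2.5), seed = 7L))

## Reduced-size registration case: 3 vertebrae, 128^2 detector.
tinyConfig <- function(...) {
  args <- list(nVertebrae = 3L, dim = c(48L, 64L, 48L),
               spacing = c(2.5, 2.5, 2.5), detDim = c(128L, 128L),
               pixelPitch = 2.4)
  do.call(caseConfig, utils::modifyList(args, list(...)))
}

tinyCase <- function() memo("tinyCase", function()
  makeTestCase(tinyConfig(), seed = 11L))

## Fast optimizer settings for pipeline plumbing tests: small budget with
## a short stagnation window so runs can still flag convergence.
tinyRegConfig <- function(...)
  registrationConfig(budget = 250L, stagnationGens = 5L, ...)

## Smooth sphere volume for projector oracles: radius mm, attenuation
## mu/mm, voxel sp mm (anti-aliased edge, one-voxel ramp).
sphereVolume <- function(radius = 20, mu = 0.02, sp = 0.5, n = 101L) {
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  rho <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  volumeImage(mu * pmin(pmax((radius - rho) / sp + 0.5, 0), 1), rep(sp, 3))
}

## Deterministic random rigid pose.
randomPose <- function(seed, tmax = 20, rmax = 30, center = c(0, 0, 0)) {
  set.seed(seed)
  rigidPose(runif(3, -tmax, tmax), runif(3, -rmax, rmax), center)
}

## Rotation-angle distance between two relative poses, degrees.
rotErrDeg <- function(relA, relB) {
  d <- relA@rotation %*% t(relB@rotation)
  acos(pmin(1, pmax(-1, (sum(diag(d)) - 1) / 2))) * 180 / pi
}

## Detections data.frame from exact projections (+ optional pixel noise).
syntheticDetections <- function(g, centers, sd = 0, seed = NULL) {
  px <- projectPoints(g, centers)
  if (sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    px <- px + matrix(rnorm(length(px), 0, sd), nrow(px), 2)
  }
  data.frame(row = px[, 1], col = px[, 2], response = 1, sigma = 2)
}
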