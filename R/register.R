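#' Registration configuration
#'
#' Optimizer and matching hyperparameters of the two-stage registration.
#' Defaults: CMA-ES step sizes 3 mm / 3 deg, 1500 evaluations per stage
#' with stop on 1e-3 relative objective stagnation, stage-2 search bounds
#' +/-10 mm / +/-10 deg around the stage-1 pose (the expected per-vertebra
#' changes, up to 5 deg / 2 mm, sit well inside), and a multi-resolution
#' stage 2 (half, then full detector resolution).
#'
#' @param budget CMA-ES evaluations per stage.
#' @param sigmaT,sigmaR initial step sizes, mm / degrees.
#' @param boundT,boundR stage-2 search half-widths about the start, mm /
#'   degrees.
#' @param stage1BoundT,stage1BoundR,stage1SigmaT,stage1SigmaR stage-1
#'   counterparts (wider: stage 1 absorbs patient repositioning).
#' @param roiDilatePx extra pixels around the projected vertebra bounding
#'   box defining the similarity ROI.
#' @param useTrueRelativePose bypass marker-based pose estimation with
#'   the simulation ground truth (diagnostics only).
#' @param radiusRange projected marker radius range, px, for detection.
#' @param step ray-sampling step override, mm.
#' @param stagnationTol,stagnationGens stopping rule passed to
#'   [cmaesMinimize()]; a run counts as converged when the best objective
#'   stagnates within this window.
#' @export
registrationConfig <- function(budget = 1500L, sigmaT = 3, sigmaR = 3,
                               boundT = 10, boundR = 10,
                               stage1BoundT = 15, stage1BoundR = 10,
                               stage1SigmaT = 2, stage1SigmaR = 2,
                               roiDilatePx = 5L,
                               useTrueRelativePose = FALSE,
                               radiusRange = c(1.5, 4.5), step = NULL,
                               stagnationTol = 1e-3,
                               stagnationGens = 15L) {
  list(budget = as.integer(budget), sigmaT = sigmaT, sigmaR = sigmaR,
       boundT = boundT, boundR = boundR, stage1BoundT = stage1BoundT,
       stage1BoundR = stage1BoundR, stage1SigmaT = stage1SigmaT,
       stage1SigmaR = stage1SigmaR, roiDilatePx = as.integer(roiDilatePx),
       useTrueRelativePose = isTRUE(useTrueRelativePose),
       radiusRange = radiusRange, step = step,
       stagnationTol = stagnationTol,
       stagnationGens = as.integer(stagnationGens))
}

#' Is a vertebra fully captured by both views?
#'
#' TRUE iff the projected bounding box of the vertebra's mask, under the
#' given pose, lies fully inside both detectors (and in front of both
#' sources).
#'
#' @param vert [VertebraModel-class].
#' @param pose [RigidPose-class] candidate pose.
#' @param g1,g2 view geometries.
#' @export
checkCapture <- function(vert, pose, g1, g2) {
  bb <- maskBBoxWorld(vert@mask, vert@vol@spacing, vert@vol@origin)
  corners <- applyPose(pose, boxCorners(bb$lo, bb$hi))
  for (g in list(g1, g2)) {
    px <- tryCatch(projectPoints(g, corners), error = function(e) NULL)
    if (is.null(px)) return(FALSE)
    if (any(px[, 1] < 0) || any(px[, 1] > g@detDim[1] - 1) ||
        any(px[, 2] < 0) || any(px[, 2] > g@detDim[2] - 1)) return(FALSE)
  }
  TRUE
}

## Block-mean downsampling of an image by an integer factor (crops any
## remainder rows/cols, matching downsampleGeometry()).
downsampleImage <- function(m, factor = 2L) {
  f <- as.integer(factor)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- (matrix(colMeans(matrix(m, f)), nr %/% f, nc))
  t(matrix(colMeans(matrix(t(m), f)), nc %/% f, nr %/% f))
}

## One view's similarity evaluator: fixes the ROI, fluoro gradients and
## A-constants at the initial pose, returns function(pose) -> S.
viewObjective <- function(verts, fluoro, g, initPose, cfg, resFactor = 1L) {
  gU <- if (resFactor > 1L) downsampleGeometry(g, resFactor) else g
  img <- if (resFactor > 1L) downsampleImage(fluoro@data, resFactor) else
    fluoro@data
  ## union ROI over the vertebrae, inflated by the search bounds
  roi <- NULL
  for (v in verts) {
    bb <- maskBBoxWorld(v@mask, v@vol@spacing, v@vol@origin)
    corners <- applyPose(initPose, boxCorners(bb$lo, bb$hi))
    px <- projectPoints(gU, corners)
    ctr <- applyPose(initPose, v@bodyCenter)
    w <- (gU@detCenter - gU@source) / gU@sdd
    mag <- gU@sdd / sum((ctr - gU@source) * w)
    rObj <- vnorm(bb$hi - bb$lo) / 2
    marg <- ceiling((cfg$boundT + deg2rad(cfg$boundR) * rObj) * mag /
                      gU@pixelPitch) + cfg$roiDilatePx
    r <- c(floor(min(px[, 1])) - marg, ceiling(max(px[, 1])) + marg,
           floor(min(px[, 2])) - marg, ceiling(max(px[, 2])) + marg)
    roi <- if (is.null(roi)) r else
      c(min(roi[1], r[1]), max(roi[2], r[2]), min(roi[3], r[3]),
        max(roi[4], r[4]))
  }
  roi <- as.integer(c(max(roi[1], 0), min(roi[2], gU@detDim[1] - 1),
                      max(roi[3], 0), min(roi[4], gU@detDim[2] - 1)))
  if (roi[2] < roi[1] || roi[4] < roi[3])
    stop("vertebra projects outside the detector")
  flROI <- img[(roi[1]:roi[2]) + 1L, (roi[3]:roi[4]) + 1L, drop = FALSE]
  gfl <- gradientImages(flROI)
  A <- autoA(gfl)
  function(pose) {
    drr <- 0
    for (v in verts)
      drr <- drr + projectCore(v@vol, gU, pose = pose, roi = roi,
                               step = cfg$step)
    gdr <- gradientImages(drr)
    s <- as.numeric(estimateScale(gfl, gdr))
    dV <- gfl$di - s * gdr$di
    dH <- gfl$dj - s * gdr$dj
    sum(A / (A + dV^2)) + sum(A / (A + dH^2))
  }
}

## 6-vector <-> pose about a fixed center
vecToPose <- function(x, center) rigidPose(x[1:3], x[4:6], center)

## CMA-ES with independent restarts: when a run stagnates suspiciously
## early (more than 40% of the budget unspent), it has usually settled in
## a local optimum; rerun from the start point with a fresh seed and keep
## the best. Restart strategies are the standard remedy for multimodal
## CMA-ES landscapes.
cmaesRestarts <- function(objective, x0, sigma0, lower, upper, seed,
                          budget, stagnationTol, stagnationGens) {
  used <- 0L
  best <- NULL
  k <- 0L
  repeat {
    k <- k + 1L
    opt <- cmaesMinimize(objective, x0, sigma0 = sigma0, lower = lower,
                         upper = upper, seed = deriveSeed(seed, 300L + k),
                         budget = budget - used,
                         stagnationTol = stagnationTol,
                         stagnationGens = stagnationGens)
    used <- used + opt$evals
    if (is.null(best) || opt$value < best$value) best <- opt
    if (k >= 3L || used >= budget || budget - used <= 0.4 * budget) break
  }
  best$evals <- used
  best
}

#' Stage 1: coarse single-view registration of two adjacent vertebrae
#'
#' A single shared rigid pose (about `center`, typically the volume
#' center) is optimized so that the combined DRR of the two vertebrae
#' matches view 1, at half detector resolution. This reduces the search
#' space for the per-vertebra two-view stage. The CMA-ES search is
#' preceded by an exhaustive in-plane translation grid at quarter
#' resolution (3 mm steps over the search range): in-plane shifts are the
#' axis along which the single-view similarity is most multimodal, and
#' the grid costs a fraction of a percent of the optimization budget.
#'
#' @param verts list of two adjacent [VertebraModel-class] objects.
#' @param fluoro1 [FluoroImage-class] view 1.
#' @param g1 its [ProjectionGeometry-class].
#' @param center rotation center of the coarse pose, mm.
#' @param cfg [registrationConfig()].
#' @param seed integer seed.
#' @param init optional initial [RigidPose-class] (defaults to identity).
#' @return list with `pose` (coarse [RigidPose-class]), `value`
#'   (similarity per ROI pixel), `evals`, `converged`.
#' @export
stage1Coarse <- function(verts, fluoro1, g1, center, cfg = registrationConfig(),
                         seed = 1L, init = NULL) {
  if (length(verts) != 2L) stop("stage 1 matches exactly two vertebrae")
  if (is.null(init)) init <- identityPose(center)
  init <- recenterPose(init, center)
  for (v in verts)
    if (!checkCapture(v, init, g1, g1))
      stop("vertebra pair not captured in view 1")
  cfg1 <- cfg
  cfg1$boundT <- cfg$stage1BoundT
  cfg1$boundR <- cfg$stage1BoundR
  x0 <- poseVector(init)

  ## coarse in-plane translation grid seeds the search (quarter
  ## resolution, or half on small detectors where a quarter image would
  ## fall below ~48 px)
  gridRes <- if (min(g1@detDim) >= 192L) 4L else 2L
  obj4 <- viewObjective(verts, fluoro1, g1, init, cfg1, resFactor = gridRes)
  span <- seq(-0.8 * cfg$stage1BoundT, 0.8 * cfg$stage1BoundT, by = 3)
  bestX <- x0
  bestV <- obj4(vecToPose(x0, center))
  for (a in span) for (b in span) {
    xx <- x0
    xx[1:3] <- xx[1:3] + a * g1@detRow + b * g1@detCol
    val <- obj4(vecToPose(xx, center))
    if (val > bestV) { bestV <- val; bestX <- xx }
  }
  lower <- x0 - c(rep(cfg$stage1BoundT, 3), rep(cfg$stage1BoundR, 3))
  upper <- x0 + c(rep(cfg$stage1BoundT, 3), rep(cfg$stage1BoundR, 3))
  bestX <- clampVec(bestX, lower, upper)

  obj <- viewObjective(verts, fluoro1, g1, init, cfg1, resFactor = 2L)
  opt <- cmaesRestarts(function(x) -obj(vecToPose(x, center)),
                       x0 = bestX,
                       sigma0 = c(rep(cfg$stage1SigmaT, 3), rep(cfg$stage1SigmaR, 3)),
                       lower = lower, upper = upper,
                       seed = deriveSeed(seed, 7L), budget = cfg$budget,
                       stagnationTol = cfg$stagnationTol,
                       stagnationGens = cfg$stagnationGens)
  list(pose = vecToPose(opt$par, center), value = -opt$value,
       evals = opt$evals, converged = opt$converged)
}

#' Stage 2: per-vertebra two-view registration
#'
#' Maximizes the unweighted sum of the gradient-difference similarities
#' over both views (view-2 geometry = view-1 geometry composed with the
#' relative pose) over the vertebra's 6-DOF pose, with CMA-ES at half and
#' then full detector resolution. The pose rotates about the vertebral
#' body center.
#'
#' @param vert [VertebraModel-class].
#' @param fluoro1,fluoro2 the two views.
#' @param g1 view-1 geometry (reference frame).
#' @param rel [RelativePose-class] mapping view 1 into view 2 (estimated
#'   or true).
#' @param init initial [RigidPose-class] (typically the stage-1 pose).
#' @param cfg [registrationConfig()].
#' @param seed integer seed.
#' @return A [RegistrationResult-class].
#' @export
stage2Vertebra <- function(vert, fluoro1, fluoro2, g1, rel, init,
                           cfg = registrationConfig(), seed = 1L) {
  center <- vert@bodyCenter
  init <- recenterPose(init, center)
  g2 <- attr(rel, "geometry2")
  if (is.null(g2)) g2 <- applyRelativePose(rel, g1)
  if (!checkCapture(vert, init, g1, g2))
    return(new("RegistrationResult", label = vert@label, pose = init,
               similarity = NA_real_, s1 = NA_real_, s2 = NA_real_,
               evals = 0, converged = FALSE, captured = FALSE))
  x0 <- poseVector(init)
  lo <- x0 - c(rep(cfg$boundT, 3), rep(cfg$boundR, 3))
  hi <- x0 + c(rep(cfg$boundT, 3), rep(cfg$boundR, 3))

  bHalf <- max(1L, as.integer(round(cfg$budget * 0.5)))
  bFull <- max(1L, cfg$budget - bHalf)
  objH <- twoViewObjective(vert, fluoro1, fluoro2, g1, g2, init, cfg, 2L)
  optH <- cmaesRestarts(function(x) -objH(vecToPose(x, center)), x0 = x0,
                        sigma0 = c(rep(cfg$sigmaT, 3), rep(cfg$sigmaR, 3)),
                        lower = lo, upper = hi,
                        seed = deriveSeed(seed, 13L), budget = bHalf,
                        stagnationTol = cfg$stagnationTol,
                        stagnationGens = cfg$stagnationGens)
  objF <- twoViewObjective(vert, fluoro1, fluoro2, g1, g2, init, cfg, 1L)
  optF <- cmaesMinimize(function(x) -objF(vecToPose(x, center)),
                        x0 = optH$par,
                        sigma0 = c(rep(cfg$sigmaT / 2, 3), rep(cfg$sigmaR / 2, 3)),
                        lower = lo, upper = hi,
                        seed = deriveSeed(seed, 17L), budget = bFull,
                        stagnationTol = cfg$stagnationTol,
                        stagnationGens = cfg$stagnationGens)
  pose <- vecToPose(optF$par, center)
  s1 <- viewObjective(list(vert), fluoro1, g1, init, cfg, 1L)(pose)
  s2 <- viewObjective(list(vert), fluoro2, g2, init, cfg, 1L)(pose)
  new("RegistrationResult", label = vert@label, pose = pose,
      similarity = s1 + s2, s1 = s1, s2 = s2,
      evals = optH$evals + optF$evals,
      converged = optH$converged || optF$converged, captured = TRUE)
}

twoViewObjective <- function(vert, fluoro1, fluoro2, g1, g2, init, cfg,
                             resFactor) {
  o1 <- viewObjective(list(vert), fluoro1, g1, init, cfg, resFactor)
  o2 <- viewObjective(list(vert), fluoro2, g2, init, cfg, resFactor)
  function(pose) o1(pose) + o2(pose)
}

#' Register a full case
#'
#' The complete pipeline on one [SpineTestCase-class]: marker-based
#' relative-pose estimation, stage-1 coarse registration of the centered
#' vertebra and its cranial neighbor on view 1, then stage-2 per-vertebra
#' two-view registration of every registrable, captured vertebra, seeded
#' from the coarse pose. Vertebrae flagged non-registrable or not fully
#' captured on both views are recorded as skips, not silently dropped.
#'
#' @param tc [SpineTestCase-class].
#' @param cfg [registrationConfig()].
#' @param seed integer seed.
#' @param labels optional subset of vertebra labels to register.
#' @return list with `results` (list of [RegistrationResult-class]),
#'   `skips` (data.frame label/reason), `stage1` (coarse pose), `rel`
#'   (relative pose used), `radEstimate` (its RAD, degrees).
#' @export
registerCase <- function(tc, cfg = registrationConfig(), seed = 1L,
                         labels = NULL) {
  g1 <- tc@fluoro1@geometry
  if (is.null(g1)) stop("case lacks a view-1 geometry")

  ## relative pose: marker chain unless ground truth is requested
  if (cfg$useTrueRelativePose) {
    rel <- trueRelativePose(tc)
    g2 <- tc@fluoro2@geometry
    attr(rel, "geometry2") <- g2
  } else {
    nomA <- makeCArmGeometry(tc@config$angulations[1], sdd = g1@sdd,
                             sod = g1@sod, pixelPitch = g1@pixelPitch,
                             detDim = g1@detDim)
    nomB <- makeCArmGeometry(tc@config$angulations[2], sdd = g1@sdd,
                             sod = g1@sod, pixelPitch = g1@pixelPitch,
                             detDim = g1@detDim)
    g2nom <- applyRelativePose(relativeAngulation(nomA, nomB), g1)
    rel <- markerRelativePose(tc@fluoro1, tc@fluoro2, g1, g2nom,
                              radiusRange = cfg$radiusRange)
    g2 <- attr(rel, "geometry2")
  }

  ## stage 1 on the centered vertebra and its cranial neighbor
  verts <- tc@phantom@vertebrae
  labs <- vertebraLabels(tc@phantom)
  mid <- ceiling(length(verts) / 2)
  pair <- verts[c(max(mid - 1L, 1L), mid)]
  center <- volumeCenter(tc@phantom@background)
  st1 <- stage1Coarse(pair, tc@fluoro1, g1, center, cfg,
                      seed = deriveSeed(seed, 3L))

  sel <- if (is.null(labels)) labs else intersect(labs, labels)
  results <- list()
  skips <- data.frame(label = character(0), reason = character(0))
  for (lab in sel) {
    v <- getVertebra(tc@phantom, lab)
    if (!v@registrable) {
      skips <- rbind(skips, data.frame(label = lab,
                                       reason = "not registrable"))
      next
    }
    res <- stage2Vertebra(v, tc@fluoro1, tc@fluoro2, g1, rel,
                          init = st1$pose, cfg = cfg,
                          seed = deriveSeed(seed, 23L,
                                            match(lab, spineLabels)))
    if (!res@captured) {
      skips <- rbind(skips, data.frame(label = lab,
                                       reason = "not fully captured on both views"))
      next
    }
    results[[lab]] <- res
  }
  list(results = results, skips = skips, stage1 = st1$pose, rel = rel,
       radEstimate = rad(rel))
}

setMethod("show", "RegistrationResult", function(object) {
  if (!object@captured) {
    cat(sprintf("RegistrationResult %s: not captured\n", object@label))
  } else {
    cat(sprintf(
      "RegistrationResult %s: S = %.4f (S1 %.4f, S2 %.4f), %d evals, %s\n",
      object@label, object@similarity, object@s1, object@s2,
      as.integer(object@evals),
      if (object@converged) "converged" else "not converged"))
  }
})
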