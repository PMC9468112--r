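## Marker detection in 2D, correspondence across the two views, and
## refinement of the relative C-arm pose from the matched sphere rays.

## Replicate-padded separable Gaussian blur.
gaussBlur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), ,
                       drop = FALSE]
  smooth1 <- function(m) {
    m <- pad(m)
    out <- stats::filter(m, k, sides = 2)
    out[(r + 1):(nrow(m) - r), , drop = FALSE]
  }
  t(smooth1(t(smooth1(img))))
}

#' Detect radiopaque sphere markers in a 2D image
#'
#' Scale-space blob detection: difference-of-Gaussian responses over a
#' small set of scales spanning `radiusRange`, 8-neighborhood local
#' maxima above a robust threshold, then subpixel refinement by a
#' quadratic fit to the response peak. Detections closer than one marker
#' diameter are merged (strongest wins) and results are sorted by
#' response.
#'
#' @param img [FluoroImage-class], [DRRImage-class] or numeric matrix.
#' @param radiusRange numeric(2), expected projected marker radius, px.
#' @param threshold detections must exceed `threshold` times the robust
#'   spread (MAD) of the response image.
#' @param relThreshold markers are identical manufactured spheres, so
#'   their blob responses are nearly equal; detections weaker than
#'   `relThreshold` times the median of the five strongest responses are
#'   discarded as anatomy clutter. Set 0 to disable.
#' @param maxDetections keep at most this many strongest detections.
#' @return data.frame with columns `row`, `col` (0-based subpixel px),
#'   `response`, `sigma`; zero rows when nothing is found.
#' @export
detectMarkers2d <- function(img, radiusRange = c(1.5, 4.5), threshold = 8,
                            relThreshold = 0.6, maxDetections = 12L) {
  m <- if (is(img, "FluoroImage")) img@data else as.matrix(img)
  if (any(radiusRange <= 0)) stop("radius range must be positive")
  sigmas <- exp(seq(log(min(radiusRange) / sqrt(2)),
                    log(max(radiusRange) / sqrt(2)), length.out = 4L))
  det <- NULL
  for (sg in sigmas) {
    resp <- (gaussBlur(m, sg) - gaussBlur(m, 1.6 * sg)) * sg
    spread <- mad(resp)
    thr <- max(threshold * spread, 1e-9)
    d <- dim(resp)
    core <- resp[2:(d[1] - 1), 2:(d[2] - 1)]
    isMax <- core > thr
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      isMax <- isMax & core >= resp[2:(d[1] - 1) + di, 2:(d[2] - 1) + dj]
    }
    idx <- which(isMax, arr.ind = TRUE)
    if (!nrow(idx)) next
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1] + 1L; j <- idx[q, 2] + 1L
      ## quadratic subpixel offset from the local 3x3 response patch
      gi <- (resp[i + 1, j] - resp[i - 1, j]) / 2
      gj <- (resp[i, j + 1] - resp[i, j - 1]) / 2
      hii <- resp[i + 1, j] - 2 * resp[i, j] + resp[i - 1, j]
      hjj <- resp[i, j + 1] - 2 * resp[i, j] + resp[i, j - 1]
      hij <- (resp[i + 1, j + 1] - resp[i + 1, j - 1] -
                resp[i - 1, j + 1] + resp[i - 1, j - 1]) / 4
      H <- matrix(c(hii, hij, hij, hjj), 2, 2)
      off <- c(0, 0)
      if (det(H) > 1e-12 || det(H) < -1e-12) {
        off <- tryCatch(-solve(H, c(gi, gj)), error = function(e) c(0, 0))
        off <- clampVec(off, -1, 1)
      }
      det <- rbind(det, data.frame(row = i - 1 + off[1], col = j - 1 + off[2],
                                   response = resp[i, j], sigma = sg))
    }
  }
  if (is.null(det))
    return(data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0), sigma = numeric(0)))
  det <- det[order(-det$response), ]
  ## non-maximum suppression at one marker diameter
  keep <- logical(nrow(det))
  for (q in seq_len(nrow(det))) {
    if (!any(keep)) { keep[q] <- TRUE; next }
    sel <- which(keep)
    dd <- sqrt((det$row[sel] - det$row[q])^2 + (det$col[sel] - det$col[q])^2)
    if (all(dd > 2 * sqrt(2) * det$sigma[q])) keep[q] <- TRUE
  }
  det <- det[keep, , drop = FALSE]
  if (relThreshold > 0 && nrow(det) > 1L) {
    ref <- median(head(det$response, 5L))
    det <- det[det$response >= relThreshold * ref, , drop = FALSE]
  }
  det <- head(det, maxDetections)
  rownames(det) <- NULL
  det
}

## Ray through a (0-based) detector pixel: list(origin, dir) in world mm.
pixelRays <- function(g, rows, cols) {
  half <- (g@detDim - 1) / 2
  P <- outer(rep(1, length(rows)), g@detCenter) +
    outer((rows - half[1]) * g@pixelPitch, g@detRow) +
    outer((cols - half[2]) * g@pixelPitch, g@detCol)
  dir <- sweep(P, 2, g@source)
  dir <- dir / sqrt(rowSums(dir^2))
  list(origin = g@source, dir = dir)
}

## Closest-approach of two rays; returns midpoint and distance. Falls back
## to a point at `fallbackDepth` along ray 1 for near-parallel rays.
triangulateRay <- function(o1, d1, o2, d2, fallbackDepth = 600) {
  r <- o1 - o2
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  d <- sum(d1 * r); e <- sum(d2 * r)
  den <- a * c - b * b
  if (den < 1e-12) {
    X <- o1 + fallbackDepth * d1
    return(list(point = X, dist = vnorm(r - sum(r * d2) * d2)))
  }
  t1 <- (b * e - c * d) / den
  t2 <- (a * e - b * d) / den
  p1 <- o1 + t1 * d1
  p2 <- o2 + t2 * d2
  list(point = (p1 + p2) / 2, dist = vnorm(p1 - p2))
}

#' Match marker detections across the two views
#'
#' Finds the correspondence between the two detection sets that is most
#' geometrically consistent under the nominal geometries: every candidate
#' pair is scored by its two-ray triangulation residual and the global
#' assignment minimizing total residual is found exactly by dynamic
#' programming over subsets (detections may stay unmatched at a fixed
#' skip penalty, which absorbs spurious detections).
#'
#' @param d1,d2 detection data.frames from [detectMarkers2d()].
#' @param g1,g2 nominal [ProjectionGeometry-class] of the two views (the
#'   declared angulations; a coarse guess within ~15 degrees suffices).
#' @param skipPenalty mm; leaving a detection unmatched costs this much.
#' @return data.frame with columns `i1`, `i2` (row indices into `d1`,
#'   `d2`) and `residual` (mm), ordered by `i1`.
#' @export
matchMarkers <- function(d1, d2, g1, g2, skipPenalty = 60) {
  if (nrow(d1) < 5L || nrow(d2) < 5L)
    stop("insufficient markers: a minimum of five skin markers is required")
  swap <- nrow(d1) > nrow(d2)
  A <- if (swap) d2 else d1
  B <- if (swap) d1 else d2
  gA <- if (swap) g2 else g1
  gB <- if (swap) g1 else g2
  na <- nrow(A); nb <- nrow(B)
  raysA <- pixelRays(gA, A$row, A$col)
  raysB <- pixelRays(gB, B$row, B$col)
  cost <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    cost[i, j] <- triangulateRay(raysA$origin, raysA$dir[i, ],
                                 raysB$origin, raysB$dir[j, ],
                                 fallbackDepth = gA@sod)$dist
  ## exact min-cost assignment with skips: DP over subsets of B
  nmask <- bitwShiftL(1L, nb)
  INF <- 1e18
  dp <- matrix(INF, na + 1L, nmask)
  choice <- matrix(-1L, na + 1L, nmask)
  dp[1L, 1L] <- 0
  bits <- bitwShiftL(1L, seq_len(nb) - 1L)
  for (i in seq_len(na)) {
    alive <- which(dp[i, ] < INF)
    for (mask in alive) {
      base <- dp[i, mask]
      ## skip detection i of A
      if (base + skipPenalty < dp[i + 1L, mask]) {
        dp[i + 1L, mask] <- base + skipPenalty
        choice[i + 1L, mask] <- 0L
      }
      free <- which(bitwAnd(mask - 1L, bits) == 0L)
      for (j in free) {
        nm <- mask + bits[j]
        val <- base + min(cost[i, j], skipPenalty * 2)
        if (val < dp[i + 1L, nm]) {
          dp[i + 1L, nm] <- val
          choice[i + 1L, nm] <- j
        }
      }
    }
  }
  mask <- which.min(dp[na + 1L, ])
  pairs <- NULL
  for (i in rev(seq_len(na))) {
    ch <- choice[i + 1L, mask]
    if (ch > 0L) {
      pairs <- rbind(c(i, ch, cost[i, ch]), pairs)
      mask <- mask - bits[ch]
    }
  }
  if (is.null(pairs) || nrow(pairs) < 5L)
    stop("no consistent marker assignment with at least five pairs found")
  out <- data.frame(i1 = pairs[, 1], i2 = pairs[, 2], residual = pairs[, 3])
  if (swap) out[, 1:2] <- out[, 2:1]
  out <- out[order(out$i1), ]
  rownames(out) <- NULL
  out
}

#' Estimate the relative pose between the two views from matched markers
#'
#' Alternating triangulation / Umeyama refinement: the matched sphere
#' rays are triangulated into a 3D marker point set under the current
#' relative-pose estimate, the view-2 rays' closest points to that set
#' are computed in the nominal view-2 frame, and the rigid correction of
#' view 2 is re-estimated by Umeyama alignment; iterated to convergence.
#' Initialization is the nominal (config-declared) angulation. Because
#' two calibrated central projections leave the baseline length
#' unobservable, the estimate is projected onto the C-arm's isocentric
#' constraint (view-2 source at its known source-object distance) when
#' `fixSod = TRUE`.
#'
#' @param d1,d2 detections from [detectMarkers2d()].
#' @param matches correspondence from [matchMarkers()].
#' @param g1,g2 nominal geometries (view 1 is the reference frame).
#' @param maxIter,tol iteration budget and convergence threshold (mm).
#' @param isocentric constrain the refined relative pose to rotations
#'   about the view-1 isocenter, the family a (possibly imprecisely
#'   read-off) isocentric C-arm can realize. This removes the
#'   ill-conditioning of the unconstrained problem when the markers are
#'   nearly coplanar, as skin markers are. Set FALSE for free-form
#'   two-view geometry.
#' @param fixSod apply the isocentric baseline-scale constraint after an
#'   unconstrained fit (ignored when `isocentric = TRUE`, which implies
#'   it).
#' @param trim drop matches with residuals above 3x the median and refit
#'   once (robustness to a mismatched pair).
#' @return A [RelativePose-class] mapping view-1 geometry into the
#'   refined view-2 geometry, with attributes `geometry2` (the refined
#'   [ProjectionGeometry-class]), `points` (triangulated marker centers),
#'   `residual` (mean ray-ray distance, mm), `iterations` and
#'   `converged`.
#' @export
estimateRelativePose <- function(d1, d2, matches, g1, g2, maxIter = 200L,
                                 tol = 1e-10, isocentric = TRUE,
                                 fixSod = TRUE, trim = TRUE) {
  if (nrow(matches) < 5L)
    stop("insufficient markers: a minimum of five skin markers is required")
  r1 <- pixelRays(g1, d1$row[matches$i1], d1$col[matches$i1])
  r2 <- pixelRays(g2, d2$row[matches$i2], d2$col[matches$i2])
  n <- nrow(matches)

  refine <- function(sel) {
    Q_R <- diag(3); Q_t <- c(0, 0, 0)
    iter <- 0L
    converged <- FALSE
    X <- NULL; dists <- NULL
    while (iter < maxIter) {
      iter <- iter + 1L
      o2 <- as.numeric(Q_R %*% r2$origin + Q_t)
      X <- matrix(0, length(sel), 3)
      Z <- matrix(0, length(sel), 3)
      dists <- numeric(length(sel))
      for (q in seq_along(sel)) {
        k <- sel[q]
        d2w <- as.numeric(Q_R %*% r2$dir[k, ])
        tri <- triangulateRay(r1$origin, r1$dir[k, ], o2, d2w,
                              fallbackDepth = g1@sod)
        X[q, ] <- tri$point
        dists[q] <- tri$dist
        ## closest point on the nominal view-2 ray to Q^-1 X
        y <- as.numeric(crossprod(Q_R, tri$point - Q_t))
        tproj <- sum((y - r2$origin) * r2$dir[k, ])
        Z[q, ] <- r2$origin + tproj * r2$dir[k, ]
      }
      fit <- umeyamaAlign(Z, X)
      delta <- max(abs(fit$rotation - Q_R)) + vnorm(fit$translation - Q_t)
      Q_R <- fit$rotation; Q_t <- fit$translation
      if (delta < tol) { converged <- TRUE; break }
    }
    list(R = Q_R, t = Q_t, X = X, dists = dists, iter = iter,
         converged = converged)
  }

  ## squared ray-ray residuals of a candidate correction (R, t)
  residuals <- function(R, t, sel) {
    o2 <- as.numeric(R %*% r2$origin + t)
    X <- matrix(0, length(sel), 3)
    dists <- numeric(length(sel))
    for (q in seq_along(sel)) {
      k <- sel[q]
      tri <- triangulateRay(r1$origin, r1$dir[k, ], o2,
                            as.numeric(R %*% r2$dir[k, ]),
                            fallbackDepth = g1@sod)
      X[q, ] <- tri$point
      dists[q] <- tri$dist
    }
    list(X = X, dists = dists)
  }

  w1 <- (g1@detCenter - g1@source) / g1@sdd
  iso <- g1@source + g1@sod * w1

  ## direct least-squares polish (the alternating scheme approaches the
  ## optimum but closes the last fraction slowly). With `isocentric` the
  ## correction is constrained to rotations about the isocenter - the
  ## C-arm family that generated both views - which removes the
  ## near-planar-marker degeneracy of the unconstrained 6-DOF problem.
  polish <- function(R0, t0, sel) {
    if (isocentric) {
      f <- function(par) {
        R <- rotationFromAngles(par) %*% R0
        sum(residuals(R, iso - as.numeric(R %*% iso), sel)$dists^2)
      }
      opt <- stats::optim(rep(0, 3), f, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-15))
      opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-15))
      R <- rotationFromAngles(opt$par) %*% R0
      return(list(R = R, t = iso - as.numeric(R %*% iso)))
    }
    ctr <- colMeans(residuals(R0, t0, sel)$X)
    f <- function(par) {
      Rd <- rotationFromAngles(par[4:6])
      R <- Rd %*% R0
      t <- as.numeric(Rd %*% (t0 - ctr)) + ctr + par[1:3]
      sum(residuals(R, t, sel)$dists^2)
    }
    opt <- stats::optim(rep(0, 6), f, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    Rd <- rotationFromAngles(opt$par[4:6])
    list(R = Rd %*% R0,
         t = as.numeric(Rd %*% (t0 - ctr)) + ctr + opt$par[1:3])
  }

  runFit <- function(sel) {
    fit <- refine(sel)
    R0 <- fit$R; t0 <- fit$t
    if (isocentric) t0 <- iso - as.numeric(R0 %*% iso)
    pol <- polish(R0, t0, sel)
    res <- residuals(pol$R, pol$t, sel)
    list(R = pol$R, t = pol$t, X = res$X, dists = res$dists,
         iter = fit$iter, converged = TRUE)
  }

  sel <- seq_len(n)
  fit <- runFit(sel)
  if (trim && n >= 7L) {
    medr <- median(fit$dists)
    good <- fit$dists <= max(3 * medr, 0.5)
    if (any(!good) && sum(good) >= 5L) {
      sel <- sel[good]
      fit <- runFit(sel)
    }
  }

  ## isocentric baseline-scale constraint
  if (isTRUE(fixSod) && !isocentric) {
    S1 <- g1@source
    S2 <- as.numeric(fit$R %*% g2@source + fit$t)
    b <- S2 - S1
    aa <- sum(b^2)
    bb <- 2 * sum(b * (S1 - iso))
    cc <- sum((S1 - iso)^2) - g2@sod^2
    disc <- bb^2 - 4 * aa * cc
    if (disc >= 0 && aa > 1e-12) {
      roots <- (-bb + c(-1, 1) * sqrt(disc)) / (2 * aa)
      s <- roots[which.min(abs(roots - 1))]
      fit$t <- fit$t + (s - 1) * b
      res <- residuals(fit$R, fit$t, sel)
      fit$X <- res$X
      fit$dists <- res$dists
    }
  }

  Q <- relativePose(fit$R, fit$t)
  g2ref <- applyRelativePose(Q, g2)
  rel <- relativeAngulation(g1, g2ref)
  attr(rel, "geometry2") <- g2ref
  attr(rel, "points") <- fit$X
  attr(rel, "residual") <- mean(fit$dists)
  attr(rel, "iterations") <- fit$iter
  attr(rel, "converged") <- fit$converged
  attr(rel, "used") <- sel
  rel
}

#' Full marker-based relative pose estimation for a case
#'
#' Convenience wrapper running detection on both views, matching, and
#' relative-pose refinement with the nominal angulations of a
#' configuration. Because a coarse nominal angulation inflates the
#' triangulation residuals that score the correspondence search, matching
#' and refinement are iterated: after a first fit, detections are
#' re-matched under the refined geometry and the pose re-estimated until
#' the correspondence is stable (at most three rounds).
#'
#' @param f1,f2 [FluoroImage-class] views.
#' @param g1,g2 nominal geometries.
#' @param radiusRange passed to [detectMarkers2d()].
#' @return As [estimateRelativePose()].
#' @export
markerRelativePose <- function(f1, f2, g1, g2, radiusRange = c(1.5, 4.5)) {
  d1 <- detectMarkers2d(f1, radiusRange)
  d2 <- detectMarkers2d(f2, radiusRange)
  m <- matchMarkers(d1, d2, g1, g2)
  rel <- estimateRelativePose(d1, d2, m, g1, g2)
  for (round in 1:2) {
    g2ref <- attr(rel, "geometry2")
    m2 <- matchMarkers(d1, d2, g1, g2ref)
    if (identical(m2[, 1:2], m[, 1:2])) break
    m <- m2
    rel <- estimateRelativePose(d1, d2, m, g1, g2ref)
  }
  ## the nominal angulation is trusted to +-15 degrees; an estimate
  ## outside that band means the correspondence search latched onto a
  ## spurious configuration - fall back to the nominal geometry
  radNom <- rad(relativeAngulation(g1, g2))
  if (abs(rad(rel) - radNom) > 15) {
    rel <- relativeAngulation(g1, g2)
    attr(rel, "geometry2") <- g2
    attr(rel, "residual") <- NA_real_
    attr(rel, "converged") <- FALSE
    attr(rel, "fallback") <- TRUE
  }
  rel
}
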