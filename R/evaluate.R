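#' Target registration error at a point
#'
#' Euclidean distance, in mm, between a target point mapped by the
#' estimated and by the reference pose.
#'
#' @param est,truth [RigidPose-class] objects (any rotation centers; the
#'   underlying rigid maps are compared).
#' @param target numeric(3) target point, mm.
#' @export
computeTre <- function(est, truth, target) {
  vnorm(applyPose(est, target) - applyPose(truth, target))
}

#' Signed per-axis registration error
#'
#' `est(target) - truth(target)` per patient axis; positive z is dorsal.
#' The Euclidean norm of the three components equals [computeTre()].
#'
#' @inheritParams computeTre
#' @return named numeric(3) (x, y, z), mm.
#' @export
axisDecomposition <- function(est, truth, target) {
  d <- applyPose(est, target) - applyPose(truth, target)
  setNames(as.numeric(d), c("x", "y", "z"))
}

#' Rotational-error indicator
#'
#' The signed difference between the TREs of two points of one vertebra,
#' `TRE(left pedicle) - TRE(body center)`: zero under a pure translation
#' error, positive when a rotation about the body center is present.
#'
#' @inheritParams computeTre
#' @param bodyCenter,leftPedicle the two landmarks, mm.
#' @export
rotationalErrorIndicator <- function(est, truth, bodyCenter, leftPedicle) {
  computeTre(est, truth, leftPedicle) - computeTre(est, truth, bodyCenter)
}

#' Cohort summary with Tukey fences
#'
#' Median, quartiles (linear-interpolation quantiles), the interquartile
#' range, Tukey fences at Q1 - 1.5 IQR and Q3 + 1.5 IQR, the outliers
#' outside the fences, and an optional per-stratum breakdown.
#'
#' @param values numeric vector (mm); NAs are dropped with a count.
#' @param strata optional factor/character vector of the same length.
#' @return list with `n`, `median`, `q1`, `q3`, `iqr`, `fences`,
#'   `outliers` (values), `outlierIdx`, `max`, and `byStratum`
#'   (data.frame) when strata are given.
#' @export
summarizeTre <- function(values, strata = NULL) {
  ok <- !is.na(values)
  nDropped <- sum(!ok)
  v <- values[ok]
  if (!length(v)) stop("no values to summarize")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[3] + 1.5 * iqr)
  out <- which(v < fences[1] | v > fences[2])
  res <- list(n = length(v), nDropped = nDropped, median = q[2],
              q1 = q[1], q3 = q[3], iqr = iqr, fences = fences,
              outliers = v[out], outlierIdx = which(ok)[out], max = max(v))
  if (!is.null(strata)) {
    st <- strata[ok]
    res$byStratum <- do.call(rbind, lapply(split(v, st), function(x) {
      qq <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
      data.frame(n = length(x), median = qq[2], q1 = qq[1], q3 = qq[3])
    }))
    res$byStratum <- cbind(stratum = rownames(res$byStratum),
                           res$byStratum)
    rownames(res$byStratum) <- NULL
  }
  res
}

#' Per-vertebra accuracy table of one registered case
#'
#' Joins registration results with the case's ground-truth poses:
#' body-center TRE, its signed axis components, the left-pedicle TRE and
#' the rotational-error indicator.
#'
#' @param tc [SpineTestCase-class].
#' @param run output of [registerCase()].
#' @return data.frame, one row per attempted vertebra; skipped vertebrae
#'   appear with `status` and NA errors.
#' @export
evaluateCase <- function(tc, run) {
  rows <- list()
  for (res in run$results) {
    v <- getVertebra(tc@phantom, res@label)
    tre <- computeTre(res@pose, v@truePose, v@bodyCenter)
    ax <- axisDecomposition(res@pose, v@truePose, v@bodyCenter)
    treP <- computeTre(res@pose, v@truePose, v@leftPedicle)
    rows[[res@label]] <- data.frame(
      label = res@label, status = "registered", tre = tre,
      ex = ax[1], ey = ax[2], ez = ax[3], trePedicle = treP,
      rotIndicator = treP - tre, similarity = res@similarity,
      converged = res@converged)
  }
  if (nrow(run$skips)) {
    for (q in seq_len(nrow(run$skips)))
      rows[[paste0("skip", q)]] <- data.frame(
        label = run$skips$label[q], status = run$skips$reason[q],
        tre = NA_real_, ex = NA_real_, ey = NA_real_, ez = NA_real_,
        trePedicle = NA_real_, rotIndicator = NA_real_,
        similarity = NA_real_, converged = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' RAD sweep experiment
#'
#' The full simulate-register-evaluate loop over a set of rotation angle
#' differences: for each RAD, `replicates` cases are generated with the
#' opposed angulation pair (-RAD/2, +RAD/2), registered, and evaluated.
#' Failed or skipped registrations are recorded, not dropped.
#'
#' @param baseConfig a [caseConfig()]; its `angulations` entry is
#'   replaced per RAD.
#' @param rads numeric vector of RADs, degrees (paper set:
#'   40, 56, 60, 64, 90).
#' @param replicates cases per RAD.
#' @param seed integer master seed.
#' @param cfg [registrationConfig()].
#' @param labels optional vertebra-label subset to register per case.
#' @return list with `perVertebra` (data.frame: rad, replicate, and the
#'   [evaluateCase()] columns) and `summary` (data.frame: median TRE and
#'   IQR per RAD stratum, registered vertebrae only).
#' @export
radSweep <- function(baseConfig = caseConfig(), rads = c(40, 90),
                     replicates = 20L, seed = 1L,
                     cfg = registrationConfig(), labels = NULL) {
  stopifnot(replicates >= 1L)
  rows <- list()
  for (r in seq_along(rads)) {
    config <- baseConfig
    config$angulations <- c(-rads[r] / 2, rads[r] / 2)
    for (rep in seq_len(replicates)) {
      s <- deriveSeed(seed, r, rep)
      tc <- makeTestCase(config, seed = s)
      run <- registerCase(tc, cfg, seed = deriveSeed(s, 5L),
                          labels = labels)
      tab <- evaluateCase(tc, run)
      tab <- cbind(rad = rads[r], replicate = rep,
                   radEstimate = run$radEstimate, tab)
      rows[[paste(r, rep)]] <- tab
    }
  }
  perVertebra <- do.call(rbind, rows)
  rownames(perVertebra) <- NULL
  reg <- perVertebra[perVertebra$status == "registered" &
                       perVertebra$converged, ]
  if (!nrow(reg))
    return(list(perVertebra = perVertebra,
                summary = data.frame(rad = numeric(0), n = integer(0),
                                     medianTre = numeric(0))))
  summary <- do.call(rbind, lapply(split(reg, reg$rad), function(x) {
    s <- summarizeTre(x$tre)
    data.frame(rad = x$rad[1], n = s$n, medianTre = s$median,
               q1 = s$q1, q3 = s$q3,
               medianAbsX = median(abs(x$ex)), medianAbsY = median(abs(x$ey)),
               medianAbsZ = median(abs(x$ez)),
               medianX = median(x$ex), medianY = median(x$ey),
               medianZ = median(x$ez))
  }))
  rownames(summary) <- NULL
  list(perVertebra = perVertebra, summary = summary)
}
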