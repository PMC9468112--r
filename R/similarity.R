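#' Construct a similarity configuration
#'
#' @param Av,Ah maximum vertical / horizontal similarity constants
#'   (positive); `NA` (default) derives each as the squared median
#'   absolute fluoro gradient over the ROI, which keeps the per-pixel
#'   normalization meaningful across noise levels.
#' @param s DRR intensity scale; `NA` (default) re-estimates it by least
#'   squares at every evaluation.
#' @param roi optional logical matrix selecting the summed pixels.
#' @return A [SimilarityConfig-class].
#' @export
similarityConfig <- function(Av = NA_real_, Ah = NA_real_, s = NA_real_,
                             roi = NULL) {
  new("SimilarityConfig", Av = as.numeric(Av), Ah = as.numeric(Ah),
      s = as.numeric(s), roi = roi)
}

#' Vertical and horizontal derivative images
#'
#' Central differences along rows (`i`, vertical) and columns (`j`,
#' horizontal) with replicated borders.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return list with matrices `di` and `dj`.
#' @export
gradientImages <- function(img) {
  d <- dim(img)
  if (any(d < 2L)) stop("image must be at least 2 x 2")
  up <- img[c(1L, seq_len(d[1] - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(d[1] - 1L) + 1L, d[1]), , drop = FALSE]
  lf <- img[, c(1L, seq_len(d[2] - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(d[2] - 1L) + 1L, d[2]), drop = FALSE]
  list(di = (dn - up) / 2, dj = (rt - lf) / 2)
}

#' Least-squares DRR intensity scale
#'
#' The scale s minimizing `sum((grad_fl - s grad_drr)^2)` over the ROI,
#' pooling both gradient directions. An all-zero DRR gradient is
#' degenerate: s = 1 is returned with attribute `degenerate = TRUE`.
#'
#' @param gfl,gdrr gradient lists from [gradientImages()].
#' @param roi optional logical matrix.
#' @return numeric scale with attribute `degenerate`.
#' @export
estimateScale <- function(gfl, gdrr, roi = NULL) {
  sel <- if (is.null(roi)) TRUE else as.vector(roi)
  num <- sum(gfl$di[sel] * gdrr$di[sel]) + sum(gfl$dj[sel] * gdrr$dj[sel])
  den <- sum(gdrr$di[sel]^2) + sum(gdrr$dj[sel]^2)
  if (den <= 0) return(structure(1, degenerate = TRUE))
  structure(num / den, degenerate = FALSE)
}

#' Gradient-difference similarity between a fluoro image and a DRR
#'
#' The similarity
#' \deqn{S = \sum_{i,j} \frac{A_v}{A_v + I_{diffV}(i,j)^2} +
#'           \sum_{i,j} \frac{A_h}{A_h + I_{diffH}(i,j)^2}}
#' with the vertical and horizontal difference images
#' `IdiffV = dIfl/di - s dIdrr/di` and `IdiffH = dIfl/dj - s dIdrr/dj`.
#' Every per-pixel term lies in (0, 1], so `0 < S <= 2 N` with `N` the
#' number of ROI pixels, and the upper bound is attained exactly when both
#' difference images vanish on the ROI.
#'
#' @param fluoro [FluoroImage-class] or numeric matrix.
#' @param drr [DRRImage-class] or numeric matrix of the same size.
#' @param cfg [SimilarityConfig-class].
#' @return numeric S, with attributes `s` (scale used), `Av`, `Ah` and
#'   `degenerate`.
#' @export
gradientDifferenceSimilarity <- function(fluoro, drr,
                                         cfg = similarityConfig()) {
  fl <- if (is(fluoro, "FluoroImage")) fluoro@data else as.matrix(fluoro)
  dr <- if (is(drr, "FluoroImage")) drr@data else as.matrix(drr)
  if (!all(dim(fl) == dim(dr))) stop("image and DRR sizes differ")
  validObject(cfg)
  roi <- cfg@roi
  if (!is.null(roi) && !all(dim(roi) == dim(fl)))
    stop("ROI size differs from the images")
  gfl <- gradientImages(fl)
  gdr <- gradientImages(dr)
  s <- cfg@s
  degenerate <- FALSE
  if (is.na(s)) {
    s <- estimateScale(gfl, gdr, roi)
    degenerate <- attr(s, "degenerate")
    s <- as.numeric(s)
  }
  sel <- if (is.null(roi)) TRUE else as.vector(roi)
  dV <- gfl$di[sel] - s * gdr$di[sel]
  dH <- gfl$dj[sel] - s * gdr$dj[sel]
  Av <- cfg@Av; Ah <- cfg@Ah
  if (is.na(Av)) Av <- autoA(gfl, roi)
  if (is.na(Ah)) Ah <- autoA(gfl, roi)
  S <- sum(Av / (Av + dV^2)) + sum(Ah / (Ah + dH^2))
  structure(S, s = s, Av = Av, Ah = Ah, degenerate = degenerate)
}

## Automatic similarity constant: squared median absolute fluoro gradient
## over the ROI (both directions pooled), floored to keep A > 0 on
## constant images.
autoA <- function(gfl, roi = NULL) {
  sel <- if (is.null(roi)) TRUE else as.vector(roi)
  g <- c(abs(gfl$di[sel]), abs(gfl$dj[sel]))
  max(median(g)^2, 1e-12)
}
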