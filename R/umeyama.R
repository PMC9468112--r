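#' Least-squares rigid alignment of corresponded point sets
#'
#' Closed-form (SVD-based) estimate of the rigid transform minimizing
#' `sum_i || (c R src_i + t) - dst_i ||^2` over rotations `R`, translations
#' `t` and, optionally, a uniform scale `c`. The default is rigid
#' (`scale = FALSE`, c fixed at 1), matching a rigid registration problem;
#' the similarity mode exists but is off by default.
#'
#' @param src,dst n x 3 matrices (n >= 3) of corresponding points, mm.
#' @param scale estimate a uniform scale as well? Default FALSE.
#' @return list with `rotation` (3x3), `translation` (3), `scale`,
#'   `rms` (root-mean-square residual, mm) and `pose` (the equivalent
#'   [RigidPose-class] about the origin; only when `scale` is 1).
#' @examples
#' src <- matrix(rnorm(18), 6, 3)
#' fit <- umeyamaAlign(src, src)
#' fit$rms # 0
#' @export
umeyamaAlign <- function(src, dst, scale = FALSE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == dim(dst)))
    stop("src and dst must have the same number of points")
  n <- nrow(src)
  if (n < 3L) stop("need at least 3 corresponding points")
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  xs <- sweep(src, 2, mu_s); xd <- sweep(dst, 2, mu_d)
  H <- crossprod(xd, xs) / n                  # dst-centered x src-centered
  sv <- svd(H)
  ## degenerate (collinear) configurations: covariance rank < 2
  if (sv$d[2] < max(sv$d[1], 1e-300) * 1e-9)
    stop("degenerate (collinear or coincident) point configuration")
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  c_ <- 1
  if (isTRUE(scale)) {
    var_s <- sum(xs^2) / n
    c_ <- sum(diag(diag(sv$d) %*% S)) / var_s
  }
  t <- mu_d - c_ * as.numeric(R %*% mu_s)
  res <- sweep(c_ * src %*% t(R), 2, t, "+") - dst
  out <- list(rotation = R, translation = t, scale = c_,
              rms = sqrt(mean(rowSums(res^2))))
  if (c_ == 1) {
    M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- t
    out$pose <- poseFromMatrix(M)
  }
  out
}
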