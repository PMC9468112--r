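#' Construct a rigid pose
#'
#' @param translation numeric(3), mm.
#' @param angles numeric(3), degrees (wx, wy, wz), applied extrinsically in
#'   the order x, then y, then z (right-handed; `R = Rz Ry Rx`).
#' @param center numeric(3), rotation center, mm.
#' @return A [RigidPose-class].
#' @examples
#' p <- rigidPose(c(1, 2, 2), c(0, 0, 90))
#' applyPose(p, c(10, 0, 0))
#' @export
rigidPose <- function(translation = c(0, 0, 0), angles = c(0, 0, 0),
                      center = c(0, 0, 0)) {
  new("RigidPose",
      translation = stopIfNot3(translation, "translation"),
      angles = stopIfNot3(angles, "angles"),
      center = stopIfNot3(center, "center"))
}

#' @rdname rigidPose
#' @export
identityPose <- function(center = c(0, 0, 0)) rigidPose(center = center)

#' Rotation matrix of extrinsic x-y-z angles
#'
#' @param angles numeric(3) degrees.
#' @return 3x3 rotation matrix `Rz %*% Ry %*% Rx`.
#' @export
rotationFromAngles <- function(angles) {
  a <- deg2rad(angles)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Extrinsic x-y-z angles of a rotation matrix
#'
#' Inverse of [rotationFromAngles()]; near gimbal lock (|wy| = 90 deg) the
#' x/z split is fixed by setting wz from the remaining free rotation.
#' @param R 3x3 rotation matrix.
#' @return numeric(3) degrees.
#' @export
anglesFromRotation <- function(R) {
  sy <- -R[3, 1]
  sy <- clampVec(sy, -1, 1)
  if (abs(sy) < 1 - 1e-10) {
    wx <- atan2(R[3, 2], R[3, 3])
    wy <- asin(sy)
    wz <- atan2(R[2, 1], R[1, 1])
  } else {
    wy <- asin(sy)
    wx <- atan2(-R[2, 3], R[2, 2])
    wz <- 0
  }
  rad2deg(c(wx, wy, wz))
}

#' Homogeneous 4x4 matrix of a pose
#'
#' @param p [RigidPose-class].
#' @return 4x4 matrix `M` with `M %*% c(x, 1) = applyPose(p, x)`.
#' @export
poseMatrix <- function(p) {
  R <- rotationFromAngles(p@angles)
  m <- p@center + p@translation - R %*% p@center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- m
  M
}

#' Pose from a homogeneous matrix
#'
#' @param M 4x4 rigid homogeneous matrix.
#' @param center rotation center the resulting pose should use, mm.
#' @return [RigidPose-class].
#' @export
poseFromMatrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("matrix is not rigid (rotation part not orthonormal)")
  m <- M[1:3, 4]
  center <- stopIfNot3(center, "center")
  t <- as.numeric(m - center + R %*% center)
  rigidPose(t, anglesFromRotation(R), center)
}

#' Apply a rigid pose to points
#'
#' @param p [RigidPose-class].
#' @param points numeric(3) or n x 3 matrix, mm.
#' @return Same shape as `points`.
#' @export
applyPose <- function(p, points) {
  R <- rotationFromAngles(p@angles)
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else as.matrix(points)
  if (!all(is.finite(pts))) stop("points must be finite")
  out <- sweep(pts, 2, p@center) %*% t(R)
  out <- sweep(out, 2, p@center + p@translation, "+")
  if (one) as.numeric(out) else out
}

#' Compose two poses
#'
#' `applyPose(composePose(a, b), x)` equals `applyPose(a, applyPose(b, x))`.
#' Both poses must share a rotation center; re-center one with
#' [recenterPose()] first if they do not. The result uses that center.
#'
#' @param a,b [RigidPose-class] objects.
#' @export
composePose <- function(a, b) {
  if (max(abs(a@center - b@center)) > 1e-9)
    stop("poses have different rotation centers; recenterPose() one first")
  poseFromMatrix(poseMatrix(a) %*% poseMatrix(b), center = a@center)
}

#' Invert a pose
#'
#' @param p [RigidPose-class].
#' @return The pose with `composePose(p, invertPose(p))` equal to identity.
#' @export
invertPose <- function(p) {
  M <- poseMatrix(p)
  Mi <- diag(4)
  R <- t(M[1:3, 1:3])
  Mi[1:3, 1:3] <- R
  Mi[1:3, 4] <- -R %*% M[1:3, 4]
  poseFromMatrix(Mi, center = p@center)
}

#' Re-express a pose about a different rotation center
#'
#' The underlying rigid map is unchanged; only the (translation, center)
#' split changes.
#' @param p [RigidPose-class].
#' @param center new rotation center, mm.
#' @export
recenterPose <- function(p, center) poseFromMatrix(poseMatrix(p), center)

#' @describeIn rigidPose the 6-vector (tx, ty, tz, wx, wy, wz).
#' @param p a `RigidPose`.
#' @export
poseVector <- function(p) {
  setNames(c(p@translation, p@angles),
           c("tx", "ty", "tz", "wx", "wy", "wz"))
}

setMethod("show", "RigidPose", function(object) {
  cat(sprintf("RigidPose: t = (%.3f, %.3f, %.3f) mm, w = (%.3f, %.3f, %.3f) deg\n",
              object@translation[1], object@translation[2], object@translation[3],
              object@angles[1], object@angles[2], object@angles[3]))
  cat(sprintf("  rotation center (%.2f, %.2f, %.2f) mm\n",
              object@center[1], object@center[2], object@center[3]))
})
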