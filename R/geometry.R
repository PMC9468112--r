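#' Construct a projection geometry
#'
#' Low-level constructor; most users want [makeCArmGeometry()].
#'
#' @param source,detCenter numeric(3) mm.
#' @param detRow,detCol unit 3-vectors along increasing row / column index.
#' @param pixelPitch mm per pixel.
#' @param detDim integer(2) (rows, cols).
#' @param sod source-object (isocenter) distance, mm.
#' @param angulation degrees from AP about the patient y axis.
#' @return A [ProjectionGeometry-class].
#' @export
projectionGeometry <- function(source, detCenter, detRow, detCol,
                               pixelPitch, detDim, sod, angulation = NA_real_) {
  new("ProjectionGeometry",
      source = stopIfNot3(source, "source"),
      detCenter = stopIfNot3(detCenter, "detCenter"),
      detRow = stopIfNot3(detRow, "detRow"),
      detCol = stopIfNot3(detCol, "detCol"),
      pixelPitch = as.numeric(pixelPitch),
      detDim = as.integer(detDim),
      sdd = vnorm(detCenter - source),
      sod = as.numeric(sod),
      angulation = as.numeric(angulation))
}

#' C-arm geometry at a given angulation
#'
#' Builds the cone-beam geometry of a mobile C-arm rotated about the
#' patient's longitudinal (y) axis. At 0 deg (AP) the source sits
#' anteriorly at `iso - (0,0,sod)` and the central ray points dorsally
#' (+z); positive angulation rotates the whole assembly about y around the
#' isocenter. Rows of the image run along +y (cranial), columns along the
#' rotated +x.
#'
#' @param angulation degrees from AP about the patient y axis.
#' @param sdd source-detector distance, mm (default 1000).
#' @param sod source-isocenter distance, mm (default 600).
#' @param pixelPitch detector pixel pitch, mm/px (default 0.3, a typical
#'   flat-panel value; the clinical protocol does not state intrinsics,
#'   so these defaults are configuration, not claims).
#' @param detDim integer(2) detector (rows, cols); default 768 x 768.
#' @param iso isocenter, mm (default origin).
#' @return A [ProjectionGeometry-class].
#' @examples
#' g <- makeCArmGeometry(20)
#' projectPoints(g, c(0, 0, 0)) # principal point
#' @export
makeCArmGeometry <- function(angulation, sdd = 1000, sod = 600,
                             pixelPitch = 0.3, detDim = c(768L, 768L),
                             iso = c(0, 0, 0)) {
  R <- rotationFromAngles(c(0, angulation, 0))
  iso <- stopIfNot3(iso, "iso")
  src <- iso + as.numeric(R %*% c(0, 0, -sod))
  det <- iso + as.numeric(R %*% c(0, 0, sdd - sod))
  projectionGeometry(source = src, detCenter = det,
                     detRow = c(0, 1, 0),
                     detCol = as.numeric(R %*% c(1, 0, 0)),
                     pixelPitch = pixelPitch, detDim = detDim,
                     sod = sod, angulation = angulation)
}

#' Perspective projection of 3D points onto the detector
#'
#' Pinhole projection through the source onto the detector plane, returned
#' as 0-based pixel coordinates (pixel-center convention): the principal
#' point maps to `((rows-1)/2, (cols-1)/2)`.
#'
#' @param g [ProjectionGeometry-class].
#' @param points numeric(3) or n x 3 matrix, mm; each point must lie
#'   strictly between the source plane and the detector.
#' @return n x 2 matrix with columns `row`, `col` (px).
#' @export
projectPoints <- function(g, points) {
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else as.matrix(points)
  w <- (g@detCenter - g@source) / g@sdd
  rel <- sweep(pts, 2, g@source)
  d <- as.numeric(rel %*% w)
  if (any(d <= 1e-9))
    stop("point at or behind the source plane cannot be projected")
  if (any(d >= g@sdd - 1e-9))
    stop("point at or beyond the detector plane cannot be projected")
  q <- rel * (g@sdd / d)                 # detector-plane intersection - source
  qc <- sweep(q, 2, g@detCenter - g@source)
  half <- (g@detDim - 1) / 2
  out <- cbind(row = as.numeric(qc %*% g@detRow) / g@pixelPitch + half[1],
               col = as.numeric(qc %*% g@detCol) / g@pixelPitch + half[2])
  out
}

## Orthonormal frame of a geometry: columns (detRow, detCol, ray axis).
geomFrame <- function(g) {
  w <- (g@detCenter - g@source) / g@sdd
  cbind(g@detRow, g@detCol, w)
}

#' Relative pose between two views
#'
#' The rigid transform mapping view-1 geometry into view-2 geometry, and
#' its rotation angle RAD in degrees. RAD is symmetric in the two views.
#'
#' @param g1,g2 [ProjectionGeometry-class] objects in the same patient
#'   frame.
#' @return A [RelativePose-class].
#' @examples
#' rad(relativeAngulation(makeCArmGeometry(-20), makeCArmGeometry(20))) # 40
#' @export
relativeAngulation <- function(g1, g2) {
  R <- geomFrame(g2) %*% t(geomFrame(g1))
  t <- g2@source - as.numeric(R %*% g1@source)
  relativePose(R, t)
}

#' Construct a relative pose from rotation and translation
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3) mm.
#' @export
relativePose <- function(rotation, translation = c(0, 0, 0)) {
  ang <- rad2deg(acos(clampVec((sum(diag(rotation)) - 1) / 2, -1, 1)))
  new("RelativePose", rotation = rotation,
      translation = stopIfNot3(translation, "translation"),
      rad = ang)
}

#' Rotation angle difference of a relative pose
#'
#' @param rp [RelativePose-class].
#' @return degrees, between 0 and 180.
#' @export
rad <- function(rp) rp@rad

#' Invert a relative pose
#' @param rp [RelativePose-class].
#' @export
invertRelativePose <- function(rp) {
  R <- t(rp@rotation)
  relativePose(R, -as.numeric(R %*% rp@translation))
}

#' Apply a relative pose to a geometry
#'
#' Maps a view-1 geometry into the view-2 geometry it predicts:
#' source, detector center and detector axes are transported by the rigid
#' transform.
#' @param rp [RelativePose-class].
#' @param g [ProjectionGeometry-class].
#' @export
applyRelativePose <- function(rp, g) {
  R <- rp@rotation; t <- rp@translation
  projectionGeometry(source = as.numeric(R %*% g@source + t),
                     detCenter = as.numeric(R %*% g@detCenter + t),
                     detRow = as.numeric(R %*% g@detRow),
                     detCol = as.numeric(R %*% g@detCol),
                     pixelPitch = g@pixelPitch, detDim = g@detDim,
                     sod = g@sod, angulation = NA_real_)
}

#' Re-express a geometry under a pose
#'
#' Returns the geometry `g . t` with
#' `projectPoints(g, applyPose(t, x)) == projectPoints(transformGeometry(g, t), x)`:
#' moving the object by `t` is equivalent to pulling the camera back by
#' `t^-1`.
#'
#' @param g [ProjectionGeometry-class].
#' @param pose [RigidPose-class].
#' @export
transformGeometry <- function(g, pose) {
  Mi <- poseMatrix(invertPose(pose))
  R <- Mi[1:3, 1:3]; m <- Mi[1:3, 4]
  projectionGeometry(source = as.numeric(R %*% g@source + m),
                     detCenter = as.numeric(R %*% g@detCenter + m),
                     detRow = as.numeric(R %*% g@detRow),
                     detCol = as.numeric(R %*% g@detCol),
                     pixelPitch = g@pixelPitch, detDim = g@detDim,
                     sod = g@sod, angulation = NA_real_)
}

#' Downsample a geometry by an integer factor
#'
#' Halved (or coarser) detector used by the multi-resolution registration:
#' pixel pitch grows by `factor`, the pixel count shrinks accordingly, the
#' physical detector stays in place.
#' @param g [ProjectionGeometry-class].
#' @param factor integer >= 1.
#' @export
downsampleGeometry <- function(g, factor = 2L) {
  factor <- as.integer(factor)
  projectionGeometry(source = g@source, detCenter = g@detCenter,
                     detRow = g@detRow, detCol = g@detCol,
                     pixelPitch = g@pixelPitch * factor,
                     detDim = g@detDim %/% factor,
                     sod = g@sod, angulation = g@angulation)
}

#' Serialize / read a geometry as JSON
#'
#' All fields are stored in mm / degrees as documented in
#' [ProjectionGeometry-class].
#' @param g [ProjectionGeometry-class].
#' @param path file path.
#' @export
writeGeometry <- function(g, path) {
  jsonlite::write_json(list(
    source = g@source, detCenter = g@detCenter, detRow = g@detRow,
    detCol = g@detCol, pixelPitch = g@pixelPitch, detDim = g@detDim,
    sdd = g@sdd, sod = g@sod, angulation = g@angulation,
    units = list(length = "mm", angle = "deg", pixels = "0-based")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  projectionGeometry(x$source, x$detCenter, x$detRow, x$detCol,
                     x$pixelPitch, x$detDim, x$sod,
                     if (is.null(x$angulation)) NA_real_ else x$angulation)
}

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf(
    "ProjectionGeometry: %d x %d px @ %.3f mm, SDD %.1f mm, SOD %.1f mm\n",
    object@detDim[1], object@detDim[2], object@pixelPitch, object@sdd,
    object@sod))
  if (is.finite(object@angulation))
    cat(sprintf("  angulation %.1f deg from AP\n", object@angulation))
})

setMethod("show", "RelativePose", function(object) {
  cat(sprintf("RelativePose: RAD %.3f deg, |t| = %.2f mm\n",
              object@rad, vnorm(object@translation)))
})
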