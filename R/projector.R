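#' Construct a volume image
#'
#' @param data 3D array of attenuation values (1/mm).
#' @param spacing numeric(3) mm per voxel.
#' @param origin numeric(3) world position of voxel (1,1,1); the default
#'   centers the volume on the world origin.
#' @return A [VolumeImage-class].
#' @export
volumeImage <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  spacing <- stopIfNot3(spacing, "spacing")
  if (is.null(origin)) origin <- -(dim(data) - 1) * spacing / 2
  new("VolumeImage", data = data, spacing = spacing,
      origin = stopIfNot3(origin, "origin"))
}

#' @describeIn volumeImage the raw array.
#' @param v a `VolumeImage`.
#' @export
imgData <- function(v) v@data

#' @describeIn volumeImage voxel spacing in mm.
#' @export
voxelSpacing <- function(v) v@spacing

#' @describeIn volumeImage world position of voxel (1,1,1) in mm.
#' @export
imgOrigin <- function(v) v@origin

#' @describeIn volumeImage world center of the volume in mm.
#' @export
volumeCenter <- function(v) v@origin + (dim(v@data) - 1) * v@spacing / 2

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f mm, attenuation range [%.4g, %.4g]\n",
              d[1] * object@spacing[1], d[2] * object@spacing[2],
              d[3] * object@spacing[3], min(object@data), max(object@data)))
})

setMethod("show", "FluoroImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s (%s): %d x %d px, range [%.4g, %.4g]\n",
              class(object), object@provenance, d[1], d[2],
              min(object@data), max(object@data)))
})

## Shared ray-casting core; returns a plain matrix for the ROI.
projectCore <- function(v, g, pose = NULL, roi = NULL, step = NULL) {
  if (is.null(step)) step <- 0.5 * min(v@spacing)
  if (step <= 0) stop("step must be > 0")
  if (is.null(roi)) roi <- c(0L, g@detDim[1] - 1L, 0L, g@detDim[2] - 1L)
  if (is.null(pose)) pose <- identityPose()
  Mi <- poseMatrix(invertPose(pose))
  ## degenerate geometry: source inside the volume
  lo <- v@origin - v@spacing / 2
  hi <- v@origin + (dim(v@data) - 0.5) * v@spacing
  if (all(g@source > lo) && all(g@source < hi))
    stop("degenerate geometry: source lies inside the volume")
  cpp_drr_project(as.numeric(v@data), dim(v@data), v@spacing, v@origin,
                  g@source, g@detCenter, g@detRow, g@detCol,
                  g@pixelPitch, g@detDim, as.integer(roi),
                  Mi[1:3, 1:3], Mi[1:3, 4], step)
}

#' Forward-project a volume into a DRR
#'
#' Each detector pixel receives the line integral of the (optionally
#' masked) attenuation volume along the ray from the source to the pixel
#' center, sampled trilinearly at a fixed step. A rigid `pose` applied to
#' the volume is realized by inverse-transforming the rays, so no volume
#' resampling occurs.
#'
#' @param v [VolumeImage-class].
#' @param g [ProjectionGeometry-class].
#' @param pose optional [RigidPose-class] applied to the volume.
#' @param mask optional logical array on the grid of `v`; voxels outside
#'   the mask do not contribute. The grid (and hence the ray sampling
#'   lattice) is unchanged, so masked projections are exactly additive:
#'   splitting a volume over disjoint masks and summing the DRRs
#'   reproduces the full DRR to machine precision.
#' @param step sampling step along the ray, mm; default half the smallest
#'   voxel spacing.
#' @param roi optional integer(4) detector ROI (row0, row1, col0, col1),
#'   0-based inclusive; when given, a plain matrix of that size is
#'   returned instead of a full-detector [DRRImage-class].
#' @return [DRRImage-class], or a matrix if `roi` is non-NULL.
#' @export
forwardProject <- function(v, g, pose = NULL, mask = NULL, step = NULL,
                           roi = NULL) {
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(v@data)))
      stop("mask must match the volume grid")
    v <- volumeImage(v@data * mask, v@spacing, v@origin)
  }
  m <- projectCore(v, g, pose, roi, step)
  if (!is.null(roi)) return(m)
  new("DRRImage", data = m, geometry = g, provenance = "drr")
}

## Crop a masked volume to the mask bounding box (plus one voxel of air so
## trilinear interpolation sees the object boundary).
cropMasked <- function(v, mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(volumeImage(array(0, c(2, 2, 2)), v@spacing, v@origin))
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(v@data))
  dat <- v@data * mask
  dat <- dat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  volumeImage(dat, v@spacing, v@origin + (lo - 1) * v@spacing)
}

#' Render skin-marker spheres analytically
#'
#' Adds, per pixel, the exact line integral `2 mu sqrt(r^2 - d^2)` of each
#' homogeneous radiopaque sphere (`d` = ray-to-center distance).
#'
#' @param g [ProjectionGeometry-class].
#' @param m [MarkerModel-class].
#' @param roi optional detector ROI as in [forwardProject()].
#' @return [DRRImage-class], or a matrix if `roi` is non-NULL.
#' @export
renderMarkers <- function(g, m, roi = NULL) {
  full <- is.null(roi)
  if (full) roi <- c(0L, g@detDim[1] - 1L, 0L, g@detDim[2] - 1L)
  mat <- cpp_render_spheres(m@centers, m@radius, m@attenuation,
                            g@source, g@detCenter, g@detRow, g@detCol,
                            g@pixelPitch, g@detDim, as.integer(roi))
  if (!full) return(mat)
  new("DRRImage", data = mat, geometry = g, provenance = "drr")
}

#' Default noise model of the fluoroscopy simulator
#'
#' `gain` is the unattenuated photon count per pixel driving Poisson-like
#' quantum noise in the line-integral domain (0 disables it), `gaussianSd`
#' an additive electronic-noise term, and `scale`/`offset` an affine
#' detector response change that forces the similarity's intensity scale
#' factor s to matter. Defaults are the package's realistic study
#' conditions; `noiseFree()` switches everything off.
#'
#' @param gain photons per unattenuated pixel (default 20000).
#' @param gaussianSd additive Gaussian sd in line-integral units.
#' @param scale,offset affine intensity response applied last.
#' @export
noiseModel <- function(gain = 20000, gaussianSd = 0.01, scale = 1.3,
                       offset = 0.1) {
  stopifnot(gain >= 0, gaussianSd >= 0, scale > 0)
  list(gain = gain, gaussianSd = gaussianSd, scale = scale, offset = offset)
}

#' @rdname noiseModel
#' @export
noiseFree <- function() noiseModel(gain = 0, gaussianSd = 0, scale = 1,
                                   offset = 0)

#' Simulate one fluoroscopic view
#'
#' Composites the soft-tissue background DRR, each vertebra's DRR under
#' its true pose (rigid per-vertebra motion applied at projection time),
#' and the analytic marker spheres; then applies Poisson-like quantum
#' noise, Gaussian noise, and an affine intensity change. Images live in
#' the line-integral (log-transformed) domain throughout.
#'
#' @param phantom [SpinePhantom-class] with true poses set.
#' @param markers [MarkerModel-class] or NULL.
#' @param g [ProjectionGeometry-class].
#' @param noise a [noiseModel()] list.
#' @param seed integer seed for the noise draws.
#' @param step ray sampling step, mm.
#' @return [FluoroImage-class] with provenance "simulated".
#' @export
simulateFluoro <- function(phantom, markers, g, noise = noiseModel(),
                           seed = 1L, step = NULL) {
  img <- projectCore(phantom@background, g, step = step)
  for (vert in phantom@vertebrae) {
    roi <- vertebraROI(vert, vert@truePose, g, marginPx = 3L)
    if (is.null(roi)) next
    sub <- projectCore(vert@vol, g, pose = vert@truePose, roi = roi,
                       step = step)
    img[(roi[1]:roi[2]) + 1L, (roi[3]:roi[4]) + 1L] <-
      img[(roi[1]:roi[2]) + 1L, (roi[3]:roi[4]) + 1L] + sub
  }
  if (!is.null(markers)) img <- img + renderMarkers(g, markers)@data

  set.seed(deriveSeed(seed, 211L))
  if (noise$gain > 0) {
    counts <- rpois(length(img), noise$gain * exp(-img))
    img[] <- -log(pmax(counts, 0.5) / noise$gain)
  }
  if (noise$gaussianSd > 0)
    img[] <- img + rnorm(length(img), sd = noise$gaussianSd)
  img[] <- noise$scale * img + noise$offset
  new("FluoroImage", data = img, geometry = g, provenance = "simulated")
}

## Detector ROI (0-based inclusive, clamped) covering a vertebra under a
## pose, with a pixel margin; NULL if the projection misses the detector.
vertebraROI <- function(vert, pose, g, marginPx = 5L) {
  bb <- maskBBoxWorld(vert@mask, vert@vol@spacing, vert@vol@origin)
  corners <- applyPose(pose, boxCorners(bb$lo, bb$hi))
  px <- projectPoints(g, corners)
  r0 <- floor(min(px[, 1])) - marginPx; r1 <- ceiling(max(px[, 1])) + marginPx
  c0 <- floor(min(px[, 2])) - marginPx; c1 <- ceiling(max(px[, 2])) + marginPx
  r0 <- max(r0, 0); c0 <- max(c0, 0)
  r1 <- min(r1, g@detDim[1] - 1); c1 <- min(c1, g@detDim[2] - 1)
  if (r1 < r0 || c1 < c0) return(NULL)
  as.integer(c(r0, r1, c0, c1))
}
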