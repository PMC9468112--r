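## Central S4 classes. Conventions (everywhere in the package):
## patient axes x = left-right (+left), y = caudo-cranial (+cranial),
## z = fronto-dorsal (+dorsal); lengths mm; angles degrees.

#' Rigid 6-DOF pose
#'
#' A rigid transform q = (tx, ty, tz, wx, wy, wz) acting on 3D points as
#' `y = R (x - center) + center + t`, with `R` built from the three angles
#' (degrees) applied extrinsically in the order x, then y, then z
#' (`R = Rz Ry Rx`, right-handed). The rotation center is part of the
#' object so that per-vertebra poses (about the vertebral body center) and
#' coarse/global poses (about the volume center) keep comparable
#' translation magnitudes.
#'
#' @slot translation numeric(3), mm.
#' @slot angles numeric(3), degrees (wx, wy, wz).
#' @slot center numeric(3), rotation center, mm.
#' @export
setClass("RigidPose", representation(
  translation = "numeric",
  angles = "numeric",
  center = "numeric"
))

setValidity("RigidPose", function(object) {
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  if (length(object@angles) != 3L || !all(is.finite(object@angles)))
    return("angles must be a finite 3-vector (degrees)")
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  TRUE
})

#' Cone-beam projection geometry
#'
#' Point-source / flat-detector model of one fluoroscopic view. The
#' detector plane is orthogonal to the source-to-detector-center ray (no
#' tilt); pixel coordinates are 0-based with the pixel-center convention,
#' so the principal point maps to pixel `((nrow-1)/2, (ncol-1)/2)`.
#'
#' @slot source numeric(3), X-ray source position, mm.
#' @slot detCenter numeric(3), detector center, mm.
#' @slot detRow numeric(3), unit vector along increasing row index.
#' @slot detCol numeric(3), unit vector along increasing column index.
#' @slot pixelPitch numeric(1), mm per pixel (isotropic).
#' @slot detDim integer(2), (rows, cols).
#' @slot sdd numeric(1), source-detector distance, mm.
#' @slot sod numeric(1), source-object (isocenter) distance, mm.
#' @slot angulation numeric(1), degrees from AP about the patient y axis.
#' @export
setClass("ProjectionGeometry", representation(
  source = "numeric",
  detCenter = "numeric",
  detRow = "numeric",
  detCol = "numeric",
  pixelPitch = "numeric",
  detDim = "integer",
  sdd = "numeric",
  sod = "numeric",
  angulation = "numeric"
))

setClassUnion("GeometryOrNULL", members = c("ProjectionGeometry", "NULL"))

setValidity("ProjectionGeometry", function(object) {
  tol <- 1e-6
  w <- object@detCenter - object@source
  sdd <- sqrt(sum(w^2))
  if (abs(sdd - object@sdd) > 1e-3)
    return("sdd must equal |detCenter - source|")
  w <- w / sdd
  if (abs(sum(object@detRow^2) - 1) > tol || abs(sum(object@detCol^2) - 1) > tol)
    return("detRow/detCol must be unit vectors")
  if (abs(sum(object@detRow * object@detCol)) > tol)
    return("detRow and detCol must be orthogonal")
  if (abs(sum(object@detRow * w)) > tol || abs(sum(object@detCol * w)) > tol)
    return("detector axes must be orthogonal to the central ray")
  if (!(object@sdd > object@sod && object@sod > 0))
    return("need sdd > sod > 0")
  if (length(object@detDim) != 2L || any(object@detDim < 2L))
    return("detDim must be two integers >= 2")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  TRUE
})

#' Relative pose between two views
#'
#' Rigid transform mapping view-1 geometry into view-2 geometry, plus its
#' rotation angle RAD (degrees, between 0 and 180); RAD is invariant under
#' inversion of the transform.
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation numeric(3), mm.
#' @slot rad numeric(1), rotation angle difference, degrees.
#' @export
setClass("RelativePose", representation(
  rotation = "matrix",
  translation = "numeric",
  rad = "numeric"
))

setValidity("RelativePose", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    return("rotation must be orthonormal with det +1")
  if (object@rad < -1e-9 || object@rad > 180 + 1e-9)
    return("rad must lie in [0, 180] degrees")
  TRUE
})

#' 3D attenuation volume
#'
#' Real-valued attenuation grid (1/mm) on a regular, possibly anisotropic
#' lattice. Array dimension 1 is the patient x axis, 2 the y (slice) axis,
#' 3 the z axis; voxel (i, j, k) sits at `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), mm per voxel.
#' @slot origin numeric(3), world position of voxel (1,1,1), mm.
#' @export
setClass("VolumeImage", representation(
  data = "array",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  if (any(object@data < 0)) return("attenuation values must be >= 0")
  TRUE
})

#' 2D projection image
#'
#' A fluoroscopy-like image: pixel grid plus (for simulated data) its true
#' projection geometry. DRRs use the subclass [DRRImage-class].
#'
#' @slot data numeric matrix (rows x cols).
#' @slot geometry the [ProjectionGeometry-class], or NULL for external data.
#' @slot provenance "simulated", "external" or "drr".
#' @export
setClass("FluoroImage", representation(
  data = "matrix",
  geometry = "GeometryOrNULL",
  provenance = "character"
))

setValidity("FluoroImage", function(object) {
  if (!all(is.finite(object@data))) return("image intensities must be finite")
  if (!object@provenance %in% c("simulated", "external", "drr"))
    return("provenance must be simulated, external or drr")
  if (!is.null(object@geometry)) {
    if (!all(dim(object@data) == object@geometry@detDim))
      return("image size must match the geometry's detector size")
  }
  TRUE
})

#' Digitally reconstructed radiograph
#'
#' A [FluoroImage-class] whose pixels are line integrals of an attenuation
#' volume (non-negative before any display transform).
#' @export
setClass("DRRImage", contains = "FluoroImage")

#' One labeled vertebra of a phantom
#'
#' Cropped attenuation excess (bone minus surrounding soft tissue) of one
#' vertebra, its binary masks, the two TRE landmarks and the ground-truth
#' intraoperative pose (about the body center).
#'
#' @slot label character, e.g. "L1".
#' @slot vol [VolumeImage-class], cropped masked attenuation excess.
#' @slot mask logical array, same grid as `vol`.
#' @slot bodyMask logical array, the vertebral-body subset of `mask`.
#' @slot bodyCenter numeric(3), body-center landmark, mm.
#' @slot leftPedicle numeric(3), left-pedicle-center landmark, mm.
#' @slot truePose [RigidPose-class], ground-truth intraoperative pose.
#' @slot registrable logical, FALSE for levels the pipeline must skip.
#' @export
setClass("VertebraModel", representation(
  label = "character",
  vol = "VolumeImage",
  mask = "array",
  bodyMask = "array",
  bodyCenter = "numeric",
  leftPedicle = "numeric",
  truePose = "RigidPose",
  registrable = "logical"
))

setValidity("VertebraModel", function(object) {
  if (!all(dim(object@mask) == dim(object@vol@data)))
    return("mask must match the cropped volume grid")
  bb <- maskBBoxWorld(object@mask, object@vol@spacing, object@vol@origin)
  for (p in list(object@bodyCenter, object@leftPedicle)) {
    if (any(p < bb$lo - 1e-6) || any(p > bb$hi + 1e-6))
      return("landmarks must lie inside the mask bounding box")
  }
  TRUE
})

#' Skin-marker model
#'
#' Radiopaque sphere markers on the dorsal skin surface, confined to a
#' square frame (default 150 x 150 mm) centered over the centered vertebra.
#'
#' @slot centers n x 3 matrix of sphere centers, mm.
#' @slot radius numeric(1), sphere radius, mm.
#' @slot attenuation numeric(1), sphere attenuation, 1/mm.
#' @slot frame numeric(1), frame edge length, mm.
#' @export
setClass("MarkerModel", representation(
  centers = "matrix",
  radius = "numeric",
  attenuation = "numeric",
  frame = "numeric"
))

setValidity("MarkerModel", function(object) {
  if (ncol(object@centers) != 3L) return("centers must be n x 3")
  if (nrow(object@centers) < 5L)
    return("at least five skin markers are required")
  if (object@radius <= 0 || object@attenuation <= 0)
    return("radius and attenuation must be > 0")
  TRUE
})

#' Procedural spine phantom
#'
#' Soft-tissue background volume plus labeled vertebra models; the
#' synthetic stand-in for a segmented baseline CT.
#'
#' @slot background [VolumeImage-class], soft tissue only.
#' @slot vertebrae list of [VertebraModel-class], cranio-caudally ordered.
#' @slot seed integer used to generate the phantom.
#' @export
setClass("SpinePhantom", representation(
  background = "VolumeImage",
  vertebrae = "list",
  seed = "integer"
))

setValidity("SpinePhantom", function(object) {
  if (!length(object@vertebrae)) return("need at least one vertebra")
  if (!all(vapply(object@vertebrae, is, TRUE, "VertebraModel")))
    return("vertebrae must be VertebraModel objects")
  labs <- vapply(object@vertebrae, function(v) v@label, "")
  if (anyDuplicated(labs)) return("vertebra labels must be unique")
  TRUE
})

#' Simulated registration test case
#'
#' Everything one registration run needs, with full ground truth: the
#' phantom (with perturbed true poses), marker model, the two simulated
#' fluoroscopic views with their true geometries, and the resolved
#' configuration.
#'
#' @slot phantom [SpinePhantom-class].
#' @slot markers [MarkerModel-class].
#' @slot fluoro1,fluoro2 [FluoroImage-class] simulated views.
#' @slot rad numeric(1), true rotation angle difference, degrees.
#' @slot config list, fully resolved configuration.
#' @slot seed integer master seed.
#' @export
setClass("SpineTestCase", representation(
  phantom = "SpinePhantom",
  markers = "MarkerModel",
  fluoro1 = "FluoroImage",
  fluoro2 = "FluoroImage",
  rad = "numeric",
  config = "list",
  seed = "integer"
))

#' Similarity configuration
#'
#' Constants of the gradient-difference similarity. `Av`/`Ah` are the
#' maximum vertical/horizontal similarity constants; `NA` means "derive
#' from the fluoro gradient scale" (squared median absolute gradient over
#' the ROI). `s = NA` means "re-estimate the DRR intensity scale by least
#' squares at every evaluation".
#'
#' @slot Av,Ah numeric(1), positive, or NA for automatic.
#' @slot s numeric(1), fixed scale, or NA to estimate.
#' @slot roi optional logical matrix restricting the summed pixels.
#' @export
setClass("SimilarityConfig", representation(
  Av = "numeric",
  Ah = "numeric",
  s = "numeric",
  roi = "ANY"
))

setValidity("SimilarityConfig", function(object) {
  for (a in c(object@Av, object@Ah))
    if (!is.na(a) && a <= 0) return("Av and Ah must be > 0 (or NA = auto)")
  if (!is.null(object@roi) && !is.logical(object@roi))
    return("roi must be NULL or a logical matrix")
  TRUE
})

#' Result of one per-vertebra registration
#'
#' @slot label vertebra label.
#' @slot pose estimated [RigidPose-class] (about the body center).
#' @slot similarity final two-view similarity S1 + S2.
#' @slot s1,s2 per-view similarity split.
#' @slot evals optimizer evaluations used.
#' @slot converged logical; FALSE excludes the vertebra from accuracy
#'   summaries.
#' @slot captured logical; FALSE means no pose was estimated at all.
#' @export
setClass("RegistrationResult", representation(
  label = "character",
  pose = "RigidPose",
  similarity = "numeric",
  s1 = "numeric",
  s2 = "numeric",
  evals = "numeric",
  converged = "logical",
  captured = "logical"
))
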