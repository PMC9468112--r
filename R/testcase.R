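#' Default test-case configuration
#'
#' The resolved factor set of one simulated registration case. Defaults
#' are the package's study conditions: five captured vertebrae, an
#' opposed-angulation pair (here +/-45 deg, i.e. a nominal RAD of 90),
#' eight skin markers in a 150 mm frame, a 200 mm detector-skin distance,
#' and the realistic [noiseModel()]. `angulationJitter` (degrees,
#' uniform, per view) models the manually rotated C-arm whose exact
#' angulation is unknown; the marker-based pose estimation recovers it.
#'
#' @param nVertebrae vertebrae in the phantom.
#' @param dim,spacing phantom grid (see [makeSpinePhantom()]).
#' @param angulations numeric(2), nominal view angulations, degrees from
#'   AP, each within +/-45.
#' @param markerCount 5 to 9 markers.
#' @param detectorSkinDistance mm, from AP position (paper setup: 200 or
#'   300).
#' @param sdd,pixelPitch,detDim C-arm intrinsics (not stated by the
#'   clinical protocol; configuration, not claims).
#' @param noise a [noiseModel()].
#' @param perturb per-vertebra ranges from [perturbRanges()].
#' @param globalShift,globalTilt half-widths of the shared patient
#'   repositioning pose (mm / degrees).
#' @param angulationJitter degrees, uniform half-width per view.
#' @param frame marker frame edge, mm.
#' @param excludeLabels labels flagged non-registrable (e.g. sacral).
#' @param sliceThickness if non-NULL, the registration-side volume is
#'   degraded to this slice thickness (mm) while fluoroscopy is simulated
#'   from the original volume.
#' @param step ray-sampling step override, mm.
#' @return Named list ("fluororegConfig").
#' @export
caseConfig <- function(nVertebrae = 5L, dim = c(96L, 96L, 96L),
                       spacing = c(1.5, 1.5, 1.5),
                       angulations = c(-45, 45), markerCount = 8L,
                       detectorSkinDistance = 200, sdd = 1000,
                       pixelPitch = 1.2, detDim = c(256L, 256L),
                       noise = noiseModel(), perturb = perturbRanges(),
                       globalShift = 5, globalTilt = 3,
                       angulationJitter = 3, frame = 150,
                       excludeLabels = character(0),
                       sliceThickness = NULL, step = NULL) {
  cfg <- list(nVertebrae = as.integer(nVertebrae), dim = as.integer(dim),
              spacing = spacing, angulations = angulations,
              markerCount = as.integer(markerCount),
              detectorSkinDistance = detectorSkinDistance, sdd = sdd,
              pixelPitch = pixelPitch, detDim = as.integer(detDim),
              noise = noise, perturb = perturb,
              globalShift = globalShift, globalTilt = globalTilt,
              angulationJitter = angulationJitter, frame = frame,
              excludeLabels = excludeLabels,
              sliceThickness = sliceThickness, step = step)
  validateConfig(cfg)
  cfg
}

#' Validate a configuration list
#'
#' Strict: unknown keys are errors, marker counts below five and
#' angulations beyond +/-45 degrees are rejected.
#' @param cfg list as from [caseConfig()].
#' @export
validateConfig <- function(cfg) {
  known <- names(formals(caseConfig))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("missing configuration keys: ", paste(missing, collapse = ", "))
  if (cfg$markerCount < 5L)
    stop("insufficient markers: a minimum of five skin markers is required")
  if (length(cfg$angulations) != 2L || any(abs(cfg$angulations) > 45))
    stop("angulations must be two values within +/-45 degrees")
  invisible(TRUE)
}

#' Nominal RAD of a configuration
#' @param cfg list as from [caseConfig()].
#' @export
nominalRad <- function(cfg) abs(diff(cfg$angulations))

#' Build a complete simulated test case
#'
#' Generates the phantom, draws the shared and per-vertebra ground-truth
#' poses, places the markers, derives both view geometries (including the
#' angulation jitter), and simulates both fluoroscopic images. Everything
#' is a pure function of `(config, seed)`.
#'
#' @param config list from [caseConfig()].
#' @param seed integer master seed; sub-seeds are derived per stage.
#' @return A [SpineTestCase-class].
#' @export
makeTestCase <- function(config = caseConfig(), seed = 1L) {
  validateConfig(config)
  phantom <- makeSpinePhantom(config$nVertebrae, config$dim, config$spacing,
                              seed = deriveSeed(seed, 1L))
  set.seed(deriveSeed(seed, 2L))
  u <- runif(6, -1, 1)
  global <- rigidPose(u[1:3] * config$globalShift,
                      u[4:6] * config$globalTilt,
                      center = volumeCenter(phantom@background))
  phantom <- perturbSpine(phantom, config$perturb, global,
                          seed = deriveSeed(seed, 3L))
  markers <- placeMarkers(phantom, config$markerCount, config$frame,
                          seed = deriveSeed(seed, 4L))

  extent <- dim(phantom@background@data) * phantom@background@spacing
  skinTop <- 0.40 * extent[3] + 3
  sod <- config$sdd - config$detectorSkinDistance - skinTop
  if (sod <= 100)
    stop("detector-skin distance too large for this source-detector distance")
  set.seed(deriveSeed(seed, 5L))
  trueAng <- config$angulations +
    runif(2, -1, 1) * config$angulationJitter
  g1 <- makeCArmGeometry(trueAng[1], sdd = config$sdd, sod = sod,
                         pixelPitch = config$pixelPitch,
                         detDim = config$detDim)
  g2 <- makeCArmGeometry(trueAng[2], sdd = config$sdd, sod = sod,
                         pixelPitch = config$pixelPitch,
                         detDim = config$detDim)
  f1 <- simulateFluoro(phantom, markers, g1, config$noise,
                       seed = deriveSeed(seed, 6L), step = config$step)
  f2 <- simulateFluoro(phantom, markers, g2, config$noise,
                       seed = deriveSeed(seed, 7L), step = config$step)
  if (length(config$excludeLabels)) {
    for (i in seq_along(phantom@vertebrae))
      if (phantom@vertebrae[[i]]@label %in% config$excludeLabels)
        phantom@vertebrae[[i]]@registrable <- FALSE
  }
  if (!is.null(config$sliceThickness))
    phantom <- degradePhantom(phantom, config$sliceThickness)
  new("SpineTestCase", phantom = phantom, markers = markers,
      fluoro1 = f1, fluoro2 = f2, rad = nominalRad(config),
      config = config, seed = as.integer(seed))
}

#' True relative pose of a simulated case
#'
#' Computed from the two stored ground-truth geometries; its [rad()]
#' includes the angulation jitter and therefore differs slightly from the
#' nominal stratum RAD in `tc@rad`.
#' @param tc [SpineTestCase-class].
#' @export
trueRelativePose <- function(tc)
  relativeAngulation(tc@fluoro1@geometry, tc@fluoro2@geometry)

setMethod("show", "SpineTestCase", function(object) {
  cat(sprintf(
    "SpineTestCase: %d vertebrae, %d markers, nominal RAD %.0f deg (true %.2f)\n",
    length(object@phantom@vertebrae), nrow(object@markers@centers),
    object@rad, rad(trueRelativePose(object))))
  cat(sprintf("  views %d x %d px, seed %d\n", dim(object@fluoro1@data)[1],
              dim(object@fluoro1@data)[2], object@seed))
})
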