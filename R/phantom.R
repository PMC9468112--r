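## Procedural spine phantom: stylized vertebrae (ellipsoidal body with a
## denser cortical shell + posterior ring + pedicle struts + spinous
## process) stacked along the cranio-caudal axis inside an elliptical
## soft-tissue torso. Stylized geometry gives analytic landmark ground
## truth while still producing the structured gradients the registration
## needs.

spineLabels <- c(paste0("T", 1:12), paste0("L", 1:5), "S1")

#' Generate a synthetic spine phantom
#'
#' Builds a soft-tissue torso volume and `nVertebrae` stacked vertebra
#' models with per-vertebra masks, analytic landmarks (body center, left
#' pedicle center) and identity ground-truth poses. The generator is a
#' pure function of its arguments and `seed`.
#'
#' @param nVertebrae number of vertebrae (>= 2; default 5, the number of
#'   levels captured per view in the intended workflow).
#' @param dim integer(3) voxel counts (x, y, z).
#' @param spacing numeric(3) voxel spacing, mm; dimension 2 is the slice
#'   (caudo-cranial) axis, so anisotropic CT protocols set `spacing[2]`.
#' @param seed integer seed.
#' @param centeredLabel label given to the middle vertebra (default "L1").
#' @return A [SpinePhantom-class]; vertebrae are ordered cranio-caudally.
#' @examples
#' ph <- makeSpinePhantom(nVertebrae = 3, dim = c(48, 64, 48),
#'                        spacing = c(2, 2, 2), seed = 1)
#' vapply(ph@vertebrae, function(v) v@label, "")
#' @export
makeSpinePhantom <- function(nVertebrae = 5L, dim = c(96L, 96L, 96L),
                             spacing = c(1.5, 1.5, 1.5), seed = 1L,
                             centeredLabel = "L1") {
  nVertebrae <- as.integer(nVertebrae)
  if (nVertebrae < 2L) stop("need at least 2 vertebrae")
  spacing <- stopIfNot3(spacing, "spacing")
  dim <- as.integer(dim)
  extent <- dim * spacing
  yMargin <- max(8, 0.08 * extent[2])
  pitch <- (extent[2] - 2 * yMargin) / nVertebrae
  if (pitch < 18) stop("volume too small to hold the requested spine")
  if (extent[1] < 60 || extent[3] < 60)
    stop("volume too small to hold the requested spine")

  set.seed(deriveSeed(seed, 11L))
  origin <- -(dim - 1) * spacing / 2
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]

  ## soft-tissue torso: elliptical cylinder + low-frequency texture
  ax <- 0.47 * extent[1]; bz <- 0.40 * extent[3]
  muSoft <- 0.018
  inTorso <- outer(xs^2 / ax^2, zs^2 / bz^2, "+") <= 1      # (nx, nz)
  bg <- array(0, dim)
  phase <- runif(6, 0, 2 * pi)
  cx <- cos(2 * pi * xs / 47 + phase[1])
  cy <- cos(2 * pi * ys / 61 + phase[2])
  cz <- cos(2 * pi * zs / 53 + phase[3])
  cx2 <- cos(2 * pi * xs / 29 + phase[4])
  cy2 <- cos(2 * pi * ys / 37 + phase[5])
  cz2 <- cos(2 * pi * zs / 41 + phase[6])
  tex <- 0.0012 * (outer(cx, cy) %o% cz) + 0.0009 * (outer(cx2, cy2) %o% cz2)
  for (k in seq_len(dim[3]))
    bg[, , k] <- (muSoft + tex[, , k]) * inTorso[, k]
  bg <- pmax(bg, 0)
  background <- volumeImage(bg, spacing, origin)

  ## label window centered on centeredLabel
  ci <- match(centeredLabel, spineLabels)
  if (is.na(ci)) stop("unknown centered label")
  first <- ci - (ceiling(nVertebrae / 2) - 1L)
  if (first < 1L || first + nVertebrae - 1L > length(spineLabels))
    stop("label window out of range")
  labs <- spineLabels[seq(first, length.out = nVertebrae)]  # cranial last?
  ## store cranio-caudally: element 1 = most cranial = first label
  yTop <- nVertebrae * pitch / 2

  ## per-vertebra shape (slight deterministic jitter for realism)
  a0 <- 0.60 * pitch; b0 <- 0.36 * pitch; c0 <- 0.46 * pitch
  zSpine <- -0.08 * extent[3]
  vertebrae <- vector("list", nVertebrae)
  for (v in seq_len(nVertebrae)) {
    yc <- yTop - pitch * (v - 0.5)
    jit <- runif(5, -1, 1)
    a <- a0 * (1 + 0.05 * jit[1]); b <- b0 * (1 + 0.04 * jit[2])
    cc <- c0 * (1 + 0.05 * jit[3])
    x0 <- 1.2 * jit[4]; z0 <- zSpine + 1.5 * jit[5]
    ringR <- 0.34 * pitch; tube <- 0.13 * pitch
    zRing <- z0 + cc + 0.22 * pitch
    pedX <- 0.30 * pitch; pedR <- 0.13 * pitch
    spinR <- 0.11 * pitch; zSpin1 <- zRing + ringR + 0.28 * pitch

    ## crop ranges (indices)
    lo <- c(x0 - a - 3, yc - 0.45 * pitch, z0 - cc - 3)
    hi <- c(x0 + a + 3, yc + 0.45 * pitch, zSpin1 + 3)
    il <- pmax(floor((lo - origin) / spacing) + 1, 1)
    ih <- pmin(ceiling((hi - origin) / spacing) + 1, dim)
    sx <- xs[il[1]:ih[1]]; sy <- ys[il[2]:ih[2]]; sz <- zs[il[3]:ih[3]]
    nsub <- c(length(sx), length(sy), length(sz))
    X <- array(sx, nsub)
    Y <- aperm(array(sy, nsub[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(sz, nsub[c(3, 1, 2)]), c(2, 3, 1))

    rho2 <- (X - x0)^2 / a^2 + (Y - yc)^2 / b^2 + (Z - z0)^2 / cc^2
    body <- rho2 <= 1
    shell <- rho2 <= 1 & rho2 > 0.72^2
    ringD <- (sqrt((X - x0)^2 + (Z - zRing)^2) - ringR)^2 + 0 * Y
    ring <- ringD <= tube^2 & abs(Y - yc) <= 0.28 * pitch
    ped <- ((abs(X - (x0 + pedX)) <= pedR) | (abs(X - (x0 - pedX)) <= pedR)) &
      abs(Y - yc) <= pedR & Z >= z0 + 0.4 * cc & Z <= zRing
    spin <- (X - x0)^2 + (Y - yc)^2 <= spinR^2 & Z >= zRing & Z <= zSpin1

    bone <- array(0, nsub)
    bone[body] <- 0.032
    bone[shell] <- 0.065
    bone[ring | ped | spin] <- pmax(bone[ring | ped | spin], 0.055)
    mask <- bone > 0
    bgcrop <- bg[il[1]:ih[1], il[2]:ih[2], il[3]:ih[3], drop = FALSE]
    excess <- pmax(bone - bgcrop, 0) * mask
    subOrigin <- origin + (il - 1) * spacing
    pedMidZ <- (z0 + 0.4 * cc + zRing) / 2
    vertebrae[[v]] <- new("VertebraModel",
      label = labs[v],
      vol = volumeImage(excess, spacing, subOrigin),
      mask = mask, bodyMask = body,
      bodyCenter = c(x0, yc, z0),
      leftPedicle = c(x0 + pedX, yc, pedMidZ),
      truePose = identityPose(center = c(x0, yc, z0)),
      registrable = TRUE)
  }
  new("SpinePhantom", background = background, vertebrae = vertebrae,
      seed = as.integer(seed))
}

#' @describeIn makeSpinePhantom vertebra labels, cranio-caudal order.
#' @param phantom a `SpinePhantom`.
#' @export
vertebraLabels <- function(phantom)
  vapply(phantom@vertebrae, function(v) v@label, "")

#' @describeIn makeSpinePhantom fetch one vertebra by label.
#' @param label vertebra label such as "L1".
#' @export
getVertebra <- function(phantom, label) {
  i <- match(label, vertebraLabels(phantom))
  if (is.na(i)) stop("no vertebra labeled ", label)
  phantom@vertebrae[[i]]
}

#' @describeIn makeSpinePhantom the centered (middle) vertebra's label.
#' @export
centeredLabel <- function(phantom) {
  labs <- vertebraLabels(phantom)
  labs[ceiling(length(labs) / 2)]
}

#' Compose the full baseline volume
#'
#' Soft-tissue background plus every vertebra at its baseline (identity)
#' position: the synthetic stand-in for the patient's baseline CT.
#' @param phantom [SpinePhantom-class].
#' @return [VolumeImage-class].
#' @export
baselineVolume <- function(phantom) {
  bg <- phantom@background
  dat <- bg@data
  for (v in phantom@vertebrae) {
    il <- round((v@vol@origin - bg@origin) / bg@spacing) + 1
    ih <- il + dim(v@vol@data) - 1
    dat[il[1]:ih[1], il[2]:ih[2], il[3]:ih[3]] <-
      dat[il[1]:ih[1], il[2]:ih[2], il[3]:ih[3]] + v@vol@data
  }
  volumeImage(dat, bg@spacing, bg@origin)
}

setMethod("show", "SpinePhantom", function(object) {
  d <- dim(object@background@data)
  cat(sprintf("SpinePhantom: %d vertebrae (%s), %d x %d x %d voxels\n",
              length(object@vertebrae),
              paste(vertebraLabels(object), collapse = ", "),
              d[1], d[2], d[3]))
})

#' Per-vertebra perturbation ranges
#'
#' Half-widths of the uniform per-vertebra pose perturbation. Defaults are
#' the per-vertebra positional-change bounds the registration is expected
#' to absorb: up to 5 degrees of rotation about the x axis and up to 2 mm
#' of translation along the z axis; the other four components default to
#' zero but are configurable.
#'
#' @param tx,ty,tz translation half-widths, mm.
#' @param rx,ry,rz rotation half-widths, degrees.
#' @export
perturbRanges <- function(tx = 0, ty = 0, tz = 2, rx = 5, ry = 0, rz = 0) {
  r <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (any(r < 0)) stop("ranges must be >= 0")
  r
}

#' Draw the intraoperative per-vertebra poses
#'
#' Gives every vertebra an independent random rigid pose, uniform within
#' `ranges`, about its own body center; optionally composed with a shared
#' global pose (patient repositioning between CT and fluoroscopy) about
#' the volume center.
#'
#' @param phantom [SpinePhantom-class].
#' @param ranges half-widths from [perturbRanges()].
#' @param global optional shared [RigidPose-class] applied to all
#'   vertebrae (composed after the local perturbation).
#' @param seed integer seed; the same seed reproduces the same poses.
#' @return The phantom with `truePose` set on every vertebra.
#' @export
perturbSpine <- function(phantom, ranges = perturbRanges(), global = NULL,
                         seed = 1L) {
  set.seed(deriveSeed(seed, 29L))
  for (i in seq_along(phantom@vertebrae)) {
    v <- phantom@vertebrae[[i]]
    u <- runif(6, -1, 1)
    local <- rigidPose(translation = u[1:3] * ranges[c("tx", "ty", "tz")],
                       angles = u[4:6] * ranges[c("rx", "ry", "rz")],
                       center = v@bodyCenter)
    pose <- if (is.null(global)) local else
      composePose(recenterPose(global, v@bodyCenter), local)
    v@truePose <- pose
    phantom@vertebrae[[i]] <- v
  }
  phantom
}

#' Place radiopaque skin markers
#'
#' Random non-overlapping sphere markers on the dorsal skin surface of the
#' torso, inside a square frame centered over the centered vertebra. At
#' least five markers are required for registration.
#'
#' @param phantom [SpinePhantom-class].
#' @param count number of markers, 5 to 9 typical.
#' @param frame frame edge length, mm (default 150: a 15 x 15 cm frame).
#' @param seed integer seed.
#' @param radius sphere radius, mm.
#' @param attenuation sphere attenuation, 1/mm.
#' @param minSep minimum center separation, mm.
#' @return A [MarkerModel-class].
#' @export
placeMarkers <- function(phantom, count = 8L, frame = 150, seed = 1L,
                         radius = 2, attenuation = 1.2, minSep = 15) {
  count <- as.integer(count)
  if (count < 5L)
    stop("insufficient markers: a minimum of five skin markers is required")
  bg <- phantom@background
  extent <- dim(bg@data) * bg@spacing
  ax <- 0.47 * extent[1]; bz <- 0.40 * extent[3]
  mid <- getVertebra(phantom, centeredLabel(phantom))
  cx <- 0; cy <- mid@bodyCenter[2]
  set.seed(deriveSeed(seed, 43L))
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < count) {
    tries <- tries + 1L
    if (tries > 2000L) stop("could not place non-overlapping markers")
    x <- cx + runif(1, -frame / 2, frame / 2)
    y <- cy + runif(1, -frame / 2, frame / 2)
    if (abs(x) > 0.85 * ax) next
    z <- bz * sqrt(1 - (x / ax)^2) + 1
    if (nrow(centers) &&
        min(sqrt(rowSums(sweep(centers, 2, c(x, y, z))^2))) < minSep) next
    centers <- rbind(centers, c(x, y, z))
  }
  dimnames(centers) <- NULL
  new("MarkerModel", centers = centers, radius = radius,
      attenuation = attenuation, frame = frame)
}

#' Resample a volume to a thicker slice spacing
#'
#' Emulates a coarser CT protocol: slab-averages the volume along the
#' slice (y) axis with a box of width `thickness` and resamples onto a
#' lattice with that spacing (volume center preserved). Landmarks are
#' world coordinates and therefore unchanged.
#'
#' @param v [VolumeImage-class].
#' @param thickness new slice thickness, mm; must be >= the current slice
#'   spacing.
#' @return [VolumeImage-class] with spacing `(sx, thickness, sz)`.
#' @export
resampleSliceThickness <- function(v, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  sy <- v@spacing[2]
  if (thickness < sy - 1e-9)
    stop("thickness must be >= the current slice spacing")
  d <- dim(v@data)
  nyNew <- max(1L, as.integer(round(d[2] * sy / thickness)))
  centerY <- v@origin[2] + (d[2] - 1) * sy / 2
  originY <- centerY - (nyNew - 1) * thickness / 2
  ## overlap weights of the averaging box with each original slice
  W <- matrix(0, nyNew, d[2])
  oldLo <- v@origin[2] + (seq_len(d[2]) - 1.5) * sy
  for (q in seq_len(nyNew)) {
    bLo <- originY + (q - 1) * thickness - thickness / 2
    bHi <- bLo + thickness
    ov <- pmin(bHi, oldLo + sy) - pmax(bLo, oldLo)
    ov <- pmax(ov, 0)
    if (sum(ov) > 0) W[q, ] <- ov / sum(ov)
  }
  perm <- aperm(v@data, c(2, 1, 3))
  dim(perm) <- c(d[2], d[1] * d[3])
  res <- W %*% perm
  dim(res) <- c(nyNew, d[1], d[3])
  out <- aperm(res, c(2, 1, 3))
  volumeImage(out, c(v@spacing[1], thickness, v@spacing[3]),
              c(v@origin[1], originY, v@origin[3]))
}

#' Degrade a phantom's baseline volume to a thicker slice protocol
#'
#' Applies [resampleSliceThickness()] to the background and to every
#' vertebra's cropped volume and masks. Simulated fluoroscopy should be
#' generated from the original phantom (the intraoperative scene is not
#' degraded); the degraded phantom stands in for a coarse baseline CT on
#' the registration side.
#'
#' @param phantom [SpinePhantom-class].
#' @param thickness new slice thickness, mm.
#' @return Degraded [SpinePhantom-class].
#' @export
degradePhantom <- function(phantom, thickness) {
  phantom@background <- resampleSliceThickness(phantom@background, thickness)
  for (i in seq_along(phantom@vertebrae)) {
    v <- phantom@vertebrae[[i]]
    sp <- v@vol@spacing; or <- v@vol@origin
    resampMask <- function(m) {
      mv <- resampleSliceThickness(
        volumeImage(array(as.numeric(m), dim(m)), sp, or), thickness)
      array(mv@data > 0.25, dim(mv@data))
    }
    v@mask <- resampMask(v@mask)
    v@bodyMask <- resampMask(v@bodyMask)
    v@vol <- resampleSliceThickness(v@vol, thickness)
    phantom@vertebrae[[i]] <- v
  }
  phantom
}
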