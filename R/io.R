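## File interfaces: NIfTI volumes, 16-bit TIFF images with JSON sidecars,
## pose/landmark tables, test-case directories.

#' Write / read a volume as NIfTI
#'
#' The grid is stored at full double precision; voxel spacing goes into
#' `pixdim` and the world origin into the sform/qform offset, so a
#' write-read round trip reproduces grid and spacing bit-identically.
#'
#' @param v [VolumeImage-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
writeVolume <- function(v, path) {
  img <- RNifti::asNifti(structure(v@data, pixdim = v@spacing),
                         datatype = "double")
  xf <- diag(4)
  diag(xf)[1:3] <- v@spacing
  xf[1:3, 4] <- v@origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @return `readVolume`: a [VolumeImage-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  if (any(spacing <= 0)) stop("volume lacks positive voxel spacing")
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  volumeImage(array(as.numeric(img), dim(img)[1:3]), spacing, origin)
}

#' Write / read a 2D image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are affinely mapped onto the 16-bit range; the mapping and
#' the projection geometry (if any) go into `<path>.json`. Reading
#' inverts the mapping, so a second write-read cycle is lossless.
#'
#' @param f [FluoroImage-class] or [DRRImage-class].
#' @param path file path (`.tif`).
#' @export
writeFluoro <- function(f, path) {
  x <- f@data
  mn <- min(x); mx <- max(x)
  scale <- if (mx > mn) mx - mn else 1
  u <- round((x - mn) / scale * 65535) / 65535
  tiff::writeTIFF(u, path, bits.per.sample = 16L)
  side <- list(min = mn, max = mx, provenance = f@provenance,
               class = class(f)[1])
  if (!is.null(f@geometry)) {
    g <- f@geometry
    side$geometry <- list(source = g@source, detCenter = g@detCenter,
                          detRow = g@detRow, detCol = g@detCol,
                          pixelPitch = g@pixelPitch, detDim = g@detDim,
                          sod = g@sod, angulation = g@angulation)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFluoro
#' @return `readFluoro`: a [FluoroImage-class] (or [DRRImage-class]).
#' @export
readFluoro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  u <- tiff::readTIFF(path)
  scale <- if (side$max > side$min) side$max - side$min else 1
  x <- side$min + u * scale
  g <- NULL
  if (!is.null(side$geometry)) {
    gg <- side$geometry
    g <- projectionGeometry(gg$source, gg$detCenter, gg$detRow, gg$detCol,
                            gg$pixelPitch, gg$detDim, gg$sod,
                            if (is.null(gg$angulation)) NA_real_ else
                              gg$angulation)
  }
  cls <- if (identical(side$class, "DRRImage")) "DRRImage" else "FluoroImage"
  new(cls, data = x, geometry = g, provenance = side$provenance)
}

#' Write a pose table as CSV
#'
#' One row per pose: the 6-vector plus the rotation center.
#' @param poses named list of [RigidPose-class].
#' @param path file path.
#' @export
writePoses <- function(poses, path) {
  tab <- do.call(rbind, lapply(names(poses), function(nm) {
    p <- poses[[nm]]
    data.frame(label = nm, tx = p@translation[1], ty = p@translation[2],
               tz = p@translation[3], wx = p@angles[1], wy = p@angles[2],
               wz = p@angles[3], cx = p@center[1], cy = p@center[2],
               cz = p@center[3])
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoses
#' @export
readPoses <- function(path) {
  tab <- read.csv(path)
  out <- lapply(seq_len(nrow(tab)), function(i)
    rigidPose(c(tab$tx[i], tab$ty[i], tab$tz[i]),
              c(tab$wx[i], tab$wy[i], tab$wz[i]),
              c(tab$cx[i], tab$cy[i], tab$cz[i])))
  names(out) <- tab$label
  out
}

#' Write / read a test case as a self-describing directory
#'
#' The directory holds the two fluoroscopic views (16-bit TIFF + JSON
#' sidecars), the composed baseline volume (NIfTI), landmark and
#' true-pose tables (CSV) and a JSON manifest with the fully resolved
#' configuration and master seed. Because every generator is a pure
#' function of (config, seed), `readTestCase` rebuilds the phantom
#' deterministically from the manifest and re-attaches the stored images.
#'
#' @param tc [SpineTestCase-class].
#' @param dir directory (created if needed).
#' @export
writeTestCase <- function(tc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFluoro(tc@fluoro1, file.path(dir, "fluoro1.tif"))
  writeFluoro(tc@fluoro2, file.path(dir, "fluoro2.tif"))
  writeVolume(baselineVolume(tc@phantom), file.path(dir, "baseline.nii.gz"))
  lmk <- do.call(rbind, lapply(tc@phantom@vertebrae, function(v)
    data.frame(label = v@label, bodyX = v@bodyCenter[1],
               bodyY = v@bodyCenter[2], bodyZ = v@bodyCenter[3],
               pedX = v@leftPedicle[1], pedY = v@leftPedicle[2],
               pedZ = v@leftPedicle[3])))
  write.csv(lmk, file.path(dir, "landmarks.csv"), row.names = FALSE)
  poses <- lapply(tc@phantom@vertebrae, function(v) v@truePose)
  names(poses) <- vertebraLabels(tc@phantom)
  writePoses(poses, file.path(dir, "true_poses.csv"))
  cfg <- tc@config
  cfg$noise <- unclass(cfg$noise)
  cfg$perturb <- as.list(cfg$perturb)
  jsonlite::write_json(
    list(config = cfg, seed = tc@seed, rad = tc@rad,
         markers = list(centers = tc@markers@centers,
                        radius = tc@markers@radius,
                        attenuation = tc@markers@attenuation)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTestCase
#' @export
readTestCase <- function(dir) {
  man <- file.path(dir, "manifest.json")
  for (f in c(man, file.path(dir, c("fluoro1.tif", "fluoro2.tif"))))
    if (!file.exists(f)) stop("incomplete case directory: missing ", basename(f))
  x <- jsonlite::read_json(man, simplifyVector = TRUE)
  cfg <- x$config
  cfg$dim <- as.integer(cfg$dim)
  cfg$detDim <- as.integer(cfg$detDim)
  cfg$markerCount <- as.integer(cfg$markerCount)
  cfg$nVertebrae <- as.integer(cfg$nVertebrae)
  cfg$perturb <- unlist(cfg$perturb)
  cfg$excludeLabels <- as.character(unlist(cfg$excludeLabels))
  for (key in c("sliceThickness", "step"))
    if (length(cfg[[key]]) == 0L) cfg[key] <- list(NULL)
  tc <- makeTestCase(cfg, seed = as.integer(x$seed))
  tc@fluoro1 <- readFluoro(file.path(dir, "fluoro1.tif"))
  tc@fluoro2 <- readFluoro(file.path(dir, "fluoro2.tif"))
  tc
}
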