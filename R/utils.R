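## Internal helpers.

## World-coordinate bounding box of a logical mask living on the grid
## described by (spacing, origin). Returns list(lo, hi) in mm.
maskBBoxWorld <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  lo <- origin + (apply(idx, 2, min) - 1) * spacing
  hi <- origin + (apply(idx, 2, max) - 1) * spacing
  list(lo = as.numeric(lo), hi = as.numeric(hi))
}

## Corner points (8 x 3) of a world-space axis-aligned box.
boxCorners <- function(lo, hi) {
  as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                        z = c(lo[3], hi[3])))
}

## Deterministic sub-seed derivation: all randomness flows from one master
## seed; stage/replicate indices map to distinct 31-bit seeds.
deriveSeed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

## Degrees <-> radians
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(x) sqrt(sum(x^2))

## Clamp numeric vector into [lo, hi] elementwise.
clampVec <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopIfNot3 <- function(x, what) {
  if (length(x) != 3L || !is.numeric(x) || !all(is.finite(x)))
    stop(what, " must be a finite numeric 3-vector")
  as.numeric(x)
}
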