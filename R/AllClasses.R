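#' @import methods
NULL

#' Pinhole camera intrinsics
#'
#' Holds the calibration constants needed to convert pixel extents observed
#' at a known depth into millimetres: the horizontal and vertical focal
#' lengths \code{fw}, \code{fh} (pixels), the principal point
#' \code{cx}, \code{cy} (pixels), and \code{depthScale}, the number of
#' millimetres represented by one count of the depth map.
#'
#' @slot fw horizontal focal length, pixels.
#' @slot fh vertical focal length, pixels.
#' @slot cx,cy principal point, pixels.
#' @slot depthScale millimetres per depth-map count.
#' @aliases CameraIntrinsics-class
#' @exportClass CameraIntrinsics
setClass("CameraIntrinsics",
  representation(fw = "numeric", fh = "numeric",
                 cx = "numeric", cy = "numeric",
                 depthScale = "numeric"),
  prototype(fw = 700, fh = 700, cx = 320, cy = 240, depthScale = 1))

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  for (s in c("fw", "fh", "cx", "cy", "depthScale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(object@fw) == 1L && is.finite(object@fw) && object@fw <= 0)
    msg <- c(msg, "'fw' must be > 0")
  if (length(object@fh) == 1L && is.finite(object@fh) && object@fh <= 0)
    msg <- c(msg, "'fh' must be > 0")
  if (length(object@depthScale) == 1L && is.finite(object@depthScale) &&
      object@depthScale <= 0)
    msg <- c(msg, "'depthScale' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct camera intrinsics
#'
#' @param fw,fh focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param depthScale millimetres per depth-map count.
#' @return A \linkS4class{CameraIntrinsics} object.
#' @examples
#' intr <- CameraIntrinsics(fw = 1000, fh = 1000, cx = 320, cy = 240)
#' focalLengths(intr)
#' @export
CameraIntrinsics <- function(fw = 700, fh = 700, cx = 320, cy = 240,
                             depthScale = 1) {
  new("CameraIntrinsics", fw = as.numeric(fw), fh = as.numeric(fh),
      cx = as.numeric(cx), cy = as.numeric(cy),
      depthScale = as.numeric(depthScale))
}

#' @describeIn CameraIntrinsics focal lengths \code{c(fw, fh)} in pixels.
#' @param object,x a \code{CameraIntrinsics}.
#' @export
focalLengths <- function(x) c(fw = x@fw, fh = x@fh)

#' @describeIn CameraIntrinsics principal point \code{c(cx, cy)} in pixels.
#' @export
principalPoint <- function(x) c(cx = x@cx, cy = x@cy)

#' @describeIn CameraIntrinsics millimetres per depth count.
#' @export
depthScale <- function(x) x@depthScale

setMethod("show", "CameraIntrinsics", function(object) {
  cat("CameraIntrinsics\n")
  cat(sprintf("  focal lengths : fw=%.2f fh=%.2f px\n", object@fw, object@fh))
  cat(sprintf("  principal pt  : (%.2f, %.2f) px\n", object@cx, object@cy))
  cat(sprintf("  depth scale   : %.4g mm/count\n", object@depthScale))
})

#' Cultivar-specific thresholds and coefficients
#'
#' Bundles every per-cultivar constant of the ripeness and yield models:
#' hue bands for the three maturity stages and the piecewise colour-score
#' coefficients; diameter thresholds and size-score weights; shape-score
#' coefficients and deviation breakpoints; fusion weights; classification
#' thresholds; the ellipticity correction factor \code{k}; and the yield
#' density \code{omega}.
#'
#' Hue bands are half-open on the right except the upper ripe band
#' \code{[330, 360]}, mirroring the convention of the scoring model.
#'
#' @slot name cultivar name.
#' @slot ripeBands 2x2 matrix, rows are the two ripe hue intervals (deg).
#' @slot overripeBand,unripeBand length-2 hue intervals (deg).
#' @slot h1,h2,c1,c2 colour-score coefficients.
#' @slot fallbackScore colour score assigned to hues no band covers.
#' @slot dUnripe,dRipe,dOverripe diameter thresholds, mm.
#' @slot s1,s2,s3 size-score weights.
#' @slot p1,p2,p3 shape-score weights.
#' @slot break1,break2 shape-deviation breakpoints.
#' @slot wc,wd,ws fusion weights (colour, size/diameter, shape); sum to 1.
#' @slot classifyLo,classifyHi ripeness-score classification thresholds.
#' @slot k ellipticity volume correction factor.
#' @slot omega yield density parameter, per mm^3.
#' @aliases CultivarProfile-class
#' @exportClass CultivarProfile
setClass("CultivarProfile",
  representation(name = "character",
                 ripeBands = "matrix",
                 overripeBand = "numeric", unripeBand = "numeric",
                 h1 = "numeric", h2 = "numeric",
                 c1 = "numeric", c2 = "numeric",
                 fallbackScore = "numeric",
                 dUnripe = "numeric", dRipe = "numeric", dOverripe = "numeric",
                 s1 = "numeric", s2 = "numeric", s3 = "numeric",
                 p1 = "numeric", p2 = "numeric", p3 = "numeric",
                 break1 = "numeric", break2 = "numeric",
                 wc = "numeric", wd = "numeric", ws = "numeric",
                 classifyLo = "numeric", classifyHi = "numeric",
                 k = "numeric", omega = "numeric"))

setValidity("CultivarProfile", function(object) {
  msg <- character()
  allh <- c(object@ripeBands, object@overripeBand, object@unripeBand)
  if (any(!is.finite(allh)) || any(allh < 0) || any(allh > 360))
    msg <- c(msg, "hue bands must lie within [0, 360] degrees")
  if (!(object@dUnripe > 0 && object@dUnripe < object@dRipe &&
        object@dRipe < object@dOverripe))
    msg <- c(msg, "diameter thresholds must satisfy 0 < dUnripe < dRipe < dOverripe")
  w <- c(object@wc, object@wd, object@ws)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "fusion weights must be non-negative and sum to 1")
  if (object@fallbackScore < 0 || object@fallbackScore > 1)
    msg <- c(msg, "fallbackScore must lie in [0, 1]")
  if (object@classifyLo >= object@classifyHi)
    msg <- c(msg, "classifyLo must be < classifyHi")
  if (object@k <= 0 || object@k > 1)
    msg <- c(msg, "ellipticity factor k must lie in (0, 1]")
  if (object@omega <= 0)
    msg <- c(msg, "yield density omega must be > 0")
  if (object@break1 <= 0 || object@break2 <= object@break1)
    msg <- c(msg, "shape breakpoints must satisfy 0 < break1 < break2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CultivarProfile", function(object) {
  cat(sprintf("CultivarProfile '%s'\n", object@name))
  cat(sprintf("  hue bands (deg): ripe [%g,%g)+[%g,%g]  overripe [%g,%g)  unripe [%g,%g)\n",
              object@ripeBands[1, 1], object@ripeBands[1, 2],
              object@ripeBands[2, 1], object@ripeBands[2, 2],
              object@overripeBand[1], object@overripeBand[2],
              object@unripeBand[1], object@unripeBand[2]))
  cat(sprintf("  diameters (mm) : unripe<%g  ripe [%g,%g]  overripe>%g\n",
              object@dUnripe, object@dUnripe, object@dRipe, object@dRipe))
  cat(sprintf("  fusion weights : wc=%g wd=%g ws=%g; classify at %g/%g\n",
              object@wc, object@wd, object@ws,
              object@classifyLo, object@classifyHi))
  cat(sprintf("  k=%g  omega=%g /mm^3\n", object@k, object@omega))
})

#' Synthetic greenhouse scene
#'
#' An RGB image, a pixel-aligned depth map (mm) and a fully known ground
#' truth table produced by \code{\link{generateScene}}.
#'
#' @slot rgb numeric array height x width x 3 in [0, 1].
#' @slot depth numeric matrix height x width, millimetres.
#' @slot truth per-fruit ground truth \code{data.frame}.
#' @slot spec the scene specification list used for generation.
#' @slot seed integer seed the scene was generated from.
#' @aliases TomatoScene-class
#' @exportClass TomatoScene
setClass("TomatoScene",
  representation(rgb = "array", depth = "matrix",
                 truth = "data.frame", spec = "list", seed = "integer"))

setValidity("TomatoScene", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    return("'rgb' must be a height x width x 3 array")
  if (!all(dim(object@depth) == d[1:2]))
    return("'depth' must be pixel-aligned with 'rgb'")
  TRUE
})

setMethod("show", "TomatoScene", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("TomatoScene %dx%d px, %d fruits on %d plants (seed %d)\n",
              d[2], d[1], nrow(object@truth),
              length(unique(object@truth$plant_id)), object@seed))
  print(table(stage = object@truth$stage))
})

#' @describeIn TomatoScene ground-truth table of a scene.
#' @param x a \code{TomatoScene}.
#' @export
sceneTruth <- function(x) x@truth

#' Per-scene fruit analysis result
#'
#' Output of \code{\link{analyzeScene}}: a per-fruit measurement/score table
#' and a per-plant cluster summary.
#'
#' @slot fruits per-fruit \code{data.frame} (metric size, 3D centroid,
#'   volume, component scores, fused score, stage, plant assignment).
#' @slot plants per-plant \code{data.frame} (count, total volume, yield).
#' @slot noise integer ids of fruits labelled as DBSCAN noise.
#' @slot params list of analysis parameters (eps, minSamples, coordinate
#'   mode, profile name).
#' @aliases FruitAnalysis-class
#' @exportClass FruitAnalysis
setClass("FruitAnalysis",
  representation(fruits = "data.frame", plants = "data.frame",
                 noise = "integer", params = "list"))

setMethod("show", "FruitAnalysis", function(object) {
  cat(sprintf("FruitAnalysis: %d fruits, %d plants, %d noise\n",
              nrow(object@fruits), nrow(object@plants), length(object@noise)))
  if (nrow(object@fruits))
    print(table(stage = object@fruits$stage))
})

#' @describeIn FruitAnalysis per-fruit measurement and score table.
#' @param x a \code{FruitAnalysis}.
#' @export
fruitTable <- function(x) x@fruits

#' @describeIn FruitAnalysis per-plant cluster summary table.
#' @export
plantTable <- function(x) x@plants
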