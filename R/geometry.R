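#' Build a bounding-box table
#'
#' Boxes are stored centre+extent in pixels (image origin top-left, x
#' right, y down, pixel centres at integer coordinates); annotation-format
#' corner conventions are converted at I/O time.
#'
#' @param cx_px,cy_px box-centre coordinates, pixels.
#' @param w_px,h_px box extents, pixels; must be > 0.
#' @param label class name.
#' @param confidence detector confidence in [0, 1].
#' @return \code{data.frame} with one row per box.
#' @examples
#' boundingBoxes(100, 80, 40, 50)
#' @export
boundingBoxes <- function(cx_px, cy_px, w_px, h_px,
                          label = "tomato", confidence = 1) {
  n <- length(cx_px)
  stopifnot(length(cy_px) == n, length(w_px) == n, length(h_px) == n)
  if (any(w_px <= 0) || any(h_px <= 0))
    stop("box extents must be strictly positive")
  if (any(confidence < 0) || any(confidence > 1))
    stop("confidence must lie in [0, 1]")
  data.frame(cx_px = as.numeric(cx_px), cy_px = as.numeric(cy_px),
             w_px = as.numeric(w_px), h_px = as.numeric(h_px),
             label = rep_len(as.character(label), n),
             confidence = rep_len(as.numeric(confidence), n))
}

#' Robust depth of a detection
#'
#' Samples the depth map over a sub-box scaled to 50% of the detection
#' extent about its centre (so background pixels caught at box corners are
#' excluded), drops zero and non-finite counts, and returns the median of
#' the remainder multiplied by \code{depthScale}. A box whose sub-box
#' holds no valid count yields \code{NA} with no error, so downstream
#' code can flag the measurement invalid rather than abort a scene.
#'
#' @param depthMap numeric matrix of depth counts, rows = image rows.
#' @param box single-row box table (see \code{\link{boundingBoxes}}).
#' @param intr \linkS4class{CameraIntrinsics}; supplies \code{depthScale}.
#' @param shrink fraction of the box extent retained (default 0.5).
#' @return depth in millimetres, or \code{NA_real_} if no valid pixel.
#' @examples
#' z <- extractDepth(matrix(1000, 40, 40),
#'                   boundingBoxes(20, 20, 10, 10), CameraIntrinsics())
#' @export
extractDepth <- function(depthMap, box, intr, shrink = 0.5) {
  stopifnot(is.matrix(depthMap), nrow(box) == 1L)
  hw <- box$w_px * shrink / 2
  hh <- box$h_px * shrink / 2
  x0 <- max(1L, floor(box$cx_px - hw)); x1 <- min(ncol(depthMap), ceiling(box$cx_px + hw))
  y0 <- max(1L, floor(box$cy_px - hh)); y1 <- min(nrow(depthMap), ceiling(box$cy_px + hh))
  if (x0 > x1 || y0 > y1) return(NA_real_)
  counts <- depthMap[y0:y1, x0:x1]
  counts <- counts[is.finite(counts) & counts > 0]
  if (!length(counts)) return(NA_real_)
  stats::median(counts) * intr@depthScale
}

#' Pixel extents to metric size
#'
#' Pinhole similar triangles: an extent of \code{w_px} pixels at depth
#' \code{z} spans \code{w_px * z / fw} millimetres (and likewise for the
#' height with \code{fh}).
#'
#' @param box single-row box table.
#' @param z depth in millimetres; must be > 0.
#' @param intr \linkS4class{CameraIntrinsics}.
#' @return named numeric \code{c(wreal, hreal)} in millimetres.
#' @examples
#' pixelToMetric(boundingBoxes(0, 0, 100, 120), 1000,
#'               CameraIntrinsics(fw = 1000, fh = 1000))
#' @export
pixelToMetric <- function(box, z, intr) {
  if (!is.finite(z) || z <= 0) stop("invalid depth: z must be > 0")
  c(wreal = box$w_px * z / intr@fw, hreal = box$h_px * z / intr@fh)
}

#' Estimate fruit diameter from metric extents
#'
#' The default \code{mode = "mean"} takes the arithmetic mean
#' \code{(wreal + hreal) / 2}, the only reading that round-trips a sphere
#' projected through the pinhole model back to its true diameter.
#' \code{mode = "literal"} evaluates \code{(wreal + hreal) * z / (fw + fh)}
#' exactly as the source formula prints it; the two agree precisely when
#' \code{z == (fw + fh) / 2}.
#'
#' @param wreal,hreal metric extents, mm.
#' @param z depth, mm (used by \code{literal} mode only).
#' @param intr \linkS4class{CameraIntrinsics} (ditto).
#' @param mode \code{"mean"} (default) or \code{"literal"}.
#' @return diameter estimate in millimetres.
#' @export
estimateDiameter <- function(wreal, hreal, z = NULL, intr = NULL,
                             mode = c("mean", "literal")) {
  mode <- match.arg(mode)
  stopifnot(wreal >= 0, hreal >= 0)
  if (mode == "mean") return((wreal + hreal) / 2)
  if (is.null(z) || is.null(intr))
    stop("'literal' mode needs z and intrinsics")
  (wreal + hreal) * z / (intr@fw + intr@fh)
}

#' Back-project a box centre to camera coordinates
#'
#' Inverts the pinhole projection at the measured depth:
#' \code{X = (cx_px - cx) * z / fw}, \code{Y = (cy_px - cy) * z / fh},
#' \code{Z = z} (millimetres, camera frame, x right / y down / z forward).
#'
#' @param box single-row box table.
#' @param z depth, mm; must be > 0.
#' @param intr \linkS4class{CameraIntrinsics}.
#' @return named numeric \code{c(X, Y, Z)} in millimetres.
#' @export
backprojectCenter <- function(box, z, intr) {
  if (!is.finite(z) || z <= 0) stop("invalid depth: z must be > 0")
  c(X = (box$cx_px - intr@cx) * z / intr@fw,
    Y = (box$cy_px - intr@cy) * z / intr@fh,
    Z = z)
}

#' Spherical fruit volume
#'
#' \code{(4/3) * pi * (dreal/2)^3} under the idealised spherical
#' assumption.
#'
#' @param dreal diameter, mm; must be >= 0.
#' @return volume in mm^3.
#' @examples
#' sphereVolume(20) # 4188.79 mm^3
#' @export
sphereVolume <- function(dreal) {
  if (any(dreal < 0)) stop("diameter must be non-negative")
  (4 / 3) * pi * (dreal / 2)^3
}

#' Ellipticity correction of a spherical volume
#'
#' Tomatoes are not perfect spheres; the spherical estimate is scaled by a
#' cultivar ellipticity factor \code{k}, typically 0.85-0.95. Values of
#' \code{k} outside that typical band are accepted with a warning;
#' non-positive \code{k} is an error.
#'
#' @param volumeRaw spherical volume, mm^3.
#' @param k correction factor in (0, 1].
#' @return corrected volume in mm^3.
#' @export
applyEllipticity <- function(volumeRaw, k) {
  if (k <= 0) stop("ellipticity factor k must be > 0")
  if (k < 0.85 || k > 0.95)
    warning("ellipticity factor k = ", k,
            " is outside the typical 0.85-0.95 band")
  k * volumeRaw
}

#' Measure every detection in a scene
#'
#' Runs the full geometric chain per box: depth extraction, metric sizing,
#' diameter estimation, centre back-projection, spherical volume and
#' ellipticity correction. Boxes without valid depth are kept with
#' \code{valid = FALSE} and NA measurements.
#'
#' @param boxes box table (see \code{\link{boundingBoxes}}).
#' @param depthMap depth-count matrix aligned to the image.
#' @param intr \linkS4class{CameraIntrinsics}.
#' @param k ellipticity factor (default from \code{profile} if given).
#' @param profile optional \linkS4class{CultivarProfile} supplying \code{k}.
#' @param diameterMode passed to \code{\link{estimateDiameter}}.
#' @return \code{data.frame}: one row per box with \code{z, wreal, hreal,
#'   dreal, X, Y, Z, volume_raw, volume, valid}.
#' @export
measureFruits <- function(boxes, depthMap, intr, k = NULL, profile = NULL,
                          diameterMode = c("mean", "literal")) {
  diameterMode <- match.arg(diameterMode)
  if (is.null(k)) k <- if (is.null(profile)) 0.9 else profile@k
  n <- nrow(boxes)
  out <- data.frame(id = seq_len(n), z = NA_real_, wreal = NA_real_,
                    hreal = NA_real_, dreal = NA_real_, X = NA_real_,
                    Y = NA_real_, Z = NA_real_, volume_raw = NA_real_,
                    volume = NA_real_, valid = FALSE)
  for (i in seq_len(n)) {
    z <- extractDepth(depthMap, boxes[i, ], intr)
    if (is.na(z)) next
    wh <- pixelToMetric(boxes[i, ], z, intr)
    d <- estimateDiameter(wh[["wreal"]], wh[["hreal"]], z, intr, diameterMode)
    ctr <- backprojectCenter(boxes[i, ], z, intr)
    vraw <- sphereVolume(d)
    out[i, c("z", "wreal", "hreal", "dreal")] <- c(z, wh, d)
    out[i, c("X", "Y", "Z")] <- ctr
    out$volume_raw[i] <- vraw
    out$volume[i] <- applyEllipticity(vraw, k)
    out$valid[i] <- TRUE
  }
  out
}
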