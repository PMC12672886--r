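#' Dominant hue inside a detection
#'
#' Converts the region of interest to HSV, keeps pixels with saturation
#' >= \code{sMin} and value >= \code{vMin} that lie inside the inscribed
#' ellipse of the box (the fruit fills the inscribed ellipse of its own
#' bounding box far better than the box corners do), bins hue into 1-degree
#' bins and returns the lower edge of the modal bin, ties broken toward the
#' lower bin. With no qualifying pixel the hue is undefined and
#' \code{NA_real_} is returned.
#'
#' @param rgb numeric height x width x 3 array in [0, 1].
#' @param box optional single-row box table selecting the ROI; when
#'   omitted the whole image is the ROI (with a full-extent ellipse mask
#'   unless \code{mask} overrides it).
#' @param mask optional logical/0-1 matrix, same size as the ROI,
#'   replacing the inscribed-ellipse mask.
#' @param sMin,vMin saturation and value cutoffs (defaults 0.3 and 0.2).
#' @return modal hue in degrees (lower bin edge), or \code{NA_real_}.
#' @examples
#' img <- array(0, c(8, 8, 3)); img[, , 1] <- 1  # pure red
#' dominantHue(img)
#' @export
dominantHue <- function(rgb, box = NULL, mask = NULL,
                        sMin = 0.3, vMin = 0.2) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  if (!is.null(box)) {
    stopifnot(nrow(box) == 1L)
    x0 <- max(1L, round(box$cx_px - box$w_px / 2))
    x1 <- min(W, round(box$cx_px + box$w_px / 2))
    y0 <- max(1L, round(box$cy_px - box$h_px / 2))
    y1 <- min(H, round(box$cy_px + box$h_px / 2))
    if (x0 > x1 || y0 > y1) return(NA_real_)
    roi <- rgb[y0:y1, x0:x1, , drop = FALSE]
  } else {
    roi <- rgb
  }
  h <- dim(roi)[1]; w <- dim(roi)[2]
  if (is.null(mask)) {
    # inscribed ellipse of the ROI
    yy <- (seq_len(h) - (h + 1) / 2) / (h / 2)
    xx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
    mask <- outer(yy^2, xx^2, `+`) <= 1
  }
  stopifnot(all(dim(mask) == c(h, w)))
  sel <- which(as.logical(mask))
  if (!length(sel)) return(NA_real_)
  r <- roi[, , 1][sel]; g <- roi[, , 2][sel]; b <- roi[, , 3][sel]
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  keep <- hsv[2, ] >= sMin & hsv[3, ] >= vMin
  if (!any(keep)) return(NA_real_)
  hue <- hsv[1, keep] * 360
  bins <- floor(hue) %% 360
  tab <- tabulate(bins + 1L, nbins = 360L)
  # which.max takes the first maximum, i.e. the lower bin on ties
  as.numeric(which.max(tab) - 1L)
}

#' Hue-based colour score
#'
#' Piecewise in hue \code{H} (degrees): 1.0 inside the ripe red bands;
#' \code{h1 + c1 * (upper - H)} inside the overripe orange/brown band;
#' \code{h2 + c2 * (H - lower)} inside the unripe green/yellow band. Hues
#' outside every band (the model leaves [40, 50) and (100, 330) undefined)
#' receive the profile's \code{fallbackScore} and are flagged via the
#' \code{"fallback"} attribute — no extrapolation is attempted. Scores are
#' clipped to [0, 1].
#'
#' @param H hue(s) in degrees; must lie in [0, 360].
#' @param profile \linkS4class{CultivarProfile}.
#' @return numeric score(s) with logical attribute \code{"fallback"}.
#' @examples
#' prof <- cultivarProfile()
#' colorScore(10, prof)   # 1.0
#' colorScore(30, prof)   # 0.65
#' colorScore(75, prof)   # 0.45
#' @export
colorScore <- function(H, profile = cultivarProfile()) {
  if (any(!is.finite(H)) || any(H < 0) || any(H > 360))
    stop("hue must lie in [0, 360] degrees")
  rb <- profile@ripeBands; ob <- profile@overripeBand; ub <- profile@unripeBand
  inRipe <- (H >= rb[1, 1] & H < rb[1, 2]) | (H >= rb[2, 1] & H <= rb[2, 2])
  inOver <- H >= ob[1] & H < ob[2]
  inUnripe <- H >= ub[1] & H < ub[2]
  s <- rep(profile@fallbackScore, length(H))
  s[inRipe] <- 1.0
  s[inOver] <- profile@h1 + profile@c1 * (ob[2] - H[inOver])
  s[inUnripe] <- profile@h2 + profile@c2 * (H[inUnripe] - ub[1])
  s <- pmin(1, pmax(0, s))
  attr(s, "fallback") <- !(inRipe | inOver | inUnripe)
  s
}

#' Diameter-based size score
#'
#' Piecewise in measured diameter \code{dreal} (mm) against the cultivar
#' thresholds: below \code{dUnripe} the score ramps as
#' \code{s1 * dreal / dUnripe}; on \code{[dUnripe, dRipe]} it ramps as
#' \code{s1 + s2 * (dreal - dUnripe) / (dRipe - dUnripe)} (boundaries are
#' attached to this branch, which is value-identical by continuity);
#' beyond \code{dRipe} it decays as
#' \code{1 - s3 * (dreal - dRipe) / (dOverripe - dRipe)}, floored at 0.
#' Scores are clipped to [0, 1].
#'
#' @param dreal diameter(s), mm; must be >= 0.
#' @param profile \linkS4class{CultivarProfile}.
#' @return numeric score(s) in [0, 1].
#' @examples
#' prof <- cultivarProfile() # thresholds 50/70/85 mm
#' sizeScore(25, prof)   # 0.15
#' sizeScore(60, prof)   # 0.65
#' sizeScore(77.5, prof) # 0.90
#' @export
sizeScore <- function(dreal, profile = cultivarProfile()) {
  if (any(dreal < 0)) stop("diameter must be non-negative")
  dU <- profile@dUnripe; dR <- profile@dRipe; dO <- profile@dOverripe
  s <- ifelse(dreal < dU,
              profile@s1 * dreal / dU,
              ifelse(dreal <= dR,
                     profile@s1 + profile@s2 * (dreal - dU) / (dR - dU),
                     1 - profile@s3 * (dreal - dR) / (dO - dR)))
  pmin(1, pmax(0, s))
}

#' Aspect ratio of a fruit
#'
#' @param wreal,hreal metric extents, mm; \code{hreal} must be > 0.
#' @return \code{wreal / hreal}.
#' @export
aspectRatio <- function(wreal, hreal) {
  if (any(hreal <= 0)) stop("hreal must be > 0")
  wreal / hreal
}

#' Shape score from aspect-ratio deviation
#'
#' With deviation \code{d = |r - 1|}: \code{1 - p1 * d} for
#' \code{d <= break1}; \code{0.7 - p2 * (d - break1)} for
#' \code{break1 < d <= break2}; \code{0.4 - p3 * (d - break2)}, floored at
#' 0, beyond. The breakpoints are genuine discontinuities of the model
#' (1 - p1*0.3 = 0.94 vs 0.7 at \code{d = 0.3}) and are implemented as
#' printed. Scores are clipped to [0, 1].
#'
#' @param r aspect ratio(s); must be > 0.
#' @param profile \linkS4class{CultivarProfile}.
#' @return numeric score(s) in [0, 1].
#' @examples
#' prof <- cultivarProfile()
#' shapeScore(1.0, prof) # 1.0
#' shapeScore(1.2, prof) # 0.96
#' shapeScore(1.5, prof) # 0.64
#' shapeScore(2.0, prof) # 0.28
#' @export
shapeScore <- function(r, profile = cultivarProfile()) {
  if (any(r <= 0)) stop("aspect ratio must be > 0")
  d <- abs(r - 1)
  b1 <- profile@break1; b2 <- profile@break2
  s <- ifelse(d <= b1, 1 - profile@p1 * d,
              ifelse(d <= b2, 0.7 - profile@p2 * (d - b1),
                     0.4 - profile@p3 * (d - b2)))
  pmin(1, pmax(0, s))
}

#' Contour circularity of a fruit mask (diagnostic)
#'
#' Computes \code{4 * pi * A / P^2} of the largest connected foreground
#' component, where the perimeter \code{P} is the Euclidean length of the
#' traced boundary polygon (EBImage contour tracing). A perfect disc
#' approaches 1; elongated shapes fall toward 0. The value is an auxiliary
#' diagnostic only — it does not enter the fused ripeness score, as the
#' model defines no mapping from circularity to a score.
#'
#' @param mask binary matrix (0/1 or logical), foreground = fruit.
#' @return circularity, or \code{NA_real_} for an empty mask.
#' @export
contourCircularity <- function(mask) {
  m <- matrix(as.numeric(as.logical(mask)), nrow = nrow(mask))
  if (!any(m > 0)) return(NA_real_)
  # EBImage images are x,y ordered; transpose the row/col matrix
  lab <- EBImage::bwlabel(EBImage::Image(t(m)))
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  biggest <- which.max(sizes)
  oc <- EBImage::ocontour(lab)[[biggest]]
  if (is.null(dim(oc)) || nrow(oc) < 3L) return(NA_real_)
  nxt <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE])
  P <- sum(sqrt(rowSums((oc - nxt)^2)))
  A <- sizes[biggest]
  4 * pi * A / P^2
}

#' Fuse component scores into a ripeness score
#'
#' Convex combination \code{wc * sColor + wd * sSize + ws * sShape}; the
#' weights must be non-negative and sum to 1, so the result stays in
#' [0, 1] whenever the components do.
#'
#' @param sColor,sSize,sShape component scores in [0, 1].
#' @param profile \linkS4class{CultivarProfile} supplying the weights.
#' @return fused score(s) in [0, 1].
#' @examples
#' fuseScores(0.65, 0.65, 0.96) # 0.712 under default weights
#' @export
fuseScores <- function(sColor, sSize, sShape, profile = cultivarProfile()) {
  scores <- c(sColor, sSize, sShape)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("component scores must lie in [0, 1]")
  profile@wc * sColor + profile@wd * sSize + profile@ws * sShape
}

#' Classify a ripeness score into a maturity stage
#'
#' \code{score < lo} is immature, \code{lo <= score <= hi} is ripe
#' (both boundary scores inclusive on the ripe side), \code{score > hi}
#' is overripe.
#'
#' @param score ripeness score(s) in [0, 1].
#' @param lo,hi thresholds; default 0.4 and 0.7.
#' @return character vector over \code{c("immature", "ripe", "overripe")}.
#' @examples
#' classifyRipeness(c(0.39, 0.40, 0.70, 0.71))
#' @export
classifyRipeness <- function(score, lo = 0.4, hi = 0.7) {
  if (lo >= hi) stop("classification thresholds must satisfy lo < hi")
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]")
  ifelse(score < lo, "immature", ifelse(score <= hi, "ripe", "overripe"))
}

#' Score and classify every measured fruit
#'
#' Per fruit: dominant hue of the box ROI, colour/size/shape scores,
#' fusion under the profile weights, and stage classification. Fruits
#' whose hue is undefined (no qualifying pixel) take the profile fallback
#' colour score and are flagged.
#'
#' @param rgb image array (height x width x 3, values in [0, 1]).
#' @param boxes box table aligned row-for-row with \code{measurements}.
#' @param measurements output of \code{\link{measureFruits}}.
#' @param profile \linkS4class{CultivarProfile}.
#' @return \code{data.frame} with \code{hue, s_color, s_size, s_shape,
#'   score, stage, flag_hue} per fruit (NA scores for invalid
#'   measurements).
#' @export
scoreFruits <- function(rgb, boxes, measurements,
                        profile = cultivarProfile()) {
  n <- nrow(boxes)
  stopifnot(nrow(measurements) == n)
  out <- data.frame(hue = NA_real_, s_color = NA_real_, s_size = NA_real_,
                    s_shape = NA_real_, score = NA_real_,
                    stage = NA_character_, flag_hue = FALSE)[rep(1, n), ]
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    if (!measurements$valid[i]) next
    hue <- dominantHue(rgb, boxes[i, ])
    if (is.na(hue)) {
      sc <- profile@fallbackScore
      out$flag_hue[i] <- TRUE
    } else {
      s <- colorScore(hue, profile)
      sc <- as.numeric(s)
      out$flag_hue[i] <- attr(s, "fallback")
      out$hue[i] <- hue
    }
    ss <- sizeScore(measurements$dreal[i], profile)
    r <- aspectRatio(measurements$wreal[i], measurements$hreal[i])
    ssh <- shapeScore(r, profile)
    out$s_color[i] <- sc
    out$s_size[i] <- ss
    out$s_shape[i] <- ssh
    out$score[i] <- fuseScores(sc, ss, ssh, profile)
    out$stage[i] <- classifyRipeness(out$score[i],
                                     profile@classifyLo, profile@classifyHi)
  }
  out
}
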