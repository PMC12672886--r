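#' Build a continuous box
#'
#' Centre + extent representation in a shared frame, arbitrary length
#' units. Used by the regression-loss reference numerics.
#'
#' @param cx,cy centre coordinates.
#' @param w,h extents; must be > 0.
#' @return named numeric vector \code{c(cx, cy, w, h)}.
#' @export
box <- function(cx, cy, w, h) {
  if (w <= 0 || h <= 0) stop("box extents must be > 0")
  c(cx = cx, cy = cy, w = w, h = h)
}

boxCorners <- function(b) {
  c(x0 = b[["cx"]] - b[["w"]] / 2, x1 = b[["cx"]] + b[["w"]] / 2,
    y0 = b[["cy"]] - b[["h"]] / 2, y1 = b[["cy"]] + b[["h"]] / 2)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes from \code{\link{box}} (or any named \code{c(cx, cy,
#'   w, h)} vector).
#' @return IoU in [0, 1]; 0 for disjoint boxes.
#' @examples
#' boxIoU(box(0, 0, 2, 2), box(1, 0, 2, 2)) # 1/3
#' @export
boxIoU <- function(a, b) {
  ca <- boxCorners(a); cb <- boxCorners(b)
  iw <- max(0, min(ca[["x1"]], cb[["x1"]]) - max(ca[["x0"]], cb[["x0"]]))
  ih <- max(0, min(ca[["y1"]], cb[["y1"]]) - max(ca[["y0"]], cb[["y0"]]))
  inter <- iw * ih
  union <- a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter
  inter / union
}

#' EIoU bounding-box regression loss
#'
#' Sum of four scale-normalised penalties between a predicted and a
#' ground-truth box: the IoU term \code{1 - IoU}; the squared
#' centre distance divided by the squared diagonal of the smallest
#' enclosing box; and separate squared width and height differences,
#' each divided by the corresponding squared enclosing-box extent.
#' Decoupling width and height (rather than penalising their ratio
#' jointly) is what distinguishes EIoU from CIoU.
#'
#' The loss is 0 iff the boxes coincide, and is invariant under joint
#' translation and joint uniform scaling of both boxes.
#'
#' @param pred,gt boxes from \code{\link{box}}.
#' @return non-negative loss value.
#' @examples
#' eiouLoss(box(0, 0, 2, 2), box(1, 0, 2, 2)) # 2/3 + 1/13
#' @export
eiouLoss <- function(pred, gt) {
  iou <- boxIoU(pred, gt)
  cp <- boxCorners(pred); cg <- boxCorners(gt)
  wc <- max(cp[["x1"]], cg[["x1"]]) - min(cp[["x0"]], cg[["x0"]])
  hc <- max(cp[["y1"]], cg[["y1"]]) - min(cp[["y0"]], cg[["y0"]])
  rho2 <- (pred[["cx"]] - gt[["cx"]])^2 + (pred[["cy"]] - gt[["cy"]])^2
  (1 - iou) +
    rho2 / (wc^2 + hc^2) +
    (pred[["w"]] - gt[["w"]])^2 / wc^2 +
    (pred[["h"]] - gt[["h"]])^2 / hc^2
}

#' Focal-EIoU loss
#'
#' Reweights the EIoU loss by \code{IoU^gamma}, so higher-quality
#' (higher-IoU) regression samples carry larger loss magnitudes and
#' low-quality outliers are suppressed. \code{0^gamma} is defined as 0
#' for \code{gamma > 0} (disjoint boxes contribute nothing);
#' \code{gamma = 0} recovers the plain EIoU loss.
#'
#' @param pred,gt boxes from \code{\link{box}}.
#' @param gamma focusing exponent; must be >= 0 (default 0.5).
#' @return non-negative loss value.
#' @examples
#' focalEiouLoss(box(0, 0, 2, 2), box(1, 0, 2, 2), gamma = 0.5)
#' @export
focalEiouLoss <- function(pred, gt, gamma = 0.5) {
  if (gamma < 0) stop("gamma must be >= 0")
  iou <- boxIoU(pred, gt)
  w <- if (iou == 0 && gamma > 0) 0 else iou^gamma
  w * eiouLoss(pred, gt)
}
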