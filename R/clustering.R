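#' Euclidean distance between two 3D fruit points
#'
#' @param p,q numeric length-3 coordinate vectors, mm.
#' @return distance in mm.
#' @export
euclid3 <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Density-based (DBSCAN) clustering of fruit points
#'
#' Standard DBSCAN semantics: a point is a core point when at least
#' \code{minSamples} points (itself included) lie within \code{eps} of it;
#' clusters are maximal density-connected sets grown from core points;
#' points that are neither core nor reachable from one are labelled noise
#' (\code{0L}). Points are scanned in row order, and cluster ids are
#' afterwards relabelled canonically by their smallest member row, so the
#' induced partition is invariant under input reordering.
#'
#' With \code{minSamples = 1} every point is core and the clusters are
#' exactly the connected components of the graph joining points at
#' distance <= \code{eps}; noise can only arise when \code{minSamples > 1}.
#'
#' @param coords numeric matrix, one row per point, columns X/Y/Z (mm).
#'   Any column count >= 1 is accepted.
#' @param eps neighbourhood radius, mm; must be > 0.
#' @param minSamples minimum neighbourhood size for a core point
#'   (self-inclusive); must be >= 1. Default 1: an isolated fruit is its
#'   own plant.
#' @return integer vector of cluster labels (1, 2, ...; 0 = noise),
#'   one per row of \code{coords}.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(1000, 0, 0))
#' dbscanLabels(pts, eps = 50)
#' @export
dbscanLabels <- function(coords, eps, minSamples = 1L) {
  if (eps <= 0) stop("eps must be > 0")
  if (minSamples < 1) stop("minSamples must be >= 1")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  # all-pairs neighbourhoods; fruit counts per scene are small (<= a few
  # hundred), so the O(n^2) distance matrix is the simple right tool
  d2 <- as.matrix(stats::dist(coords))^2
  nbrs <- d2 <= eps^2
  core <- rowSums(nbrs) >= minSamples
  labels <- integer(n)       # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      if (!core[p]) next
      for (q in which(nbrs[p, ])) {
        if (labels[q] == 0L) labels[q] <- cl       # border or new core
        if (!visited[q]) {
          visited[q] <- TRUE
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  # canonical relabelling by smallest member row
  nz <- labels != 0L
  if (any(nz)) {
    firsts <- tapply(which(nz), labels[nz], min)
    order_map <- rank(firsts)
    labels[nz] <- as.integer(order_map[as.character(labels[nz])])
  }
  labels
}

#' Summarise DBSCAN labels into plant clusters
#'
#' One summary row per non-noise cluster: member count and summed fruit
#' volume. Noise points are reported separately (attribute
#' \code{"noise"}), never silently dropped. Clusters are sorted by
#' ascending plant id.
#'
#' @param labels integer labels from \code{\link{dbscanLabels}}.
#' @param points \code{data.frame} with at least \code{id} and
#'   \code{volume} columns, aligned row-for-row with \code{labels}.
#' @return \code{data.frame} with \code{plant_id, n_fruits, total_volume}
#'   and a \code{list} column \code{members}; attribute \code{"noise"}
#'   holds the noise ids.
#' @export
summarizeClusters <- function(labels, points) {
  stopifnot(length(labels) == nrow(points))
  ids <- if (!is.null(points$id)) points$id else seq_along(labels)
  vols <- if (!is.null(points$volume)) points$volume else rep(NA_real_, nrow(points))
  keep <- labels != 0L
  cls <- sort(unique(labels[keep]))
  out <- data.frame(plant_id = cls,
                    n_fruits = vapply(cls, function(cl) sum(labels == cl), 1L),
                    total_volume = vapply(cls, function(cl)
                      sum(vols[labels == cl]), 1.0))
  out$members <- lapply(cls, function(cl) ids[labels == cl])
  attr(out, "noise") <- ids[!keep]
  out
}

#' Volume-based per-plant yield estimate
#'
#' \code{yield = omega * total_volume}: the cultivar density parameter
#' \code{omega} (per mm^3) converts a cluster's summed fruit volume into a
#' yield figure. \code{omega} is a cultivar calibration constant with no
#' default claim of biological accuracy, which is why the count-based
#' tally \code{n_fruits} is always reported alongside it.
#'
#' @param totalVolume summed member volume, mm^3.
#' @param omega density parameter, per mm^3; must be > 0.
#' @return yield estimate (unitless, cultivar-calibrated).
#' @examples
#' plantYield(2 * sphereVolume(20), omega = 2.4e-4) # 2.011
#' @export
plantYield <- function(totalVolume, omega) {
  if (omega <= 0) stop("yield density omega must be > 0")
  omega * totalVolume
}

#' Cluster measured fruits into plants and estimate yield
#'
#' Runs DBSCAN on the fruits' 3D coordinates and summarises the result,
#' attaching the volume-based yield estimate per plant. By default the
#' pinhole back-projected centroids (X, Y, Z) are clustered — the reading
#' under which same-plant fruits are actually spatially proximal. Setting
#' \code{literalCoords = TRUE} instead clusters the printed feature triple
#' (wreal, hreal, z).
#'
#' @param measurements output of \code{\link{measureFruits}}; invalid rows
#'   are excluded from clustering.
#' @param eps neighbourhood radius, mm (default 300).
#' @param minSamples DBSCAN core threshold (default 1).
#' @param profile \linkS4class{CultivarProfile} supplying \code{omega}.
#' @param literalCoords cluster (wreal, hreal, z) instead of centroids.
#' @return list with \code{labels} (full-length; NA for invalid rows,
#'   0 noise) and \code{plants} (summary table with \code{yield_estimate}).
#' @export
clusterFruits <- function(measurements, eps = 300, minSamples = 1L,
                          profile = cultivarProfile(),
                          literalCoords = FALSE) {
  valid <- measurements$valid
  cols <- if (literalCoords) c("wreal", "hreal", "z") else c("X", "Y", "Z")
  coords <- as.matrix(measurements[valid, cols])
  lab <- dbscanLabels(coords, eps = eps, minSamples = minSamples)
  labels <- rep(NA_integer_, nrow(measurements))
  labels[valid] <- lab
  plants <- summarizeClusters(lab, measurements[valid, , drop = FALSE])
  plants$yield_estimate <- plantYield(plants$total_volume, profile@omega)
  list(labels = labels, plants = plants)
}
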