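#' Specify a synthetic greenhouse scene
#'
#' Collects every knob of the scene generator. Defaults describe a small
#' greenhouse row imaged by a stereo depth camera: a 640x480 frame, two
#' plants 700 mm apart at 1.5 m depth, five fruits per plant drawn
#' uniformly over the nominal maturity stages, no occlusion.
#'
#' Stage-conditional attributes (hue, diameter, aspect ratio) are sampled
#' inside the cultivar's per-stage bands, at least \code{bandMargin}
#' (fraction of band width, default 10\%) away from the band edges. On
#' top of that, fruits whose true fused ripeness score falls within
#' \code{scoreMargin} of a classification threshold, or whose aspect
#' ratio deviation falls within 0.04 of a shape-score breakpoint, are
#' resampled, so the ground-truth stage is unambiguous. \code{hard = TRUE}
#' disables all margins for robustness testing.
#'
#' @param width,height image size, pixels.
#' @param intrinsics a \linkS4class{CameraIntrinsics}.
#' @param nPlants number of plants.
#' @param plantSpacing spacing along the ground line, mm.
#' @param plantZ depth of the ground line, mm.
#' @param plantPositions optional nPlants x 2 matrix of (X, Z) mm,
#'   overriding spacing/depth.
#' @param fruitsPerPlant fruits per plant (single count or range
#'   \code{c(lo, hi)}).
#' @param stageMix named proportions over immature/ripe/overripe used for
#'   nominal-stage sampling; must sum to 1.
#' @param profile a \linkS4class{CultivarProfile}.
#' @param occlusionFraction fraction of fruits deliberately placed to
#'   overlap an earlier fruit of the same plant.
#' @param fruitSpread half-extent of the uniform fruit offset around the
#'   plant centre, mm, per axis.
#' @param backgroundHue foliage background hue, degrees.
#' @param bandMargin stage-band sampling margin (fraction of band width).
#' @param scoreMargin minimum distance of the true fused score from the
#'   classification thresholds.
#' @param hard disable sampling margins.
#' @param seed integer seed; the scene is a deterministic function of the
#'   spec including this seed.
#' @return a validated scene-spec list (class \code{"tomatoSceneSpec"}).
#' @export
sceneSpec <- function(width = 640, height = 480,
                      intrinsics = CameraIntrinsics(cx = width / 2,
                                                    cy = height / 2),
                      nPlants = 2, plantSpacing = 700, plantZ = 1500,
                      plantPositions = NULL,
                      fruitsPerPlant = 5,
                      stageMix = c(immature = 1/3, ripe = 1/3,
                                   overripe = 1/3),
                      profile = cultivarProfile(),
                      occlusionFraction = 0,
                      fruitSpread = 140,
                      backgroundHue = 120,
                      bandMargin = 0.1, scoreMargin = 0.05,
                      hard = FALSE, seed = 42L) {
  if (abs(sum(stageMix) - 1) > 1e-9) stop("stageMix must sum to 1")
  if (!all(names(stageMix) %in% c("immature", "ripe", "overripe")))
    stop("stageMix names must be immature/ripe/overripe")
  if (is.null(plantPositions))
    plantPositions <- cbind(X = (seq_len(nPlants) - (nPlants + 1) / 2) *
                              plantSpacing,
                            Z = rep(plantZ, nPlants))
  if (occlusionFraction < 0 || occlusionFraction > 1)
    stop("occlusionFraction must lie in [0, 1]")
  spec <- list(width = as.integer(width), height = as.integer(height),
               intrinsics = intrinsics, nPlants = as.integer(nPlants),
               plantPositions = plantPositions,
               fruitsPerPlant = fruitsPerPlant, stageMix = stageMix,
               profile = profile, occlusionFraction = occlusionFraction,
               fruitSpread = fruitSpread, backgroundHue = backgroundHue,
               bandMargin = bandMargin, scoreMargin = scoreMargin,
               hard = hard, seed = as.integer(seed))
  class(spec) <- c("tomatoSceneSpec", "list")
  spec
}

shrinkBand <- function(band, margin) {
  w <- band[2] - band[1]
  c(band[1] + margin * w, band[2] - margin * w)
}

# draw (hue, diameter, ratio, component scores, fused score, truth stage)
# for one fruit of the given nominal stage
sampleStageAttributes <- function(profile, stage, bandMargin, scoreMargin,
                                  hard, maxTries = 200L) {
  m <- if (hard) 0 else bandMargin
  dU <- profile@dUnripe; dR <- profile@dRipe; dO <- profile@dOverripe
  for (try in seq_len(maxTries)) {
    if (stage == "immature") {
      hb <- shrinkBand(profile@unripeBand, m)
      # fruitlets below ~20 mm are not reliably detectable; sample the
      # detectable part of the unripe interval
      db <- shrinkBand(c(min(20, 0.4 * dU), dU), m)
      rb <- shrinkBand(c(0.9, 1.1), m)
    } else if (stage == "ripe") {
      bands <- profile@ripeBands
      wids <- bands[, 2] - bands[, 1]
      pick <- sample.int(2, 1, prob = wids)
      hb <- shrinkBand(bands[pick, ], m)
      db <- shrinkBand(c(dU, dR), m)
      rb <- shrinkBand(if (stats::runif(1) < 0.5) c(0.7, 0.9)
                       else c(1.1, 1.3), m)
    } else {
      hb <- shrinkBand(profile@overripeBand, m)
      db <- shrinkBand(c(dR, dO + (dO - dR)), m)
      rb <- shrinkBand(if (stats::runif(1) < 0.5) c(0.45, 0.7)
                       else c(1.3, 1.6), m)
    }
    hue <- stats::runif(1, hb[1], hb[2])
    d <- stats::runif(1, db[1], db[2])
    r <- stats::runif(1, rb[1], rb[2])
    if (!hard) {
      dev <- abs(r - 1)
      if (min(abs(dev - profile@break1), abs(dev - profile@break2)) < 0.04)
        next
    }
    sc <- as.numeric(colorScore(hue, profile))
    ss <- sizeScore(d, profile)
    ssh <- shapeScore(r, profile)
    score <- fuseScores(sc, ss, ssh, profile)
    if (!hard &&
        min(abs(score - profile@classifyLo),
            abs(score - profile@classifyHi)) < scoreMargin)
      next
    return(list(hue = hue, diameter = d, ratio = r,
                s_color = sc, s_size = ss, s_shape = ssh, score = score,
                stage = classifyRipeness(score, profile@classifyLo,
                                         profile@classifyHi)))
  }
  stop("could not sample unambiguous stage attributes after ",
       maxTries, " tries")
}

boxesOverlap <- function(b, others) {
  if (!nrow(others)) return(rep(FALSE, 1))
  ox <- abs(others$cx_px - b$cx_px) < (others$w_px + b$w_px) / 2
  oy <- abs(others$cy_px - b$cy_px) < (others$h_px + b$h_px) / 2
  any(ox & oy)
}

#' Generate a ground-truthed synthetic greenhouse scene
#'
#' Renders fruits as filled axis-aligned ellipses (the inscribed ellipse
#' of each fruit's bounding box) into an RGB image and a pixel-aligned
#' depth map, at pinhole-projected positions, with stage-conditional hue,
#' diameter and aspect ratio. Farther fruits are drawn first, so a nearer
#' fruit naturally occludes in both channels. The ground truth records,
#' per fruit, the nominal sampling stage, the score-implied true stage,
#' the true attributes, the 3D centroid and the exact (real-valued)
#' projected box. The whole scene is a deterministic function of the
#' spec, including its seed.
#'
#' Fruits that would project outside the frame (or, in occlusion-free
#' scenes, overlap another fruit) are resampled up to a bounded retry
#' count, after which generation fails.
#'
#' @param spec a scene spec from \code{\link{sceneSpec}}.
#' @return a \linkS4class{TomatoScene}.
#' @examples
#' scn <- generateScene(sceneSpec(seed = 1))
#' head(sceneTruth(scn))
#' @export
generateScene <- function(spec = sceneSpec()) {
  stopifnot(inherits(spec, "tomatoSceneSpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  intr <- spec$intrinsics
  W <- spec$width; H <- spec$height
  prof <- spec$profile
  rows <- list()
  placed <- data.frame()
  fid <- 0L
  for (p in seq_len(spec$nPlants)) {
    nf <- if (length(spec$fruitsPerPlant) == 2L)
      sample(spec$fruitsPerPlant[1]:spec$fruitsPerPlant[2], 1)
    else spec$fruitsPerPlant
    for (f in seq_len(nf)) {
      fid <- fid + 1L
      nominal <- sample(names(spec$stageMix), 1, prob = spec$stageMix)
      att <- sampleStageAttributes(prof, nominal, spec$bandMargin,
                                   spec$scoreMargin, spec$hard)
      occlude <- stats::runif(1) < spec$occlusionFraction && fid > 1L
      tryPlace <- function(occlude) {
        prev <- if (fid > 1L) do.call(rbind, rows) else NULL
        for (try in seq_len(60L)) {
          if (occlude) {
            # deliberately drop the fruit next to an earlier one so the
            # boxes overlap; prefer a neighbour on the same plant
            same <- prev[prev$plant_id == p, , drop = FALSE]
            base <- if (nrow(same)) same[sample.int(nrow(same), 1), ]
                    else prev[sample.int(nrow(prev), 1), ]
            X <- base$X + stats::runif(1, -0.6, 0.6) * att$diameter
            Y <- base$Y + stats::runif(1, -0.6, 0.6) * att$diameter
            Z <- base$Z + stats::runif(1, -40, 40)
          } else {
            off <- stats::runif(3, -spec$fruitSpread, spec$fruitSpread)
            X <- spec$plantPositions[p, 1] + off[1]
            Y <- off[2]
            Z <- spec$plantPositions[p, 2] + off[3]
          }
          if (Z <= 0) next
          wreal <- 2 * att$diameter * att$ratio / (1 + att$ratio)
          hreal <- 2 * att$diameter / (1 + att$ratio)
          cx_px <- intr@cx + X * intr@fw / Z
          cy_px <- intr@cy + Y * intr@fh / Z
          w_px <- wreal * intr@fw / Z
          h_px <- hreal * intr@fh / Z
          b <- data.frame(cx_px = cx_px, cy_px = cy_px,
                          w_px = w_px, h_px = h_px)
          inside <- cx_px - w_px / 2 >= 2 && cx_px + w_px / 2 <= W - 1 &&
            cy_px - h_px / 2 >= 2 && cy_px + h_px / 2 <= H - 1
          if (!inside) next
          overlaps <- boxesOverlap(b, placed)
          if (occlude && !overlaps) next
          if (!occlude && overlaps) next
          return(list(b = b, X = X, Y = Y, Z = Z,
                      wreal = wreal, hreal = hreal, occlude = occlude))
        }
        NULL
      }
      pl <- tryPlace(occlude)
      if (is.null(pl) && occlude) pl <- tryPlace(FALSE)
      if (is.null(pl)) stop("failed to place fruit ", fid,
                            " inside the frame; enlarge the image or ",
                            "reduce fruit count/spread")
      b <- pl$b; X <- pl$X; Y <- pl$Y; Z <- pl$Z
      wreal <- pl$wreal; hreal <- pl$hreal
      cx_px <- b$cx_px; cy_px <- b$cy_px; w_px <- b$w_px; h_px <- b$h_px
      occlude <- pl$occlude
      placed <- rbind(placed, b)
      rows[[fid]] <- data.frame(
        id = fid, plant_id = p, stage_nominal = nominal, stage = att$stage,
        hue = att$hue, diameter_mm = att$diameter, ratio = att$ratio,
        wreal = wreal, hreal = hreal, depth_mm = Z,
        X = X, Y = Y, Z = Z,
        cx_px = cx_px, cy_px = cy_px, w_px = w_px, h_px = h_px,
        s_color = att$s_color, s_size = att$s_size, s_shape = att$s_shape,
        score_true = att$score, occluded = occlude,
        saturation = stats::runif(1, 0.75, 0.95),
        value = stats::runif(1, 0.70, 0.90))
    }
  }
  truth <- do.call(rbind, rows)
  # occlusion bookkeeping: a fruit is occluded when a nearer fruit's box
  # overlaps its own (ground truth keeps the full box)
  for (i in seq_len(nrow(truth))) {
    nearer <- truth[truth$Z < truth$Z[i] & truth$id != truth$id[i], ]
    if (nrow(nearer) && boxesOverlap(truth[i, ], nearer))
      truth$occluded[i] <- TRUE
  }

  # render: background, then fruits far to near
  bg <- grDevices::col2rgb(grDevices::hsv(spec$backgroundHue / 360,
                                          0.45, 0.35)) / 255
  rgb <- array(0, c(H, W, 3))
  noise <- matrix(stats::runif(H * W, -0.04, 0.04), H, W)
  for (ch in 1:3) rgb[, , ch] <- pmin(1, pmax(0, bg[ch] + noise))
  depth <- matrix(max(truth$Z) + 1500, H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  for (i in order(truth$Z, decreasing = TRUE)) {
    tr <- truth[i, ]
    ell <- ((xs - tr$cx_px) / (tr$w_px / 2))^2 +
      ((ys - tr$cy_px) / (tr$h_px / 2))^2 <= 1
    col <- grDevices::col2rgb(grDevices::hsv(tr$hue / 360, tr$saturation,
                                             tr$value)) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ell] <- col[ch]
      rgb[, , ch] <- plane
    }
    depth[ell] <- tr$Z
  }
  truth$saturation <- NULL; truth$value <- NULL
  rownames(truth) <- NULL
  new("TomatoScene", rgb = rgb, depth = depth, truth = truth,
      spec = unclass(spec), seed = spec$seed)
}

#' Randomised box-pair fixtures for the regression losses
#'
#' The first four pairs are systematic: identical, nested, disjoint and
#' the partial-overlap pair \code{(0,0,2,2)} vs \code{(1,0,2,2)}; the
#' remainder are uniform-random pairs. Deterministic given the seed.
#'
#' @param n total number of pairs; must be >= 1.
#' @param seed integer seed.
#' @return list of \code{list(pred = , gt = )} box pairs.
#' @export
generateBoxPairs <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sys <- list(
    list(pred = box(0, 0, 2, 2), gt = box(0, 0, 2, 2)),       # identical
    list(pred = box(0, 0, 1, 1), gt = box(0, 0, 4, 4)),       # nested
    list(pred = box(0, 0, 2, 2), gt = box(10, 10, 2, 2)),     # disjoint
    list(pred = box(0, 0, 2, 2), gt = box(1, 0, 2, 2)))       # partial
  out <- sys[seq_len(min(n, 4L))]
  while (length(out) < n) {
    out[[length(out) + 1L]] <- list(
      pred = box(stats::runif(1, -5, 5), stats::runif(1, -5, 5),
                 stats::runif(1, 0.5, 6), stats::runif(1, 0.5, 6)),
      gt = box(stats::runif(1, -5, 5), stats::runif(1, -5, 5),
               stats::runif(1, 0.5, 6), stats::runif(1, 0.5, 6)))
  }
  out
}

#' Gaussian blob fixtures for clustering
#'
#' Cluster centres sit on a line \code{interSpacing} mm apart; members are
#' offset by truncated Gaussian noise (sd \code{intraSpread / 2}, clipped
#' to \code{intraSpread} per axis), so blob extents are bounded and blobs
#' never merge when \code{interSpacing > 2 * intraSpread}. Deterministic
#' given the seed.
#'
#' @param nClusters,pointsPerCluster blob count and size.
#' @param intraSpread per-axis offset bound, mm.
#' @param interSpacing centre spacing, mm; must exceed
#'   \code{2 * intraSpread}.
#' @param seed integer seed.
#' @return list with \code{points} (matrix n x 3) and \code{labels}
#'   (true blob ids, 1-based).
#' @export
generateClusterPoints <- function(nClusters, pointsPerCluster,
                                  intraSpread = 50, interSpacing = 1000,
                                  seed = 1L) {
  if (interSpacing <= 2 * intraSpread)
    stop("interSpacing must exceed 2 * intraSpread")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  pts <- list(); labs <- integer(0)
  for (cl in seq_len(nClusters)) {
    ctr <- c((cl - 1) * interSpacing, 0, 1500)
    off <- matrix(stats::rnorm(pointsPerCluster * 3, sd = intraSpread / 2),
                  ncol = 3)
    off[] <- pmin(intraSpread, pmax(-intraSpread, off))
    pts[[cl]] <- sweep(off, 2, ctr, `+`)
    labs <- c(labs, rep(cl, pointsPerCluster))
  }
  list(points = do.call(rbind, pts), labels = labs)
}
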