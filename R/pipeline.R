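#' Analyze a scene: detections + depth to phenotypes
#'
#' Runs the complete post-detection chain: robust depth per box, metric
#' sizing and diameter, centre back-projection, ellipticity-corrected
#' volume, hue/size/shape scoring and ripeness classification, and
#' DBSCAN plant clustering with per-plant yield.
#'
#' Inputs may be in-memory objects or file paths (PNG image, native or
#' PNG depth map, VOC/YOLO detections, YAML/JSON intrinsics and profile).
#'
#' @param image RGB array (height x width x 3 in [0, 1]) or PNG path.
#' @param depth depth matrix in mm, or a depth-file path (interpreted
#'   with the intrinsics' \code{depthScale}).
#' @param detections box table, or an annotation file path.
#' @param intrinsics a \linkS4class{CameraIntrinsics} or file path.
#' @param profile a \linkS4class{CultivarProfile} or YAML path.
#' @param eps,minSamples DBSCAN parameters (mm, count).
#' @param literalCoords cluster (wreal, hreal, z) instead of 3D centroids.
#' @param diameterMode passed to \code{\link{estimateDiameter}}.
#' @return a \linkS4class{FruitAnalysis}.
#' @examples
#' scn <- generateScene(sceneSpec(seed = 7))
#' boxes <- boundingBoxes(sceneTruth(scn)$cx_px, sceneTruth(scn)$cy_px,
#'                        sceneTruth(scn)$w_px, sceneTruth(scn)$h_px)
#' fa <- analyzeScene(scn@rgb, scn@depth, boxes,
#'                    CameraIntrinsics(cx = 320, cy = 240))
#' plantTable(fa)
#' @export
analyzeScene <- function(image, depth, detections,
                         intrinsics = CameraIntrinsics(),
                         profile = cultivarProfile(),
                         eps = 300, minSamples = 1L,
                         literalCoords = FALSE,
                         diameterMode = c("mean", "literal")) {
  diameterMode <- match.arg(diameterMode)
  if (is.character(intrinsics)) intrinsics <- readCameraIntrinsics(intrinsics)
  if (is.character(profile)) profile <- readCultivarProfile(profile)
  if (is.character(image)) {
    if (!file.exists(image)) stop("image file not found: ", image)
    image <- png::readPNG(image)
    if (length(dim(image)) == 3L && dim(image)[3] == 4L)
      image <- image[, , 1:3]
  }
  if (is.character(depth)) depth <- readDepth(depth, intrinsics)
  if (is.character(detections)) {
    W <- dim(image)[2]; H <- dim(image)[1]
    detections <- readDetections(detections, imageSize = c(W, H))$boxes
  }
  meas <- measureFruits(detections, depth, intrinsics, profile = profile,
                        diameterMode = diameterMode)
  sco <- scoreFruits(image, detections, meas, profile)
  cl <- clusterFruits(meas, eps = eps, minSamples = minSamples,
                      profile = profile, literalCoords = literalCoords)
  fruits <- cbind(id = meas$id, detections,
                  meas[, setdiff(names(meas), "id")], sco,
                  plant_id = cl$labels)
  plants <- cl$plants
  # per-plant maturity-stage histogram
  for (st in c("immature", "ripe", "overripe"))
    plants[[paste0("n_", st)]] <- vapply(plants$plant_id, function(p)
      sum(fruits$stage[!is.na(fruits$plant_id) &
                         fruits$plant_id == p] == st, na.rm = TRUE), 1L)
  noise <- fruits$id[!is.na(fruits$plant_id) & fruits$plant_id == 0L]
  new("FruitAnalysis", fruits = fruits, plants = plants,
      noise = as.integer(noise),
      params = list(eps = eps, minSamples = minSamples,
                    literalCoords = literalCoords,
                    diameterMode = diameterMode, profile = profile@name))
}

#' Write analysis outputs
#'
#' Per-fruit CSV ('.' decimal separator, UTF-8, header row) and a
#' per-plant JSON report carrying a schema-version field, fruit ids,
#' counts, summed volumes, the volume-based yield estimate and the
#' maturity-stage histogram, plus the noise ids.
#'
#' @param analysis a \linkS4class{FruitAnalysis}.
#' @param csvPath,jsonPath output paths (either may be \code{NULL} to
#'   skip).
#' @return invisibly, the written paths.
#' @export
writeAnalysis <- function(analysis, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(analysis@fruits, csvPath, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(jsonPath)) {
    pl <- analysis@plants
    plants <- lapply(seq_len(nrow(pl)), function(i) list(
      plant_id = pl$plant_id[i],
      fruit_ids = pl$members[[i]],
      n_fruits = pl$n_fruits[i],
      total_volume_mm3 = pl$total_volume[i],
      yield_estimate = pl$yield_estimate[i],
      stage_histogram = list(immature = pl$n_immature[i],
                             ripe = pl$n_ripe[i],
                             overripe = pl$n_overripe[i])))
    jsonlite::write_json(list(schema_version = "1.0",
                              params = analysis@params,
                              plants = plants,
                              noise_ids = analysis@noise),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csvPath, json = jsonPath))
}
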