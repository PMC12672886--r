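#' Read detections from PASCAL VOC XML or YOLO text
#'
#' Both formats are mapped to the internal centre+extent pixel
#' convention. VOC corners are 1-based inclusive, so a box
#' (xmin 10, xmax 110) has extent 101 px and centre 60; YOLO rows are
#' \code{class cx cy w h [confidence]} normalised to [0, 1] and are
#' denormalised with the image size. Malformed records raise an error
#' naming the file and record index; an empty file yields an empty box
#' table with a warning.
#'
#' @param path annotation file.
#' @param format \code{"voc_xml"} or \code{"yolo_txt"}; guessed from the
#'   extension when omitted.
#' @param imageSize \code{c(width, height)} in pixels; required for YOLO,
#'   read from the XML for VOC when present.
#' @param classNames optional character vector mapping 0-based YOLO class
#'   indices to labels.
#' @return list with \code{source}, \code{format}, \code{imageSize} and
#'   the \code{boxes} table (see \code{\link{boundingBoxes}}).
#' @export
readDetections <- function(path, format = c("auto", "voc_xml", "yolo_txt"),
                           imageSize = NULL, classNames = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("detections file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE))
      "voc_xml" else "yolo_txt"
  if (format == "voc_xml") {
    doc <- xml2::read_xml(path)
    sz <- xml2::xml_find_first(doc, ".//size")
    if (!inherits(sz, "xml_missing"))
      imageSize <- c(as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./width"))),
                     as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./height"))))
    objs <- xml2::xml_find_all(doc, ".//object")
    if (!length(objs)) {
      warning("no objects in ", path)
      boxes <- boundingBoxes(numeric(0), numeric(0), numeric(0) + 1,
                             numeric(0) + 1)[0, ]
    } else {
      rows <- lapply(seq_along(objs), function(i) {
        o <- objs[[i]]
        get1 <- function(xp) {
          nd <- xml2::xml_find_first(o, xp)
          if (inherits(nd, "xml_missing"))
            stop("malformed VOC object ", i, " in ", path,
                 ": missing ", xp)
          xml2::xml_text(nd)
        }
        cc <- suppressWarnings(as.numeric(c(get1(".//xmin"), get1(".//ymin"),
                                            get1(".//xmax"), get1(".//ymax"))))
        if (any(is.na(cc)) || cc[3] < cc[1] || cc[4] < cc[2])
          stop("malformed VOC box in object ", i, " of ", path)
        conf <- xml2::xml_find_first(o, ".//confidence")
        data.frame(cx_px = (cc[1] + cc[3]) / 2, cy_px = (cc[2] + cc[4]) / 2,
                   w_px = cc[3] - cc[1] + 1, h_px = cc[4] - cc[2] + 1,
                   label = get1("./name"),
                   confidence = if (inherits(conf, "xml_missing")) 1
                                else as.numeric(xml2::xml_text(conf)))
      })
      boxes <- do.call(rbind, rows)
    }
  } else {
    if (is.null(imageSize))
      stop("YOLO detections need imageSize = c(width, height)")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("no detections in ", path)
      boxes <- boundingBoxes(numeric(0), numeric(0), numeric(0) + 1,
                             numeric(0) + 1)[0, ]
    } else {
      rows <- lapply(seq_along(lines), function(i) {
        f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                  "\\s+")[[1]]))
        if (length(f) < 5 || any(is.na(f[1:5])))
          stop("malformed YOLO row ", i, " in ", path)
        if (any(f[2:5] < 0) || any(f[2:5] > 1))
          stop("YOLO row ", i, " in ", path,
               " has coordinates outside [0, 1]")
        cls <- f[1]
        lab <- if (!is.null(classNames)) classNames[cls + 1]
               else as.character(cls)
        data.frame(cx_px = f[2] * imageSize[1], cy_px = f[3] * imageSize[2],
                   w_px = f[4] * imageSize[1], h_px = f[5] * imageSize[2],
                   label = lab,
                   confidence = if (length(f) >= 6) f[6] else 1)
      })
      boxes <- do.call(rbind, rows)
    }
  }
  list(source = path, format = format, imageSize = imageSize, boxes = boxes)
}

#' Write detections as PASCAL VOC XML or YOLO text
#'
#' Inverse of \code{\link{readDetections}}. VOC corners are rounded to
#' integers (1-based inclusive), so a round trip recovers boxes within
#' one pixel; YOLO coordinates are written at full precision and round
#' trip exactly.
#'
#' @param boxes box table.
#' @param path output file.
#' @param format \code{"voc_xml"} or \code{"yolo_txt"}.
#' @param imageSize \code{c(width, height)} pixels.
#' @param classNames labels, in 0-based class-index order, for YOLO.
#' @return \code{path}, invisibly.
#' @export
writeDetections <- function(boxes, path, format = c("voc_xml", "yolo_txt"),
                            imageSize, classNames = NULL) {
  format <- match.arg(format)
  if (format == "voc_xml") {
    doc <- xml2::xml_new_root("annotation")
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(imageSize[1]))
    xml2::xml_add_child(sz, "height", as.character(imageSize[2]))
    xml2::xml_add_child(sz, "depth", "3")
    for (i in seq_len(nrow(boxes))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", boxes$label[i])
      xml2::xml_add_child(o, "confidence",
                          format(boxes$confidence[i], digits = 10))
      bb <- xml2::xml_add_child(o, "bndbox")
      xmin <- round(boxes$cx_px[i] - (boxes$w_px[i] - 1) / 2)
      xmax <- round(boxes$cx_px[i] + (boxes$w_px[i] - 1) / 2)
      ymin <- round(boxes$cy_px[i] - (boxes$h_px[i] - 1) / 2)
      ymax <- round(boxes$cy_px[i] + (boxes$h_px[i] - 1) / 2)
      xml2::xml_add_child(bb, "xmin", as.character(xmin))
      xml2::xml_add_child(bb, "ymin", as.character(ymin))
      xml2::xml_add_child(bb, "xmax", as.character(xmax))
      xml2::xml_add_child(bb, "ymax", as.character(ymax))
    }
    xml2::write_xml(doc, path)
  } else {
    cls <- if (is.null(classNames)) rep(0L, nrow(boxes))
           else match(boxes$label, classNames) - 1L
    lines <- sprintf("%d %.10g %.10g %.10g %.10g %.10g",
                     cls,
                     boxes$cx_px / imageSize[1], boxes$cy_px / imageSize[2],
                     boxes$w_px / imageSize[1], boxes$h_px / imageSize[2],
                     boxes$confidence)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read or write a depth map
#'
#' The package's native depth format is a raw little-endian binary file:
#' a 4-byte magic \code{"TPDM"}, two int32 (rows, cols), then float32
#' depth counts in column-major order. \code{readDepth} additionally
#' accepts single-channel PNG depth maps (8- or 16-bit), whose counts are
#' recovered from the PNG sample depth. In both cases counts are
#' multiplied by the intrinsics' \code{depthScale} to yield millimetres.
#'
#' @param path depth file (\code{.png} or raw binary).
#' @param intr \linkS4class{CameraIntrinsics} supplying \code{depthScale}.
#' @return \code{readDepth}: numeric matrix of depths in millimetres.
#' @export
readDepth <- function(path, intr = CameraIntrinsics()) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    if (length(dim(img)) == 3L) img <- img[, , 1]
    counts <- matrix(as.numeric(img) * (2^bits - 1),
                     nrow(img), ncol(img))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", 4))
    if (magic != "TPDM") stop(path, " is not a depth-map file")
    dims <- readBin(con, "integer", 2, size = 4, endian = "little")
    vals <- readBin(con, "numeric", prod(dims), size = 4,
                    endian = "little")
    counts <- matrix(vals, dims[1], dims[2])
  }
  counts * intr@depthScale
}

#' @rdname readDepth
#' @param depth numeric matrix of depths in millimetres.
#' @return \code{writeDepth}: \code{path}, invisibly.
#' @export
writeDepth <- function(depth, path, intr = CameraIntrinsics()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TPDM"), con)
  writeBin(as.integer(dim(depth)), con, size = 4, endian = "little")
  writeBin(as.numeric(depth / intr@depthScale), con, size = 4,
           endian = "little")
  invisible(path)
}

#' Write a scene bundle to disk
#'
#' Emits the RGB image (8-bit PNG), the depth map (native raw format,
#' in counts of the intrinsics' \code{depthScale}), annotations in both
#' PASCAL VOC XML and YOLO text, a JSON ground-truth sidecar, the camera
#' intrinsics (YAML) and the cultivar profile (YAML).
#'
#' @param scene a \linkS4class{TomatoScene}.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default \code{"scene"}).
#' @return named character vector of the written paths, invisibly.
#' @export
writeScene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  intr <- scene@spec$intrinsics
  W <- dim(scene@rgb)[2]; H <- dim(scene@rgb)[1]
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             depth = file.path(dir, paste0(stem, ".depth")),
             voc = file.path(dir, paste0(stem, ".xml")),
             yolo = file.path(dir, paste0(stem, ".txt")),
             truth = file.path(dir, paste0(stem, "_truth.json")),
             intrinsics = file.path(dir, paste0(stem, "_intrinsics.yaml")),
             profile = file.path(dir, paste0(stem, "_cultivar.yaml")))
  png::writePNG(scene@rgb, paths[["image"]])
  writeDepth(scene@depth, paths[["depth"]], intr)
  boxes <- boundingBoxes(scene@truth$cx_px, scene@truth$cy_px,
                         scene@truth$w_px, scene@truth$h_px)
  writeDetections(boxes, paths[["voc"]], "voc_xml", c(W, H))
  writeDetections(boxes, paths[["yolo"]], "yolo_txt", c(W, H))
  jsonlite::write_json(list(schema_version = "1.0",
                            seed = scene@seed,
                            image_size = c(W, H),
                            fruits = scene@truth),
                       paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  writeCameraIntrinsics(intr, paths[["intrinsics"]])
  writeCultivarProfile(scene@spec$profile, paths[["profile"]])
  invisible(paths)
}

#' Read a scene ground-truth sidecar
#'
#' @param path the \code{*_truth.json} file written by
#'   \code{\link{writeScene}}.
#' @return list with \code{seed}, \code{image_size} and the \code{fruits}
#'   ground-truth \code{data.frame}.
#' @export
readSceneTruth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
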