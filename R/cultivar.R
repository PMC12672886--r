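#' Construct a cultivar profile
#'
#' Returns a \linkS4class{CultivarProfile} whose defaults encode the
#' beefsteak-tomato calibration: hue bands ripe \eqn{[0,20)\cup[330,360]},
#' overripe \eqn{[20,40)}, unripe \eqn{[50,100)}; colour coefficients
#' \code{h1=0.5, h2=0.2, c1=0.015, c2=0.01}; diameter thresholds
#' 50/70/85 mm with size weights \code{s1=0.3, s2=0.7, s3=0.2}; shape
#' weights \code{p1=0.2, p2=0.3, p3=0.4} with breakpoints 0.3/0.7;
#' fusion weights \code{wc=0.5, wd=0.3, ws=0.2} (colour most
#' discriminative, shape least); classification thresholds 0.4/0.7;
#' ellipticity \code{k=0.9}; yield density \code{omega=1e-5} per mm^3.
#'
#' The overripe diameter threshold must be strictly greater than the ripe
#' one (the overripe branch of the size score divides by their difference);
#' equality is rejected at construction.
#'
#' @param name cultivar name.
#' @param ripeBands 2x2 matrix of the two ripe hue intervals, degrees.
#' @param overripeBand,unripeBand hue intervals, degrees.
#' @param h1,h2,c1,c2 colour-score coefficients.
#' @param fallbackScore score for hues outside every band (default 0).
#' @param dUnripe,dRipe,dOverripe diameter thresholds, mm.
#' @param s1,s2,s3 size-score weights.
#' @param p1,p2,p3 shape-score weights.
#' @param break1,break2 shape-deviation breakpoints.
#' @param wc,wd,ws fusion weights; must sum to 1.
#' @param classifyLo,classifyHi ripeness classification thresholds.
#' @param k ellipticity correction factor, typically 0.85-0.95.
#' @param omega yield density parameter, per mm^3.
#' @return A validated \linkS4class{CultivarProfile}.
#' @examples
#' prof <- cultivarProfile()
#' prof
#' @export
cultivarProfile <- function(name = "beefsteak",
                            ripeBands = rbind(c(0, 20), c(330, 360)),
                            overripeBand = c(20, 40),
                            unripeBand = c(50, 100),
                            h1 = 0.5, h2 = 0.2, c1 = 0.015, c2 = 0.01,
                            fallbackScore = 0,
                            dUnripe = 50, dRipe = 70, dOverripe = 85,
                            s1 = 0.3, s2 = 0.7, s3 = 0.2,
                            p1 = 0.2, p2 = 0.3, p3 = 0.4,
                            break1 = 0.3, break2 = 0.7,
                            wc = 0.5, wd = 0.3, ws = 0.2,
                            classifyLo = 0.4, classifyHi = 0.7,
                            k = 0.9, omega = 1e-5) {
  new("CultivarProfile", name = name,
      ripeBands = matrix(as.numeric(ripeBands), ncol = 2),
      overripeBand = as.numeric(overripeBand),
      unripeBand = as.numeric(unripeBand),
      h1 = h1, h2 = h2, c1 = c1, c2 = c2, fallbackScore = fallbackScore,
      dUnripe = dUnripe, dRipe = dRipe, dOverripe = dOverripe,
      s1 = s1, s2 = s2, s3 = s3, p1 = p1, p2 = p2, p3 = p3,
      break1 = break1, break2 = break2,
      wc = wc, wd = wd, ws = ws,
      classifyLo = classifyLo, classifyHi = classifyHi,
      k = k, omega = omega)
}

profileToList <- function(p) {
  list(name = p@name,
       hue = list(ripe = list(as.numeric(p@ripeBands[1, ]),
                              as.numeric(p@ripeBands[2, ])),
                  overripe = as.numeric(p@overripeBand),
                  unripe = as.numeric(p@unripeBand)),
       color = list(h1 = p@h1, h2 = p@h2, c1 = p@c1, c2 = p@c2,
                    fallback = p@fallbackScore),
       size = list(dUnripe = p@dUnripe, dRipe = p@dRipe,
                   dOverripe = p@dOverripe, s1 = p@s1, s2 = p@s2, s3 = p@s3),
       shape = list(p1 = p@p1, p2 = p@p2, p3 = p@p3,
                    break1 = p@break1, break2 = p@break2),
       fusion = list(wc = p@wc, wd = p@wd, ws = p@ws),
       classify = list(lo = p@classifyLo, hi = p@classifyHi),
       k = p@k, omega = p@omega)
}

#' Read or write a cultivar profile as YAML
#'
#' The on-disk schema mirrors the model groups: \code{hue}, \code{color},
#' \code{size}, \code{shape}, \code{fusion}, \code{classify}, plus scalar
#' \code{k} and \code{omega}. Fields absent from the file keep their
#' defaults; structurally invalid values are rejected by the class
#' validity checks at load time.
#'
#' @param path file path.
#' @return \code{readCultivarProfile}: a \linkS4class{CultivarProfile}.
#' @export
readCultivarProfile <- function(path) {
  if (!file.exists(path)) stop("cultivar profile not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$name)) args$name <- y$name
  if (!is.null(y$hue)) {
    if (!is.null(y$hue$ripe))
      args$ripeBands <- rbind(unlist(y$hue$ripe[[1]]), unlist(y$hue$ripe[[2]]))
    if (!is.null(y$hue$overripe)) args$overripeBand <- unlist(y$hue$overripe)
    if (!is.null(y$hue$unripe)) args$unripeBand <- unlist(y$hue$unripe)
  }
  grab <- function(group, fields, rename = NULL) {
    g <- y[[group]]
    for (f in fields) if (!is.null(g[[f]])) {
      nm <- if (!is.null(rename[[f]])) rename[[f]] else f
      args[[nm]] <<- g[[f]]
    }
  }
  grab("color", c("h1", "h2", "c1", "c2", "fallback"),
       list(fallback = "fallbackScore"))
  grab("size", c("dUnripe", "dRipe", "dOverripe", "s1", "s2", "s3"))
  grab("shape", c("p1", "p2", "p3", "break1", "break2"))
  grab("fusion", c("wc", "wd", "ws"))
  grab("classify", c("lo", "hi"), list(lo = "classifyLo", hi = "classifyHi"))
  if (!is.null(y$k)) args$k <- y$k
  if (!is.null(y$omega)) args$omega <- y$omega
  do.call(cultivarProfile, args)
}

#' @rdname readCultivarProfile
#' @param profile a \linkS4class{CultivarProfile}.
#' @return \code{writeCultivarProfile}: \code{path}, invisibly.
#' @export
writeCultivarProfile <- function(profile, path) {
  yaml::write_yaml(profileToList(profile), path)
  invisible(path)
}

#' Read or write camera intrinsics (YAML or JSON)
#'
#' A flat mapping \code{fw, fh, cx, cy, depth_scale} (snake_case, the
#' conventional calibration-file key) or \code{depthScale} is accepted;
#' format is chosen by file extension (\code{.json} versus anything else
#' parsed as YAML, of which JSON is a subset).
#'
#' @param path file path.
#' @return \code{readCameraIntrinsics}: a \linkS4class{CameraIntrinsics}.
#' @export
readCameraIntrinsics <- function(path) {
  if (!file.exists(path)) stop("intrinsics file not found: ", path)
  y <- yaml::read_yaml(path)
  ds <- if (!is.null(y$depth_scale)) y$depth_scale else y$depthScale
  if (is.null(ds)) ds <- 1
  for (f in c("fw", "fh", "cx", "cy"))
    if (is.null(y[[f]])) stop("intrinsics file ", path, " lacks field '", f, "'")
  CameraIntrinsics(fw = y$fw, fh = y$fh, cx = y$cx, cy = y$cy, depthScale = ds)
}

#' @rdname readCameraIntrinsics
#' @param intr a \linkS4class{CameraIntrinsics}.
#' @return \code{writeCameraIntrinsics}: \code{path}, invisibly.
#' @export
writeCameraIntrinsics <- function(intr, path) {
  yaml::write_yaml(list(fw = intr@fw, fh = intr@fh, cx = intr@cx,
                        cy = intr@cy, depth_scale = intr@depthScale), path)
  invisible(path)
}
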