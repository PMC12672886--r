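boxIoUpx <- function(a, b) {
  boxIoU(c(cx = a$cx_px, cy = a$cy_px, w = a$w_px, h = a$h_px),
         c(cx = b$cx_px, cy = b$cy_px, w = b$w_px, h = b$h_px))
}

#' Detection precision, recall and average precision
#'
#' Greedy confidence-ranked matching: predictions are visited in
#' decreasing confidence and matched to the unmatched truth of highest
#' IoU; a match at or above the IoU threshold is a true positive,
#' anything else a false positive, unmatched truths are false negatives.
#' Precision is TP / (TP + FP), recall TP / (TP + FN), and AP the area
#' under the precision envelope of the PR curve (all-points
#' interpolation). With no predictions, precision is reported as 0 with
#' the \code{undefined_precision} flag set.
#'
#' @param preds box table with a \code{confidence} column.
#' @param truths box table of ground-truth boxes (same pixel frame).
#' @param iouThreshold matching threshold (default 0.5).
#' @return list with \code{precision}, \code{recall}, \code{ap},
#'   \code{tp}, \code{fp}, \code{fn}, \code{matches} (pred row ->
#'   truth row or NA) and \code{undefined_precision}.
#' @export
detectionPrAp <- function(preds, truths, iouThreshold = 0.5) {
  nP <- nrow(preds); nT <- nrow(truths)
  if (nP == 0L)
    return(list(precision = 0, recall = 0, ap = 0, tp = 0L, fp = 0L,
                fn = nT, matches = integer(0), undefined_precision = TRUE))
  ord <- order(preds$confidence, decreasing = TRUE)
  matchedT <- logical(nT)
  isTP <- logical(nP)
  matches <- rep(NA_integer_, nP)
  for (i in ord) {
    if (nT == 0L) break
    ious <- vapply(seq_len(nT), function(j)
      boxIoUpx(preds[i, ], truths[j, ]), 1.0)
    ious[matchedT] <- -1
    j <- which.max(ious)
    if (ious[j] >= iouThreshold) {
      isTP[i] <- TRUE
      matchedT[j] <- TRUE
      matches[i] <- j
    }
  }
  tp <- sum(isTP); fp <- nP - tp; fn <- nT - tp
  # PR curve down the confidence ranking
  cumTP <- cumsum(isTP[ord]); cumFP <- cumsum(!isTP[ord])
  rec <- if (nT > 0) cumTP / nT else rep(0, nP)
  prec <- cumTP / (cumTP + cumFP)
  # precision envelope, then sum rectangle areas between recall steps
  env <- rev(cummax(rev(prec)))
  r0 <- c(0, rec[-nP])
  ap <- sum((rec - r0) * env)
  list(precision = tp / (tp + fp), recall = if (nT > 0) tp / nT else 0,
       ap = ap, tp = tp, fp = fp, fn = fn, matches = matches,
       undefined_precision = FALSE)
}

stageLevels <- c("immature", "ripe", "overripe")

#' Maturity-stage confusion matrix
#'
#' 3x3 matrix with true stages as rows and predicted stages as columns,
#' ordered immature / ripe / overripe; overall accuracy is the trace over
#' the total, and per-class F1 the harmonic mean of per-class precision
#' and recall (0 where undefined).
#'
#' @param pred,truth equal-length character vectors of stage labels.
#' @return list with \code{confusion}, \code{accuracy}, \code{f1}.
#' @export
stageConfusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (!all(c(pred, truth) %in% stageLevels))
    stop("unknown stage label; expected one of ",
         paste(stageLevels, collapse = "/"))
  cm <- table(factor(truth, stageLevels), factor(pred, stageLevels))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(truth = stageLevels, pred = stageLevels))
  acc <- if (sum(cm) > 0) sum(diag(cm)) / sum(cm) else NA_real_
  f1 <- vapply(seq_len(3), function(i) {
    p <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
    r <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, 1.0)
  names(f1) <- stageLevels
  list(confusion = cm, accuracy = acc, f1 = f1)
}

#' Per-plant counting error metrics
#'
#' Standard definitions over paired per-plant counts: mean absolute
#' error, mean squared error, the coefficient of determination
#' \code{R^2 = 1 - SSres / SStot} (reported as computed, so it may be
#' negative; undefined and flagged with fewer than two plants or zero
#' truth variance) and the signed-error histogram.
#'
#' @param predCounts,trueCounts equal-length numeric vectors.
#' @return list with \code{mae}, \code{mse}, \code{r2},
#'   \code{r2_defined}, \code{errors} (pred - true) and
#'   \code{error_histogram}.
#' @examples
#' countingMetrics(c(5, 6), c(4, 6)) # MAE 0.5, MSE 0.5
#' @export
countingMetrics <- function(predCounts, trueCounts) {
  stopifnot(length(predCounts) == length(trueCounts))
  err <- predCounts - trueCounts
  mae <- mean(abs(err)); mse <- mean(err^2)
  sstot <- sum((trueCounts - mean(trueCounts))^2)
  defined <- length(trueCounts) >= 2 && sstot > 0
  r2 <- if (defined) 1 - sum(err^2) / sstot else NA_real_
  list(mae = mae, mse = mse, r2 = r2, r2_defined = defined,
       errors = err, error_histogram = table(err))
}

#' Evaluate an analysis against scene ground truth
#'
#' Matches analysed fruits to ground-truth fruits by box IoU (greedy,
#' threshold 0.3 — the boxes come from the same scene, so matching is
#' essentially identity), then reports: the stage confusion
#' matrix/accuracy/F1 over matched fruits; diameter absolute errors;
#' per-plant counting MAE/MSE/R2 (predicted cluster sizes against true
#' per-plant counts, clusters paired to plants by majority membership of
#' their matched fruits); and the Adjusted Rand Index between the DBSCAN
#' partition and the true plant partition.
#'
#' @param analysis a \linkS4class{FruitAnalysis}.
#' @param truth ground-truth \code{data.frame} (from
#'   \code{\link{sceneTruth}} or \code{\link{readSceneTruth}}).
#' @return an evaluation-report list with a \code{schema_version} field.
#' @export
evaluateScene <- function(analysis, truth) {
  fr <- analysis@fruits
  mt <- detectionPrAp(fr, truth, iouThreshold = 0.3)
  matched <- which(!is.na(mt$matches))
  ti <- mt$matches[matched]
  stage <- stageConfusion(fr$stage[matched], truth$stage[ti])
  dErr <- abs(fr$dreal[matched] - truth$diameter_mm[ti])
  # pair clusters with plants by majority vote of matched members
  predLab <- fr$plant_id[matched]
  trueLab <- truth$plant_id[ti]
  ari <- mclust::adjustedRandIndex(predLab, trueLab)
  trueCounts <- table(factor(truth$plant_id,
                             sort(unique(truth$plant_id))))
  predCounts <- stats::setNames(rep(0, length(trueCounts)),
                                names(trueCounts))
  for (cl in setdiff(unique(predLab), NA)) {
    members <- trueLab[predLab == cl]
    plant <- names(sort(table(members), decreasing = TRUE))[1]
    predCounts[plant] <- predCounts[plant] +
      sum(fr$plant_id == cl, na.rm = TRUE)
  }
  cnt <- countingMetrics(as.numeric(predCounts), as.numeric(trueCounts))
  list(schema_version = "1.0",
       n_truth = nrow(truth), n_pred = nrow(fr),
       n_matched = length(matched),
       stage_confusion = stage$confusion,
       stage_accuracy = stage$accuracy,
       stage_f1 = as.list(stage$f1),
       diameter_mae_mm = if (length(dErr)) mean(dErr) else NA_real_,
       diameter_max_err_mm = if (length(dErr)) max(dErr) else NA_real_,
       clustering_ari = ari,
       counting = cnt[c("mae", "mse", "r2", "r2_defined")],
       detection = mt[c("precision", "recall", "ap", "tp", "fp", "fn")])
}

#' Write an evaluation report as JSON
#'
#' @param report list from \code{\link{evaluateScene}} (or any
#'   JSON-serialisable report).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvaluation <- function(report, path) {
  report$stage_confusion <- as.data.frame(as.table(report$stage_confusion))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
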