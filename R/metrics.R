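#' Intersection-over-union of two boxes
#'
#' Boxes are lists/one-row data.frames with x_min, y_min, x_max, y_max in the
#' half-open pixel convention.
#'
#' @param a,b boxes.
#' @return IoU in [0, 1].
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
           (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  if (union <= 0) 0 else inter / union
}

#' Greedily match detections to ground-truth boxes
#'
#' Detections are processed in descending confidence (ties: earlier row
#' first); each claims the not-yet-matched ground truth of the same image
#' with the highest IoU at or above the threshold (ties: earlier ground-truth
#' row) and becomes a true positive, otherwise a false positive. Each ground
#' truth matches at most one detection; unmatched ground truths are the false
#' negatives.
#'
#' @param dets data.frame of detections (image_id, x_min, y_min, x_max,
#'   y_max, confidence).
#' @param gts data.frame of ground-truth boxes (image_id, x_min, y_min,
#'   x_max, y_max).
#' @param iouThreshold matching threshold in (0, 1), default 0.5.
#' @return a \linkS4class{MatchOutcome}.
#' @export
matchDetections <- function(dets, gts, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold >= 1)
    stopf("iouThreshold must be in (0, 1)")
  if (nrow(dets)) {
    if (!"confidence" %in% names(dets)) stopf("detections need a confidence column")
    if (any(dets$confidence < 0 | dets$confidence > 1))
      stopf("confidence must be in [0, 1]")
    checkBoxes(dets, what = "detection")
  }
  if (nrow(gts)) checkBoxes(gts, what = "ground-truth box")
  ord <- if (nrow(dets)) order(-dets$confidence, seq_len(nrow(dets))) else integer(0)
  gtMatched <- rep(FALSE, nrow(gts))
  tp <- logical(length(ord))
  for (i in seq_along(ord)) {
    d <- dets[ord[i], ]
    cand <- which(!gtMatched & gts$image_id == d$image_id)
    if (length(cand)) {
      ious <- vapply(cand, function(g) boxIoU(d, gts[g, ]), 0)
      best <- which(ious >= iouThreshold)
      if (length(best)) {
        # highest IoU, earliest ground-truth row on ties
        pick <- cand[best[which.max(ious[best])]]
        gtMatched[pick] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  det <- data.frame(
    image_id = if (nrow(dets)) as.character(dets$image_id[ord]) else character(0),
    confidence = if (nrow(dets)) dets$confidence[ord] else numeric(0),
    tp = tp, stringsAsFactors = FALSE)
  new("MatchOutcome", detections = det,
      nGroundTruths = as.integer(nrow(gts)), iouThreshold = iouThreshold)
}

#' Precision-recall points from a match outcome
#'
#' Sweeps the confidence threshold down the sorted detections; after each cut
#' precision = TP / (TP + FP) and recall = TP / (TP + FN), where FN counts
#' the ground truths not matched above the cut.
#'
#' @param outcome a \linkS4class{MatchOutcome} with at least one detection or
#'   ground truth.
#' @return a \linkS4class{PRCurve} (ap not yet computed).
#' @export
precisionRecall <- function(outcome) {
  det <- outcome@detections
  nGT <- outcome@nGroundTruths
  if (nrow(det) == 0L && nGT == 0L)
    stopf("zero detections and zero ground truths: nothing to evaluate")
  tpCum <- cumsum(det$tp)
  fpCum <- cumsum(!det$tp)
  n <- nrow(det)
  points <- data.frame(
    confidence = det$confidence,
    tp_cum = tpCum, fp_cum = fpCum,
    precision = if (n) tpCum / seq_len(n) else numeric(0),
    recall = if (n) { if (nGT > 0) tpCum / nGT else rep(0, n) } else numeric(0))
  new("PRCurve", points = points, ap = NA_real_, nGroundTruths = nGT)
}

.apInterpolated <- function(recall, precision) {
  # all-point interpolation: envelope precision from the right, integrate
  # over recall steps
  penv <- rev(cummax(rev(precision)))  # max precision at recall >= r
  dr <- diff(c(0, recall))
  sum(dr * penv)
}

.apElevenPoint <- function(recall, precision) {
  env <- rev(cummax(rev(precision)))
  pts <- vapply(seq(0, 1, 0.1), function(r) {
    ok <- which(recall >= r - 1e-12)
    if (length(ok)) env[ok[1]] else 0
  }, 0)
  mean(pts)
}

#' Average precision of a PR curve
#'
#' Integrates precision over recall in [0, 1] using the interpolated-
#' precision envelope (precision at recall r is replaced by the maximum
#' precision achieved at any recall >= r), summed over the distinct recall
#' steps. The classic 11-point interpolation is available for comparison.
#'
#' @param x a \linkS4class{PRCurve} (or its points data.frame with columns
#'   recall and precision).
#' @param method "interpolated" (all-point, default) or "eleven_point".
#' @param ... unused.
#' @return AP in [0, 1].
#' @export
setMethod("averagePrecision", "PRCurve", function(x, method = c("interpolated", "eleven_point"), ...) {
  averagePrecision(x@points, method = method)
})

#' @rdname averagePrecision-PRCurve-method
#' @export
setMethod("averagePrecision", "data.frame", function(x, method = c("interpolated", "eleven_point"), ...) {
  method <- match.arg(method)
  if (nrow(x) == 0L) stopf("empty PR curve")
  if (method == "interpolated") .apInterpolated(x$recall, x$precision)
  else .apElevenPoint(x$recall, x$precision)
})

#' Evaluate detections end to end
#'
#' Convenience wrapper: match, sweep, integrate. Returns the PR curve with
#' its AP filled in.
#'
#' @param dets,gts,iouThreshold as in \code{\link{matchDetections}}.
#' @param method AP interpolation method.
#' @return a \linkS4class{PRCurve} with \code{ap} set.
#' @export
evaluateDetections <- function(dets, gts, iouThreshold = 0.5,
                               method = "interpolated") {
  outcome <- matchDetections(dets, gts, iouThreshold)
  curve <- precisionRecall(outcome)
  ap <- if (nrow(curve@points)) averagePrecision(curve, method = method) else 0
  new("PRCurve", points = curve@points, ap = ap,
      nGroundTruths = curve@nGroundTruths)
}
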