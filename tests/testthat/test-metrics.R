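box <- function(xm, ym, xM, yM, image_id = "img", confidence = NULL) {
  b <- data.frame(image_id = image_id, x_min = xm, y_min = ym,
                  x_max = xM, y_max = yM, stringsAsFactors = FALSE)
  if (!is.null(confidence)) b$confidence <- confidence
  b
}

test_that("IoU handles identity, disjointness and the half-offset square", {
  a <- list(x_min = 0, y_min = 0, x_max = 2, y_max = 2)
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, list(x_min = 5, y_min = 5, x_max = 7, y_max = 7)), 0)
  # unit squares offset by half their width: overlap 0.5, union 1.5
  u1 <- list(x_min = 0, y_min = 0, x_max = 1, y_max = 1)
  u2 <- list(x_min = 0.5, y_min = 0, x_max = 1.5, y_max = 1)
  expect_equal(boxIoU(u1, u2), 1 / 3)
})

test_that("coincident detections all match; no detections leaves all FNs", {
  gts <- rbind(box(0, 0, 10, 10), box(20, 20, 30, 30))
  dets <- rbind(box(0, 0, 10, 10, confidence = 0.9),
                box(20, 20, 30, 30, confidence = 0.8))
  out <- matchDetections(dets, gts)
  expect_true(all(out@detections$tp))
  expect_equal(out@nGroundTruths - sum(out@detections$tp), 0)

  none <- matchDetections(dets[0, ], gts)
  expect_equal(nrow(none@detections), 0)
  expect_equal(none@nGroundTruths, 2L)
  expect_error(matchDetections(dets, gts, iouThreshold = 1.5), "in \\(0, 1\\)")
})

test_that("greedy matching equals exhaustive assignment enumeration", {
  set.seed(404)
  for (rep in 1:25) {
    nG <- sample(1:4, 1); nD <- sample(1:5, 1)
    gts <- do.call(rbind, lapply(seq_len(nG), function(i) {
      xm <- sample(0:30, 1); ym <- sample(0:30, 1)
      box(xm, ym, xm + sample(5:15, 1), ym + sample(5:15, 1))
    }))
    dets <- do.call(rbind, lapply(seq_len(nD), function(i) {
      g <- sample(nG, 1)
      off <- sample(-6:6, 2)
      box(gts$x_min[g] + off[1], gts$y_min[g] + off[2],
          gts$x_max[g] + off[1], gts$y_max[g] + off[2],
          confidence = round(runif(1), 3))
    }))
    got <- matchDetections(dets, gts, 0.5)
    oracle <- matchOracle(dets, gts, 0.5)
    expect_equal(got@detections$tp, oracle$tp)
    # conservation: TP + FN = #GT
    expect_equal(sum(got@detections$tp) +
                   (got@nGroundTruths - sum(got@detections$tp)),
                 got@nGroundTruths)
    expect_lte(sum(got@detections$tp), min(nD, nG))
  }
})

test_that("precision/recall sweep matches the tabulated hand computation", {
  # 5 detections sorted by confidence: TP, FP, TP, TP, FP against 4 GTs
  det <- data.frame(image_id = "img",
                    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5),
                    tp = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- new("MatchOutcome", detections = det, nGroundTruths = 4L,
             iouThreshold = 0.5)
  curve <- precisionRecall(out)
  p <- prPoints(curve)
  expect_equal(p$precision, c(1, 1/2, 2/3, 3/4, 3/5))
  expect_equal(p$recall, c(1/4, 1/4, 2/4, 3/4, 3/4))
  expect_equal(p$tp_cum + p$fp_cum, 1:5)
  expect_false(is.unsorted(p$recall))
  expect_error(precisionRecall(new("MatchOutcome",
                                   detections = det[0, ],
                                   nGroundTruths = 0L, iouThreshold = 0.5)),
               "nothing to evaluate")
})

test_that("average precision integrates the interpolated envelope", {
  pts <- data.frame(recall = c(0.5, 1.0), precision = c(1.0, 0.5))
  expect_equal(averagePrecision(pts), 0.75)
  # perfect detector
  perfect <- data.frame(recall = c(0.5, 1), precision = c(1, 1))
  expect_equal(averagePrecision(perfect), 1)
  # all false positives
  expect_equal(averagePrecision(data.frame(recall = c(0, 0),
                                           precision = c(0, 0))), 0)
  expect_error(averagePrecision(pts[0, ]), "empty")
  # random curves agree with the direct step-area oracle
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    tp <- runif(n) < 0.6
    nGT <- sum(tp) + sample(0:3, 1)
    det <- data.frame(image_id = "i", confidence = sort(runif(n), TRUE),
                      tp = tp)
    curve <- precisionRecall(new("MatchOutcome", detections = det,
                                 nGroundTruths = as.integer(max(nGT, 1)),
                                 iouThreshold = 0.5))
    p <- prPoints(curve)
    ap <- averagePrecision(curve)
    expect_equal(ap, apOracle(p$recall, p$precision), tolerance = 1e-12)
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
})

test_that("AP is invariant under monotone confidence rescaling", {
  gts <- rbind(box(0, 0, 10, 10), box(30, 0, 45, 12), box(0, 30, 14, 44))
  dets <- rbind(box(1, 1, 11, 11, confidence = 0.9),
                box(31, 0, 45, 12, confidence = 0.6),
                box(60, 60, 70, 70, confidence = 0.5),
                box(0, 29, 14, 43, confidence = 0.3))
  ap1 <- evaluateDetections(dets, gts)@ap
  dets2 <- dets; dets2$confidence <- dets$confidence^3 / 2
  expect_equal(evaluateDetections(dets2, gts)@ap, ap1)
  expect_gt(ap1, 0); expect_lt(ap1, 1)
  # eleven-point variant stays within [0, 1] and near the all-point value
  curve <- evaluateDetections(dets, gts)
  ap11 <- averagePrecision(curve, method = "eleven_point")
  expect_gte(ap11, 0); expect_lte(ap11, 1)
})
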