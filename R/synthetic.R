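#' Create a synthetic scene specification
#'
#' Scenes emulate overhead wheat-spike imagery: elliptical Gaussian-intensity
#' blobs ("spikes") on a flat or textured background, with bounding-box areas
#' drawn from a log-normal distribution. The log-normal's median is given in
#' px^2, mirroring the "average spike size" scale of multi-site wheat
#' phenotyping data; its log-sd controls the within-scene size spread.
#'
#' @param imageSize integer c(height, width), default c(1024, 1024).
#' @param nObjects number of spikes.
#' @param medianArea median bounding-box area, px^2.
#' @param dispersion log-scale sd of the area distribution (default 0.25,
#'   a moderate ~25\% spread).
#' @param aspectRatioRange width/height range of the boxes, default
#'   c(0.5, 2).
#' @param maxOverlapIoU maximum tolerated box-box IoU, default 0.3.
#' @param background "flat" or "textured-noise".
#' @param noiseSd additive pixel-noise sd, default 0.02.
#' @param seed integer seed.
#' @return a \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(imageSize = c(1024L, 1024L), nObjects = 30L,
                      medianArea = 4660, dispersion = 0.25,
                      aspectRatioRange = c(0.5, 2), maxOverlapIoU = 0.3,
                      background = "flat", noiseSd = 0.02, seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      nObjects = as.integer(nObjects), medianArea = medianArea,
      dispersion = dispersion, aspectRatioRange = as.numeric(aspectRatioRange),
      maxOverlapIoU = maxOverlapIoU, background = background,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Scene presets emulating the four multi-site sub-dataset scales
#'
#' Median bounding-box areas and per-image object counts follow the average
#' spike sizes and spikes-per-image of the four sub-datasets used for
#' interpretive analysis: ethz-like 4783 px^2 (69 spikes), arvalis-like
#' 6312 px^2 (43), usask-like 9247 px^2 (29), inrae-like 15271 px^2 (21),
#' all on 1024 x 1024 images.
#'
#' @param name one of "ethz-like", "arvalis-like", "usask-like",
#'   "inrae-like".
#' @param seed integer seed.
#' @return a \linkS4class{SceneSpec}.
#' @export
scenePreset <- function(name = c("ethz-like", "arvalis-like", "usask-like",
                                 "inrae-like"), seed = 1L) {
  name <- match.arg(name)
  p <- switch(name,
    "ethz-like"    = list(area = 4783,  n = 69L),
    "arvalis-like" = list(area = 6312,  n = 43L),
    "usask-like"   = list(area = 9247,  n = 29L),
    "inrae-like"   = list(area = 15271, n = 21L))
  sceneSpec(imageSize = c(1024L, 1024L), nObjects = p$n,
            medianArea = p$area, seed = seed)
}

.PLACEMENT_RETRIES <- 200L

#' Generate a labeled synthetic spike scene
#'
#' Places elliptical Gaussian-intensity blobs with log-normally distributed
#' bounding-box areas and uniform aspect ratios, rejecting placements whose
#' box IoU with any earlier box exceeds the spec's cap (up to 200 retries per
#' object). A blob's support is the set of pixels above 10\% of its peak —
#' an ellipse inscribed in the sampled box — and its ground-truth box is the
#' tight bounding box of that support. Fully deterministic under the spec's
#' seed.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param imageId image identifier written into the box table.
#' @return list with \code{image} (H x W matrix in [0, 1]) and \code{boxes}
#'   (data.frame image_id, box_id, x_min, y_min, x_max, y_max in 0-based
#'   half-open pixels).
#' @export
generateScene <- function(spec, imageId = "scene") {
  validObject(spec)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  withLocalSeed(spec@seed, {
    img <- matrix(0.15, H, W)
    if (spec@background == "textured-noise")
      img <- img + matrix(stats::rnorm(H * W, 0, 0.03), H, W)
    boxes <- list()
    placed <- data.frame(x_min = numeric(0), y_min = numeric(0),
                         x_max = numeric(0), y_max = numeric(0))
    for (obj in seq_len(spec@nObjects)) {
      ok <- FALSE
      for (try in seq_len(.PLACEMENT_RETRIES)) {
        area <- stats::rlnorm(1, log(spec@medianArea), spec@dispersion)
        q <- stats::runif(1, spec@aspectRatioRange[1], spec@aspectRatioRange[2])
        bw <- sqrt(area * q)           # box width  (x extent)
        bh <- sqrt(area / q)           # box height (y extent)
        rx <- bw / 2; ry <- bh / 2     # support ellipse semi-axes
        if (2 * rx >= W - 2 || 2 * ry >= H - 2) next
        cx <- stats::runif(1, rx + 1, W - rx - 1)
        cy <- stats::runif(1, ry + 1, H - ry - 1)
        cand <- list(x_min = cx - rx, y_min = cy - ry,
                     x_max = cx + rx, y_max = cy + ry)
        clash <- FALSE
        if (nrow(placed)) {
          for (p in seq_len(nrow(placed))) {
            if (boxIoU(cand, placed[p, ]) > spec@maxOverlapIoU) {
              clash <- TRUE; break
            }
          }
        }
        if (clash) next
        # rasterise the blob on a local window
        peak <- stats::runif(1, 0.5, 0.9)
        cols <- max(1L, floor(cx - rx)):min(W, ceiling(cx + rx) + 1L)
        rows <- max(1L, floor(cy - ry)):min(H, ceiling(cy + ry) + 1L)
        # pixel (r, c) has center (c - 0.5, r - 0.5) in continuous coords
        dx <- (cols - 0.5 - cx) / rx
        dy <- (rows - 0.5 - cy) / ry
        # support boundary at 10% of peak: Gaussian sigma chosen so the
        # 10%-level set is the ellipse (dx^2 + dy^2 = 1)
        e2 <- outer(dy^2, dx^2, "+")
        blob <- peak * exp(-log(10) * e2)
        support <- e2 <= 1
        if (!any(support)) next
        sr <- range(rows[rowSums(support) > 0])
        sc <- range(cols[colSums(support) > 0])
        img[rows, cols] <- img[rows, cols] + blob
        placed <- rbind(placed, as.data.frame(cand))
        boxes[[obj]] <- data.frame(
          image_id = imageId, box_id = as.character(obj),
          x_min = sc[1] - 1L, y_min = sr[1] - 1L,
          x_max = sc[2], y_max = sr[2],
          stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok)
        stopf("placement infeasible for object %d after %d retries",
              obj, .PLACEMENT_RETRIES)
    }
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    img <- pmin(pmax(img, 0), 1)
    boxDf <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(image_id = character(0), box_id = character(0),
                 x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0),
                 stringsAsFactors = FALSE)
    list(image = img, boxes = boxDf)
  })
}

#' Corrupt ground-truth boxes into synthetic detections
#'
#' Emulates an imperfect detector with known ground truth: each kept box
#' (dropped with probability \code{dropRate}) is jittered by rounded Gaussian
#' pixel offsets on every coordinate, with confidence decreasing in the
#' realised jitter magnitude (confidence = 1 / (1 + mean absolute offset)).
#' Uniform-confidence false positives are appended at the requested rate.
#'
#' @param boxes ground-truth data.frame (image_id, x_min, y_min, x_max,
#'   y_max).
#' @param jitterSd sd (pixels) of the corner jitter, >= 0.
#' @param dropRate per-box drop probability in [0, 1].
#' @param falsePositiveRate expected false positives per ground-truth box.
#' @param seed integer seed.
#' @param imageSize c(height, width) used to clamp jittered and random boxes.
#' @return detections data.frame (image_id, x_min, y_min, x_max, y_max,
#'   confidence).
#' @export
corruptDetections <- function(boxes, jitterSd = 0, dropRate = 0,
                              falsePositiveRate = 0, seed = 1L,
                              imageSize = c(1024L, 1024L)) {
  if (jitterSd < 0) stopf("jitterSd must be >= 0")
  if (dropRate < 0 || dropRate > 1) stopf("dropRate must be in [0, 1]")
  if (falsePositiveRate < 0 || falsePositiveRate > 1)
    stopf("falsePositiveRate must be in [0, 1]")
  H <- imageSize[1]; W <- imageSize[2]
  withLocalSeed(seed, {
    dets <- list()
    for (b in seq_len(nrow(boxes))) {
      if (stats::runif(1) < dropRate) next
      off <- round(stats::rnorm(4, 0, jitterSd))
      xm <- max(0, boxes$x_min[b] + off[1])
      ym <- max(0, boxes$y_min[b] + off[2])
      xM <- min(W, boxes$x_max[b] + off[3])
      yM <- min(H, boxes$y_max[b] + off[4])
      if (xM <= xm) { xm <- boxes$x_min[b]; xM <- boxes$x_max[b] }
      if (yM <= ym) { ym <- boxes$y_min[b]; yM <- boxes$y_max[b] }
      conf <- 1 / (1 + mean(abs(off)))
      dets[[length(dets) + 1L]] <- data.frame(
        image_id = boxes$image_id[b], x_min = xm, y_min = ym,
        x_max = xM, y_max = yM, confidence = conf,
        stringsAsFactors = FALSE)
    }
    nFP <- if (nrow(boxes)) stats::rbinom(1, nrow(boxes), falsePositiveRate) else 0L
    imgIds <- unique(as.character(boxes$image_id))
    for (f in seq_len(nFP)) {
      w <- stats::runif(1, 10, max(20, W / 8))
      h <- stats::runif(1, 10, max(20, H / 8))
      xm <- stats::runif(1, 0, W - w)
      ym <- stats::runif(1, 0, H - h)
      dets[[length(dets) + 1L]] <- data.frame(
        image_id = sample(imgIds, 1), x_min = floor(xm), y_min = floor(ym),
        x_max = ceiling(xm + w), y_max = ceiling(ym + h),
        confidence = stats::runif(1, 0.05, 0.95),
        stringsAsFactors = FALSE)
    }
    if (length(dets)) do.call(rbind, dets) else
      data.frame(image_id = character(0), x_min = numeric(0),
                 y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
                 confidence = numeric(0), stringsAsFactors = FALSE)
  })
}
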