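#' Extract the binary attention region from a Grad-CAM map
#'
#' The attention area is the set of pixels whose Grad-CAM value exceeds the
#' threshold; with the default threshold 0 this is the strictly positive
#' ("non-empty") Grad-CAM region.
#'
#' @param cam a \linkS4class{CamMap} (typically at image resolution).
#' @param threshold non-negative cut; pixels with value > threshold are
#'   attended.
#' @param imageId image identifier carried into the mask.
#' @return an \linkS4class{AttentionMask}.
#' @export
attentionMask <- function(cam, threshold = 0, imageId = "image") {
  if (threshold < 0) stopf("threshold must be >= 0")
  new("AttentionMask", layerId = cam@layerId, imageId = imageId,
      grid = cam@values > threshold)
}

#' Attention score of one ground-truth box on one layer
#'
#' S = |attention area within the box| / |box|, the fraction of the labeled
#' box's pixels that the layer attends to. Bounded in [0, 1] by construction:
#' attention extending beyond the box (common for large-stride layers) does
#' not inflate the score.
#'
#' @param mask an \linkS4class{AttentionMask}.
#' @param box one-row data.frame (or list) with x_min, y_min, x_max, y_max in
#'   0-based half-open pixel coordinates, and optionally image_id and box_id.
#' @return one-row data.frame with columns image_id, box_id, layer_id, score,
#'   spike_size.
#' @export
attentionScore <- function(mask, box) {
  xm <- box$x_min; ym <- box$y_min; xM <- box$x_max; yM <- box$y_max
  if (xM <= xm || yM <= ym) stopf("degenerate box")
  d <- dim(mask@grid)
  if (xm < 0 || ym < 0 || xM > d[2] || yM > d[1])
    stopf("box (%g,%g,%g,%g) outside %d x %d mask", xm, ym, xM, yM, d[1], d[2])
  area <- (xM - xm) * (yM - ym)
  inside <- sum(mask@grid[(ym + 1L):yM, (xm + 1L):xM])
  data.frame(
    image_id = if (!is.null(box$image_id)) box$image_id else mask@imageId,
    box_id = if (!is.null(box$box_id)) as.character(box$box_id) else "1",
    layer_id = mask@layerId,
    score = inside / area,
    spike_size = area,
    stringsAsFactors = FALSE)
}

#' Score every box against every layer's attention mask
#'
#' Produces one attention-score record per (box, layer) pair. Records are
#' ordered by image_id, then box_id, then layer (small, medium, large, others
#' after).
#'
#' @param masks list of \linkS4class{AttentionMask} covering every
#'   (image, layer) pair the boxes reference.
#' @param boxes data.frame of ground-truth boxes with columns image_id,
#'   box_id (added when absent), x_min, y_min, x_max, y_max.
#' @return data.frame of score records (image_id, box_id, layer_id, score,
#'   spike_size).
#' @export
scoreAll <- function(masks, boxes) {
  cols <- c("image_id", "box_id", "layer_id", "score", "spike_size")
  empty <- data.frame(image_id = character(0), box_id = character(0),
                      layer_id = character(0), score = numeric(0),
                      spike_size = numeric(0), stringsAsFactors = FALSE)
  if (nrow(boxes) == 0L) return(empty)
  checkBoxes(boxes, what = "ground-truth box")
  if (is.null(boxes$box_id))
    boxes$box_id <- as.character(seq_len(nrow(boxes)))
  keys <- vapply(masks, function(m) paste(m@imageId, m@layerId, sep = "\r"),
                 "")
  allLayers <- unique(vapply(masks, function(m) m@layerId, ""))
  allLayers <- allLayers[order(layerOrderIndex(allLayers))]
  records <- list()
  for (b in seq_len(nrow(boxes))) {
    img <- as.character(boxes$image_id[b])
    for (lyr in allLayers) {
      hit <- match(paste(img, lyr, sep = "\r"), keys)
      if (is.na(hit))
        stopf("no attention mask for (image '%s', layer '%s')", img, lyr)
      records[[length(records) + 1L]] <-
        attentionScore(masks[[hit]], boxes[b, ])
    }
  }
  out <- do.call(rbind, records)
  out <- out[order(out$image_id, out$box_id, layerOrderIndex(out$layer_id)), ]
  rownames(out) <- NULL
  out[cols]
}
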