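#' Explain one image: activations to CAMs, masks and score records
#'
#' Runs the full per-image interpretive chain: Grad-CAM channel weights and
#' rectified map per tapped layer, upsampling to image resolution, binary
#' attention-mask extraction, and the attention score of every ground-truth
#' box on every layer.
#'
#' @param activations list of \linkS4class{LayerActivation} (one per tapped
#'   layer), e.g. from \code{\link{forwardBackward}} or
#'   \code{\link{loadExternalActivations}}.
#' @param boxes ground-truth data.frame for this image.
#' @param imageSize c(height, width) of the source image.
#' @param imageId image identifier.
#' @param threshold attention-mask extraction threshold (default 0).
#' @param method upsampling method, "bilinear" or "nearest".
#' @return list with \code{cams} (image-resolution \linkS4class{CamMap}s),
#'   \code{masks} (\linkS4class{AttentionMask}s) and \code{records}
#'   (score-record data.frame).
#' @export
explainImage <- function(activations, boxes, imageSize, imageId = "image",
                         threshold = 0, method = "bilinear") {
  cams <- lapply(activations, function(act)
    upsampleCam(gradcamMap(act), imageSize, method = method))
  masks <- lapply(cams, attentionMask, threshold = threshold,
                  imageId = imageId)
  records <- scoreAll(masks, boxes)
  logStage("explain", image = imageId, layers = length(cams),
           boxes = nrow(boxes), records = nrow(records))
  list(cams = cams, masks = masks, records = records)
}

#' Run the synthetic end-to-end attention study
#'
#' Generates seeded labeled scenes, runs the toy detector's forward/backward
#' pass on each, extracts per-layer attention masks, scores every spike on
#' every layer, aggregates per-layer statistics and derives refinement
#' advice. This is the full interpretive-analysis loop on data with known
#' ground truth.
#'
#' @param nScenes number of scenes.
#' @param sceneTemplate a \linkS4class{SceneSpec}; its seed is offset per
#'   scene.
#' @param detector a \linkS4class{ToyDetector} whose input size matches the
#'   scenes.
#' @param threshold mask extraction threshold.
#' @param method upsampling method.
#' @param thresholds advisor thresholds.
#' @return list with \code{records}, \code{stats}, \code{advice},
#'   \code{scenes}.
#' @export
runAttentionStudy <- function(nScenes = 3L, sceneTemplate, detector,
                              threshold = 0, method = "bilinear",
                              thresholds = advisorThresholds()) {
  records <- list()
  scenes <- list()
  for (i in seq_len(nScenes)) {
    spec <- sceneTemplate
    spec@seed <- sceneTemplate@seed + (i - 1L)
    imageId <- sprintf("scene_%03d", i)
    scene <- generateScene(spec, imageId = imageId)
    fb <- forwardBackward(detector, scene$image)
    ex <- explainImage(fb$activations, scene$boxes,
                       imageSize = dim(scene$image), imageId = imageId,
                       threshold = threshold, method = method)
    records[[i]] <- ex$records
    scenes[[i]] <- scene
  }
  records <- do.call(rbind, records)
  stats <- allLayerSummaries(records)
  advice <- advise(stats, thresholds)
  logStage("study", scenes = nScenes, records = nrow(records),
           layers = length(stats))
  list(records = records, stats = stats, advice = advice, scenes = scenes)
}
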