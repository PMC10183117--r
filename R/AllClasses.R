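#' Canonical detection-layer ordering
#'
#' Detection layers are named after the object scale they serve; strides
#' increase (and feature-map sizes shrink) from small to large.
#' @keywords internal
.LAYER_ORDER <- c("small", "medium", "large")

#' Configuration of the bundled toy multi-scale detector
#'
#' Describes a stack of strided, zero-padded, ReLU-activated convolutions with
#' three tapped detection layers ("small", "medium", "large"). The default
#' configuration taps cumulative strides 8, 16 and 32, so that successive
#' detection-layer pixel counts differ by a factor of 4 — the scale structure
#' of a standard three-head detector.
#'
#' @slot inputSize integer height and width of the expected input image.
#' @slot layerSpecs list of per-layer specs, each a list with elements
#'   \code{kernel}, \code{stride}, \code{inChannels}, \code{outChannels}.
#' @slot detectionLayers named integer vector mapping layer roles
#'   (\code{small}, \code{medium}, \code{large}, ...) to indices into
#'   \code{layerSpecs}.
#' @slot headLayers character; which tapped layers feed the scalar target
#'   score y (each through its own 1x1 single-channel response head whose
#'   global spatial sum contributes to y).
#' @slot weightSeed integer seed from which all weights are drawn.
#' @exportClass ToyDetectorSpec
setClass("ToyDetectorSpec", representation(
  inputSize = "integer",
  layerSpecs = "list",
  detectionLayers = "integer",
  headLayers = "character",
  weightSeed = "integer"
))

setValidity("ToyDetectorSpec", function(object) {
  msgs <- character(0)
  if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
    msgs <- c(msgs, "inputSize must be two positive integers (height, width)")
  for (i in seq_along(object@layerSpecs)) {
    ls <- object@layerSpecs[[i]]
    need <- c("kernel", "stride", "inChannels", "outChannels")
    if (!all(need %in% names(ls)))
      msgs <- c(msgs, sprintf("layer %d: missing fields", i))
    else if (any(unlist(ls[need]) <= 0))
      msgs <- c(msgs, sprintf("layer %d: kernel/stride/channels must be positive", i))
  }
  # channel chaining
  for (i in seq_along(object@layerSpecs)[-1]) {
    if (object@layerSpecs[[i]]$inChannels !=
        object@layerSpecs[[i - 1L]]$outChannels)
      msgs <- c(msgs, sprintf("layer %d: inChannels does not match layer %d outChannels",
                              i, i - 1L))
  }
  if (is.null(names(object@detectionLayers)) ||
      any(!nzchar(names(object@detectionLayers))))
    msgs <- c(msgs, "detectionLayers must be a named integer vector")
  if (any(object@detectionLayers < 1L) ||
      any(object@detectionLayers > length(object@layerSpecs)))
    msgs <- c(msgs, "detectionLayers indices out of range")
  # cumulative stride at tapped layers must strictly increase in the
  # declared order (small < medium < large)
  if (length(object@layerSpecs) > 0L && length(object@detectionLayers) > 0L &&
      length(msgs) == 0L) {
    cum <- cumprod(vapply(object@layerSpecs, function(l) as.numeric(l$stride), 0))
    taps <- cum[object@detectionLayers]
    if (any(diff(taps) <= 0))
      msgs <- c(msgs, "cumulative strides of tapped layers must be strictly increasing")
  }
  if (!all(object@headLayers %in% names(object@detectionLayers)))
    msgs <- c(msgs, "headLayers must name tapped detection layers")
  if (length(msgs)) msgs else TRUE
})

#' A built toy detector (weights materialised from a spec)
#'
#' @slot spec the \linkS4class{ToyDetectorSpec} the detector was built from.
#' @slot weights list of 4-d arrays (outChannels x inChannels x kernel x
#'   kernel), one per layer.
#' @slot headWeights named list of numeric vectors, one per tapped layer: the
#'   1x1 single-channel response-head weights.
#' @slot cumStrides numeric cumulative downsampling factor after each layer.
#' @exportClass ToyDetector
setClass("ToyDetector", representation(
  spec = "ToyDetectorSpec",
  weights = "list",
  headWeights = "list",
  cumStrides = "numeric"
))

#' One detection layer's feature maps and their gradients
#'
#' Holds the K x H x W feature values A^k_ij of a tapped layer together with
#' the gradients dy/dA^k_ij of the scalar target score with respect to each
#' value, plus the layer's cumulative stride. The Grad-CAM normaliser Z is
#' always H*W and is never stored.
#'
#' @slot layerId layer role label ("small", "medium", "large", ...).
#' @slot values numeric array K x H x W of feature-map values.
#' @slot gradients numeric array K x H x W of dy/dA values.
#' @slot stride cumulative downsampling factor relative to the input image.
#' @exportClass LayerActivation
setClass("LayerActivation", representation(
  layerId = "character",
  values = "array",
  gradients = "array",
  stride = "numeric"
))

setValidity("LayerActivation", function(object) {
  msgs <- character(0)
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, "values must be a K x H x W array")
  if (!identical(dim(object@values), dim(object@gradients)))
    msgs <- c(msgs, "values and gradients must have identical shape")
  if (!all(is.finite(object@values)) || !all(is.finite(object@gradients)))
    msgs <- c(msgs, "values and gradients must be finite")
  if (length(object@stride) != 1L || object@stride < 1)
    msgs <- c(msgs, "stride must be a single value >= 1")
  if (length(msgs)) msgs else TRUE
})

#' The scalar prediction score the gradients are taken of
#'
#' @slot value the scalar y (finite).
#' @slot definitionTag label describing how y was formed (e.g. which response
#'   heads were summed).
#' @exportClass TargetScore
setClass("TargetScore", representation(
  value = "numeric",
  definitionTag = "character"
))

setValidity("TargetScore", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    "value must be a single finite number" else TRUE
})

#' Per-channel Grad-CAM weights
#'
#' alpha_k = (1/Z) * sum_ij dy/dA^k_ij, one weight per feature channel.
#'
#' @slot layerId layer role label.
#' @slot weights numeric vector of length K (alpha_k).
#' @exportClass ChannelWeights
setClass("ChannelWeights", representation(
  layerId = "character",
  weights = "numeric"
))

setValidity("ChannelWeights", function(object) {
  if (!all(is.finite(object@weights))) "weights must be finite" else TRUE
})

#' A non-negative class-activation map
#'
#' The ReLU-rectified weighted sum of a layer's feature maps, at either the
#' layer's native resolution or upsampled to the image resolution.
#'
#' @slot layerId layer role label.
#' @slot resolution "layer" or "image".
#' @slot values numeric H x W matrix, all entries >= 0.
#' @exportClass CamMap
setClass("CamMap", representation(
  layerId = "character",
  resolution = "character",
  values = "matrix"
))

setValidity("CamMap", function(object) {
  msgs <- character(0)
  if (!object@resolution %in% c("layer", "image"))
    msgs <- c(msgs, "resolution must be 'layer' or 'image'")
  if (any(object@values < 0) || !all(is.finite(object@values)))
    msgs <- c(msgs, "values must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Binary attention region of one layer on one image
#'
#' Pixels where the (upsampled) Grad-CAM map exceeds the extraction
#' threshold; the "non-empty Grad-CAM value area" used for attention scoring.
#'
#' @slot layerId layer role label.
#' @slot imageId image identifier.
#' @slot grid logical H x W matrix at image resolution.
#' @exportClass AttentionMask
setClass("AttentionMask", representation(
  layerId = "character",
  imageId = "character",
  grid = "matrix"
))

setValidity("AttentionMask", function(object) {
  if (!is.logical(object@grid)) "grid must be a logical matrix" else TRUE
})

#' Per-layer attention-score statistics
#'
#' The bin table (0.1-wide score intervals with spike proportions and mean
#' spike sizes), the score range and mean, and the zero-score audit
#' (proportion and mean size of spikes the layer ignores entirely).
#'
#' @slot layerId layer role label.
#' @slot bins data.frame with columns lower, upper, count, proportion_pct,
#'   mean_spike_size (NA for empty bins).
#' @slot scoreMin,scoreMax,meanScore score summary over all records.
#' @slot zeroProportionPct percentage of spikes with score exactly 0.
#' @slot zeroMeanSpikeSize mean pixel size of those spikes (NA when none).
#' @slot nRecords number of score records aggregated.
#' @exportClass LayerScoreStats
setClass("LayerScoreStats", representation(
  layerId = "character",
  bins = "data.frame",
  scoreMin = "numeric",
  scoreMax = "numeric",
  meanScore = "numeric",
  zeroProportionPct = "numeric",
  zeroMeanSpikeSize = "numeric",
  nRecords = "integer"
))

setValidity("LayerScoreStats", function(object) {
  msgs <- character(0)
  if (abs(sum(object@bins$proportion_pct) - 100) > 1e-9)
    msgs <- c(msgs, "bin proportions must sum to 100")
  if (object@nRecords > 0L &&
      !(object@scoreMin <= object@meanScore && object@meanScore <= object@scoreMax))
    msgs <- c(msgs, "mean score must lie within the score range")
  if (length(msgs)) msgs else TRUE
})

#' Layer-refinement advice derived from attention-score statistics
#'
#' @slot verdicts named character ("poor"/"moderate"/"excellent") per layer.
#' @slot actions named list of character vectors per layer; values among
#'   "remove", "keep", "enhance_features", "add_micro_scale_companion".
#' @slot rationale named character, human-readable justification embedding the
#'   deciding statistics.
#' @slot thresholds numeric c(zero_poor_pct=, zero_excellent_pct=).
#' @exportClass RefinementAdvice
setClass("RefinementAdvice", representation(
  verdicts = "character",
  actions = "list",
  rationale = "character",
  thresholds = "numeric"
))

#' Outcome of greedy IoU matching of detections to ground truths
#'
#' @slot detections data.frame with one row per detection (columns image_id,
#'   confidence, tp) ordered by descending confidence.
#' @slot nGroundTruths total number of ground-truth boxes.
#' @slot iouThreshold the matching threshold used.
#' @exportClass MatchOutcome
setClass("MatchOutcome", representation(
  detections = "data.frame",
  nGroundTruths = "integer",
  iouThreshold = "numeric"
))

#' Precision-recall curve with average precision
#'
#' @slot points data.frame with columns confidence, tp_cum, fp_cum, precision,
#'   recall, one row per confidence cut (descending confidence).
#' @slot ap average precision (NA until computed).
#' @slot nGroundTruths total ground truths backing the recall denominator.
#' @exportClass PRCurve
setClass("PRCurve", representation(
  points = "data.frame",
  ap = "numeric",
  nGroundTruths = "integer"
))

setValidity("PRCurve", function(object) {
  msgs <- character(0)
  if (nrow(object@points) && is.unsorted(object@points$recall))
    msgs <- c(msgs, "recall must be non-decreasing along the curve")
  if (!is.na(object@ap) && (object@ap < 0 || object@ap > 1))
    msgs <- c(msgs, "ap must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic labeled spike scene
#'
#' Controls image size, the number of objects, the log-normal distribution of
#' object bounding-box areas (median in px^2 and log-scale dispersion), the
#' aspect-ratio range, the maximum tolerated box overlap, background type,
#' pixel noise and the seed.
#'
#' @slot imageSize integer c(height, width).
#' @slot nObjects number of spike-like blobs to place.
#' @slot medianArea median bounding-box area in px^2.
#' @slot dispersion log-scale sd of the log-normal area distribution.
#' @slot aspectRatioRange c(min, max) of width/height ratios.
#' @slot maxOverlapIoU maximum IoU tolerated between placed boxes, in [0, 1).
#' @slot background "flat" or "textured-noise".
#' @slot noiseSd sd of additive Gaussian pixel noise.
#' @slot seed integer seed.
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  imageSize = "integer",
  nObjects = "integer",
  medianArea = "numeric",
  dispersion = "numeric",
  aspectRatioRange = "numeric",
  maxOverlapIoU = "numeric",
  background = "character",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msgs <- character(0)
  if (any(object@imageSize < 8L)) msgs <- c(msgs, "imageSize too small")
  if (object@nObjects < 0L) msgs <- c(msgs, "nObjects must be >= 0")
  if (object@medianArea <= 0) msgs <- c(msgs, "medianArea must be positive")
  if (object@dispersion < 0) msgs <- c(msgs, "dispersion must be >= 0")
  if (object@maxOverlapIoU < 0 || object@maxOverlapIoU >= 1)
    msgs <- c(msgs, "maxOverlapIoU must be in [0, 1)")
  if (!object@background %in% c("flat", "textured-noise"))
    msgs <- c(msgs, "background must be 'flat' or 'textured-noise'")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

# ---- accessors ----

#' @rdname LayerActivation-class
#' @export
setMethod("layerId", "LayerActivation", function(x) x@layerId)
#' @rdname LayerActivation-class
#' @export
setMethod("activationValues", "LayerActivation", function(x) x@values)
#' @rdname LayerActivation-class
#' @export
setMethod("activationGradients", "LayerActivation", function(x) x@gradients)
#' @rdname LayerActivation-class
#' @export
setMethod("layerStride", "LayerActivation", function(x) x@stride)

#' @rdname CamMap-class
#' @export
setMethod("layerId", "CamMap", function(x) x@layerId)
#' @rdname CamMap-class
#' @export
setMethod("camValues", "CamMap", function(x) x@values)
#' @rdname CamMap-class
#' @export
setMethod("camResolution", "CamMap", function(x) x@resolution)

#' @rdname AttentionMask-class
#' @export
setMethod("layerId", "AttentionMask", function(x) x@layerId)
#' @rdname AttentionMask-class
#' @export
setMethod("maskGrid", "AttentionMask", function(x) x@grid)

#' @rdname PRCurve-class
#' @export
setMethod("prPoints", "PRCurve", function(x) x@points)

#' @rdname LayerScoreStats-class
#' @export
setMethod("layerId", "LayerScoreStats", function(x) x@layerId)
#' @rdname LayerScoreStats-class
#' @export
setMethod("scoreBins", "LayerScoreStats", function(x) x@bins)
#' @rdname LayerScoreStats-class
#' @export
setMethod("meanScore", "LayerScoreStats", function(x) x@meanScore)
#' @rdname LayerScoreStats-class
#' @export
setMethod("zeroProportion", "LayerScoreStats", function(x) x@zeroProportionPct)
#' @rdname LayerScoreStats-class
#' @export
setMethod("zeroMeanSpikeSize", "LayerScoreStats", function(x) x@zeroMeanSpikeSize)

#' @rdname RefinementAdvice-class
#' @export
setMethod("adviceVerdicts", "RefinementAdvice", function(x) x@verdicts)
#' @rdname RefinementAdvice-class
#' @export
setMethod("adviceActions", "RefinementAdvice", function(x) x@actions)
#' @rdname RefinementAdvice-class
#' @export
setMethod("adviceRationale", "RefinementAdvice", function(x) x@rationale)

# ---- show methods ----

setMethod("show", "LayerActivation", function(object) {
  d <- dim(object@values)
  cat(sprintf("LayerActivation '%s': %d channels, %d x %d, stride %g\n",
              object@layerId, d[1], d[2], d[3], object@stride))
})

setMethod("show", "CamMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("CamMap '%s' (%s resolution): %d x %d, max %.4g\n",
              object@layerId, object@resolution, d[1], d[2],
              if (length(object@values)) max(object@values) else 0))
})

setMethod("show", "AttentionMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("AttentionMask '%s' on image '%s': %d x %d, %d attended pixels\n",
              object@layerId, object@imageId, d[1], d[2], sum(object@grid)))
})

setMethod("show", "LayerScoreStats", function(object) {
  cat(sprintf("LayerScoreStats '%s': %d spikes, mean score %.3f, range [%.3f, %.3f]\n",
              object@layerId, object@nRecords, object@meanScore,
              object@scoreMin, object@scoreMax))
  cat(sprintf("  zero-score: %.1f%% of spikes (mean size %s px)\n",
              object@zeroProportionPct,
              if (is.na(object@zeroMeanSpikeSize)) "-" else
                format(round(object@zeroMeanSpikeSize))))
})

setMethod("show", "RefinementAdvice", function(object) {
  cat("RefinementAdvice\n")
  for (l in names(object@verdicts)) {
    cat(sprintf("  %-7s %-9s -> %s\n", l, object@verdicts[[l]],
                paste(object@actions[[l]], collapse = " + ")))
  }
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d points, %d ground truths, AP = %s\n",
              nrow(object@points), object@nGroundTruths,
              if (is.na(object@ap)) "not computed" else sprintf("%.4f", object@ap)))
})

setMethod("show", "ToyDetector", function(object) {
  cat(sprintf("ToyDetector: %d conv layers, taps {%s} at cumulative strides {%s}\n",
              length(object@weights),
              paste(names(object@spec@detectionLayers), collapse = ", "),
              paste(object@cumStrides[object@spec@detectionLayers], collapse = ", ")))
})
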