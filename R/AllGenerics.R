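#' @import methods
NULL

#' @rdname LayerActivation-class
#' @param x object
#' @export
setGeneric("layerId", function(x) standardGeneric("layerId"))

#' @rdname LayerActivation-class
#' @export
setGeneric("activationValues", function(x) standardGeneric("activationValues"))

#' @rdname LayerActivation-class
#' @export
setGeneric("activationGradients", function(x) standardGeneric("activationGradients"))

#' @rdname LayerActivation-class
#' @export
setGeneric("layerStride", function(x) standardGeneric("layerStride"))

#' @rdname CamMap-class
#' @param x object
#' @export
setGeneric("camValues", function(x) standardGeneric("camValues"))

#' @rdname CamMap-class
#' @export
setGeneric("camResolution", function(x) standardGeneric("camResolution"))

#' @rdname AttentionMask-class
#' @param x object
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname PRCurve-class
#' @param x object
#' @export
setGeneric("prPoints", function(x) standardGeneric("prPoints"))

#' @rdname PRCurve-class
#' @export
setGeneric("averagePrecision", function(x, ...) standardGeneric("averagePrecision"))

#' @rdname LayerScoreStats-class
#' @param x object
#' @export
setGeneric("scoreBins", function(x) standardGeneric("scoreBins"))

#' @rdname LayerScoreStats-class
#' @export
setGeneric("meanScore", function(x) standardGeneric("meanScore"))

#' @rdname LayerScoreStats-class
#' @export
setGeneric("zeroProportion", function(x) standardGeneric("zeroProportion"))

#' @rdname LayerScoreStats-class
#' @export
setGeneric("zeroMeanSpikeSize", function(x) standardGeneric("zeroMeanSpikeSize"))

#' @rdname RefinementAdvice-class
#' @param x object
#' @export
setGeneric("adviceVerdicts", function(x) standardGeneric("adviceVerdicts"))

#' @rdname RefinementAdvice-class
#' @export
setGeneric("adviceActions", function(x) standardGeneric("adviceActions"))

#' @rdname RefinementAdvice-class
#' @export
setGeneric("adviceRationale", function(x) standardGeneric("adviceRationale"))
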