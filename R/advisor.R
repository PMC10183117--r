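#' Advisor thresholds
#'
#' The refinement rules grade each layer on the percentage of spikes it
#' ignores entirely (zero-score proportion): "poor" at or above
#' \code{zeroPoorPct}, "excellent" at or below \code{zeroExcellentPct},
#' "moderate" in between. The defaults (25 / 20) classify observed multi-site
#' wheat values of 30\% as poor and 17.5\% / 4\% as excellent with margin.
#'
#' @param zeroPoorPct poor boundary (inclusive), default 25.
#' @param zeroExcellentPct excellent boundary (inclusive), default 20.
#' @return named numeric vector.
#' @export
advisorThresholds <- function(zeroPoorPct = 25, zeroExcellentPct = 20) {
  if (!(zeroExcellentPct >= 0 && zeroExcellentPct <= zeroPoorPct &&
        zeroPoorPct <= 100))
    stopf("need 0 <= zeroExcellentPct <= zeroPoorPct <= 100")
  c(zero_poor_pct = zeroPoorPct, zero_excellent_pct = zeroExcellentPct)
}

#' Classify one layer's attention quality
#'
#' @param stats a \linkS4class{LayerScoreStats} (or a single zero-score
#'   percentage).
#' @param thresholds from \code{\link{advisorThresholds}}.
#' @return "poor", "moderate" or "excellent".
#' @export
classifyLayer <- function(stats, thresholds = advisorThresholds()) {
  z <- if (is(stats, "LayerScoreStats")) stats@zeroProportionPct else stats
  if (z >= thresholds[["zero_poor_pct"]]) "poor"
  else if (z <= thresholds[["zero_excellent_pct"]]) "excellent"
  else "moderate"
}

.adviceForRole <- function(role, verdict) {
  switch(role,
    large = if (verdict == "poor") "remove" else "keep",
    small = switch(verdict,
                   excellent = c("keep", "add_micro_scale_companion"),
                   poor = "remove",
                   "keep"),
    medium = if (verdict == "excellent") "enhance_features" else "keep",
    "keep")
}

#' Rule-based layer-refinement advice
#'
#' Turns per-layer attention statistics into architecture recommendations:
#' a poor large-scale layer is removed; an excellent small-scale layer is
#' kept and gains a micro-scale companion head for very small objects (a
#' poor one is removed); an excellent medium-scale layer gets its features
#' enhanced. The advisor only recommends; it modifies no network.
#'
#' @param stats named list of \linkS4class{LayerScoreStats} including layers
#'   "small", "medium" and "large".
#' @param thresholds from \code{\link{advisorThresholds}}.
#' @return a \linkS4class{RefinementAdvice}.
#' @export
advise <- function(stats, thresholds = advisorThresholds()) {
  ids <- vapply(stats, layerId, "")
  names(stats) <- ids
  missing <- setdiff(.LAYER_ORDER, ids)
  if (length(missing))
    stopf("missing layer role(s): %s", paste(missing, collapse = ", "))
  verdicts <- character(0); actions <- list(); rationale <- character(0)
  for (role in .LAYER_ORDER) {
    st <- stats[[role]]
    v <- classifyLayer(st, thresholds)
    verdicts[[role]] <- v
    actions[[role]] <- .adviceForRole(role, v)
    rationale[[role]] <- sprintf(
      paste0("%s-scale layer is %s: %.1f%% of spikes score 0 ",
             "(poor >= %.1f%%, excellent <= %.1f%%); mean score %.3f, ",
             "mean size of missed spikes %s px"),
      role, v, st@zeroProportionPct,
      thresholds[["zero_poor_pct"]], thresholds[["zero_excellent_pct"]],
      st@meanScore,
      if (is.na(st@zeroMeanSpikeSize)) "-" else
        format(round(st@zeroMeanSpikeSize)))
  }
  new("RefinementAdvice", verdicts = verdicts, actions = actions,
      rationale = rationale, thresholds = thresholds)
}

#' Build minimal layer statistics from reported summary numbers
#'
#' Convenience constructor for feeding the advisor with externally reported
#' per-layer summaries (e.g. a published zero-score proportion) when the raw
#' score records are not available. The bin table only records the zero /
#' non-zero split.
#'
#' @param layerId layer role label.
#' @param zeroProportionPct percentage of spikes with score 0.
#' @param meanScore optional mean attention score.
#' @param zeroMeanSpikeSize optional mean size of the missed spikes.
#' @return a \linkS4class{LayerScoreStats}.
#' @export
layerStatsFromSummary <- function(layerId, zeroProportionPct,
                                  meanScore = NA_real_,
                                  zeroMeanSpikeSize = NA_real_) {
  prop <- rep(0, 10)
  prop[1] <- zeroProportionPct
  prop[10] <- 100 - zeroProportionPct
  bins <- data.frame(lower = seq(0, 0.9, 0.1), upper = seq(0.1, 1, 0.1),
                     count = NA_integer_, proportion_pct = prop,
                     mean_spike_size = NA_real_)
  new("LayerScoreStats", layerId = layerId, bins = bins,
      scoreMin = NA_real_, scoreMax = NA_real_, meanScore = meanScore,
      zeroProportionPct = zeroProportionPct,
      zeroMeanSpikeSize = zeroMeanSpikeSize, nRecords = 0L)
}

#' Serialise advice to a JSON string
#'
#' @param advice a \linkS4class{RefinementAdvice}.
#' @return character scalar of JSON.
#' @export
adviceToJson <- function(advice) {
  jsonlite::toJSON(list(
    thresholds = as.list(advice@thresholds),
    layers = lapply(names(advice@verdicts), function(l) list(
      layer_id = l,
      verdict = advice@verdicts[[l]],
      actions = as.list(advice@actions[[l]]),
      rationale = advice@rationale[[l]]))),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
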