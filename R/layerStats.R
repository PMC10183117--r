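#' Bin attention scores into 0.1-wide intervals
#'
#' Bins are [0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]; the last bin is closed so
#' a perfect score of 1.0 is counted. Proportions are percentages of the
#' layer's records; each bin also carries the mean pixel size of its member
#' spikes (NA when empty).
#'
#' @param records data.frame of attention-score records for ONE layer, with
#'   columns score (in [0, 1]) and spike_size.
#' @return data.frame with columns lower, upper, count, proportion_pct,
#'   mean_spike_size.
#' @export
binScores <- function(records) {
  n <- nrow(records)
  if (n == 0L) stopf("no records to bin")
  s <- records$score
  if (any(s < 0 | s > 1)) stopf("scores must lie in [0, 1]")
  idx <- pmin(floor(s * 10) + 1L, 10L)
  counts <- tabulate(idx, nbins = 10L)
  sizes <- vapply(1:10, function(b) {
    m <- idx == b
    if (any(m)) mean(records$spike_size[m]) else NA_real_
  }, 0)
  data.frame(
    lower = seq(0, 0.9, by = 0.1),
    upper = seq(0.1, 1, by = 0.1),
    count = counts,
    proportion_pct = 100 * counts / n,
    mean_spike_size = sizes)
}

#' Zero-score audit of one layer
#'
#' The spikes a layer ignores entirely: proportion (percent) of records with
#' score exactly 0 and their mean pixel size (NA when there are none).
#'
#' @param records data.frame of score records for one layer.
#' @return list with elements zero_proportion_pct and zero_mean_spike_size.
#' @export
zeroScoreAudit <- function(records) {
  n <- nrow(records)
  if (n == 0L) stopf("no records to audit")
  z <- records$score == 0
  list(zero_proportion_pct = 100 * sum(z) / n,
       zero_mean_spike_size = if (any(z)) mean(records$spike_size[z]) else NA_real_)
}

#' Full per-layer attention-score summary
#'
#' Assembles the bin table, the score range and mean, and the zero-score
#' audit into one \linkS4class{LayerScoreStats}.
#'
#' @param records data.frame of score records for one layer.
#' @param layerId layer label; taken from the records when omitted.
#' @return a \linkS4class{LayerScoreStats}.
#' @export
layerSummary <- function(records, layerId = NULL) {
  if (is.null(layerId)) {
    layerId <- unique(as.character(records$layer_id))
    if (length(layerId) != 1L)
      stopf("records span %d layers; pass one layer at a time", length(layerId))
  }
  bins <- binScores(records)
  audit <- zeroScoreAudit(records)
  new("LayerScoreStats",
      layerId = layerId,
      bins = bins,
      scoreMin = min(records$score),
      scoreMax = max(records$score),
      meanScore = mean(records$score),
      zeroProportionPct = audit$zero_proportion_pct,
      zeroMeanSpikeSize = audit$zero_mean_spike_size,
      nRecords = nrow(records))
}

#' Summaries for every layer present in a record table
#'
#' @param records data.frame of score records with a layer_id column.
#' @return named list of \linkS4class{LayerScoreStats}, in small/medium/large
#'   order.
#' @export
allLayerSummaries <- function(records) {
  ids <- unique(as.character(records$layer_id))
  ids <- ids[order(layerOrderIndex(ids))]
  stats <- lapply(ids, function(l)
    layerSummary(records[records$layer_id == l, , drop = FALSE], l))
  names(stats) <- ids
  stats
}

#' Rank detection layers by attention quality
#'
#' Layers are ranked by ascending zero-score proportion (the fraction of
#' spikes a layer misses entirely is the primary quality signal), with mean
#' attention score (descending) as tie-break, then the canonical
#' small/medium/large order. The best and worst layers are marked.
#'
#' @param stats list of \linkS4class{LayerScoreStats} (>= 2 layers, unique
#'   ids).
#' @return data.frame ranked best-first, with columns layer_id,
#'   zero_proportion_pct, mean_score, mean_spike_size_zero, rank, verdict_mark
#'   ("best"/"worst"/"").
#' @export
compareLayers <- function(stats) {
  if (length(stats) < 2L) stopf("need at least two layers to compare")
  ids <- vapply(stats, layerId, "")
  if (anyDuplicated(ids)) stopf("duplicate layer_ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  df <- data.frame(
    layer_id = ids,
    zero_proportion_pct = vapply(stats, zeroProportion, 0),
    mean_score = vapply(stats, meanScore, 0),
    mean_spike_size_zero = vapply(stats, zeroMeanSpikeSize, 0),
    stringsAsFactors = FALSE)
  ord <- order(df$zero_proportion_pct, -df$mean_score, layerOrderIndex(ids))
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  df$verdict_mark <- ""
  df$verdict_mark[1] <- "best"
  df$verdict_mark[nrow(df)] <- "worst"
  rownames(df) <- NULL
  df
}

#' Format a layer's statistics the way the reference tables print them
#'
#' Display rounding: proportions to 1 decimal, mean sizes to the nearest
#' integer, mean scores to 3 decimals; empty bins print "-". Full precision
#' stays in the \linkS4class{LayerScoreStats} object.
#'
#' @param stats a \linkS4class{LayerScoreStats}.
#' @return character vector of table lines.
#' @export
formatLayerStats <- function(stats) {
  b <- stats@bins
  lines <- c(
    sprintf("Layer: %s  (n = %d)", stats@layerId, stats@nRecords),
    sprintf("  score range %.3g-%.3g, mean score %.3f",
            stats@scoreMin, stats@scoreMax, stats@meanScore),
    sprintf("  zero-score spikes: %.1f%%, mean size %s",
            stats@zeroProportionPct,
            if (is.na(stats@zeroMeanSpikeSize)) "-"
            else format(round(stats@zeroMeanSpikeSize))),
    "  score bin   % spikes   mean size (px)")
  for (i in seq_len(nrow(b))) {
    lines <- c(lines, sprintf(
      "  %.1f-%.1f     %7s   %s",
      b$lower[i], b$upper[i],
      if (b$count[i] == 0L) "-" else sprintf("%.1f", b$proportion_pct[i]),
      if (is.na(b$mean_spike_size[i])) "-"
      else format(round(b$mean_spike_size[i]))))
  }
  lines
}
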