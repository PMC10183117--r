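# Readers and writers for the annotation and result formats the toolkit
# touches. All box tables use 0-based half-open pixel coordinates internally;
# dialect conversion happens on read/write only.

#' Read ground-truth boxes from a GWHD-style CSV
#'
#' Two dialects are supported: one box per row with columns image_id, x_min,
#' y_min, x_max, y_max; or the packed dialect with columns image_id and boxes
#' (semicolon-separated "x_min y_min x_max y_max" quadruples with inclusive
#' max corners, converted to half-open by adding 1 on read).
#'
#' @param path CSV file with header.
#' @param dialect "auto" (default; inferred from the header), "per_row" or
#'   "packed".
#' @param imageSize optional c(height, width) for bounds validation.
#' @return data.frame image_id, box_id, x_min, y_min, x_max, y_max.
#' @export
readGwhdCsv <- function(path, dialect = c("auto", "per_row", "packed"),
                        imageSize = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "auto")
    dialect <- if ("boxes" %in% names(df)) "packed" else "per_row"
  if (dialect == "per_row") {
    need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
    out <- df[need]
  } else {
    if (!all(c("image_id", "boxes") %in% names(df)))
      stopf("%s: packed dialect needs columns image_id, boxes", path)
    rows <- list()
    for (i in seq_len(nrow(df))) {
      s <- trimws(df$boxes[i])
      if (!nzchar(s)) next
      for (quad in strsplit(s, ";", fixed = TRUE)[[1]]) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(quad), "\\s+")[[1]]))
        if (length(v) != 4L || any(is.na(v)))
          stopf("%s line %d: malformed box quadruple '%s'", path, i + 1L, quad)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = df$image_id[i], x_min = v[1], y_min = v[2],
          x_max = v[3] + 1, y_max = v[4] + 1,   # inclusive -> half-open
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(image_id = character(0), x_min = numeric(0),
                 y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))
  }
  bad <- which(out$x_max <= out$x_min | out$y_max <= out$y_min)
  if (length(bad))
    stopf("%s line %d: degenerate box (x_max <= x_min or y_max <= y_min)",
          path, bad[1] + 1L)
  checkBoxes(out, imageSize = imageSize, what = "ground-truth box")
  out$box_id <- as.character(stats::ave(seq_len(nrow(out)), out$image_id,
                                        FUN = seq_along))
  out[c("image_id", "box_id", "x_min", "y_min", "x_max", "y_max")]
}

#' Write ground-truth boxes as one-box-per-row CSV
#'
#' Round-trips exactly with \code{\link{readGwhdCsv}}'s per-row dialect.
#'
#' @param boxes data.frame with image_id, x_min, y_min, x_max, y_max.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeGwhdCsv <- function(boxes, path) {
  checkBoxes(boxes, what = "ground-truth box")
  utils::write.csv(
    boxes[c("image_id", "x_min", "y_min", "x_max", "y_max")],
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read YOLO-format labels
#'
#' Rows "class cx cy w h" with all coordinates normalised to [0, 1] relative
#' to the image size. Converted to absolute half-open pixel boxes with the
#' documented rounding: floor of the min corner, ceiling of the max corner.
#'
#' @param path label text file (one object per line; empty file allowed).
#' @param imageSize c(height, width) in pixels.
#' @param imageId identifier for the resulting boxes.
#' @return data.frame image_id, box_id, x_min, y_min, x_max, y_max.
#' @export
readYoloLabels <- function(path, imageSize, imageId = "image") {
  H <- imageSize[1]; W <- imageSize[2]
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 5L || any(is.na(v)))
      stopf("%s line %d: expected 'class cx cy w h'", path, i)
    if (any(v[2:5] < 0 | v[2:5] > 1))
      stopf("%s line %d: normalised coordinate outside [0, 1]", path, i)
    # snap to 9 decimals before floor/ceil so decimal inputs behave as
    # written (0.3 * 100 is 30, not 30 + 4e-15)
    snap <- function(x) round(x, 9)
    data.frame(image_id = imageId, box_id = as.character(i),
               x_min = floor(snap((v[2] - v[4] / 2) * W)),
               y_min = floor(snap((v[3] - v[5] / 2) * H)),
               x_max = ceiling(snap((v[2] + v[4] / 2) * W)),
               y_max = ceiling(snap((v[3] + v[5] / 2) * H)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(image_id = character(0), box_id = character(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  out <- do.call(rbind, rows)
  out$x_min <- pmax(out$x_min, 0); out$y_min <- pmax(out$y_min, 0)
  out$x_max <- pmin(out$x_max, W); out$y_max <- pmin(out$y_max, H)
  checkBoxes(out, what = "YOLO label")
  out
}

#' Read/write detection CSVs
#'
#' Columns image_id, x_min, y_min, x_max, y_max, confidence.
#'
#' @param path CSV path.
#' @return data.frame of detections.
#' @export
readDetectionsCsv <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df[need]
}

#' @rdname readDetectionsCsv
#' @param dets detections data.frame.
#' @export
writeDetectionsCsv <- function(dets, path) {
  utils::write.csv(
    dets[c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")],
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read/write attention-score record CSVs
#'
#' Columns image_id, box_id, layer_id, score, spike_size.
#'
#' @param path CSV path.
#' @return data.frame of score records.
#' @export
readScoreRecords <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(box_id = "character"))
  need <- c("image_id", "box_id", "layer_id", "score", "spike_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df[need]
}

#' @rdname readScoreRecords
#' @param records score-record data.frame.
#' @export
writeScoreRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an attention mask as a 1-bit style PNG (0/255)
#'
#' @param mask an \linkS4class{AttentionMask}.
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask@grid * 1, path)
  invisible(path)
}

#' Read an attention mask PNG written by \code{\link{writeMaskPng}}
#'
#' @param path PNG path.
#' @param layerId,imageId labels for the reconstructed mask.
#' @return an \linkS4class{AttentionMask}.
#' @export
readMaskPng <- function(path, layerId = "unknown", imageId = "image") {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  new("AttentionMask", layerId = layerId, imageId = imageId, grid = g > 0.5)
}

#' Write a scene to disk (PNG + GWHD CSV + YOLO txt)
#'
#' @param scene list(image, boxes) from \code{\link{generateScene}}.
#' @param dir output directory.
#' @param name base file name.
#' @return character vector of the paths written.
#' @export
writeScene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pngPath <- file.path(dir, paste0(name, ".png"))
  csvPath <- file.path(dir, paste0(name, ".csv"))
  txtPath <- file.path(dir, paste0(name, ".txt"))
  png::writePNG(scene$image, pngPath)
  writeGwhdCsv(scene$boxes, csvPath)
  H <- nrow(scene$image); W <- ncol(scene$image)
  yolo <- sprintf("0 %.6f %.6f %.6f %.6f",
                  (scene$boxes$x_min + scene$boxes$x_max) / 2 / W,
                  (scene$boxes$y_min + scene$boxes$y_max) / 2 / H,
                  (scene$boxes$x_max - scene$boxes$x_min) / W,
                  (scene$boxes$y_max - scene$boxes$y_min) / H)
  writeLines(yolo, txtPath)
  c(pngPath, csvPath, txtPath)
}

#' Export per-layer statistics as CSV rows and nested JSON
#'
#' @param stats named list of \linkS4class{LayerScoreStats}.
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return invisibly, a list with the bin data.frame and the JSON string.
#' @export
writeLayerStats <- function(stats, csvPath = NULL, jsonPath = NULL) {
  rows <- do.call(rbind, lapply(stats, function(s) {
    b <- s@bins
    b$layer_id <- s@layerId
    b[c("layer_id", "lower", "upper", "count", "proportion_pct",
        "mean_spike_size")]
  }))
  rownames(rows) <- NULL
  js <- jsonlite::toJSON(lapply(stats, function(s) list(
    layer_id = s@layerId,
    n_records = s@nRecords,
    score_min = s@scoreMin, score_max = s@scoreMax,
    mean_score = s@meanScore,
    zero_proportion_pct = s@zeroProportionPct,
    zero_mean_spike_size = s@zeroMeanSpikeSize,
    bins = s@bins)), auto_unbox = TRUE, pretty = TRUE, digits = NA,
    na = "null")
  if (!is.null(csvPath)) utils::write.csv(rows, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) writeLines(js, jsonPath)
  invisible(list(bins = rows, json = js))
}

#' Read a run configuration from a YAML (or JSON) file
#'
#' @param path config file; top-level keys are validated against the
#'   documented ranges (mask_threshold >= 0, iou_threshold in (0, 1),
#'   upsample method, advisor thresholds).
#' @return named list of settings with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(upsample_method = "bilinear", mask_threshold = 0,
                   iou_threshold = 0.5, zero_poor_pct = 25,
                   zero_excellent_pct = 20, seed = 1L, log_level = "info")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$upsample_method %in% c("bilinear", "nearest"))
    stopf("config: upsample_method must be bilinear or nearest")
  if (cfg$mask_threshold < 0) stopf("config: mask_threshold must be >= 0")
  if (cfg$iou_threshold <= 0 || cfg$iou_threshold >= 1)
    stopf("config: iou_threshold must be in (0, 1)")
  advisorThresholds(cfg$zero_poor_pct, cfg$zero_excellent_pct)  # validates
  for (k in c("images", "labels", "activations", "output")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stopf("config: path '%s' (%s) does not exist", cfg[[k]], k)
  }
  cfg
}
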