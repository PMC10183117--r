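# misc internal helpers

# Run code under a given seed without disturbing the caller's RNG stream.
withLocalSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

# Order layer labels small -> medium -> large, anything else after, alphabetically.
layerOrderIndex <- function(ids) {
  known <- match(ids, .LAYER_ORDER)
  extra <- rank(ids, ties.method = "min")
  ifelse(is.na(known), length(.LAYER_ORDER) + extra, known)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# One structured log line per pipeline stage; silenced via options(spikeCAM.quiet = TRUE).
logStage <- function(stage, ...) {
  if (isTRUE(getOption("spikeCAM.quiet", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- if (length(kv))
    paste(names(kv), unlist(kv), sep = "=", collapse = " ") else ""
  message(sprintf("[spikeCAM] %s %s", stage, msg))
  invisible(NULL)
}

# validate a boxes data.frame (0-based half-open pixel coordinates)
checkBoxes <- function(boxes, imageSize = NULL, what = "box") {
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(boxes))
  if (length(miss))
    stopf("%s table lacks columns: %s", what, paste(miss, collapse = ", "))
  bad <- which(boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min)
  if (length(bad))
    stopf("degenerate %s at row %d (x_max <= x_min or y_max <= y_min)",
          what, bad[1])
  if (!is.null(imageSize)) {
    out <- which(boxes$x_min < 0 | boxes$y_min < 0 |
                 boxes$x_max > imageSize[2] | boxes$y_max > imageSize[1])
    if (length(out))
      stopf("%s at row %d lies outside the %d x %d image",
            what, out[1], imageSize[1], imageSize[2])
  }
  invisible(boxes)
}

boxArea <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}
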