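# Portable binary n-d array files.
#
# One array per file. Layout (all integers little-endian int32):
#   bytes 0-3   magic "SCAM"
#   int32       format version (1)
#   int32       element size in bytes: 4 (float32) or 8 (float64)
#   int32       ndim
#   int32[ndim] dims (R order: first index fastest)
#   data        little-endian IEEE reals, R column-major order
#
# Any ML framework can emit this with a few lines (write header, then the
# raw little-endian buffer of a Fortran-ordered array).

.ARRAY_MAGIC <- charToRaw("SCAM")

#' Write an array to a portable binary array file
#'
#' @param x numeric array (or matrix/vector).
#' @param path output file path.
#' @param dtype "float64" (default; lossless for R doubles) or "float32".
#' @return invisibly, \code{path}.
#' @export
writeArrayFile <- function(x, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  size <- if (dtype == "float64") 8L else 4L
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.ARRAY_MAGIC, con)
  writeBin(c(1L, size, length(d), as.integer(d)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(x), con, size = size, endian = "little")
  invisible(path)
}

#' Read a portable binary array file
#'
#' @param path file written by \code{\link{writeArrayFile}} (or an external
#'   framework following the same layout).
#' @return numeric array with its stored dimensions.
#' @export
readArrayFile <- function(path) {
  if (!file.exists(path)) stopf("cannot read array file '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .ARRAY_MAGIC))
    stopf("'%s' is not a portable array file (bad magic)", path)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stopf("unsupported array file version %d", hdr[1])
  size <- hdr[2]
  if (!size %in% c(4L, 8L)) stopf("unsupported element size %d", size)
  dims <- readBin(con, "integer", hdr[3], size = 4L, endian = "little")
  n <- prod(dims)
  vals <- readBin(con, "numeric", n, size = size, endian = "little")
  if (length(vals) != n) stopf("'%s' is truncated", path)
  array(vals, dims)
}

#' Load externally dumped activations and gradients
#'
#' Bridge for real detectors: reads a (values, gradients) pair of portable
#' array files dumped by an external framework for one detection layer and
#' wraps them as a \linkS4class{LayerActivation}. No numerical transformation
#' is applied. The documented shape order is K x H x W and the file naming
#' convention is \code{<image_id>__<layer_id>__{values|grads}}.
#'
#' @param valuesPath,gradientsPath paths to the two array files.
#' @param layerId label of the detection layer ("small", "medium", ...).
#' @param stride the layer's cumulative downsampling factor.
#' @return a \linkS4class{LayerActivation}.
#' @export
loadExternalActivations <- function(valuesPath, gradientsPath, layerId, stride) {
  v <- readArrayFile(valuesPath)
  g <- readArrayFile(gradientsPath)
  if (!identical(dim(v), dim(g)))
    stopf("shape mismatch: values %s vs gradients %s",
          paste(dim(v), collapse = "x"), paste(dim(g), collapse = "x"))
  if (length(dim(v)) != 3L)
    stopf("expected K x H x W arrays, got %d dimensions", length(dim(v)))
  new("LayerActivation", layerId = layerId, values = v, gradients = g,
      stride = stride)
}

#' Dump a tapped layer's activations and gradients to array files
#'
#' Writes \code{<image_id>__<layer_id>__values} and
#' \code{<image_id>__<layer_id>__grads} under \code{dir}.
#'
#' @param activation a \linkS4class{LayerActivation}.
#' @param imageId image identifier used in the file names.
#' @param dir output directory.
#' @return character vector of the two paths written.
#' @export
dumpActivations <- function(activation, imageId, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, sprintf("%s__%s__values", imageId, activation@layerId))
  gp <- file.path(dir, sprintf("%s__%s__grads", imageId, activation@layerId))
  writeArrayFile(activation@values, vp)
  writeArrayFile(activation@gradients, gp)
  c(vp, gp)
}
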