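#' Grad-CAM channel weights
#'
#' Computes alpha_k, the spatial mean of the gradient of the target score over
#' each feature channel: alpha_k = (1/Z) * sum_i sum_j dy/dA^k_ij, with
#' Z = H * W the number of positions in the feature map.
#'
#' @param activation a \linkS4class{LayerActivation} with gradients.
#' @return a \linkS4class{ChannelWeights}.
#' @export
channelWeights <- function(activation) {
  g <- activation@gradients
  d <- dim(g)
  if (d[2] * d[3] == 0L) stopf("empty layer: H*W = 0")
  w <- apply(g, 1, mean)
  new("ChannelWeights", layerId = activation@layerId, weights = as.numeric(w))
}

#' Grad-CAM map at layer resolution
#'
#' The weighted sum of the feature maps, rectified: value[i,j] =
#' max(0, sum_k alpha_k * A^k_ij). The ReLU keeps only the features with a
#' positive influence on the target class.
#'
#' @param activation a \linkS4class{LayerActivation}.
#' @param weights matching \linkS4class{ChannelWeights}; computed from the
#'   activation when omitted.
#' @return a \linkS4class{CamMap} with resolution "layer".
#' @export
gradcamMap <- function(activation, weights = channelWeights(activation)) {
  d <- dim(activation@values)
  if (length(weights@weights) != d[1])
    stopf("channel count mismatch: %d weights vs %d channels",
          length(weights@weights), d[1])
  vmat <- matrix(activation@values, nrow = d[1])   # K x (H*W)
  combined <- colSums(vmat * weights@weights)
  grid <- matrix(pmax(combined, 0), d[2], d[3])
  new("CamMap", layerId = activation@layerId, resolution = "layer",
      values = grid)
}

# interpolation weight matrix mapping `src` source rows to `dst` target rows,
# pixel-center aligned; each target row is a convex combination of <= 2 rows.
.bilinearWeights <- function(src, dst) {
  W <- matrix(0, dst, src)
  scale <- src / dst
  for (i in seq_len(dst)) {
    s <- (i - 0.5) * scale + 0.5       # source coordinate in [0.5, src + 0.5]
    s <- min(max(s, 1), src)           # edge replication
    i0 <- floor(s)
    frac <- s - i0
    if (i0 >= src) { i0 <- src; frac <- 0 }
    W[i, i0] <- W[i, i0] + (1 - frac)
    if (frac > 0) W[i, i0 + 1L] <- W[i, i0 + 1L] + frac
  }
  W
}

.nearestIndex <- function(src, dst) {
  idx <- floor((seq_len(dst) - 0.5) * src / dst) + 1L
  pmin(pmax(idx, 1L), src)
}

#' Upsample a Grad-CAM map to image resolution
#'
#' Resamples a layer-resolution map onto the image pixel grid, with
#' pixel-center alignment. Bilinear interpolation (default) yields the smooth
#' attention surfaces seen in Grad-CAM heatmaps; nearest-neighbour replicates
#' layer cells into blocks and exactly preserves the set of distinct values.
#' Non-negativity is preserved by both. Downsampling is not supported.
#'
#' @param cam a \linkS4class{CamMap} at layer resolution.
#' @param imageSize integer c(height, width) of the target image.
#' @param method "bilinear" or "nearest".
#' @return a \linkS4class{CamMap} with resolution "image".
#' @export
upsampleCam <- function(cam, imageSize, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- dim(cam@values)
  H <- as.integer(imageSize[1]); W <- as.integer(imageSize[2])
  if (H < src[1] || W < src[2])
    stopf("target %d x %d smaller than source %d x %d (downsampling unsupported)",
          H, W, src[1], src[2])
  vals <- if (method == "bilinear") {
    Wr <- .bilinearWeights(src[1], H)
    Wc <- .bilinearWeights(src[2], W)
    Wr %*% cam@values %*% t(Wc)
  } else {
    cam@values[.nearestIndex(src[1], H), .nearestIndex(src[2], W), drop = FALSE]
  }
  vals <- pmax(vals, 0)   # guard against -0/rounding at the boundary
  new("CamMap", layerId = cam@layerId, resolution = "image", values = vals)
}

# fixed colour ramp: navy -> cyan -> yellow -> red
.HEAT_COLORS <- c("#000080", "#00BFFF", "#FFFF00", "#FF0000")

# min-max normalise to [0,1]; constant positive maps become 1, all-zero stay 0
.normalizeCam <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi > lo) (v - lo) / (hi - lo)
  else if (hi > 0) array(1, dim(v))
  else array(0, dim(v))
}

#' Render a Grad-CAM heatmap over an image
#'
#' Min-max normalises the map to [0, 1] (all-zero maps stay zero), colours it
#' through a fixed navy-cyan-yellow-red ramp and alpha-blends it over the
#' image. The per-pixel blending weight is \code{opacity} times the
#' normalised map value, so unattended pixels show the pure base image.
#'
#' @param cam a \linkS4class{CamMap} at image resolution.
#' @param image H x W x 3 array (or H x W matrix) with values in [0, 1].
#' @param opacity maximum overlay opacity in [0, 1].
#' @return H x W x 3 numeric array in [0, 1].
#' @export
renderHeatmap <- function(cam, image, opacity = 0.6) {
  if (is.matrix(image))
    image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (!identical(dim(cam@values), d[1:2]))
    stopf("cam resolution %s does not match image %s",
          paste(dim(cam@values), collapse = "x"),
          paste(d[1:2], collapse = "x"))
  norm <- .normalizeCam(cam@values)
  ramp <- grDevices::colorRamp(.HEAT_COLORS)(as.vector(norm)) / 255
  alpha <- as.vector(norm) * opacity
  out <- array(0, d)
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * as.vector(image[, , ch]) + alpha * ramp[, ch]
  out
}
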