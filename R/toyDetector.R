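#' Create a toy detector specification
#'
#' Constructor for \linkS4class{ToyDetectorSpec}. The default configuration is
#' a stack of five stride-2, kernel-3 convolutions tapped at cumulative
#' strides 8, 16 and 32 ("small", "medium", "large"), so successive
#' detection-layer pixel counts differ by a factor of 4, mirroring the scale
#' structure of a three-head detector such as YOLOv5.
#'
#' @param inputSize integer c(height, width) of the expected input.
#' @param layerSpecs list of per-layer lists with elements kernel, stride,
#'   inChannels, outChannels; the default builds the stride-8/16/32 stack.
#' @param detectionLayers named integer vector of tapped layer indices.
#' @param headLayers which tapped layers contribute to the scalar target y;
#'   defaults to all of them.
#' @param weightSeed integer seed for weight initialisation.
#' @return a validated \linkS4class{ToyDetectorSpec}.
#' @export
toyDetectorSpec <- function(inputSize = c(64L, 64L),
                            layerSpecs = NULL,
                            detectionLayers = NULL,
                            headLayers = NULL,
                            weightSeed = 1L) {
  if (is.null(layerSpecs)) {
    ch <- c(3L, 4L, 8L, 8L, 8L, 8L)
    layerSpecs <- lapply(seq_len(5L), function(i)
      list(kernel = 3L, stride = 2L,
           inChannels = ch[i], outChannels = ch[i + 1L]))
    if (is.null(detectionLayers))
      detectionLayers <- c(small = 3L, medium = 4L, large = 5L)
  }
  if (is.null(detectionLayers))
    stop("detectionLayers must be given with custom layerSpecs", call. = FALSE)
  if (is.null(headLayers)) headLayers <- names(detectionLayers)
  new("ToyDetectorSpec",
      inputSize = as.integer(inputSize),
      layerSpecs = layerSpecs,
      detectionLayers = vapply(detectionLayers, as.integer, 1L),
      headLayers = as.character(headLayers),
      weightSeed = as.integer(weightSeed))
}

#' Build a toy multi-scale detector from a spec
#'
#' Materialises deterministic weights from the spec's seed: convolution
#' weights uniform in [-0.5, 0.5] (biases zero), plus one 1x1 single-channel
#' response head per tapped layer. The global spatial sum of the response
#' heads of the configured head layers defines the scalar target score y the
#' Grad-CAM gradients are taken of.
#'
#' @param spec a \linkS4class{ToyDetectorSpec}.
#' @return a \linkS4class{ToyDetector}.
#' @export
buildToyDetector <- function(spec) {
  validObject(spec)
  cum <- cumprod(vapply(spec@layerSpecs, function(l) as.numeric(l$stride), 0))
  withLocalSeed(spec@weightSeed, {
    weights <- lapply(spec@layerSpecs, function(l) {
      n <- l$outChannels * l$inChannels * l$kernel * l$kernel
      array(stats::runif(n, -0.5, 0.5),
            c(l$outChannels, l$inChannels, l$kernel, l$kernel))
    })
    headWeights <- lapply(names(spec@detectionLayers), function(nm) {
      oc <- spec@layerSpecs[[spec@detectionLayers[[nm]]]]$outChannels
      stats::runif(oc, -0.5, 0.5)
    })
  })
  names(headWeights) <- names(spec@detectionLayers)
  new("ToyDetector", spec = spec, weights = weights,
      headWeights = headWeights, cumStrides = cum)
}

# forward pass storing pre-activations z and post-ReLU activations a
.forwardAll <- function(detector, x) {
  L <- length(detector@weights)
  z <- vector("list", L); a <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    s <- detector@spec@layerSpecs[[l]]$stride
    z[[l]] <- convForward(cur, detector@weights[[l]], s)
    a[[l]] <- pmax(z[[l]], 0)
    cur <- a[[l]]
  }
  list(z = z, a = a)
}

# y = sum over head layers of sum_c headW[c] * sum_ij a[c, i, j]
.targetFromActivations <- function(detector, a) {
  y <- 0
  for (nm in detector@spec@headLayers) {
    idx <- detector@spec@detectionLayers[[nm]]
    hw <- detector@headWeights[[nm]]
    chSums <- apply(a[[idx]], 1, sum)
    y <- y + sum(hw * chSums)
  }
  y
}

.asDetectorInput <- function(detector, image) {
  sz <- detector@spec@inputSize
  d <- dim(image)
  if (is.matrix(image)) image <- array(rep(image, 3L), c(d[1], d[2], 3L))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L || d[1] != sz[1] || d[2] != sz[2])
    stopf("image must be %d x %d x 3 (got %s)", sz[1], sz[2],
          paste(d, collapse = " x "))
  if (!all(is.finite(image))) stopf("image contains non-finite pixels")
  aperm(image, c(3, 1, 2))
}

#' Forward and backward pass of the toy detector
#'
#' Runs the hand-written forward pass, forms the scalar target score y from
#' the response heads, and backpropagates y through ReLU and convolution to
#' obtain the gradient of y with respect to every tapped layer's feature
#' values. These (values, gradients) pairs are exactly the inputs Grad-CAM
#' needs.
#'
#' @param detector a \linkS4class{ToyDetector}.
#' @param image H x W x 3 numeric array (or H x W matrix, replicated to three
#'   channels) matching the spec's input size; finite values.
#' @return list with elements \code{activations} (list of
#'   \linkS4class{LayerActivation}, one per tapped layer, in spec order) and
#'   \code{target} (a \linkS4class{TargetScore}).
#' @export
forwardBackward <- function(detector, image) {
  x <- .asDetectorInput(detector, image)
  fw <- .forwardAll(detector, x)
  y <- .targetFromActivations(detector, fw$a)

  spec <- detector@spec
  L <- length(detector@weights)
  da <- lapply(fw$a, function(ai) array(0, dim(ai)))
  for (nm in spec@headLayers) {
    idx <- spec@detectionLayers[[nm]]
    hw <- detector@headWeights[[nm]]
    # head contribution: dy/da[c,i,j] = headW[c] at every position
    da[[idx]] <- da[[idx]] + array(hw, dim(fw$a[[idx]]))
  }
  for (l in rev(seq_len(L))[seq_len(L - 1L)]) {   # L, L-1, ..., 2
    dz <- da[[l]] * (fw$z[[l]] > 0)
    din <- dim(fw$a[[l - 1L]])
    da[[l - 1L]] <- da[[l - 1L]] +
      convBackwardInput(dz, detector@weights[[l]],
                        spec@layerSpecs[[l]]$stride, din[2], din[3])
  }

  acts <- lapply(names(spec@detectionLayers), function(nm) {
    idx <- spec@detectionLayers[[nm]]
    new("LayerActivation", layerId = nm,
        values = fw$a[[idx]], gradients = da[[idx]],
        stride = detector@cumStrides[[idx]])
  })
  names(acts) <- names(spec@detectionLayers)
  tag <- sprintf("sum_of_response_heads(%s)",
                 paste(spec@headLayers, collapse = "+"))
  list(activations = acts,
       target = new("TargetScore", value = y, definitionTag = tag))
}

# recompute y after replacing layer `idx`'s post-ReLU activation with `aIdx`
.targetFromLayer <- function(detector, a, idx, aIdx) {
  a[[idx]] <- aIdx
  L <- length(detector@weights)
  if (idx < L) {
    cur <- aIdx
    for (l in (idx + 1L):L) {
      s <- detector@spec@layerSpecs[[l]]$stride
      cur <- pmax(convForward(cur, detector@weights[[l]], s), 0)
      a[[l]] <- cur
    }
  }
  .targetFromActivations(detector, a)
}

#' Finite-difference gradients of the target score
#'
#' Central-difference oracle for \code{\link{forwardBackward}}: perturbs each
#' stored post-ReLU activation entry of the named tapped layer by +/- epsilon,
#' re-runs the downstream forward pass and differences the target score. Away
#' from ReLU kinks the network is locally linear in each entry, so the
#' estimate is exact up to floating-point rounding.
#'
#' @param detector a \linkS4class{ToyDetector}.
#' @param image input image as for \code{\link{forwardBackward}}.
#' @param layerId one of the tapped layer labels.
#' @param epsilon perturbation size (> 0), default 1e-4.
#' @return K x H x W numeric array of gradient estimates.
#' @export
finiteDifferenceGradients <- function(detector, image, layerId, epsilon = 1e-4) {
  if (epsilon <= 0) stopf("epsilon must be > 0")
  if (!layerId %in% names(detector@spec@detectionLayers))
    stopf("unknown layer_id '%s'", layerId)
  x <- .asDetectorInput(detector, image)
  fw <- .forwardAll(detector, x)
  idx <- detector@spec@detectionLayers[[layerId]]
  a0 <- fw$a[[idx]]
  grad <- array(0, dim(a0))
  for (n in seq_along(a0)) {
    ap <- a0; ap[n] <- ap[n] + epsilon
    am <- a0; am[n] <- am[n] - epsilon
    yp <- .targetFromLayer(detector, fw$a, idx, ap)
    ym <- .targetFromLayer(detector, fw$a, idx, am)
    grad[n] <- (yp - ym) / (2 * epsilon)
  }
  grad
}
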