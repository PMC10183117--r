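# Independent oracles used across the suite. These deliberately use naive
# loops / enumeration, not the package's vectorised paths.

quietly <- function() options(spikeCAM.quiet = TRUE)
quietly()

randomActivation <- function(seed, K = 3L, H = 4L, W = 5L, layerId = "small",
                             stride = 8) {
  set.seed(seed)
  new("LayerActivation", layerId = layerId,
      values = array(rnorm(K * H * W), c(K, H, W)),
      gradients = array(rnorm(K * H * W), c(K, H, W)),
      stride = stride)
}

# Eq-style triple-loop Grad-CAM: channel means of gradients, weighted sum of
# feature maps, clipped at zero.
camOracle <- function(values, gradients) {
  K <- dim(values)[1]; H <- dim(values)[2]; W <- dim(values)[3]
  alpha <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + gradients[k, i, j]
    alpha[k] <- s / (H * W)
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 0
    for (k in seq_len(K)) v <- v + alpha[k] * values[k, i, j]
    out[i, j] <- max(0, v)
  }
  list(alpha = alpha, cam = out)
}

# per-pixel attention-score oracle
scoreOracle <- function(grid, box) {
  hits <- 0; total <- 0
  for (y in (box$y_min + 1):box$y_max) for (x in (box$x_min + 1):box$x_max) {
    total <- total + 1
    if (grid[y, x]) hits <- hits + 1
  }
  hits / total
}

iouOracle <- function(a, b) {
  ix <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  iy <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  (inter) / ((a$x_max - a$x_min) * (a$y_max - a$y_min) +
             (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter)
}

# Enumerate every injective detection -> (ground truth | FP) assignment and
# keep the ones consistent with the greedy rule: a detection (in descending
# confidence order) must claim the still-unmatched ground truth of highest
# IoU >= threshold (ties: lowest index), else be a false positive. Exactly
# one assignment should survive.
matchOracle <- function(dets, gts, iouThreshold = 0.5) {
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  nD <- nrow(dets); nG <- nrow(gts)
  assigns <- list(integer(0))          # 0 = FP, g > 0 = gt row index
  for (i in seq_len(nD)) {
    nxt <- list()
    for (a in assigns) for (g in 0:nG) {
      if (g > 0 && g %in% a) next
      if (g > 0 && gts$image_id[g] != dets$image_id[ord[i]]) next
      nxt[[length(nxt) + 1L]] <- c(a, g)
    }
    assigns <- nxt
  }
  valid <- Filter(function(a) {
    taken <- integer(0)
    for (i in seq_len(nD)) {
      d <- dets[ord[i], ]
      cand <- setdiff(which(gts$image_id == d$image_id), taken)
      ious <- vapply(cand, function(g) iouOracle(d, gts[g, ]), 0)
      elig <- cand[ious >= iouThreshold]
      if (a[i] == 0) {
        if (length(elig)) return(FALSE)
      } else {
        if (!(a[i] %in% elig)) return(FALSE)
        myIou <- ious[match(a[i], cand)]
        better <- elig[ious[match(elig, cand)] > myIou |
                       (ious[match(elig, cand)] == myIou & elig < a[i])]
        if (length(better)) return(FALSE)
        taken <- c(taken, a[i])
      }
    }
    TRUE
  }, assigns)
  stopifnot(length(valid) == 1L)
  list(order = ord, tp = valid[[1]] > 0)
}

# direct step-area AP: envelope by explicit suffix max, area by explicit loop
apOracle <- function(recall, precision) {
  n <- length(recall)
  ap <- 0
  prev <- 0
  for (i in seq_len(n)) {
    env <- max(precision[i:n])
    ap <- ap + (recall[i] - prev) * env
    prev <- recall[i]
  }
  ap
}

# loop-based per-layer statistics recomputation
statsOracle <- function(records) {
  n <- nrow(records)
  counts <- numeric(10); sizeSums <- numeric(10)
  for (r in seq_len(n)) {
    s <- records$score[r]
    b <- if (s >= 1) 10L else floor(s * 10) + 1L
    counts[b] <- counts[b] + 1
    sizeSums[b] <- sizeSums[b] + records$spike_size[r]
  }
  zeros <- records$score == 0
  list(proportion_pct = 100 * counts / n,
       mean_spike_size = ifelse(counts > 0, sizeSums / counts, NA),
       mean_score = sum(records$score) / n,
       score_min = min(records$score), score_max = max(records$score),
       zero_pct = 100 * sum(zeros) / n,
       zero_mean_size = if (any(zeros)) mean(records$spike_size[zeros]) else NA)
}

# small detector spec used by gradient-check tests
twoLayerSpec <- function(seed) {
  toyDetectorSpec(
    inputSize = c(8L, 8L),
    layerSpecs = list(
      list(kernel = 3L, stride = 2L, inChannels = 3L, outChannels = 2L),
      list(kernel = 3L, stride = 2L, inChannels = 2L, outChannels = 3L)),
    detectionLayers = c(small = 1L, medium = 2L),
    weightSeed = seed)
}

maxRelErr <- function(a, b) max(abs(a - b) / pmax(abs(a), abs(b), 1e-6))
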