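test_that("channel weights are spatial gradient means (loop oracle)", {
  act <- randomActivation(21, K = 3L, H = 2L, W = 2L)
  cw <- channelWeights(act)
  expect_equal(cw@weights, camOracle(act@values, act@gradients)$alpha,
               tolerance = 1e-15)
  # constant gradient g over a channel -> alpha = g
  act@gradients[2, , ] <- 0.37
  expect_equal(channelWeights(act)@weights[2], 0.37)
  # zero gradients -> zero weights
  act@gradients[] <- 0
  expect_true(all(channelWeights(act)@weights == 0))
})

test_that("gradcam map equals the per-pixel brute-force loop", {
  for (seed in 1:20) {
    set.seed(seed)
    K <- sample(1:8, 1); H <- sample(1:8, 1); W <- sample(1:8, 1)
    act <- randomActivation(seed + 500, K, H, W)
    cam <- gradcamMap(act)
    expect_lt(max(abs(camValues(cam) - camOracle(act@values, act@gradients)$cam)),
              1e-12)
    expect_true(all(camValues(cam) >= 0))
  }
})

test_that("ReLU clips negative weighted sums", {
  act <- new("LayerActivation", layerId = "small",
             values = array(c(-1, 2, 0, -3), c(1, 2, 2)),
             gradients = array(1, c(1, 2, 2)), stride = 8)
  # single channel, alpha = mean(grad) = 1
  expect_equal(camValues(gradcamMap(act)),
               matrix(c(0, 2, 0, 0), 2, 2))  # [[-1,0],[2,-3]] clipped at 0
  # all-zero weights -> all-zero map
  w0 <- new("ChannelWeights", layerId = "small", weights = 0)
  expect_true(all(camValues(gradcamMap(act, w0)) == 0))
  # channel-count mismatch
  w2 <- new("ChannelWeights", layerId = "small", weights = c(1, 1))
  expect_error(gradcamMap(act, w2), "channel count mismatch")
})

test_that("CAM scales linearly with the gradients (scale equivariance)", {
  act <- randomActivation(33, K = 4L, H = 5L, W = 5L)
  c1 <- gradcamMap(act)
  act2 <- act; act2@gradients <- 3 * act@gradients
  expect_equal(camValues(gradcamMap(act2)), 3 * camValues(c1),
               tolerance = 1e-12)
  # zero gradients -> zero CAM -> empty attention region
  act@gradients[] <- 0
  cam0 <- upsampleCam(gradcamMap(act), c(40, 40))
  expect_true(all(camValues(cam0) == 0))
  expect_equal(sum(maskGrid(attentionMask(cam0))), 0)
})

test_that("upsampling: constants, nearest blocks and hand-computed bilinear", {
  one <- new("CamMap", layerId = "small", resolution = "layer",
             values = matrix(2.5, 1, 1))
  up <- upsampleCam(one, c(5, 7))
  expect_true(all(camValues(up) == 2.5))
  expect_equal(dim(camValues(up)), c(5L, 7L))
  expect_equal(camResolution(up), "image")

  src <- new("CamMap", layerId = "small", resolution = "layer",
             values = matrix(c(1, 3, 2, 4), 2, 2))
  nn <- upsampleCam(src, c(4, 4), method = "nearest")
  expect_equal(camValues(nn),
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))
  expect_setequal(unique(as.vector(camValues(nn))),
                  unique(as.vector(camValues(src))))

  # hand-derived pixel-center bilinear values for [[0,1],[1,0]] -> 4x4:
  # target centers map to source coords {1, 1.25, 1.75, 2} (after edge
  # clamping), giving row/col weight pairs (1,0), (.75,.25), (.25,.75), (0,1);
  # out[i,j] = wr1*wc2 + wr2*wc1 for this anti-diagonal source.
  anti <- new("CamMap", layerId = "small", resolution = "layer",
              values = matrix(c(0, 1, 1, 0), 2, 2))
  expected <- matrix(c(
    0.000, 0.250, 0.750, 1.000,
    0.250, 0.375, 0.625, 0.750,
    0.750, 0.625, 0.375, 0.250,
    1.000, 0.750, 0.250, 0.000), 4, 4, byrow = TRUE)
  expect_equal(camValues(upsampleCam(anti, c(4, 4))), expected,
               tolerance = 1e-12)

  expect_error(upsampleCam(src, c(1, 4)), "downsampling unsupported")
})

test_that("heatmap rendering blends only where there is attention", {
  img <- array(0.4, c(6, 6, 3))
  zero <- new("CamMap", layerId = "small", resolution = "image",
              values = matrix(0, 6, 6))
  expect_equal(renderHeatmap(zero, img, opacity = 0.8), img)

  const <- new("CamMap", layerId = "small", resolution = "image",
               values = matrix(5, 6, 6))
  out <- renderHeatmap(const, img, opacity = 1)
  # top of the navy-cyan-yellow-red ramp is pure red
  expect_true(all(out[, , 1] == 1) && all(out[, , 2] == 0) && all(out[, , 3] == 0))

  two <- matrix(0, 6, 6); two[2:3, 2:3] <- 1
  cam2 <- new("CamMap", layerId = "small", resolution = "image", values = two)
  out2 <- renderHeatmap(cam2, img, opacity = 0.5)
  cols <- unique(apply(matrix(out2, 36, 3), 1, paste, collapse = ","))
  expect_length(cols, 2)

  small <- new("CamMap", layerId = "small", resolution = "image",
               values = matrix(1, 2, 2))
  expect_error(renderHeatmap(small, img), "does not match")
})
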