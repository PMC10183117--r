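test_that("default spec taps strides 8/16/32 with factor-4 pixel counts", {
  det <- buildToyDetector(toyDetectorSpec(inputSize = c(64L, 64L)))
  img <- array(0.5, c(64, 64, 3))
  fb <- forwardBackward(det, img)
  counts <- vapply(fb$activations,
                   function(a) prod(dim(activationValues(a))[2:3]), 0)
  expect_equal(unname(counts), c(64, 16, 4))
  expect_equal(unname(vapply(fb$activations, layerStride, 0)), c(8, 16, 32))
  expect_equal(unname(counts[-3] / counts[-1]), c(4, 4))
})

test_that("weights are reproducible from the seed and differ across seeds", {
  d1 <- buildToyDetector(toyDetectorSpec(weightSeed = 1L))
  d2 <- buildToyDetector(toyDetectorSpec(weightSeed = 1L))
  d3 <- buildToyDetector(toyDetectorSpec(weightSeed = 2L))
  expect_identical(d1@weights, d2@weights)
  expect_identical(d1@headWeights, d2@headWeights)
  expect_false(identical(d1@weights, d3@weights))
})

test_that("invalid detector configurations are rejected", {
  expect_error(toyDetectorSpec(
    inputSize = c(16L, 16L),
    layerSpecs = list(list(kernel = 3L, stride = 2L, inChannels = 3L,
                           outChannels = 2L),
                      list(kernel = 3L, stride = 1L, inChannels = 2L,
                           outChannels = 2L)),
    detectionLayers = c(small = 2L, medium = 1L)),
    "strictly increasing")
  expect_error(toyDetectorSpec(
    inputSize = c(16L, 16L),
    layerSpecs = list(list(kernel = 0L, stride = 2L, inChannels = 3L,
                           outChannels = 2L)),
    detectionLayers = c(small = 1L)),
    "positive")
})

test_that("all-zero image gives all-zero activations and y = 0", {
  det <- buildToyDetector(toyDetectorSpec(inputSize = c(32L, 32L)))
  fb <- forwardBackward(det, array(0, c(32, 32, 3)))
  for (a in fb$activations)
    expect_true(all(activationValues(a) == 0))
  expect_identical(fb$target@value, 0)
})

test_that("forward/backward is deterministic and rejects bad inputs", {
  det <- buildToyDetector(toyDetectorSpec(inputSize = c(32L, 32L)))
  set.seed(4); img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fb1 <- forwardBackward(det, img)
  fb2 <- forwardBackward(det, img)
  expect_identical(fb1$target@value, fb2$target@value)
  expect_identical(lapply(fb1$activations, activationValues),
                   lapply(fb2$activations, activationValues))
  expect_identical(lapply(fb1$activations, activationGradients),
                   lapply(fb2$activations, activationGradients))
  expect_error(forwardBackward(det, array(0.1, c(16, 16, 3))), "must be 32 x 32")
  bad <- img; bad[1] <- NaN
  expect_error(forwardBackward(det, bad), "non-finite")
})

test_that("doubling the response-head weights doubles y", {
  det <- buildToyDetector(twoLayerSpec(5L))
  set.seed(6); img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y1 <- forwardBackward(det, img)$target@value
  det@headWeights <- lapply(det@headWeights, function(w) 2 * w)
  y2 <- forwardBackward(det, img)$target@value
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("backprop matches central finite differences on seeded configs", {
  for (seed in c(1L, 2L, 3L)) {
    det <- buildToyDetector(twoLayerSpec(seed))
    set.seed(seed + 100); img <- array(runif(8 * 8 * 3), c(8, 8, 3))
    fb <- forwardBackward(det, img)
    for (lyr in c("small", "medium")) {
      fd <- finiteDifferenceGradients(det, img, lyr, epsilon = 1e-4)
      an <- activationGradients(fb$activations[[lyr]])
      expect_lt(maxRelErr(an, fd), 1e-4)
    }
  }
})

test_that("a layer feeding y only through zeroed weights has zero gradient", {
  det <- buildToyDetector(twoLayerSpec(9L))
  # cut every path from the small layer to y: zero its head and layer 2
  det@headWeights$small <- det@headWeights$small * 0
  det@weights[[2]] <- det@weights[[2]] * 0
  set.seed(10); img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fb <- forwardBackward(det, img)
  expect_true(all(activationGradients(fb$activations$small) == 0))
  fd <- finiteDifferenceGradients(det, img, "small")
  expect_true(all(fd == 0))
  expect_error(finiteDifferenceGradients(det, img, "huge"), "unknown layer_id")
})

test_that("stride bookkeeping satisfies the ceil relation", {
  for (n in c(31L, 32L, 33L, 64L)) {
    det <- buildToyDetector(toyDetectorSpec(inputSize = c(n, n)))
    fb <- forwardBackward(det, array(0.3, c(n, n, 3)))
    for (a in fb$activations) {
      w <- dim(activationValues(a))[3]
      s <- layerStride(a)
      expect_true(s * w >= n)
      expect_true(n > s * (w - 1))
    }
  }
})

test_that("array files round-trip and mismatched dumps are rejected", {
  tmp <- withr::local_tempdir()
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  p <- file.path(tmp, "a")
  writeArrayFile(x, p)
  expect_identical(readArrayFile(p), x)
  # float32 loses precision but keeps shape
  writeArrayFile(x, p, dtype = "float32")
  x32 <- readArrayFile(p)
  expect_identical(dim(x32), dim(x))
  expect_equal(x32, x, tolerance = 1e-6)
  # shape mismatch between values and gradients
  writeArrayFile(array(0, c(4, 8, 8)), file.path(tmp, "v"))
  writeArrayFile(array(0, c(4, 8, 7)), file.path(tmp, "g"))
  expect_error(loadExternalActivations(file.path(tmp, "v"),
                                       file.path(tmp, "g"), "small", 8),
               "shape mismatch")
  expect_error(readArrayFile(file.path(tmp, "missing")), "cannot read")
})

test_that("dumped activations reload to an identical downstream CAM", {
  tmp <- withr::local_tempdir()
  det <- buildToyDetector(twoLayerSpec(3L))
  set.seed(12); img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fb <- forwardBackward(det, img)
  act <- fb$activations$medium
  paths <- dumpActivations(act, "img1", tmp)
  reloaded <- loadExternalActivations(paths[1], paths[2], "medium",
                                      layerStride(act))
  expect_identical(activationValues(reloaded), activationValues(act))
  expect_identical(camValues(gradcamMap(reloaded)), camValues(gradcamMap(act)))
})
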