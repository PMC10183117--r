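mkRecords <- function(scores, sizes = rep(1000, length(scores)),
                      layer = "small") {
  data.frame(image_id = "img", box_id = as.character(seq_along(scores)),
             layer_id = layer, score = scores, spike_size = sizes,
             stringsAsFactors = FALSE)
}

test_that("bin tally matches the hand-counted example", {
  recs <- mkRecords(c(0.0, 0.05, 0.15, 0.15, 0.25, 0.35, 0.45, 0.55, 0.95, 1.0))
  b <- binScores(recs)
  expect_equal(b$proportion_pct, c(20, 20, 10, 10, 10, 10, 0, 0, 0, 20))
  expect_equal(sum(b$proportion_pct), 100)
  expect_equal(sum(b$count), nrow(recs))
})

test_that("bin boundary rules: 1.0 goes to the top bin, bins are left-closed", {
  b <- binScores(mkRecords(c(1.0, 1.0)))
  expect_equal(b$proportion_pct[10], 100)
  b2 <- binScores(mkRecords(rep(0.05, 7)))
  expect_equal(b2$proportion_pct, c(100, rep(0, 9)))
  # exact decile boundaries land in their own (lower-closed) bin
  b3 <- binScores(mkRecords(c(0.1, 0.2, 0.3, 0.7)))
  expect_equal(b3$count, c(0, 1, 1, 1, 0, 0, 0, 1, 0, 0))
  expect_error(binScores(data.frame(score = numeric(0),
                                    spike_size = numeric(0))), "no records")
  expect_error(binScores(mkRecords(1.2)), "in \\[0, 1\\]")
})

test_that("zero-score audit isolates the ignored spikes", {
  expect_equal(zeroScoreAudit(mkRecords(c(0.2, 0.4)))$zero_proportion_pct, 0)
  expect_true(is.na(zeroScoreAudit(mkRecords(c(0.2, 0.4)))$zero_mean_spike_size))
  all0 <- zeroScoreAudit(mkRecords(c(0, 0), sizes = c(100, 300)))
  expect_equal(all0$zero_proportion_pct, 100)
  expect_equal(all0$zero_mean_spike_size, 200)
  mix <- zeroScoreAudit(mkRecords(c(0, 0, 0, rep(0.5, 7)),
                                  sizes = c(100, 200, 300, rep(50, 7))))
  expect_equal(mix$zero_proportion_pct, 30)
  expect_equal(mix$zero_mean_spike_size, 200)
})

test_that("layer summary agrees with an independent loop-based recomputation", {
  set.seed(202)
  recs <- mkRecords(round(runif(50), 3), sizes = sample(500:20000, 50))
  st <- layerSummary(recs)
  o <- statsOracle(recs)
  expect_equal(scoreBins(st)$proportion_pct, o$proportion_pct)
  expect_equal(scoreBins(st)$mean_spike_size, o$mean_spike_size)
  expect_equal(meanScore(st), o$mean_score)
  expect_equal(st@scoreMin, o$score_min)
  expect_equal(st@scoreMax, o$score_max)
  expect_equal(zeroProportion(st), o$zero_pct)
  # single record
  one <- layerSummary(mkRecords(0.4, 500))
  expect_equal(meanScore(one), 0.4)
  expect_equal(c(one@scoreMin, one@scoreMax), c(0.4, 0.4))
  expect_equal(scoreBins(one)$proportion_pct[5], 100)
  # symmetric pair
  expect_equal(meanScore(layerSummary(mkRecords(c(0.2, 0.8)))), 0.5)
})

test_that("statistics integrity invariants hold on random record sets", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    recs <- mkRecords(sample(c(0, runif(n - 1))), sizes = runif(n, 100, 20000))
    st <- layerSummary(recs)
    b <- scoreBins(st)
    expect_equal(sum(b$proportion_pct), 100, tolerance = 1e-12)
    # reconstruction: proportions recover the total record count
    expect_equal(sum(b$proportion_pct / 100 * st@nRecords), n)
    # bin-weighted mean of bin mean sizes equals the overall mean size
    keep <- b$count > 0
    expect_equal(sum(b$count[keep] * b$mean_spike_size[keep]) / n,
                 mean(recs$spike_size), tolerance = 1e-12)
    # zero records are inside the first bin
    expect_lte(sum(recs$score == 0), b$count[1])
  }
})

test_that("layers are ranked by zero-score proportion, then mean score", {
  mk <- function(id, zero, meanS) {
    n <- 200
    nz <- round(n * zero / 100)
    scores <- c(rep(0, nz), rep(meanS * n / (n - nz), n - nz))
    layerSummary(mkRecords(pmin(scores, 1), layer = id), id)
  }
  stats <- list(mk("small", 17.5, 0.083), mk("medium", 4, 0.25),
                mk("large", 30, 0.309))
  cmp <- compareLayers(stats)
  expect_equal(cmp$layer_id, c("medium", "small", "large"))
  expect_equal(cmp$verdict_mark, c("best", "", "worst"))

  # identical stats fall back to the small -> medium -> large order
  same <- list(mk("large", 10, 0.2), mk("small", 10, 0.2), mk("medium", 10, 0.2))
  expect_equal(compareLayers(same)$layer_id, c("small", "medium", "large"))

  # mean score breaks ties
  tie <- list(mk("small", 10, 0.1), mk("medium", 10, 0.4))
  expect_equal(compareLayers(tie)$layer_id[1], "medium")

  expect_error(compareLayers(list(mk("small", 1, 0.1))), "at least two")
  expect_error(compareLayers(list(mk("small", 1, 0.1), mk("small", 2, 0.1))),
               "duplicate")
})

test_that("formatted tables round the way the reference tables print", {
  recs <- mkRecords(c(0, 0.05, 0.55), sizes = c(8682, 3438, 2137))
  lines <- formatLayerStats(layerSummary(recs))
  expect_true(any(grepl("66.7", lines)))   # 2/3 in first bin, 1 decimal
  expect_true(any(grepl("6060", lines)))   # mean size rounded to integer
  expect_true(any(grepl("-", lines, fixed = TRUE)))  # empty bins print '-'
})
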