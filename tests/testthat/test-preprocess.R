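test_that("clipRescale maps the percentile band onto [0, grayMax]", {
  v <- array(0:999, c(10, 10, 10))
  out <- clipRescale(v, PreprocessConfig())
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_warning(res <- clipRescale(array(7, c(4, 4, 4))), "constant")
  expect_true(all(res == 0))
})

test_that("outliers are clamped to the percentile bound before scaling", {
  set.seed(1)
  v <- c(rep(100, 1000), 1e6) + c(rnorm(1000, sd = 1), 0)
  cfg <- PreprocessConfig()
  hi <- oraclePercentile(v, 0.995)
  lo <- oraclePercentile(v, 0.005)
  out <- clipRescale(array(v, c(11, 91)), cfg)
  expected <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo) * 255
  expect_equal(as.vector(out), expected, tolerance = 1e-12)
  # the outlier was clamped to the 99.5th-percentile bound, not stretched:
  # it shares grayMax with the clamped top of the main cluster
  expect_gt(sum(out == 255), 1)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("clipRescale is near-idempotent on already-rescaled volumes", {
  # re-clamping re-estimates the band from the already-clamped tails, so
  # the second pass can shift values only by a sliver of the gray range
  set.seed(2)
  v <- array(runif(4000), c(10, 20, 20))
  cfg <- PreprocessConfig()
  once <- clipRescale(v, cfg)
  twice <- clipRescale(once, cfg)
  expect_lt(max(abs(twice - once)), 0.01 * cfg@grayMax)
  expect_gt(stats::cor(as.vector(once), as.vector(twice)), 1 - 1e-10)
})

test_that("task masks follow the concentric composition and nest", {
  lab <- matrix(0, 5, 5)
  lab[1, 1:2] <- 1; lab[2, 1:3] <- 2; lab[3, 1] <- 3
  expect_equal(sum(deriveTaskMask(lab, "WT")), 6)
  expect_equal(sum(deriveTaskMask(lab, "TC")), 3)
  expect_equal(sum(deriveTaskMask(lab, "ET")), 1)
  expect_true(all(deriveTaskMask(lab, "WT") == 0 |
                  deriveTaskMask(lab, "WT") == 1))
  expect_equal(sum(deriveTaskMask(matrix(0, 4, 4), "WT")), 0)
  bad <- lab; bad[5, 5] <- 7
  expect_error(deriveTaskMask(bad, "WT"), "7")
  # nesting on random label maps
  set.seed(3)
  for (i in 1:20) {
    lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    wt <- deriveTaskMask(lab, "WT"); tc <- deriveTaskMask(lab, "TC")
    et <- deriveTaskMask(lab, "ET")
    expect_true(all(et <= tc) && all(tc <= wt))
  }
})

test_that("tumor slice selection matches a brute-force scan", {
  stack <- cachedCohort()[[1]]
  for (task in c("WT", "TC", "ET")) {
    got <- selectTumorSlices(stack, task)
    lab <- labelVolume(stack)
    codes <- switch(task, WT = c(1, 2, 3), TC = c(1, 3), ET = 3)
    manual <- integer()
    for (z in seq_len(dim(lab)[1]))
      if (any(lab[z, , ] %in% codes)) manual <- c(manual, z)
    expect_identical(got, manual)
    expect_true(all(diff(got) > 0))
  }
  empty <- new("ModalityStack", subjectId = "x",
               images = list(array(0, c(4, 5, 5))),
               labels = array(0L, c(4, 5, 5)), modalityNames = "m")
  expect_identical(selectTumorSlices(empty, "WT"), integer())
})

test_that("box prompts contain the tight box and respect image bounds", {
  mask <- matrix(0, 100, 100)
  mask[41:61, 31:41] <- 1  # rows (y) 40..60, cols (x) 30..40, 0-based
  cfg0 <- PreprocessConfig(bboxJitterMax = 0)
  expect_equal(unname(makeBboxPrompt(mask, cfg0)), c(30, 40, 40, 60))
  cfg <- PreprocessConfig(bboxJitterMax = 20)
  rng <- newRngStream(99)
  expansions <- numeric(0)
  for (i in 1:2500) {
    b <- makeBboxPrompt(mask, cfg, rng)
    expect_true(b[1] <= 30 && b[2] <= 40 && b[3] >= 40 && b[4] >= 60)
    expect_true(all(b >= 0) && all(b <= 99))
    expansions <- c(expansions, (30 - b[1]) + (40 - b[2]) +
                                (b[3] - 40) + (b[4] - 60))
  }
  # 10 000 side draws from U{0..20}: mean 10, 3-sigma tolerance 0.18;
  # the spec-level 0.6 band is comfortably satisfied
  expect_lt(abs(mean(expansions) / 4 - 10), 0.6)
  expect_error(makeBboxPrompt(matrix(0, 5, 5), cfg), "empty")
})

test_that("model inputs are rescaled, replicated and in range", {
  cfg <- PreprocessConfig(modelSize = 16, grayMax = 255)
  out <- toModelInput(list(matrix(255, 8, 8)), cfg)[[1]]
  expect_equal(dim(out), c(16L, 16L, 3L))
  expect_true(all(out == 1))
  expect_identical(out[, , 1], out[, , 3])
  set.seed(4)
  r <- toModelInput(list(matrix(runif(64, 0, 255), 8, 8)), cfg)[[1]]
  expect_true(min(r) >= 0 && max(r) <= 1)
})

test_that("bilinear resize round trip has small error", {
  board <- matrix(rep(c(0, 255), length.out = 64 * 64), 64, 64)
  cfgUp <- PreprocessConfig(modelSize = 256, grayMax = 255)
  up <- toModelInput(list(board), cfgUp)[[1]][, , 1] * 255
  down <- fuseseg:::.resize2d(up, 64) / 255
  expect_lt(mean(abs(down - board / 255)), 0.2)
})

test_that("slice datasets cover exactly the tumor slices, leakage-safe", {
  cohort <- cachedCohort()[1:3]
  recs <- buildSliceDataset(cohort, "WT", tinyPreprocess())
  expected <- sum(vapply(cohort, function(s)
    length(selectTumorSlices(s, "WT")), 1L))
  expect_equal(length(recs), expected)
  for (r in recs) expect_true(validObject(r))
  expect_setequal(unique(vapply(recs, subjectId, character(1))),
                  vapply(cohort, subjectId, character(1)))
  # deterministic given (cohort, config, seed)
  recs2 <- buildSliceDataset(cohort, "WT", tinyPreprocess())
  expect_identical(lapply(recs, bboxPrompt), lapply(recs2, bboxPrompt))
  expect_identical(lapply(recs, modalityImages),
                   lapply(recs2, modalityImages))
})

test_that("a tumor-free cohort yields an empty dataset without error", {
  empty <- new("ModalityStack", subjectId = "s0",
               images = lapply(1:4, function(i) array(runif(100), c(4, 5, 5))),
               labels = array(0L, c(4, 5, 5)),
               modalityNames = c("T1", "T1gd", "T2", "FLAIR"))
  expect_length(buildSliceDataset(list(empty), "WT", tinyPreprocess()), 0)
})
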