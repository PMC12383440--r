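test_that("shared encoder maps identical modalities to identical features", {
  model <- newFusionModel(tinyModelConfig(size = 16), seed = 3)
  img <- makeTestRecord(S = 16)@modalityImages[[1]]
  feats <- encodeModalities(model, list(img, img, img, img))
  expect_identical(feats[[1]], feats[[2]])
  expect_identical(feats[[1]], feats[[4]])
  # stride-2 shape contract
  expect_equal(dim(feats[[1]]), c(8L, 8L, 4L))
})

test_that("squeeze is exact global average pooling", {
  concat <- array(5, c(3, 4, 2))
  expect_equal(ffbSqueeze(concat), c(5, 5))
  concat[, , 2] <- rep(c(0, 1), each = 6)
  expect_equal(ffbSqueeze(concat)[2], 0.5)
  set.seed(7)
  m <- array(rnorm(8 * 5 * 7), c(5, 7, 8))
  expect_equal(ffbSqueeze(aperm(m, c(2, 3, 1))),
               oracleGap(aperm(m, c(2, 3, 1))), tolerance = 1e-6)
})

test_that("excitation is the sigmoid-ReLU bottleneck of the fusion block", {
  C2 <- 6; r <- 2
  zeroP <- list(ffb_W1 = matrix(0, C2 / r, C2), ffb_b1 = numeric(C2 / r),
                ffb_W2 = matrix(0, C2, C2 / r), ffb_b2 = numeric(C2))
  expect_equal(ffbExcite(rnorm(C2), zeroP), rep(0.5, C2))
  set.seed(8)
  for (i in 1:5) {
    p <- list(ffb_W1 = matrix(rnorm(3 * C2), 3, C2), ffb_b1 = rnorm(3),
              ffb_W2 = matrix(rnorm(C2 * 3), C2, 3), ffb_b2 = rnorm(C2))
    z <- rnorm(C2)
    s <- ffbExcite(z, p)
    expect_true(all(s > 0 & s < 1))
    expect_equal(s, oracleExcite(z, p$ffb_W1, p$ffb_b1, p$ffb_W2, p$ffb_b2),
                 tolerance = 1e-6)
  }
  expect_error(ffbExcite(rnorm(4), zeroP), "dimension mismatch")
})

test_that("channel modulation multiplies each channel by its weight", {
  set.seed(9)
  concat <- array(rnorm(60), c(3, 4, 5))
  expect_equal(ffbApply(concat, rep(1, 5)), concat)
  expect_true(all(ffbApply(concat, rep(0, 5)) == 0))
  s <- runif(5)
  got <- ffbApply(concat, s)
  for (k in 1:5)
    expect_equal(got[, , k], concat[, , k] * s[k], tolerance = 1e-7)
})

test_that("residual fusion adds the identity path before projecting", {
  set.seed(10)
  C2 <- 8; Cd <- 3
  p <- list(proj_W = matrix(rnorm(C2 * Cd), C2, Cd), proj_b = rnorm(Cd))
  concat <- array(rnorm(2 * 2 * C2), c(2, 2, C2))
  s1 <- ffbFuse(ffbApply(concat, rep(1, C2)), concat, p)
  doubled <- ffbFuse(2 * concat, array(0, dim(concat)), p)
  expect_equal(s1, doubled, tolerance = 1e-9)
  zero <- ffbFuse(array(0, dim(concat)), array(0, dim(concat)), p)
  for (k in seq_len(Cd)) expect_equal(unique(as.vector(zero[, , k])),
                                      p$proj_b[k])
})

test_that("full FFB path equals the composed equation chain on small input", {
  model <- newFusionModel(tinyModelConfig(size = 16), seed = 5)
  rec <- makeTestRecord(S = 16)
  fs <- fusionState(model, rec)
  expect_true(validObject(fs))
  z <- oracleGap(fs@concat)
  expect_equal(fs@squeeze, z, tolerance = 1e-8)
  p <- modelParams(model)
  s <- oracleExcite(z, p$ffb_W1, p$ffb_b1, p$ffb_W2, p$ffb_b2)
  expect_equal(fs@weights, s, tolerance = 1e-8)
  expect_equal(fs@fused, ffbFuse(ffbApply(fs@concat, s), fs@concat, p),
               tolerance = 1e-8)
})

test_that("logit map has the documented shape and modality-permutation symmetry", {
  model <- newFusionModel(tinyModelConfig(size = 16), seed = 6)
  rec <- makeTestRecord(S = 16)
  logits <- modelForward(model, rec)
  expect_equal(dim(logits), c(16L, 16L))
  # identical images in two slots: swapping those slots changes nothing,
  # while permuting genuinely different modalities does
  imgs <- rec@modalityImages
  imgs[[2]] <- imgs[[3]]
  swapped <- imgs; swapped[[2]] <- imgs[[3]]; swapped[[3]] <- imgs[[2]]
  expect_identical(modelForward(model, imgs, bbox = rec@bbox),
                   modelForward(model, swapped, bbox = rec@bbox))
  distinct <- rec@modalityImages
  distinct[[2]] <- 1 - distinct[[2]]
  expect_false(identical(
    modelForward(model, distinct, bbox = rec@bbox),
    modelForward(model, rev(distinct), bbox = rec@bbox)))
  badSize <- lapply(imgs, function(x) x[1:8, 1:8, , drop = FALSE])
  expect_error(modelForward(model, badSize, bbox = c(0, 0, 4, 4)),
               "resolution")
})

test_that("analytic gradients match central finite differences", {
  model <- newFusionModel(tinyModelConfig(size = 16), seed = 7)
  rec <- makeTestRecord(S = 16)
  params <- modelParams(model); cfg <- modelConfig(model)
  cache <- fuseseg:::.forwardPass(params, cfg, rec@modalityImages, rec@bbox)
  lg <- fuseseg:::.lossGrad(cache$logits, rec@gtMask)
  g <- fuseseg:::.backwardPass(params, cfg, cache, lg$dLogits)
  expect_true(all(vapply(g, function(x) all(is.finite(x)), TRUE)))
  f <- function(p) {
    cc <- fuseseg:::.forwardPass(p, cfg, rec@modalityImages, rec@bbox)
    fuseseg:::.lossGrad(cc$logits, rec@gtMask)$total
  }
  set.seed(11)
  h <- 1e-5
  for (nm in names(g)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (f(pp) - f(pm)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("frozen parts stay bit-identical through an optimizer step", {
  cfgM <- tinyModelConfig(size = 16, trainableParts = c("ffb", "decoder"))
  model <- newFusionModel(cfgM, seed = 8)
  before <- modelParams(model)
  rec <- makeTestRecord(S = 16)
  cfg <- TrainConfig(lr = 1e-2, epochs = 2, batchSize = 1, model = cfgM,
                     preprocess = tinyPreprocess(16), seed = 1)
  fit <- trainModel(list(rec), cfg, model = model)
  after <- modelParams(fit$model)
  expect_identical(after$enc_W, before$enc_W)
  expect_identical(after$enc_b, before$enc_b)
  expect_false(identical(after$dec1_W, before$dec1_W))
  expect_false(identical(after$ffb_W1, before$ffb_W1))
})

test_that("foundation mode demands a checkpoint and never trains the encoder", {
  cfg <- ModelConfig(encoderKind = "foundation_frozen", nModalities = 2,
                     encoderChannels = 4, seReduction = 2,
                     decoderChannels = 8, inputSize = 16,
                     foundationPath = "/nonexistent/foundation.rds")
  expect_false("encoder" %in% cfg@trainableParts)
  expect_error(newFusionModel(cfg), "/nonexistent/foundation.rds")
  # a minimal pluggable encoder checkpoint
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(encode = function(x) {
    d <- dim(x)
    array(x[seq(1, d[1], 2), seq(1, d[2], 2), 1], c(d[1] / 2, d[2] / 2, 4))
  }), path)
  cfg@foundationPath <- path
  model <- newFusionModel(cfg, seed = 2)
  rec <- makeTestRecord(S = 16, nModalities = 2)
  logits <- modelForward(model, rec)
  expect_equal(dim(logits), c(16L, 16L))
})

test_that("a single-modality model degrades gracefully and still learns", {
  spec <- PhantomSpec(nModalities = 1, volumeShape = c(18, 24, 24),
                      regionRadii = c(7, 4, 2), deformAmplitude = 0.4,
                      contrastMatrix = matrix(c(0.5, 0.2, 0.1), 1, 3),
                      modalityNames = "FLAIR", seed = 19)
  cohort <- generateCohort(spec, 5)
  pc <- tinyPreprocess(size = 24)
  recs <- buildSliceDataset(cohort, "WT", pc)
  mc <- ModelConfig(nModalities = 1, encoderChannels = 4, seReduction = 4,
                    decoderChannels = 8, inputSize = 24)
  cfg <- TrainConfig(lr = 1e-3, epochs = 5, batchSize = 8, model = mc,
                     preprocess = pc, seed = 1)
  fit <- trainModel(recs, cfg)
  trainDice <- mean(perSlice(evaluateModel(fit$model, recs))$dice)
  expect_gt(trainDice, 0.8)
})

test_that("checkpoints round-trip through save/load", {
  model <- cachedTrainedFit()$model
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(modelParams(back), modelParams(model))
  rec <- heldOutRecords()[[1]]
  expect_identical(modelForward(back, rec), modelForward(model, rec))
})
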