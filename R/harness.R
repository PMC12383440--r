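# Experiment harness: the 2x2 train/predict mode grid, the lambda sweep,
# and UMAP embedding of fused features.

.holdoutSplit <- function(cohort, fraction, seed) {
  ids <- vapply(cohort, subjectId, character(1))
  nTest <- max(1L, round(length(ids) * fraction))
  test <- withSeed(seed, sample(ids, nTest))
  list(train = setdiff(ids, test), test = test)
}

.meanDice <- function(report) mean(report@perSlice$dice)

# evaluate under MP over several noise seeds; returns mean/sd of the
# per-seed mean Dice plus the per-seed reports
.mpEval <- function(model, records, policy, noiseSeeds) {
  reports <- lapply(noiseSeeds, function(s)
    evaluateModel(model, records, policy, noiseSeed = s))
  dices <- vapply(reports, .meanDice, 1)
  list(meanDice = mean(dices),
       sdDice = if (length(dices) > 1) stats::sd(dices) else 0,
       reports = reports)
}

#' Train/predict mode grid for one missing modality
#'
#' Trains an FT model and an MT model on a shared subject-level holdout
#' split with identical initialization and data-order seeds (only the
#' substitution policy differs), then evaluates both under FP and MP,
#' yielding the four cells FTFP, FTMP, MTFP, MTMP. MP cells are averaged
#' over `noiseSeeds` fresh noise draws.
#'
#' @param cohort list of [ModalityStack-class].
#' @param task segmentation task.
#' @param config a [TrainConfig-class]; its policy supplies `lambda` and
#'   the seeds.
#' @param missingModality the modality designated as missing.
#' @param holdout fraction of subjects held out for evaluation.
#' @param noiseSeeds RNG seeds for MP noise draws.
#' @return list with one entry per cell (label, meanDice, sdDice, report)
#'   plus `split` and `task`.
#' @export
modeGridEval <- function(cohort, task, config, missingModality,
                         holdout = 0.3, noiseSeeds = 1:3) {
  ids <- vapply(cohort, subjectId, character(1))
  if (!missingModality %in% cohort[[1]]@modalityNames)
    stop("unknown modality: ", missingModality)
  split <- .holdoutSplit(cohort, holdout, config@seed + 17)
  records <- buildSliceDataset(cohort, task, config@preprocess)
  trainRec <- Filter(function(r) r@subjectId %in% split$train, records)
  testRec <- Filter(function(r) r@subjectId %in% split$test, records)

  mkConfig <- function(trainMode) {
    cfgPolicy <- MissingPolicy(trainMode = trainMode, predictMode = "FP",
                               lambda = config@policy@lambda,
                               missingSet = missingModality,
                               seed = config@policy@seed)
    new("TrainConfig", lr = config@lr, weightDecay = config@weightDecay,
        batchSize = config@batchSize, epochs = config@epochs,
        folds = config@folds, policy = cfgPolicy, model = config@model,
        preprocess = config@preprocess, seed = config@seed)
  }
  fpPolicy <- MissingPolicy(predictMode = "FP")
  mpPolicy <- MissingPolicy(predictMode = "MP",
                            missingSet = missingModality)
  cells <- list()
  for (tm in c("FT", "MT")) {
    fit <- trainModel(trainRec, mkConfig(tm))
    fp <- evaluateModel(fit$model, testRec, fpPolicy)
    mp <- .mpEval(fit$model, testRec, mpPolicy, noiseSeeds)
    cells[[paste0(tm, "FP")]] <- list(label = paste0(tm, "FP"),
                                      meanDice = .meanDice(fp), sdDice = 0,
                                      report = fp)
    cells[[paste0(tm, "MP")]] <- list(label = paste0(tm, "MP"),
                                      meanDice = mp$meanDice,
                                      sdDice = mp$sdDice,
                                      reports = mp$reports)
  }
  c(cells, list(split = split, task = task,
                missingModality = missingModality))
}

#' Summary table of a mode grid
#'
#' @param grid output of [modeGridEval()].
#' @return data.frame with one row per cell.
#' @export
modeGridTable <- function(grid) {
  cells <- c("FTFP", "FTMP", "MTFP", "MTMP")
  data.frame(task = grid$task, missingModality = grid$missingModality,
             mode = cells,
             meanDice = vapply(cells, function(c) grid[[c]]$meanDice, 1),
             sdDice = vapply(cells, function(c) grid[[c]]$sdDice, 1),
             row.names = NULL)
}

#' Sweep the keep probability lambda of missing-modality training
#'
#' One MT training per lambda on a shared split with shared seeds,
#' evaluated under FP and MP. With `lambda = 1` substitution never occurs,
#' so that row's training trajectory coincides with FT.
#'
#' @inheritParams modeGridEval
#' @param lambdas vector of keep probabilities in \[0, 1\].
#' @return data.frame with columns lambda, fpDice, mpDice, mpSd.
#' @export
lambdaSweep <- function(cohort, task, config, missingModality,
                        lambdas = c(0, 0.5, 1), holdout = 0.3,
                        noiseSeeds = 1:3) {
  stopifnot(all(lambdas >= 0 & lambdas <= 1))
  split <- .holdoutSplit(cohort, holdout, config@seed + 17)
  records <- buildSliceDataset(cohort, task, config@preprocess)
  trainRec <- Filter(function(r) r@subjectId %in% split$train, records)
  testRec <- Filter(function(r) r@subjectId %in% split$test, records)
  fpPolicy <- MissingPolicy(predictMode = "FP")
  mpPolicy <- MissingPolicy(predictMode = "MP",
                            missingSet = missingModality)
  rows <- lapply(lambdas, function(lam) {
    pol <- MissingPolicy(trainMode = "MT", predictMode = "FP",
                         lambda = lam, missingSet = missingModality,
                         seed = config@policy@seed)
    cfg <- new("TrainConfig", lr = config@lr,
               weightDecay = config@weightDecay,
               batchSize = config@batchSize, epochs = config@epochs,
               folds = config@folds, policy = pol, model = config@model,
               preprocess = config@preprocess, seed = config@seed)
    fit <- trainModel(trainRec, cfg)
    fp <- evaluateModel(fit$model, testRec, fpPolicy)
    mp <- .mpEval(fit$model, testRec, mpPolicy, noiseSeeds)
    data.frame(lambda = lam, fpDice = .meanDice(fp),
               mpDice = mp$meanDice, mpSd = mp$sdDice)
  })
  do.call(rbind, rows)
}

#' Embed fused features of a dataset under several policies
#'
#' For each mode (a named list of [MissingPolicy-class]) and each slice,
#' the fused feature map is spatially average-pooled to one vector; the
#' pooled vectors are projected to 2-D with UMAP. Deterministic given
#' `seed` (single-threaded embedding).
#'
#' @param model a trained [FusionModel-class].
#' @param records list of [SliceRecord-class] (>= 10 embedding rows
#'   required).
#' @param policies named list of [MissingPolicy-class]; default one FP
#'   mode.
#' @param seed embedding / noise seed.
#' @return data.frame with columns dim1, dim2, mode, subjectId, z,
#'   gtFraction.
#' @export
embedFusedFeatures <- function(model, records,
                               policies = list(FP = MissingPolicy()),
                               seed = 1L) {
  if (is.null(names(policies)) || any(names(policies) == ""))
    stop("policies must be a named list")
  feats <- list(); meta <- list()
  for (mode in names(policies)) {
    pol <- policies[[mode]]
    rng <- newRngStream(seed + match(mode, names(policies)))
    for (rec in records) {
      inputs <- applyInferenceSubstitution(rec, pol, rng)
      fs <- fusionState(model, inputs, bbox = rec@bbox)
      d <- dim(fs@fused)
      feats[[length(feats) + 1L]] <- colMeans(matrix(fs@fused,
                                                     d[1] * d[2], d[3]))
      meta[[length(meta) + 1L]] <- data.frame(
        mode = mode, subjectId = rec@subjectId, z = rec@zIndex,
        gtFraction = mean(rec@gtMask))
    }
  }
  X <- do.call(rbind, feats)
  if (nrow(X) < 10L)
    stop("need at least 10 samples for a stable embedding, got ", nrow(X))
  emb <- withSeed(seed, uwot::umap(
    X, n_neighbors = min(15, nrow(X) - 1), n_threads = 1,
    n_sgd_threads = 1, batch = TRUE))
  out <- cbind(data.frame(dim1 = emb[, 1], dim2 = emb[, 2]),
               do.call(rbind, meta))
  rownames(out) <- NULL
  out
}
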