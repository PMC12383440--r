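# Training loop (AdamW over the trainable parts only), evaluation, and
# subject-level cross-validation.

.adamwInit <- function(params, names) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

.adamwStep <- function(params, grads, st, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(st$m)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = st)
}

.trainableNames <- function(params, cfg) {
  nms <- setdiff(names(params), "foundation")
  nms[vapply(nms, function(n) .partOf(n) %in% cfg@trainableParts, TRUE)]
}

#' Train a fusion model
#'
#' Optimizes the combined Dice + BCE objective with AdamW over the
#' trainable parts only. Under an MT policy, [applyTrainingSubstitution()]
#' re-randomizes the designated modalities each iteration from the
#' policy's private RNG stream, so an MT run with `lambda = 1` (which
#' never substitutes) follows a trajectory bit-identical to FT. The run is
#' deterministic given `config@seed` and `config@policy@seed`.
#'
#' @param records nonempty list of [SliceRecord-class].
#' @param config a [TrainConfig-class].
#' @param model optional pre-initialized [FusionModel-class] (defaults to
#'   `newFusionModel(config@model, config@seed)`).
#' @param verbose print per-epoch mean loss.
#' @return list with `model` (trained), `lossCurve` (per-epoch mean total
#'   loss), `stepLosses`, and `substitutionLog` (data.frame of epoch,
#'   step, subjectId, z, modality for every substitution made).
#' @export
trainModel <- function(records, config, model = NULL, verbose = FALSE) {
  if (length(records) == 0L) stop("training dataset is empty")
  validObject(config)
  if (is.null(model)) model <- newFusionModel(config@model, config@seed)
  params <- model@params
  cfg <- model@config
  policy <- config@policy
  orderStream <- newRngStream(config@seed + 1)
  policyStream <- newRngStream(policy@seed)
  trainable <- .trainableNames(params, cfg)
  st <- .adamwInit(params, trainable)
  n <- length(records)
  bs <- as.integer(config@batchSize)
  lossCurve <- numeric(config@epochs)
  stepLosses <- numeric(0)
  subLog <- list()
  for (epoch in seq_len(config@epochs)) {
    ord <- withStream(orderStream, sample.int(n))
    epochLosses <- numeric(0)
    step <- 0L
    for (start in seq(1L, n, by = bs)) {
      step <- step + 1L
      batch <- ord[start:min(start + bs - 1L, n)]
      grads <- NULL
      batchLoss <- 0
      for (ri in batch) {
        rec <- records[[ri]]
        inputs <- rec@modalityImages
        if (policy@trainMode == "MT") {
          sub <- applyTrainingSubstitution(rec, policy, policyStream)
          inputs <- sub$images
          for (m in sub$substituted)
            subLog[[length(subLog) + 1L]] <- data.frame(
              epoch = epoch, step = step, subjectId = rec@subjectId,
              z = rec@zIndex, modality = m)
        }
        cache <- .forwardPass(params, cfg, inputs, rec@bbox)
        lg <- .lossGrad(cache$logits, rec@gtMask)
        batchLoss <- batchLoss + lg$total
        g <- .backwardPass(params, cfg, cache, lg$dLogits)
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g[names(grads)])
      }
      grads <- lapply(grads, function(x) x / length(batch))
      upd <- .adamwStep(params, grads, st, config@lr, config@weightDecay)
      params <- upd$params; st <- upd$state
      epochLosses <- c(epochLosses, batchLoss / length(batch))
    }
    lossCurve[epoch] <- mean(epochLosses)
    stepLosses <- c(stepLosses, epochLosses)
    if (verbose)
      message(sprintf("epoch %d/%d mean loss %.4f", epoch,
                      as.integer(config@epochs), lossCurve[epoch]))
  }
  model@params <- params
  list(model = model, lossCurve = lossCurve, stepLosses = stepLosses,
       substitutionLog = if (length(subLog)) do.call(rbind, subLog) else
         data.frame(epoch = integer(), step = integer(),
                    subjectId = character(), z = numeric(),
                    modality = character()))
}

#' Evaluate a model on a slice dataset
#'
#' Applies the policy's inference substitution (a no-op under FP), runs
#' the forward pass, thresholds logits at 0, and scores each slice with
#' Dice and HD95.
#'
#' @param model a trained [FusionModel-class].
#' @param records list of [SliceRecord-class].
#' @param policy a [MissingPolicy-class] (default FP: no substitution).
#' @param noiseSeed seed of the MP noise stream.
#' @param binWidth size-bin width for the report.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, records, policy = MissingPolicy(),
                          noiseSeed = policy@seed, binWidth = 500) {
  if (length(records) == 0L) stop("no records to evaluate")
  rng <- newRngStream(noiseSeed)
  rows <- lapply(records, function(rec) {
    inputs <- applyInferenceSubstitution(rec, policy, rng)
    pred <- (modelForward(model, inputs, bbox = rec@bbox) >= 0) + 0
    h <- hd95(rec@gtMask, pred, flag = TRUE)
    data.frame(subjectId = rec@subjectId, z = rec@zIndex, task = rec@task,
               gtSize = sum(rec@gtMask), dice = diceScore(rec@gtMask, pred),
               hd95 = h$value, hd95Flag = h$flagged)
  })
  evalReport(do.call(rbind, rows), binWidth)
}

#' Partition subjects into cross-validation folds
#'
#' @param subjectIds character vector of (unique) subject ids.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return list of `folds` disjoint character vectors covering all ids.
#' @export
makeFolds <- function(subjectIds, folds, seed = 1L) {
  subjectIds <- unique(subjectIds)
  if (length(subjectIds) < folds)
    stop("fewer subjects (", length(subjectIds), ") than folds (", folds, ")")
  ord <- withSeed(seed, sample(subjectIds))
  split(ord, rep_len(seq_len(folds), length(ord)))
}

#' Subject-level k-fold cross-validation
#'
#' Slices are built once per cohort; folds partition subjects, so no
#' subject's slices ever span a fold's train and test sets.
#'
#' @param cohort list of [ModalityStack-class].
#' @param task segmentation task.
#' @param config a [TrainConfig-class]; `config@folds` folds are used.
#' @return list with `folds` (per-fold: testSubjects, report, lossCurve),
#'   `pooled` (an [EvalReport-class] over all held-out rows) and
#'   `foldAssignment`.
#' @export
crossValidate <- function(cohort, task, config) {
  records <- buildSliceDataset(cohort, task, config@preprocess)
  ids <- vapply(cohort, subjectId, character(1))
  assignment <- makeFolds(ids, config@folds, config@seed)
  foldResults <- lapply(seq_along(assignment), function(k) {
    testIds <- assignment[[k]]
    trainRec <- Filter(function(r) !(r@subjectId %in% testIds), records)
    testRec <- Filter(function(r) r@subjectId %in% testIds, records)
    fit <- trainModel(trainRec, config)
    rep <- evaluateModel(fit$model, testRec, config@policy,
                         noiseSeed = config@policy@seed + k)
    list(testSubjects = testIds, report = rep, lossCurve = fit$lossCurve)
  })
  pooledRows <- do.call(rbind, lapply(foldResults,
                                      function(f) f$report@perSlice))
  list(folds = foldResults, pooled = evalReport(pooledRows),
       foldAssignment = assignment)
}
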