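# Objectives and evaluation metrics: soft Dice loss (squared
# denominators), binary cross-entropy, their sum; Dice score; percentile
# Hausdorff distance on 8-connectivity boundary pixels; size-stratified
# aggregation.

#' Soft Dice loss
#'
#' `1 - 2*sum(y*p) / (sum(y^2) + sum(p^2) + eps)` with predictions p in
#' \[0, 1\] and binary ground truth y. The squared denominator makes the
#' loss differentiable and equal to `1 - diceScore` on binary predictions
#' (as eps -> 0).
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param gt binary array of the same shape.
#' @param eps smoothing constant guarding 0/0 on empty masks.
#' @return loss in \[0, 1\].
#' @export
diceLoss <- function(pred, gt, eps = 1e-6) {
  stopifnot(length(pred) == length(gt))
  1 - 2 * sum(gt * pred) / (sum(gt^2) + sum(pred^2) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with predictions clamped to
#' `[eps, 1 - eps]`.
#'
#' @inheritParams diceLoss
#' @param eps clamping constant.
#' @export
bceLoss <- function(pred, gt, eps = 1e-7) {
  stopifnot(length(pred) == length(gt))
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

#' Combined segmentation objective
#'
#' @inheritParams diceLoss
#' @return list with `diceLoss`, `bceLoss` and `total` (their sum).
#' @export
totalLoss <- function(pred, gt, eps = 1e-6) {
  d <- diceLoss(pred, gt, eps)
  b <- bceLoss(pred, gt)
  list(diceLoss = d, bceLoss = b, total = d + b)
}

# total loss plus its gradient with respect to the logits, for training
.lossGrad <- function(logits, gt, eps = 1e-6, clampEps = 1e-7) {
  p <- sigmoid(logits)
  n <- length(p)
  pc <- pmin(pmax(p, clampEps), 1 - clampEps)
  bce <- -mean(gt * log(pc) + (1 - gt) * log(1 - pc))
  num <- 2 * sum(gt * p)
  den <- sum(gt^2) + sum(p^2) + eps
  dice <- 1 - num / den
  dBce_dp <- (pc - gt) / (pc * (1 - pc)) / n
  dBce_dp[p != pc] <- 0
  dDice_dp <- -(2 * gt) / den + (num * 2 * p) / den^2
  dLogits <- (dBce_dp + dDice_dp) * p * (1 - p)
  list(total = dice + bce, diceLoss = dice, bceLoss = bce,
       dLogits = dLogits)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|G intersect S| / (|G| + |S|)`; two empty masks score 1 by
#' convention.
#'
#' @param gt,pred binary arrays of the same shape.
#' @return Dice score in \[0, 1\].
#' @export
diceScore <- function(gt, pred) {
  stopifnot(length(gt) == length(pred))
  g <- sum(gt > 0); s <- sum(pred > 0)
  if (g + s == 0) return(1)
  2 * sum(gt > 0 & pred > 0) / (g + s)
}

# boundary pixels of a mask: positive pixels with at least one of their
# 8 neighbors (or the image edge) outside the mask; returns (row, col)
.boundaryPoints <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    interior <- interior & pad[2:(H + 1) + di, 2:(W + 1) + dj]
  }
  which(m & !interior, arr.ind = TRUE)
}

.percentileHd <- function(gt, pred, q) {
  dims <- dim(gt)
  gEmpty <- sum(gt > 0) == 0; sEmpty <- sum(pred > 0) == 0
  if (gEmpty && sEmpty) return(list(value = 0, flagged = FALSE))
  if (gEmpty || sEmpty)
    return(list(value = sqrt(sum((dims - 1)^2)), flagged = TRUE))
  G <- .boundaryPoints(gt); S <- .boundaryPoints(pred)
  dGS <- .minDistances(G + 0, S + 0)
  dSG <- .minDistances(S + 0, G + 0)
  v <- max(stats::quantile(dGS, q, names = FALSE, type = 7),
           stats::quantile(dSG, q, names = FALSE, type = 7))
  list(value = v, flagged = FALSE)
}

#' 95th-percentile Hausdorff distance between two binary masks
#'
#' Boundary point sets are the 8-connectivity boundaries of each mask.
#' Both directed distance lists (each ground-truth boundary pixel to its
#' nearest predicted boundary pixel, and vice versa) are reduced to their
#' 95th percentiles (linear interpolation); the reported value is the
#' larger of the two, in pixel units. If exactly one mask is empty the
#' image diagonal is returned as a finite worst-case penalty and the
#' result is flagged; two empty masks score 0.
#'
#' @param gt,pred binary matrices of the same shape.
#' @param flag if `TRUE`, return a list with `value` and `flagged` instead
#'   of the bare number.
#' @return HD95 in pixels (or a list when `flag = TRUE`).
#' @export
hd95 <- function(gt, pred, flag = FALSE) {
  r <- .percentileHd(gt, pred, 0.95)
  if (flag) r else r$value
}

#' Exact (maximum) Hausdorff distance
#'
#' The 100th-percentile variant of [hd95()]; same boundary extraction and
#' empty-mask conventions.
#'
#' @inheritParams hd95
#' @export
hausdorff <- function(gt, pred) .percentileHd(gt, pred, 1)$value

#' Size-stratified Dice aggregation
#'
#' Bins per-slice rows by ground-truth region size into
#' `[0, binWidth), [binWidth, 2 binWidth), ...` and reports per-bin counts
#' and mean Dice. Bins up to the largest occupied one are reported;
#' intermediate empty bins appear with `n = 0`.
#'
#' @param rows data.frame with columns `gtSize` and `dice`.
#' @param binWidth bin width in pixels (default 500).
#' @return data.frame with columns bin, lower, upper, n, meanDice.
#' @export
sizeStratified <- function(rows, binWidth = 500) {
  if (nrow(rows) == 0L) stop("rows is empty")
  if (any(rows$gtSize < 0)) stop("negative region sizes")
  idx <- floor(rows$gtSize / binWidth)
  nbins <- max(idx) + 1
  out <- data.frame(bin = seq_len(nbins),
                    lower = (seq_len(nbins) - 1) * binWidth,
                    upper = seq_len(nbins) * binWidth)
  out$n <- vapply(seq_len(nbins), function(b) sum(idx == b - 1), 1L)
  out$meanDice <- vapply(seq_len(nbins), function(b) {
    sel <- idx == b - 1
    if (any(sel)) mean(rows$dice[sel]) else NA_real_
  }, 1)
  out
}

#' Build an evaluation report from per-slice rows
#'
#' @param perSlice data.frame with columns subjectId, z, task, gtSize,
#'   dice, hd95, hd95Flag.
#' @param binWidth size-bin width in pixels.
#' @return an [EvalReport-class] with per-task aggregates (mean and sd of
#'   dice and hd95) and size bins recomputed from the rows.
#' @export
evalReport <- function(perSlice, binWidth = 500) {
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  aggregates <- do.call(rbind, lapply(split(perSlice, perSlice$task),
    function(g) data.frame(task = g$task[1], n = nrow(g),
                           meanDice = mean(g$dice), sdDice = sd0(g$dice),
                           meanHd95 = mean(g$hd95), sdHd95 = sd0(g$hd95))))
  rownames(aggregates) <- NULL
  new("EvalReport", perSlice = perSlice, aggregates = aggregates,
      sizeBins = sizeStratified(perSlice, binWidth), binWidth = binWidth)
}

#' Write an evaluation report to disk
#'
#' Per-slice rows as CSV plus aggregates and size bins as JSON.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @export
writeEvalReport <- function(report, dir, prefix = "eval") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@perSlice,
                   file.path(dir, paste0(prefix, "_per_slice.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregates = report@aggregates, sizeBins = report@sizeBins),
    file.path(dir, paste0(prefix, "_aggregates.json")),
    dataframe = "rows", digits = NA)
  invisible(report)
}
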