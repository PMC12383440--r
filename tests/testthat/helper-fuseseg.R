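# Shared fixtures (built in code) and independent brute-force oracles.

tinySpec <- function(seed = 11, ...) {
  PhantomSpec(seed = seed, ...)  # 24x32x32, radii 10/6/3
}

tinyPreprocess <- function(size = 32, seed = 5, ...) {
  PreprocessConfig(modelSize = size, seed = seed, ...)
}

tinyModelConfig <- function(size = 32, ...) {
  ModelConfig(nModalities = 4, encoderChannels = 4, seReduction = 4,
              decoderChannels = 16, inputSize = size, ...)
}

tinyTrainConfig <- function(epochs = 4, size = 32, seed = 1,
                            policy = MissingPolicy(seed = 7), ...) {
  TrainConfig(lr = 1e-3, epochs = epochs, batchSize = 8,
              model = tinyModelConfig(size), policy = policy,
              preprocess = tinyPreprocess(size), seed = seed, ...)
}

# minimal synthetic SliceRecord, bright disc on dark background
makeTestRecord <- function(S = 16, nModalities = 4, seed = 1) {
  withr::with_seed(seed, {
    ctr <- (S + 1) / 2
    d <- sqrt(outer((1:S - ctr)^2, (1:S - ctr)^2, `+`))
    mask <- (d <= S / 4) + 0
    imgs <- lapply(seq_len(nModalities), function(m) {
      img <- 0.2 + 0.5 * mask + matrix(rnorm(S * S, sd = 0.02), S, S)
      array(pmin(pmax(img, 0), 1), c(S, S, 3))
    })
    names(imgs) <- paste0("mod", seq_len(nModalities))
    new("SliceRecord", subjectId = "tst-001", zIndex = 1, task = "WT",
        modalityImages = imgs, gtMask = mask,
        bbox = as.numeric(tightBbox(mask)),
        modalityNames = names(imgs))
  })
}

# cache expensive shared fixtures across test files (same R session)
.fusesegTestCache <- new.env(parent = emptyenv())

cachedCohort <- function(n = 12, seed = 11) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fusesegTestCache[[key]]))
    .fusesegTestCache[[key]] <- generateCohort(tinySpec(seed), n)
  .fusesegTestCache[[key]]
}

cachedDataset <- function(task = "WT", n = 12, seed = 11) {
  key <- sprintf("data_%s_%d_%d", task, n, seed)
  if (is.null(.fusesegTestCache[[key]]))
    .fusesegTestCache[[key]] <-
      buildSliceDataset(cachedCohort(n, seed), task, tinyPreprocess())
  .fusesegTestCache[[key]]
}

# one small trained WT model shared by several tests (held-out subjects
# sub-001..sub-003 never seen in training)
cachedTrainedFit <- function() {
  if (is.null(.fusesegTestCache$fit)) {
    recs <- cachedDataset("WT")
    trainRec <- Filter(function(r)
      !(r@subjectId %in% c("sub-001", "sub-002", "sub-003")), recs)
    .fusesegTestCache$fit <- trainModel(trainRec, tinyTrainConfig())
  }
  .fusesegTestCache$fit
}

heldOutRecords <- function(task = "WT") {
  Filter(function(r) r@subjectId %in% c("sub-001", "sub-002", "sub-003"),
         cachedDataset(task))
}

# ---- independent oracles -------------------------------------------------

# sort-based linear-interpolation percentile (independent of quantile())
oraclePercentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# triple-loop global average pooling
oracleGap <- function(concat) {
  d <- dim(concat)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    acc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      acc <- acc + concat[i, j, k]
    out[k] <- acc / (d[1] * d[2])
  }
  out
}

# loop-based two-layer bottleneck
oracleExcite <- function(z, W1, b1, W2, b2) {
  a <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1))) {
    acc <- b1[i]
    for (j in seq_along(z)) acc <- acc + W1[i, j] * z[j]
    a[i] <- max(acc, 0)
  }
  s <- numeric(nrow(W2))
  for (i in seq_len(nrow(W2))) {
    acc <- b2[i]
    for (j in seq_along(a)) acc <- acc + W2[i, j] * a[j]
    s[i] <- 1 / (1 + exp(-acc))
  }
  s
}

# per-pixel BCE loop
oracleBce <- function(pred, gt, eps = 1e-7) {
  acc <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    acc <- acc - (gt[i] * log(p) + (1 - gt[i]) * log(1 - p))
  }
  acc / length(pred)
}

# set-counting Dice
oracleDice <- function(gt, pred) {
  G <- which(gt > 0); S <- which(pred > 0)
  if (length(G) + length(S) == 0) return(1)
  2 * length(intersect(G, S)) / (length(G) + length(S))
}

# explicit-loop 8-connectivity boundary (out-of-image = background)
oracleBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] <= 0) next
    isBoundary <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || mask[ii, jj] <= 0)
        isBoundary <- TRUE
    }
    if (isBoundary) pts <- rbind(pts, c(i, j))
  }
  pts
}

# O(|G||S|) all-pairs HD at percentile q
oracleHd <- function(gt, pred, q = 0.95) {
  gEmpty <- sum(gt > 0) == 0; sEmpty <- sum(pred > 0) == 0
  if (gEmpty && sEmpty) return(0)
  if (gEmpty || sEmpty) return(sqrt(sum((dim(gt) - 1)^2)))
  G <- oracleBoundary(gt); S <- oracleBoundary(pred)
  D <- matrix(0, nrow(G), nrow(S))
  for (a in seq_len(nrow(G))) for (b in seq_len(nrow(S)))
    D[a, b] <- sqrt(sum((G[a, ] - S[b, ])^2))
  dGS <- apply(D, 1, min); dSG <- apply(D, 2, min)
  max(oraclePercentile(dGS, q), oraclePercentile(dSG, q))
}

randomMask <- function(H, W, pFill = 0.3) {
  matrix(rbinom(H * W, 1, pFill), H, W)
}
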