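# The fusion segmentation network (light mode), written directly on top
# of the package's conv kernels with hand-derived backward passes.
#
# Architecture (light_trainable), for input size S and N modalities:
#   encoder (shared weights, applied per modality):
#     conv 3x3 stride 2 (3 -> C1), ReLU              -> (S/2, S/2, C1)
#   feature fusion block:
#     concat along channels                          -> (h, w, C2=N*C1)
#     squeeze: global average pooling                -> z in R^C2
#     excite: s = sigmoid(W2 relu(W1 z + b1) + b2)   -> s in (0,1)^C2
#     modulate: s (x) concat, residual add concat,
#     1x1 projection (C2 -> Cd)                      -> fused (h, w, Cd)
#   prompt: learned linear embedding of the normalized box corners,
#     broadcast-added to the fused map
#   decoder head:
#     ReLU, conv 3x3 (Cd -> Cd), ReLU,
#     nearest x2 upsample, conv 3x3 (Cd -> Cd), ReLU,
#     conv 1x1 (Cd -> 1)                             -> logits (S, S)
# Predicted mask: logits >= 0 (sigmoid 0.5; ties count as foreground).

.convW <- function(kh, kw, cin, cout) {
  matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
         kh * kw * cin, cout)
}

.partOf <- function(name) {
  if (startsWith(name, "enc")) "encoder"
  else if (startsWith(name, "ffb") || startsWith(name, "proj")) "ffb"
  else "decoder"
}

#' Initialize a fusion segmentation model
#'
#' He-normal initialization, deterministic given `seed`. For
#' `encoderKind = "foundation_frozen"` the external encoder checkpoint at
#' `config@foundationPath` is loaded (an RDS file providing an `encode`
#' closure and its `channels`); an actionable error names the path if it
#' is absent.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for parameter initialization.
#' @return a [FusionModel-class].
#' @export
newFusionModel <- function(config = ModelConfig(), seed = 1L) {
  validObject(config)
  C1 <- config@encoderChannels
  C2 <- fusedChannels(config)
  Cd <- config@decoderChannels
  bneck <- max(1L, floor(C2 / config@seReduction))
  foundation <- NULL
  if (config@encoderKind == "foundation_frozen") {
    p <- config@foundationPath
    if (length(p) != 1L || !file.exists(p))
      stop("foundation encoder weights not found at '",
           if (length(p)) p else "<unset>",
           "'; set ModelConfig(foundationPath=) to a checkpoint RDS ",
           "providing an encode() closure, or use encoderKind = ",
           "'light_trainable'")
    foundation <- readRDS(p)
  }
  params <- withSeed(seed, list(
    enc_W = .convW(3, 3, 3, C1), enc_b = numeric(C1),
    ffb_W1 = matrix(stats::rnorm(bneck * C2, sd = sqrt(2 / C2)), bneck, C2),
    ffb_b1 = numeric(bneck),
    ffb_W2 = matrix(stats::rnorm(C2 * bneck, sd = sqrt(2 / bneck)), C2, bneck),
    ffb_b2 = numeric(C2),
    proj_W = .convW(1, 1, C2, Cd), proj_b = numeric(Cd),
    prompt_W = matrix(stats::rnorm(Cd * 4, sd = 0.5), Cd, 4),
    prompt_b = numeric(Cd),
    dec1_W = .convW(3, 3, Cd, Cd), dec1_b = numeric(Cd),
    dec2_W = .convW(3, 3, Cd, Cd), dec2_b = numeric(Cd),
    out_W = .convW(1, 1, Cd, 1), out_b = numeric(1)))
  if (!is.null(foundation)) params$foundation <- foundation
  new("FusionModel", config = config, params = params)
}

.upsample2x <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

.downsampleGrad2x <- function(g) {
  d <- dim(g)
  i <- seq(1L, d[1], by = 2L); j <- seq(1L, d[2], by = 2L)
  g[i, j, , drop = FALSE] + g[i + 1L, j, , drop = FALSE] +
    g[i, j + 1L, , drop = FALSE] + g[i + 1L, j + 1L, , drop = FALSE]
}

#' Encode each modality with the shared encoder
#'
#' @param model a [FusionModel-class].
#' @param inputs list of N (S, S, 3) model-ready images.
#' @return list of N (S/2, S/2, C1) feature arrays.
#' @export
encodeModalities <- function(model, inputs) {
  cfg <- model@config
  if (length(inputs) != cfg@nModalities)
    stop("expected ", cfg@nModalities, " modalities, got ", length(inputs))
  if (cfg@encoderKind == "foundation_frozen")
    return(lapply(inputs, model@params$foundation$encode))
  lapply(inputs, function(x) {
    pre <- .conv2dFwd(x, model@params$enc_W, model@params$enc_b, 3L, 3L, 2L, 1L)
    pre * (pre > 0)
  })
}

#' Squeeze step of the feature fusion block (global average pooling)
#'
#' @param concat (h, w, C2) concatenated feature array.
#' @return C2-vector of per-channel spatial means.
#' @export
ffbSqueeze <- function(concat) {
  d <- dim(concat)
  colMeans(matrix(concat, d[1] * d[2], d[3]))
}

#' Excitation step: two-layer bottleneck with ReLU then sigmoid
#'
#' @param z C2-vector from [ffbSqueeze()].
#' @param params list with `ffb_W1`, `ffb_b1`, `ffb_W2`, `ffb_b2` (a
#'   [FusionModel-class] may be passed instead).
#' @return C2-vector of attention weights, each strictly in (0, 1).
#' @export
ffbExcite <- function(z, params) {
  if (is(params, "FusionModel")) params <- params@params
  if (ncol(params$ffb_W1) != length(z))
    stop("dimension mismatch: W1 expects length-", ncol(params$ffb_W1),
         " input, got ", length(z))
  a <- pmax(as.vector(params$ffb_W1 %*% z) + params$ffb_b1, 0)
  sigmoid(as.vector(params$ffb_W2 %*% a) + params$ffb_b2)
}

#' Channel-wise modulation by attention weights
#'
#' @param concat (h, w, C2) feature array.
#' @param s C2-vector of channel weights.
#' @return array of the same shape with channel k scaled by `s[k]`.
#' @export
ffbApply <- function(concat, s) {
  d <- dim(concat)
  if (length(s) != d[3]) stop("length(s) must equal the channel count")
  concat * rep(s, each = d[1] * d[2])
}

#' Residual fusion: add the identity path and project to decoder width
#'
#' @param modulated,concat (h, w, C2) arrays (modulated + concat is the
#'   residual pre-projection input).
#' @param params list with `proj_W`, `proj_b` (or a [FusionModel-class]).
#' @return (h, w, decoderChannels) fused feature array.
#' @export
ffbFuse <- function(modulated, concat, params) {
  if (is(params, "FusionModel")) params <- params@params
  .conv2dFwd(modulated + concat, params$proj_W, params$proj_b, 1L, 1L, 1L, 0L)
}

.normBbox <- function(bbox, size) as.numeric(bbox) / (size - 1)

# Full forward pass, returning logits plus every intermediate needed by
# .backwardPass. inputs: list of N (S,S,3) arrays; bbox: length-4 pixel box.
.forwardPass <- function(params, cfg, inputs, bbox) {
  S <- as.integer(cfg@inputSize)
  hw <- (S / 2L)^2
  encPre <- feats <- vector("list", length(inputs))
  for (m in seq_along(inputs)) {
    if (cfg@encoderKind == "foundation_frozen") {
      feats[[m]] <- encPre[[m]] <- params$foundation$encode(inputs[[m]])
    } else {
      encPre[[m]] <- .conv2dFwd(inputs[[m]], params$enc_W, params$enc_b,
                                3L, 3L, 2L, 1L)
      feats[[m]] <- encPre[[m]] * (encPre[[m]] > 0)
    }
  }
  C2 <- length(feats) * dim(feats[[1]])[3]
  concat <- array(unlist(feats, use.names = FALSE),
                  c(dim(feats[[1]])[1:2], C2))
  z <- ffbSqueeze(concat)
  aPre <- as.vector(params$ffb_W1 %*% z) + params$ffb_b1
  a <- pmax(aPre, 0)
  sPre <- as.vector(params$ffb_W2 %*% a) + params$ffb_b2
  s <- sigmoid(sPre)
  modulated <- ffbApply(concat, s)
  resid <- modulated + concat
  fused <- .conv2dFwd(resid, params$proj_W, params$proj_b, 1L, 1L, 1L, 0L)
  bnorm <- .normBbox(bbox, S)
  prompt <- as.vector(params$prompt_W %*% bnorm) + params$prompt_b
  d0Pre <- fused + rep(prompt, each = hw)
  d0 <- d0Pre * (d0Pre > 0)
  d1Pre <- .conv2dFwd(d0, params$dec1_W, params$dec1_b, 3L, 3L, 1L, 1L)
  d1 <- d1Pre * (d1Pre > 0)
  up <- .upsample2x(d1)
  d2Pre <- .conv2dFwd(up, params$dec2_W, params$dec2_b, 3L, 3L, 1L, 1L)
  d2 <- d2Pre * (d2Pre > 0)
  logits <- .conv2dFwd(d2, params$out_W, params$out_b, 1L, 1L, 1L, 0L)[, , 1]
  list(logits = logits, inputs = inputs, encPre = encPre, concat = concat,
       z = z, aPre = aPre, a = a, s = s, modulated = modulated,
       resid = resid, fused = fused, bnorm = bnorm, d0Pre = d0Pre, d0 = d0,
       d1Pre = d1Pre, d1 = d1, up = up, d2Pre = d2Pre, d2 = d2)
}

# Backward pass; dLogits is an (S, S) matrix. Returns gradients for every
# parameter (the caller masks frozen parts). Frozen/foundation encoders
# skip the encoder gradient.
.backwardPass <- function(params, cfg, cache, dLogits) {
  d <- dim(cache$d2)
  g <- list()
  bw <- .conv2dBwd(cache$d2, params$out_W, array(dLogits, c(d[1], d[2], 1L)),
                   1L, 1L, 1L, 0L)
  g$out_W <- bw$dW; g$out_b <- bw$db
  dd2 <- bw$dX * (cache$d2Pre > 0)
  bw <- .conv2dBwd(cache$up, params$dec2_W, dd2, 3L, 3L, 1L, 1L)
  g$dec2_W <- bw$dW; g$dec2_b <- bw$db
  dd1 <- .downsampleGrad2x(bw$dX) * (cache$d1Pre > 0)
  bw <- .conv2dBwd(cache$d0, params$dec1_W, dd1, 3L, 3L, 1L, 1L)
  g$dec1_W <- bw$dW; g$dec1_b <- bw$db
  dd0 <- bw$dX * (cache$d0Pre > 0)
  hw <- prod(dim(dd0)[1:2])
  dPrompt <- colSums(matrix(dd0, hw, dim(dd0)[3]))
  g$prompt_W <- dPrompt %o% cache$bnorm
  g$prompt_b <- dPrompt
  bw <- .conv2dBwd(cache$resid, params$proj_W, dd0, 1L, 1L, 1L, 0L)
  g$proj_W <- bw$dW; g$proj_b <- bw$db
  dResid <- bw$dX
  C2 <- dim(cache$concat)[3]
  hwc <- prod(dim(cache$concat)[1:2])
  dModM <- matrix(dResid, hwc, C2)
  concatM <- matrix(cache$concat, hwc, C2)
  ds <- colSums(dModM * concatM)
  dsPre <- ds * cache$s * (1 - cache$s)
  g$ffb_W2 <- dsPre %o% cache$a
  g$ffb_b2 <- dsPre
  da <- as.vector(crossprod(params$ffb_W2, dsPre)) * (cache$aPre > 0)
  g$ffb_W1 <- da %o% cache$z
  g$ffb_b1 <- da
  dz <- as.vector(crossprod(params$ffb_W1, da))
  dConcatM <- dModM * rep(cache$s, each = hwc) + dModM +
    matrix(rep(dz / hwc, each = hwc), hwc, C2)
  dConcat <- array(dConcatM, dim(cache$concat))
  if (cfg@encoderKind == "light_trainable") {
    C1 <- cfg@encoderChannels
    g$enc_W <- 0 * params$enc_W; g$enc_b <- numeric(length(params$enc_b))
    for (m in seq_along(cache$inputs)) {
      ch <- ((m - 1) * C1 + 1):(m * C1)
      dF <- dConcat[, , ch, drop = FALSE] * (cache$encPre[[m]] > 0)
      bw <- .conv2dBwd(cache$inputs[[m]], params$enc_W, dF, 3L, 3L, 2L, 1L)
      g$enc_W <- g$enc_W + bw$dW; g$enc_b <- g$enc_b + bw$db
    }
  }
  g
}

# gather model-ready inputs for one record, in modality order
.recordInputs <- function(record) record@modalityImages

#' Forward pass on one slice record
#'
#' @param model a [FusionModel-class].
#' @param record a [SliceRecord-class] (or a list of model-ready images,
#'   with `bbox` supplied).
#' @param bbox optional pixel bounding box overriding the record's.
#' @return (S, S) matrix of real-valued logits; the predicted mask is
#'   `logits >= 0`.
#' @export
modelForward <- function(model, record, bbox = NULL) {
  inputs <- if (is(record, "SliceRecord")) .recordInputs(record) else record
  if (is.null(bbox))
    bbox <- if (is(record, "SliceRecord")) record@bbox else
      stop("bbox required when record is a plain image list")
  S <- dim(inputs[[1]])[1]
  if (S != model@config@inputSize)
    stop("input resolution ", S, " does not match model inputSize ",
         model@config@inputSize)
  .forwardPass(model@params, model@config, inputs, bbox)$logits
}

#' Predicted binary mask for one record
#'
#' @inheritParams modelForward
#' @return (S, S) binary matrix (`logits >= 0`).
#' @export
predictMask <- function(model, record, bbox = NULL) {
  (modelForward(model, record, bbox) >= 0) + 0
}

#' Fusion-block state for one record
#'
#' Runs the forward pass and captures the fusion intermediates for
#' inspection or embedding.
#'
#' @inheritParams modelForward
#' @return a [FusionState-class].
#' @export
fusionState <- function(model, record, bbox = NULL) {
  inputs <- if (is(record, "SliceRecord")) .recordInputs(record) else record
  if (is.null(bbox)) bbox <- record@bbox
  cache <- .forwardPass(model@params, model@config, inputs, bbox)
  new("FusionState", concat = cache$concat, squeeze = cache$z,
      weights = cache$s, modulated = cache$modulated, fused = cache$fused)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration alongside the parameters.
#'
#' @param model a [FusionModel-class].
#' @param path file path.
#' @return `loadModel` returns the restored [FusionModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("FusionModel", config = x$config, params = x$params)
}
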