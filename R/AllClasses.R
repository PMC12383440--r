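#' @import methods
NULL

# ---------------------------------------------------------------------------
# PhantomSpec
# ---------------------------------------------------------------------------

#' Specification of a synthetic multi-modal phantom subject
#'
#' A `PhantomSpec` describes the geometry and contrast of a synthetic
#' multi-modal subject: three nested regions (whole-tumor, core and
#' enhancing analogs, modelled as smoothly deformed spheres) embedded in a
#' background, with a per-modality contrast profile and additive Gaussian
#' noise. The default contrast matrix gives one FLAIR-like modality that
#' lights up the whole region and one T1gd-like modality that dominates the
#' core/enhancing regions, so that modality-specific importance (and hence
#' missing-modality robustness) can be probed on phantoms.
#'
#' @slot nModalities number of modalities.
#' @slot volumeShape integer (D, H, W) voxel dimensions.
#' @slot regionRadii numeric (r_whole, r_core, r_enh), strictly decreasing.
#' @slot contrastMatrix nModalities x 3 matrix in \[0, 1\]; column k is the
#'   signal each modality adds inside the whole/core/enhancing region.
#' @slot backgroundLevel baseline intensity in \[0, 1\].
#' @slot noiseSd standard deviation of additive Gaussian noise.
#' @slot deformAmplitude amplitude (voxels) of the smooth radial boundary
#'   perturbation; capped at 25% of the smallest radius gap so nesting is
#'   preserved.
#' @slot modalityNames modality labels.
#' @slot seed integer seed fixing the subject (and cohort) byte-for-byte.
#' @export
setClass("PhantomSpec", representation(
  nModalities = "numeric", volumeShape = "numeric", regionRadii = "numeric",
  contrastMatrix = "matrix", backgroundLevel = "numeric", noiseSd = "numeric",
  deformAmplitude = "numeric", modalityNames = "character", seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  r <- object@regionRadii
  if (length(r) != 3L || any(diff(r) >= 0) || r[3] <= 0)
    msg <- c(msg, "regionRadii must be 3 strictly decreasing positive values")
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 2))
    msg <- c(msg, "volumeShape must be 3 dimensions >= 2")
  half <- (object@volumeShape - 1) / 2
  if (length(r) == 3L && r[1] + object@deformAmplitude > min(half))
    msg <- c(msg, "whole-region radius (plus deformation) exceeds volume bounds")
  if (any(object@contrastMatrix < 0) || any(object@contrastMatrix > 1))
    msg <- c(msg, "contrast values must lie in [0, 1]")
  if (nrow(object@contrastMatrix) != object@nModalities ||
      ncol(object@contrastMatrix) != 3L)
    msg <- c(msg, "contrastMatrix must be nModalities x 3")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(r) == 3L) {
    gap <- min(r[1] - r[2], r[2] - r[3])
    if (object@deformAmplitude > 0.25 * gap + 1e-12)
      msg <- c(msg, sprintf(
        "deformAmplitude must be <= 25%% of the smallest radius gap (%.3f)",
        0.25 * gap))
  }
  if (object@deformAmplitude < 0) msg <- c(msg, "deformAmplitude must be >= 0")
  if (length(object@modalityNames) != object@nModalities)
    msg <- c(msg, "modalityNames length must equal nModalities")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomSpec-class Constructor with desk-scale defaults.
#' @param nModalities,volumeShape,regionRadii,contrastMatrix,backgroundLevel,noiseSd,deformAmplitude,modalityNames,seed
#'   see the corresponding slots.
#' @export
PhantomSpec <- function(nModalities = 4L,
                        volumeShape = c(24L, 32L, 32L),
                        regionRadii = c(10, 6, 3),
                        contrastMatrix = NULL,
                        backgroundLevel = 0.15,
                        noiseSd = 0.02,
                        deformAmplitude = 0.6,
                        modalityNames = NULL,
                        seed = 1L) {
  if (is.null(modalityNames))
    modalityNames <- if (nModalities == 4L) c("T1", "T1gd", "T2", "FLAIR")
                     else sprintf("mod%02d", seq_len(nModalities))
  if (is.null(contrastMatrix)) {
    contrastMatrix <- if (nModalities == 4L)
      # rows: T1, T1gd, T2, FLAIR; cols: whole, core, enhancing
      matrix(c(0.10, 0.15, 0.05,
               0.05, 0.35, 0.35,
               0.30, 0.10, 0.05,
               0.55, 0.05, 0.00), nrow = 4, byrow = TRUE)
    else matrix(0.3, nModalities, 3)
  }
  dimnames(contrastMatrix) <- list(modalityNames, c("whole", "core", "enh"))
  new("PhantomSpec", nModalities = as.numeric(nModalities),
      volumeShape = as.numeric(volumeShape), regionRadii = regionRadii,
      contrastMatrix = contrastMatrix, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, deformAmplitude = deformAmplitude,
      modalityNames = modalityNames, seed = as.numeric(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nModalities, "modalities (",
      paste(object@modalityNames, collapse = ", "), ")\n")
  cat("  volume", paste(object@volumeShape, collapse = "x"),
      " radii", paste(object@regionRadii, collapse = "/"),
      " noise sd", object@noiseSd,
      " deform", object@deformAmplitude, "\n")
})

# ---------------------------------------------------------------------------
# ModalityStack
# ---------------------------------------------------------------------------

#' Aligned multi-modal volumes plus labels for one subject
#'
#' Label codes follow the concentric tumor convention: 0 background,
#' 1 necrotic-core analog, 2 edema analog, 3 enhancing analog.
#'
#' @slot subjectId subject identifier.
#' @slot images list of (D, H, W) arrays, one per modality, nonnegative.
#' @slot labels (D, H, W) integer array with codes in \{0, 1, 2, 3\}.
#' @slot modalityNames modality labels, parallel to `images`.
#' @export
setClass("ModalityStack", representation(
  subjectId = "character", images = "list", labels = "array",
  modalityNames = "character"))

setValidity("ModalityStack", function(object) {
  msg <- character()
  dims <- dim(object@labels)
  if (length(dims) != 3L) msg <- c(msg, "labels must be a 3-D array")
  for (img in object@images) {
    if (!identical(dim(img), dims))
      msg <- c(msg, "all volumes must share one shape")
    if (any(img < 0)) msg <- c(msg, "image intensities must be nonnegative")
  }
  codes <- unique(as.vector(object@labels))
  if (!all(codes %in% 0:3))
    msg <- c(msg, paste("label codes must lie in {0,1,2,3}; found",
                        paste(setdiff(codes, 0:3), collapse = ",")))
  if (length(object@images) != length(object@modalityNames))
    msg <- c(msg, "one modality name per image")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModalityStack", function(object) {
  cat("ModalityStack", object@subjectId, ":",
      length(object@images), "modalities,",
      paste(dim(object@labels), collapse = "x"), "voxels;",
      sum(object@labels > 0), "tumor voxels\n")
})

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "ModalityStack", function(x) x@subjectId)
#' @rdname accessors
#' @export
setGeneric("modalityNames", function(x) standardGeneric("modalityNames"))
#' @rdname accessors
#' @export
setMethod("modalityNames", "ModalityStack", function(x) x@modalityNames)
#' @rdname accessors
#' @export
setGeneric("modalityImages", function(x) standardGeneric("modalityImages"))
#' @rdname accessors
#' @export
setMethod("modalityImages", "ModalityStack", function(x) x@images)
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setMethod("labelVolume", "ModalityStack", function(x) x@labels)

# ---------------------------------------------------------------------------
# PreprocessConfig
# ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' Controls the volume-to-slice pipeline: percentile gray-level adjustment
#' (intensities outside the \[lowPct, highPct\] percentile band are clamped
#' to the band edges, then the band is mapped linearly to \[0, grayMax\]),
#' resizing to the square model resolution, and the outward random jitter
#' applied to bounding-box prompts.
#'
#' @slot lowPct,highPct percentile band bounds (defaults 0.5 and 99.5).
#' @slot grayMax upper bound of the rescaled intensity range (default 255).
#' @slot modelSize square model input resolution in pixels (default 1024).
#' @slot bboxJitterMax maximum outward jitter per box side in pixels
#'   (default 20).
#' @slot seed seed for the jitter stream.
#' @export
setClass("PreprocessConfig", representation(
  lowPct = "numeric", highPct = "numeric", grayMax = "numeric",
  modelSize = "numeric", bboxJitterMax = "numeric", seed = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (!(object@lowPct >= 0 && object@lowPct < object@highPct &&
        object@highPct <= 100))
    msg <- c(msg, "need 0 <= lowPct < highPct <= 100")
  if (object@modelSize <= 0) msg <- c(msg, "modelSize must be positive")
  if (object@bboxJitterMax < 0) msg <- c(msg, "bboxJitterMax must be >= 0")
  if (object@grayMax <= 0) msg <- c(msg, "grayMax must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn PreprocessConfig-class Constructor.
#' @param lowPct,highPct,grayMax,modelSize,bboxJitterMax,seed see slots.
#' @export
PreprocessConfig <- function(lowPct = 0.5, highPct = 99.5, grayMax = 255,
                             modelSize = 1024L, bboxJitterMax = 20L,
                             seed = 1L) {
  new("PreprocessConfig", lowPct = lowPct, highPct = highPct,
      grayMax = grayMax, modelSize = as.numeric(modelSize),
      bboxJitterMax = as.numeric(bboxJitterMax), seed = as.numeric(seed))
}

# ---------------------------------------------------------------------------
# SliceRecord
# ---------------------------------------------------------------------------

#' One 2-D training/evaluation sample
#'
#' Holds the per-modality model-ready images of one tumor-containing axial
#' slice (each resized to the model resolution, scaled to \[0, 1\] and
#' replicated to 3 identical channels), the binary task mask, and the
#' jittered bounding-box prompt. The bbox is (x0, y0, x1, y1), 0-based with
#' inclusive corners and x = column; it always contains the tight box of
#' the mask.
#'
#' @slot subjectId subject identifier (used for leakage-safe splits).
#' @slot zIndex 1-based axial slice index in the source volume.
#' @slot task one of "WT", "TC", "ET".
#' @slot modalityImages list of (S, S, 3) arrays in \[0, 1\].
#' @slot gtMask (S, S) binary matrix, nonempty.
#' @slot bbox integer (x0, y0, x1, y1).
#' @slot modalityNames modality labels.
#' @export
setClass("SliceRecord", representation(
  subjectId = "character", zIndex = "numeric", task = "character",
  modalityImages = "list", gtMask = "matrix", bbox = "numeric",
  modalityNames = "character"))

setValidity("SliceRecord", function(object) {
  msg <- character()
  S <- nrow(object@gtMask)
  if (ncol(object@gtMask) != S) msg <- c(msg, "gtMask must be square")
  for (img in object@modalityImages) {
    if (!identical(dim(img), c(S, S, 3L)))
      msg <- c(msg, "modality images must be (S, S, 3)")
    if (any(img < -1e-9) || any(img > 1 + 1e-9))
      msg <- c(msg, "pixel values must lie in [0, 1]")
  }
  if (sum(object@gtMask) < 1) msg <- c(msg, "gtMask must be nonempty")
  if (!object@task %in% c("WT", "TC", "ET"))
    msg <- c(msg, "task must be WT, TC or ET")
  b <- object@bbox
  if (length(b) != 4L || any(b < 0) || b[3] > S - 1 || b[4] > S - 1 ||
      b[1] > b[3] || b[2] > b[4])
    msg <- c(msg, "bbox out of bounds or degenerate")
  if (sum(object@gtMask) >= 1 && length(b) == 4L) {
    tb <- tightBbox(object@gtMask)
    if (!(b[1] <= tb[1] && b[2] <= tb[2] && b[3] >= tb[3] && b[4] >= tb[4]))
      msg <- c(msg, "bbox must contain the tight bounding box of gtMask")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SliceRecord", function(object) {
  cat(sprintf("SliceRecord %s z=%d task=%s %dpx mask, bbox (%s)\n",
              object@subjectId, as.integer(object@zIndex), object@task,
              as.integer(sum(object@gtMask)),
              paste(as.integer(object@bbox), collapse = ",")))
})

#' @rdname accessors
#' @export
setMethod("subjectId", "SliceRecord", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("modalityNames", "SliceRecord", function(x) x@modalityNames)
#' @rdname accessors
#' @export
setMethod("modalityImages", "SliceRecord", function(x) x@modalityImages)
#' @rdname accessors
#' @export
setGeneric("gtMask", function(x) standardGeneric("gtMask"))
#' @rdname accessors
#' @export
setMethod("gtMask", "SliceRecord", function(x) x@gtMask)
#' @rdname accessors
#' @export
setGeneric("bboxPrompt", function(x) standardGeneric("bboxPrompt"))
#' @rdname accessors
#' @export
setMethod("bboxPrompt", "SliceRecord", function(x) x@bbox)

# ---------------------------------------------------------------------------
# MissingPolicy
# ---------------------------------------------------------------------------

#' Missing-modality training/prediction policy
#'
#' Under Missing-Modality Training (MT), each designated modality of each
#' sample is kept with probability `lambda` per iteration and otherwise
#' replaced by a fresh image whose pixels are i.i.d. Uniform(0, 1) — the
#' same scale as the preprocessed inputs. Full-Modality Training (FT)
#' ignores `lambda` and never substitutes. At prediction time, Missing
#' Modality Prediction (MP) replaces every designated modality with such
#' noise; Full Modality Prediction (FP) leaves inputs untouched.
#'
#' @slot trainMode "FT" or "MT".
#' @slot predictMode "FP" or "MP".
#' @slot lambda probability of keeping the real modality per training draw.
#' @slot missingSet modality names designated as potentially missing.
#' @slot seed seed of the policy's private noise stream.
#' @export
setClass("MissingPolicy", representation(
  trainMode = "character", predictMode = "character", lambda = "numeric",
  missingSet = "character", seed = "numeric"))

setValidity("MissingPolicy", function(object) {
  msg <- character()
  if (!object@trainMode %in% c("FT", "MT")) msg <- c(msg, "trainMode must be FT or MT")
  if (!object@predictMode %in% c("FP", "MP")) msg <- c(msg, "predictMode must be FP or MP")
  if (object@lambda < 0 || object@lambda > 1) msg <- c(msg, "lambda must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn MissingPolicy-class Constructor; `lambda` defaults to 0.5.
#' @param trainMode,predictMode,lambda,missingSet,seed see slots.
#' @export
MissingPolicy <- function(trainMode = "FT", predictMode = "FP",
                          lambda = 0.5, missingSet = character(),
                          seed = 1L) {
  new("MissingPolicy", trainMode = trainMode, predictMode = predictMode,
      lambda = lambda, missingSet = missingSet, seed = as.numeric(seed))
}

setMethod("show", "MissingPolicy", function(object) {
  cat(sprintf("MissingPolicy %s%s lambda=%.2f missing={%s}\n",
              object@trainMode, object@predictMode, object@lambda,
              paste(object@missingSet, collapse = ",")))
})

# ---------------------------------------------------------------------------
# ModelConfig
# ---------------------------------------------------------------------------

#' Segmentation model configuration
#'
#' `encoderKind` selects between the small CPU-trainable convolutional
#' encoder (`"light_trainable"`) and an external pretrained foundation
#' encoder (`"foundation_frozen"`, loaded from `foundationPath` and never
#' updated). The fused channel width is always
#' `nModalities * encoderChannels`; the squeeze-and-excitation bottleneck
#' width is that divided by `seReduction`.
#'
#' @slot encoderKind "light_trainable" or "foundation_frozen".
#' @slot nModalities number of input modalities N.
#' @slot encoderChannels per-modality feature channels C1.
#' @slot seReduction SE bottleneck reduction ratio r (default 16).
#' @slot decoderChannels channel width delivered to the decoder.
#' @slot inputSize square input resolution in pixels.
#' @slot trainableParts subset of c("encoder", "ffb", "decoder").
#' @slot foundationPath checkpoint path for the foundation encoder.
#' @export
setClass("ModelConfig", representation(
  encoderKind = "character", nModalities = "numeric",
  encoderChannels = "numeric", seReduction = "numeric",
  decoderChannels = "numeric", inputSize = "numeric",
  trainableParts = "character", foundationPath = "character"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@encoderKind %in% c("light_trainable", "foundation_frozen"))
    msg <- c(msg, "unknown encoderKind")
  c2 <- object@nModalities * object@encoderChannels
  if (object@seReduction < 1 || c2 / object@seReduction < 1)
    msg <- c(msg, "SE bottleneck width C2/r must be >= 1")
  if (object@encoderKind == "foundation_frozen" &&
      "encoder" %in% object@trainableParts)
    msg <- c(msg, "a frozen foundation encoder cannot be trainable")
  if (!all(object@trainableParts %in% c("encoder", "ffb", "decoder")))
    msg <- c(msg, "trainableParts must be a subset of encoder/ffb/decoder")
  if (object@inputSize < 4 || object@inputSize %% 2 != 0)
    msg <- c(msg, "inputSize must be an even number >= 4")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelConfig-class Constructor.
#' @param encoderKind,nModalities,encoderChannels,seReduction,decoderChannels,inputSize,trainableParts,foundationPath
#'   see slots.
#' @export
ModelConfig <- function(encoderKind = "light_trainable", nModalities = 4L,
                        encoderChannels = 4L, seReduction = 16L,
                        decoderChannels = 16L, inputSize = 1024L,
                        trainableParts = c("encoder", "ffb", "decoder"),
                        foundationPath = character()) {
  if (encoderKind == "foundation_frozen")
    trainableParts <- setdiff(trainableParts, "encoder")
  new("ModelConfig", encoderKind = encoderKind,
      nModalities = as.numeric(nModalities),
      encoderChannels = as.numeric(encoderChannels),
      seReduction = as.numeric(seReduction),
      decoderChannels = as.numeric(decoderChannels),
      inputSize = as.numeric(inputSize), trainableParts = trainableParts,
      foundationPath = foundationPath)
}

#' @rdname accessors
#' @export
setGeneric("fusedChannels", function(x) standardGeneric("fusedChannels"))
#' @rdname accessors
#' @export
setMethod("fusedChannels", "ModelConfig",
          function(x) as.integer(x@nModalities * x@encoderChannels))

# ---------------------------------------------------------------------------
# FusionModel
# ---------------------------------------------------------------------------

#' A (possibly trained) fusion segmentation model
#'
#' Wraps the parameter list of the light model: a shared per-modality
#' convolutional encoder, the squeeze-and-excitation feature fusion block
#' with residual projection, a learned box-prompt embedding, and a small
#' upsampling decoder head emitting one logit per pixel.
#'
#' @slot config the [ModelConfig-class].
#' @slot params named list of parameter arrays.
#' @export
setClass("FusionModel", representation(config = "ModelConfig",
                                       params = "list"))

setMethod("show", "FusionModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("FusionModel (%s): N=%d C1=%d Cd=%d input %dpx, %d parameters\n",
              object@config@encoderKind,
              as.integer(object@config@nModalities),
              as.integer(object@config@encoderChannels),
              as.integer(object@config@decoderChannels),
              as.integer(object@config@inputSize), np))
  cat("  trainable:", paste(object@config@trainableParts, collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setMethod("modelConfig", "FusionModel", function(x) x@config)
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "FusionModel", function(x) x@params)

# ---------------------------------------------------------------------------
# FusionState
# ---------------------------------------------------------------------------

#' Intermediate state of the feature fusion block
#'
#' @slot concat (h, w, C2) concatenated per-modality features.
#' @slot squeeze C2-vector of spatial means (global average pooling).
#' @slot weights C2-vector of channel attention weights, each in (0, 1).
#' @slot modulated (h, w, C2) channel-reweighted features.
#' @slot fused (h, w, decoderChannels) output of the residual projection.
#' @export
setClass("FusionState", representation(
  concat = "array", squeeze = "numeric", weights = "numeric",
  modulated = "array", fused = "array"))

setValidity("FusionState", function(object) {
  msg <- character()
  if (any(object@weights <= 0) || any(object@weights >= 1))
    msg <- c(msg, "attention weights must lie strictly in (0, 1)")
  hw <- prod(dim(object@concat)[1:2])
  expect <- object@concat * rep(object@weights, each = hw)
  if (max(abs(expect - object@modulated)) > 1e-8)
    msg <- c(msg, "modulated must equal weights * concat channelwise")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TrainConfig
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow standard practice for prompt-based fine-tuning: AdamW
#' with learning rate 1e-4 and weight decay 0.01, batch size 8, 50 epochs,
#' 5-fold subject-level cross-validation. Desk-scale experiments override
#' these (see the vignette).
#'
#' @slot lr learning rate.
#' @slot weightDecay decoupled weight decay coefficient.
#' @slot batchSize samples per optimizer step.
#' @slot epochs training epochs.
#' @slot folds cross-validation folds.
#' @slot policy a [MissingPolicy-class].
#' @slot model a [ModelConfig-class].
#' @slot preprocess a [PreprocessConfig-class].
#' @slot seed master seed (parameter init and data order).
#' @export
setClass("TrainConfig", representation(
  lr = "numeric", weightDecay = "numeric", batchSize = "numeric",
  epochs = "numeric", folds = "numeric", policy = "MissingPolicy",
  model = "ModelConfig", preprocess = "PreprocessConfig", seed = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr <= 0 || object@weightDecay < 0 || object@batchSize < 1 ||
      object@epochs < 1)
    msg <- c(msg, "hyperparameters must be positive")
  if (object@folds < 2) msg <- c(msg, "folds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig-class Constructor.
#' @param lr,weightDecay,batchSize,epochs,folds,policy,model,preprocess,seed
#'   see slots.
#' @export
TrainConfig <- function(lr = 1e-4, weightDecay = 0.01, batchSize = 8L,
                        epochs = 50L, folds = 5L,
                        policy = MissingPolicy(),
                        model = ModelConfig(),
                        preprocess = PreprocessConfig(), seed = 1L) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.numeric(batchSize), epochs = as.numeric(epochs),
      folds = as.numeric(folds), policy = policy, model = model,
      preprocess = preprocess, seed = as.numeric(seed))
}

# ---------------------------------------------------------------------------
# EvalReport
# ---------------------------------------------------------------------------

#' Per-slice evaluation report with aggregates and size bins
#'
#' @slot perSlice data.frame with columns subjectId, z, task, gtSize,
#'   dice, hd95, hd95Flag.
#' @slot aggregates data.frame of per-task mean/sd for dice and hd95.
#' @slot sizeBins data.frame of per-bin (range, n, meanDice).
#' @slot binWidth size-bin width in pixels.
#' @export
setClass("EvalReport", representation(
  perSlice = "data.frame", aggregates = "data.frame",
  sizeBins = "data.frame", binWidth = "numeric"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (nrow(object@sizeBins) &&
      sum(object@sizeBins$n) != nrow(object@perSlice))
    msg <- c(msg, "size-bin counts must sum to the per-slice row count")
  d <- object@perSlice$dice
  if (length(d) && (any(d < 0) || any(d > 1)))
    msg <- c(msg, "dice must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", nrow(object@perSlice), "slices\n")
  if (nrow(object@aggregates)) {
    a <- object@aggregates
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %s: Dice %.3f +/- %.3f, HD95 %.2f +/- %.2f (n=%d)\n",
                  a$task[i], a$meanDice[i], a$sdDice[i],
                  a$meanHd95[i], a$sdHd95[i], a$n[i]))
  }
})

#' @rdname accessors
#' @export
setGeneric("perSlice", function(x) standardGeneric("perSlice"))
#' @rdname accessors
#' @export
setMethod("perSlice", "EvalReport", function(x) x@perSlice)
#' @rdname accessors
#' @export
setGeneric("aggregates", function(x) standardGeneric("aggregates"))
#' @rdname accessors
#' @export
setMethod("aggregates", "EvalReport", function(x) x@aggregates)
#' @rdname accessors
#' @export
setGeneric("sizeBins", function(x) standardGeneric("sizeBins"))
#' @rdname accessors
#' @export
setMethod("sizeBins", "EvalReport", function(x) x@sizeBins)
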