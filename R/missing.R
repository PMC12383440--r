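# Missing-modality substitution. A "missing" modality is stood in for by
# an image whose elements are i.i.d. Uniform(0, 1) — the same scale as the
# preprocessed inputs — so the network keeps its full input structure.
# During MT training each designated modality of each sample is kept with
# probability lambda per iteration; at MP prediction designated modalities
# are always substituted.

#' Sample a uniform-noise substitute image
#'
#' @param shape integer dimensions, e.g. `c(S, S, 3)`.
#' @param rng optional RNG stream from [newRngStream()].
#' @return array of the given shape with i.i.d. Uniform(0, 1) entries.
#' @export
sampleSubstitute <- function(shape, rng = NULL) {
  draw <- function() array(stats::runif(prod(shape)), shape)
  if (is.null(rng)) draw() else withStream(rng, draw())
}

#' Stochastic training-time substitution (MT)
#'
#' For each modality in the policy's missing set an independent
#' p ~ Uniform(0, 1) is drawn; the real image is kept iff p <= lambda,
#' otherwise a fresh substitute is drawn. FT policies return the inputs
#' unchanged without consuming randomness. One p (and, if substituting,
#' one noise image) is drawn per designated modality per call, so every
#' training iteration re-randomizes.
#'
#' @param record a [SliceRecord-class].
#' @param policy a [MissingPolicy-class].
#' @param rng RNG stream for the policy's draws.
#' @return list with `images` (possibly modified input list) and
#'   `substituted` (character vector of substituted modality names).
#' @export
applyTrainingSubstitution <- function(record, policy, rng = NULL) {
  validObject(policy)
  images <- record@modalityImages
  if (policy@trainMode == "FT" || length(policy@missingSet) == 0L)
    return(list(images = images, substituted = character()))
  substituted <- character()
  for (m in policy@missingSet) {
    idx <- match(m, record@modalityNames)
    if (is.na(idx)) stop("unknown modality in missing set: ", m)
    p <- if (is.null(rng)) stats::runif(1) else withStream(rng, stats::runif(1))
    if (p > policy@lambda) {
      images[[idx]] <- sampleSubstitute(dim(images[[idx]]), rng)
      substituted <- c(substituted, m)
    }
  }
  list(images = images, substituted = substituted)
}

#' Deterministic inference-time substitution (MP)
#'
#' FP returns the inputs unchanged; MP replaces every modality in the
#' missing set by a fresh uniform-noise substitute.
#'
#' @inheritParams applyTrainingSubstitution
#' @return the (possibly modified) list of model-ready images.
#' @export
applyInferenceSubstitution <- function(record, policy, rng = NULL) {
  validObject(policy)
  images <- record@modalityImages
  if (policy@predictMode == "FP") return(images)
  for (m in policy@missingSet) {
    idx <- match(m, record@modalityNames)
    if (is.na(idx)) stop("unknown modality in missing set: ", m)
    images[[idx]] <- sampleSubstitute(dim(images[[idx]]), rng)
  }
  images
}
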