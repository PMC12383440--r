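# Volume-to-slice preprocessing: percentile gray-level adjustment,
# tumor-slice selection along z, task-mask derivation, resizing to the
# model resolution, 3-channel replication, and bounding-box prompts.

#' Percentile gray-level adjustment of a volume
#'
#' Intensities below the `lowPct` percentile or above the `highPct`
#' percentile (computed over all voxels of the volume, linear-interpolation
#' percentiles) are clamped to the band edges; the retained band is then
#' mapped affinely onto \[0, grayMax\]. A constant volume has a degenerate
#' band and maps, by convention, to all zeros with a warning.
#'
#' @param volume numeric array (any shape, >= 1 voxel).
#' @param config a [PreprocessConfig-class].
#' @return rescaled array of the same shape.
#' @export
clipRescale <- function(volume, config = PreprocessConfig()) {
  q <- stats::quantile(volume, c(config@lowPct, config@highPct) / 100,
                       names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("constant volume: percentile band is degenerate, returning zeros")
    return(array(0, dim(volume) %||% length(volume)))
  }
  v <- pmin(pmax(volume, q[1]), q[2])
  (v - q[1]) / (q[2] - q[1]) * config@grayMax
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary task mask from a label map
#'
#' Task composition follows the concentric convention: whole tumor (WT) is
#' codes \{1, 2, 3\}, tumor core (TC) codes \{1, 3\}, enhancing tumor (ET)
#' code \{3\} — hence ET \eqn{\subseteq} TC \eqn{\subseteq} WT always.
#'
#' @param labels integer array/matrix with codes in \{0, 1, 2, 3\}.
#' @param task one of "WT", "TC", "ET".
#' @return binary array of the same shape.
#' @export
deriveTaskMask <- function(labels, task = c("WT", "TC", "ET")) {
  task <- match.arg(task)
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  codes <- switch(task, WT = c(1, 2, 3), TC = c(1, 3), ET = 3)
  out <- array(as.numeric(labels %in% codes), dim(labels) %||% length(labels))
  out
}

#' Indices of tumor-containing axial slices
#'
#' @param stack a [ModalityStack-class].
#' @param task segmentation task.
#' @return ascending 1-based z indices whose task mask has at least one
#'   positive voxel (possibly empty).
#' @export
selectTumorSlices <- function(stack, task = c("WT", "TC", "ET")) {
  task <- match.arg(task)
  mask <- deriveTaskMask(stack@labels, task)
  which(apply(mask, 1, sum) > 0)
}

#' Jittered bounding-box prompt from a mask
#'
#' The tight box of the positive pixels, with each of the four sides moved
#' outward by an independent uniform integer in \[0, bboxJitterMax\] and
#' clamped to the image bounds. Jitter only ever expands the box, so the
#' prompt always contains the tight box.
#'
#' @param mask nonempty binary matrix.
#' @param config a [PreprocessConfig-class].
#' @param rng optional RNG stream from [newRngStream()] (defaults to the
#'   current RNG).
#' @return integer (x0, y0, x1, y1), 0-based inclusive, x = column.
#' @export
makeBboxPrompt <- function(mask, config = PreprocessConfig(), rng = NULL) {
  tb <- tightBbox(mask)  # errors on empty mask
  jmax <- as.integer(config@bboxJitterMax)
  draw <- function() sample.int(jmax + 1L, 4L, replace = TRUE) - 1L
  j <- if (jmax == 0L) c(0L, 0L, 0L, 0L)
       else if (is.null(rng)) draw() else withStream(rng, draw())
  H <- nrow(mask); W <- ncol(mask)
  c(x0 = max(tb[[1]] - j[1], 0L), y0 = max(tb[[2]] - j[2], 0L),
    x1 = min(tb[[3]] + j[3], W - 1L), y1 = min(tb[[4]] + j[4], H - 1L))
}

# resize a 2-D matrix; bilinear for images, nearest-neighbor for masks
.resize2d <- function(m, size, nearest = FALSE) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::resize(m, w = size, h = size,
                         filter = if (nearest) "none" else "bilinear")
  matrix(as.numeric(out), size, size)
}

#' Convert raw slice images to model-ready inputs
#'
#' Each image is resized (bilinear, anisotropically if non-square) to
#' `modelSize` x `modelSize`, divided by `grayMax` into \[0, 1\], and
#' replicated across 3 identical channels.
#'
#' @param sliceImages list of 2-D matrices sharing one shape.
#' @param config a [PreprocessConfig-class].
#' @return list of (modelSize, modelSize, 3) arrays.
#' @export
toModelInput <- function(sliceImages, config = PreprocessConfig()) {
  lapply(sliceImages, function(m) {
    r <- .resize2d(m, as.integer(config@modelSize)) / config@grayMax
    r <- pmin(pmax(r, 0), 1)
    array(r, c(dim(r), 3L))
  })
}

#' Build the per-slice dataset for one task from a cohort
#'
#' Applies the full pipeline: per-volume percentile clip/rescale, per-task
#' tumor-slice selection, mask derivation and nearest-neighbor resizing,
#' bilinear image resizing with channel replication, and jittered box
#' prompts (jitter stream seeded by `config@seed`). Slices whose resized
#' mask comes out empty are dropped. Deterministic given
#' (cohort, config, seed).
#'
#' @param cohort list of [ModalityStack-class].
#' @param task segmentation task.
#' @param config a [PreprocessConfig-class].
#' @return list of [SliceRecord-class] objects.
#' @export
buildSliceDataset <- function(cohort, task = c("WT", "TC", "ET"),
                              config = PreprocessConfig()) {
  task <- match.arg(task)
  if (length(cohort) == 0L) stop("cohort is empty")
  size <- as.integer(config@modelSize)
  rng <- newRngStream(config@seed)
  records <- list()
  for (stack in cohort) {
    vols <- lapply(stack@images, clipRescale, config = config)
    zs <- selectTumorSlices(stack, task)
    for (z in zs) {
      mask <- .resize2d(deriveTaskMask(stack@labels[z, , ], task),
                        size, nearest = TRUE)
      mask <- (mask > 0.5) + 0
      if (sum(mask) < 1) next
      imgs <- toModelInput(lapply(vols, function(v) v[z, , ]), config)
      names(imgs) <- stack@modalityNames
      records[[length(records) + 1L]] <- new(
        "SliceRecord", subjectId = stack@subjectId, zIndex = as.numeric(z),
        task = task, modalityImages = imgs, gtMask = mask,
        bbox = as.numeric(makeBboxPrompt(mask, config, rng)),
        modalityNames = stack@modalityNames)
    }
  }
  records
}

#' Write a slice-dataset manifest
#'
#' One CSV row per record: subjectId, z, task, gtSize and the box corners.
#'
#' @param records list of [SliceRecord-class].
#' @param path CSV path.
#' @return invisibly, the manifest data.frame.
#' @export
writeSliceManifest <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(subjectId = r@subjectId, z = r@zIndex, task = r@task,
               gtSize = sum(r@gtMask), x0 = r@bbox[1], y0 = r@bbox[2],
               x1 = r@bbox[3], y1 = r@bbox[4])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
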