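# Synthetic multi-modal phantom generation. Subjects are three nested
# regions (whole > core > enhancing) modelled as spheres whose radius is
# perturbed smoothly over direction by a random low-order harmonic field,
# so boundaries are nontrivial for boundary metrics while nesting is
# guaranteed (the perturbation amplitude is capped at 25% of the smallest
# radius gap by PhantomSpec validity). Label codes follow the concentric
# convention: edema analog = whole minus core (2), necrotic-core analog =
# core minus enhancing (1), enhancing analog (3).

# low-order direction basis (degree <= 2 real harmonics, unnormalized)
.harmonicBasis <- function(ux, uy, uz) {
  cbind(ux, uy, uz, ux * uy, ux * uz, uy * uz,
        ux^2 - uy^2, 2 * uz^2 - ux^2 - uy^2)
}

#' Generate one synthetic multi-modal subject
#'
#' Each modality image is `backgroundLevel` plus the modality's contrast
#' contribution for every nested region the voxel lies in, plus additive
#' Gaussian noise clipped at zero. Deterministic given
#' `(spec@seed, subjectIndex)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param subjectIndex 0-based subject index.
#' @return a [ModalityStack-class].
#' @examples
#' stack <- generateSubject(PhantomSpec(), 0)
#' table(labelVolume(stack))
#' @export
generateSubject <- function(spec, subjectIndex = 0L) {
  validObject(spec)
  shp <- as.integer(spec@volumeShape)
  withSeed(spec@seed + 7919 * subjectIndex, {
    ctr <- (shp + 1) / 2
    zi <- slice.index(array(0, shp), 1) - ctr[1]
    yi <- slice.index(array(0, shp), 2) - ctr[2]
    xi <- slice.index(array(0, shp), 3) - ctr[3]
    rad <- sqrt(zi^2 + yi^2 + xi^2)
    nz <- pmax(rad, 1e-9)
    B <- .harmonicBasis(as.vector(xi / nz), as.vector(yi / nz),
                        as.vector(zi / nz))
    inside <- vector("list", 3L)
    for (k in 1:3) {
      f <- as.vector(B %*% stats::rnorm(ncol(B)))
      if (spec@deformAmplitude > 0 && max(abs(f)) > 0) f <- f / max(abs(f))
      inside[[k]] <- rad <= spec@regionRadii[k] +
        spec@deformAmplitude * array(f, shp)
    }
    whole <- inside[[1]]; core <- inside[[2]] & whole
    enh <- inside[[3]] & core
    labels <- array(0L, shp)
    labels[whole & !core] <- 2L   # edema analog
    labels[core & !enh] <- 1L     # necrotic-core analog
    labels[enh] <- 3L             # enhancing analog
    images <- vector("list", spec@nModalities)
    for (m in seq_len(spec@nModalities)) {
      img <- spec@backgroundLevel +
        spec@contrastMatrix[m, 1] * whole +
        spec@contrastMatrix[m, 2] * core +
        spec@contrastMatrix[m, 3] * enh
      if (spec@noiseSd > 0)
        img <- img + array(stats::rnorm(prod(shp), sd = spec@noiseSd), shp)
      images[[m]] <- pmax(img, 0)
    }
    names(images) <- spec@modalityNames
    new("ModalityStack",
        subjectId = sprintf("sub-%03d", subjectIndex + 1L),
        images = images, labels = labels,
        modalityNames = spec@modalityNames)
  })
}

#' Generate a cohort of phantom subjects
#'
#' Subjects differ by bounded per-subject jitter of the region radii
#' (multiplicative, uniform in `1 +/- radiiJitter`) and of the contrast
#' matrix (additive, uniform in `+/- contrastJitter`, clipped to \[0, 1\]),
#' then by the per-subject deformation and noise draws. With both jitters
#' zero, subject i is identical to `generateSubject(spec, i - 1)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param nSubjects number of subjects (>= 1).
#' @param radiiJitter,contrastJitter jitter half-widths (defaults 0.08 and
#'   0.03, small enough that spec invariants keep holding).
#' @return list of [ModalityStack-class] objects with distinct subject ids.
#' @export
generateCohort <- function(spec, nSubjects, radiiJitter = 0.08,
                           contrastJitter = 0.03) {
  validObject(spec)
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  specs <- withSeed(spec@seed, lapply(seq_len(nSubjects), function(i) {
    s <- spec
    s@regionRadii <- spec@regionRadii *
      (1 + stats::runif(3, -radiiJitter, radiiJitter))
    # jitter may narrow the radius gaps; keep the deformation inside the
    # safe nesting bound of the jittered geometry
    gap <- min(diff(rev(s@regionRadii)))
    s@deformAmplitude <- min(spec@deformAmplitude, 0.25 * gap)
    cm <- spec@contrastMatrix +
      matrix(stats::runif(length(spec@contrastMatrix),
                          -contrastJitter, contrastJitter),
             nrow(spec@contrastMatrix))
    s@contrastMatrix <- pmin(pmax(cm, 0), 1)
    validObject(s)
    s
  }))
  lapply(seq_len(nSubjects),
         function(i) generateSubject(specs[[i]], i - 1L))
}

#' Write a cohort to disk in the per-subject NIfTI layout
#'
#' One directory per subject containing one gzipped NIfTI file per modality
#' (`<id>_<modality>.nii.gz`) plus the segmentation (`<id>_segm.nii.gz`),
#' mirroring the layout of preprocessed multi-parametric MRI releases so
#' the real-data reader can be exercised against phantoms.
#'
#' @param cohort list of [ModalityStack-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of subject directories written.
#' @export
writeCohortNifti <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(stack) {
    sd <- file.path(dir, stack@subjectId)
    dir.create(sd, showWarnings = FALSE)
    for (m in seq_along(stack@images))
      RNifti::writeNifti(stack@images[[m]], file.path(
        sd, sprintf("%s_%s.nii.gz", stack@subjectId,
                    stack@modalityNames[m])))
    RNifti::writeNifti(stack@labels,
                       file.path(sd, sprintf("%s_segm.nii.gz",
                                             stack@subjectId)))
    sd
  }, character(1))
  invisible(paths)
}

#' Read one subject from the per-subject NIfTI layout
#'
#' @param dir cohort directory as written by [writeCohortNifti()].
#' @param subjectId subject identifier (directory name).
#' @param modalityNames modalities to load, in order.
#' @param segSuffix filename suffix of the label volume.
#' @return a [ModalityStack-class].
#' @export
readSubjectNifti <- function(dir, subjectId,
                             modalityNames = c("T1", "T1gd", "T2", "FLAIR"),
                             segSuffix = "segm") {
  sd <- file.path(dir, subjectId)
  images <- lapply(modalityNames, function(m) {
    f <- file.path(sd, sprintf("%s_%s.nii.gz", subjectId, m))
    if (!file.exists(f)) stop("missing modality file: ", f)
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim(v))
  })
  names(images) <- modalityNames
  segf <- file.path(sd, sprintf("%s_%s.nii.gz", subjectId, segSuffix))
  labels <- RNifti::readNifti(segf)
  labels <- array(as.integer(round(as.numeric(labels))), dim(labels))
  new("ModalityStack", subjectId = subjectId, images = images,
      labels = labels, modalityNames = modalityNames)
}
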