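---
title: "Multi-modal fusion segmentation with missing-modality robust training"
author: "fuseseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal fusion segmentation with missing-modality robust training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseseg)
```

## The problem

Glioma segmentation from MRI is routinely posed as three nested binary
tasks: whole tumor (WT, the union of necrotic core, edema and enhancing
tissue), tumor core (TC, necrosis plus enhancing tissue) and enhancing
tumor (ET). Different pulse sequences carry different information — FLAIR
delineates the edematous whole-tumor extent while contrast-enhanced T1
(T1gd) dominates core and enhancing contrast — so multi-modal input helps,
but clinical data are frequently incomplete: a sequence may be missing
because of artifacts, protocol differences, or contrast-agent
contraindications.

`fuseseg` implements a prompt-based multi-modal segmentation network whose
two scientific ingredients are

1. a **channel-attention feature fusion block (FFB)** that merges
   per-modality feature maps, and
2. a **probabilistic missing-modality training scheme** that makes the
   trained model usable when a modality is absent at prediction time,

together with everything needed to exercise them end to end on synthetic
data: a phantom generator, the full preprocessing pipeline, Dice/BCE
objectives, Dice and 95th-percentile Hausdorff evaluation, subject-level
cross-validation, a train/predict mode grid, a keep-probability sweep, and
UMAP embedding of fused features.

## Model

Each of the $N$ modality images is replicated to three channels, scaled to
$[0,1]$, and encoded by a *shared* encoder into a feature map
$F_n \in \mathbb{R}^{C_1 \times h \times w}$. Two encoders are available:

* `light_trainable` — a small stride-2 convolutional encoder that trains
  in seconds on a CPU; this is the tested path;
* `foundation_frozen` — a pluggable external pretrained encoder loaded
  from a checkpoint and never updated. The package deliberately does not
  re-implement or ship such a foundation model; the loader contract (an
  RDS file providing an `encode()` closure) keeps it optional.

The FFB concatenates the maps into
$F_c \in \mathbb{R}^{C_2 \times h \times w}$ with $C_2 = N C_1$ and applies
squeeze-and-excitation channel attention:

$$z_k = \frac{1}{hw}\sum_{i,j} F_c(k,i,j), \qquad
  s = \sigma\!\left(W_2\,\delta(W_1 z)\right),$$

with $\delta$ = ReLU, $\sigma$ = sigmoid and a bottleneck of width
$C_2/r$. The weights $s \in (0,1)^{C_2}$ rescale the channels,
$F_{fm}(k,\cdot,\cdot) = s_k F_c(k,\cdot,\cdot)$, and a residual layer
combines modulated and raw features. The residual layer's exact form is a
design choice of this package: we **add the identity path and then apply a
learned $1\times1$ projection**, $F_f = P(F_{fm} + F_c)$, because this
preserves the identity path the term "residual" implies while delivering
the decoder's channel width. The SE reduction ratio defaults to $r = 16$,
standard squeeze-and-excitation practice; desk-scale tests use $r = 4$
because their $C_2 = 16$ would otherwise collapse the bottleneck to a
single unit.

The decoder is conditioned on a bounding-box prompt: the box corners,
normalized by the image size, pass through a learned linear embedding that
is broadcast-added to the fused map; two $3\times3$ convolutions around a
nearest-neighbor $\times 2$ upsampling then emit one logit per pixel at the
input resolution. A pixel is foreground when its logit is $\ge 0$
(sigmoid $0.5$; the tie counts as foreground, an arbitrary but fixed
convention). One binary model is trained per task.

All gradients are hand-derived and verified against central finite
differences in the test suite; the convolution kernels are im2col/GEMM
routines in compiled code.

## Missing-modality scheme

A designated "missing" modality is stood in for by a substitute image
whose pixels are i.i.d. $\mathrm{Uniform}(0,1)$ — the same scale as the
preprocessed inputs, which is why substitution happens *after*
preprocessing. During **missing-modality training (MT)** each designated
modality of each sample is kept with probability $\lambda$ and replaced by
fresh noise otherwise, independently per modality, per sample, per
iteration; re-drawing every iteration maximizes augmentation diversity.
**Full-modality training (FT)** never substitutes. At prediction time,
**MP** always substitutes the designated modalities, **FP** never does.
$\lambda$ defaults to $0.5$. The default experiment designates one missing
modality at a time (mirroring how modality importance is usually probed);
arbitrary missing sets are supported.

Each randomness source lives in its own RNG stream (parameter
initialization, data order, policy noise, bbox jitter). A consequence worth
testing — and tested — is that MT with $\lambda = 1$ consumes only
policy-stream draws and therefore reproduces the FT trajectory
bit-for-bit.

## Preprocessing

Volumes are intensity-adjusted by clamping voxels outside the
$[0.5\%, 99.5\%]$ percentile band (percentiles computed with linear
interpolation over *all* voxels, including background zeros — documented
because skull-stripped backgrounds shift percentiles) and mapping the band
linearly to $[0, 255]$. Clamping rather than deleting out-of-band voxels
preserves the voxel grid. A constant volume maps to all zeros with a
warning. Tumor-containing axial slices are selected per task, masks are
composed by the concentric convention (WT = codes {1,2,3}, TC = {1,3},
ET = {3}), images are resized bilinearly (masks nearest-neighbor) to the
square model resolution and replicated to three channels. Box prompts are
the tight mask bounding box expanded outward per side by an independent
uniform integer in $[0, 20]$ pixels — outward only, since a shrunken
prompt could exclude tumor. The box convention is 0-based inclusive
corners $(x_0, y_0, x_1, y_1)$ with $x$ = column. Evaluation is performed
at the model resolution, in pixels; the native-resolution alternative is
not used because the model emits masks at its own resolution.

## The phantom generator

Phantoms exist so that every downstream stage is testable without any
download. A subject is three nested regions — whole, core and enhancing
analogs — modelled as spheres whose radius varies smoothly with direction
through a random degree-$\le 2$ harmonic perturbation, normalized to unit
peak and scaled by `deformAmplitude`. Deformation makes boundaries
nontrivial for HD95 (exact spheres make boundary metrics degenerate);
nesting is preserved by capping the amplitude at 25% of the smallest
radius gap, and the cohort generator additionally re-caps the amplitude
after per-subject radius jitter so the bound holds by construction. Labels
follow the concentric convention: edema analog = whole minus core,
necrotic-core analog = core minus enhancing, enhancing analog.

Each modality's image is `backgroundLevel` plus its row of the contrast
matrix summed over the regions containing the voxel, plus additive
Gaussian noise clipped at zero (no Rician model — the method under test is
noise-model agnostic). The default contrast matrix encodes the clinically
motivated asymmetry the robustness experiments need: a FLAIR-like modality
carries most whole-region contrast (0.55) and a T1gd-like modality
dominates core/enhancing contrast (0.35/0.35), while T1 and T2 carry
weaker redundant signal. Dropping the T1gd-like modality therefore cripples
a full-modality-trained TC model but leaves enough residual signal (T1
core contrast 0.15, T2 0.10) for a missing-modality-trained model to
recover — the qualitative phenomenon the acceptance experiments probe.

Default study conditions, chosen once for desk-scale CPU work: volumes
$24 \times 32 \times 32$ voxels, radii $(10, 6, 3)$, background 0.15,
noise sd 0.02, deformation amplitude 0.6, cohort jitter 8% on radii and
0.03 on contrast. The learning-sanity experiment uses
$24 \times 48 \times 48$ volumes at model size 64 with 30 subjects; the
mode-grid and sweep experiments use 12 subjects at model size 32 with a
30% subject-level holdout. What phantoms do *not* emulate: MRI physics,
bias fields, multifocal or irregular topologies, registration error,
inter-site variation. Passing tests therefore demonstrate that the
mechanisms work as specified, not that any particular accuracy transfers
to patient data.

## Objectives and metrics

Training minimizes the sum of the soft Dice loss with squared denominators,
$$L_{Dice} = 1 - \frac{2\sum_i y_i \hat y_i}
                      {\sum_i y_i^2 + \sum_i \hat y_i^2 + \varepsilon},$$
($\varepsilon = 10^{-6}$ guards 0/0 on empty masks, which slice selection
makes unreachable but is guarded anyway) and the mean binary cross-entropy
with predictions clamped to $[10^{-7}, 1 - 10^{-7}]$. On binary
predictions $L_{Dice}$ equals $1 - \mathrm{Dice}$ since $y^2 = y$ for
binary $y$.

Evaluation reports the Dice score $2|G \cap S|/(|G| + |S|)$ (two empty
masks score 1) and HD95. HD95 is computed on boundary pixels — mask pixels
with at least one 8-neighbor outside the mask — as the maximum over both
directions of the 95th percentile (linear interpolation) of directed
nearest-neighbor Euclidean distances, in pixels at model resolution.
Percentile-of-directed-distances with a max over directions is the
standard outlier-robust reading; the plain maximum (exact Hausdorff) is
exposed as `hausdorff()` for completeness, and the 95th percentile never
exceeds it. When exactly one mask is empty a finite worst-case penalty
(the image diagonal) is returned and the row is flagged so users can
exclude such slices; two empty masks score 0. Aggregation is per slice
(the pipeline is 2-D); size-stratified aggregation bins rows by
ground-truth pixel count into width-500 bins.

## Training and experiment harness

AdamW (decoupled weight decay) with the full-scale configuration defaults lr $10^{-4}$,
weight decay 0.01, batch size 8, 50 epochs and 5-fold subject-level
cross-validation preserved as configuration defaults; desk-scale
experiments use lr $10^{-3}$, 4–10 epochs, and the phantom sizes above so
each training finishes in seconds to a couple of minutes on one CPU core.
No learning-rate schedule and no early stopping (fixed epochs). Only the
configured trainable parts receive updates; a frozen encoder is verified
bit-identical after optimization.

The mode grid trains FT and MT on a *shared* subject-level holdout split
with identical initialization and data-order seeds — only the substitution
policy differs — and evaluates both under FP and MP, averaging MP over
several noise seeds (MP is stochastic; the number of draws is
configurable and the spread is reported). The grid and the $\lambda$ sweep
use a single shared holdout split rather than full cross-validation: the
comparisons are paired 2×2 contrasts at matched splits, and CV would
multiply cost without changing the contrast. `crossValidate()` provides
the full CV protocol separately. The sweep trains one MT model per
$\lambda$; its $\lambda = 1$ row coincides with FT by the stream argument
above. Whether MT should train one model per missing-modality scenario or
one model over all modalities is left open by the method description; the
default is per-scenario (matching one-missing-at-a-time evaluation), and
arbitrary missing sets support the alternative.

`embedFusedFeatures()` pools each slice's fused map spatially and embeds
the pooled vectors with UMAP (single-threaded for determinism), labelled
by mode, for the foreground/background and FT-vs-MT structure inspections.

## Numerical choices and degenerate inputs

* Percentiles: R's type-7 (linear interpolation) throughout, matching the
  HD95 percentile rule.
* Constant volume in `clipRescale`: all-zero output plus a warning.
* Empty mask: `makeBboxPrompt` errors (callers must have filtered
  slices); `hd95` applies the diagonal penalty and flags.
* Slices whose nearest-neighbor-resized mask becomes empty are dropped
  during dataset building.
* Clip/rescale is only *near*-idempotent: a second pass re-estimates the
  band from already-clamped tails and can move values by well under 1% of
  the gray range.
* Logit ties at exactly 0 count as foreground.
* He-normal initialization; all randomness flows through named RNG
  streams so every experiment is reproducible from its seeds.

## Known limitations

The light model is deliberately tiny and the phantoms deliberately easy;
headline accuracies on real multi-parametric MRI require the pretrained
foundation encoder, real data and GPU-scale training, none of which the
package ships. HD95 is reported in pixels, not millimeters, because the
pipeline has no physical spacing. Statistical significance testing between
modes is not implemented. Generative imputation of missing modalities is
out of scope — uniform-noise substitution is the point of the training
scheme under study.
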