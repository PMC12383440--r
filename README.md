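# fuseseg

Prompt-based multi-modal segmentation of nested brain-tumor regions, with
channel-attention feature fusion and missing-modality robust training.

## What this package is for

Glioma segmentation from multi-parametric MRI is posed as three nested
binary tasks — whole tumor (WT), tumor core (TC) and enhancing tumor (ET)
— and different pulse sequences matter for different tasks: FLAIR for the
whole-tumor extent, contrast-enhanced T1 (T1gd) for core and enhancing
tissue. Clinical data are frequently incomplete, so a multi-modal model
must stay usable when a sequence is missing.

`fuseseg` implements, in R with compiled convolution kernels:

* a segmentation network in which a shared encoder produces per-modality
  feature maps `F_1..F_N` that a **feature fusion block** merges by
  squeeze-and-excitation channel attention,

  ```
  z_k = mean_{i,j} F_c(k,i,j)            (global average pooling)
  s   = sigmoid(W2 . relu(W1 . z))       (bottleneck, width C2/r)
  F_fm = s (*) F_c                       (channel-wise reweighting)
  F_f  = Proj(F_fm + F_c)                (residual + 1x1 projection)
  ```

  followed by a bounding-box-prompted decoder emitting one logit per
  pixel (mask = logits >= 0);
* **missing-modality training (MT)**: each designated modality of each
  sample is kept with probability `lambda` per iteration and otherwise
  replaced by i.i.d. Uniform(0,1) noise at the input scale
  (`X_in = X_n` if `p <= lambda`, else the substitute); at prediction
  time MP substitutes the designated modalities outright, FP does not
  (`lambda = 1` under MT reproduces full-modality training bit-for-bit);
* the preprocessing pipeline (0.5/99.5 percentile intensity clamping to
  0–255, tumor-slice selection, resizing with 3-channel replication,
  jittered box prompts), the Dice + BCE objective, Dice and HD95 (95th
  percentile of directed boundary distances, max over both directions)
  with size-stratified aggregation, subject-level cross-validation, the
  FT/MT x FP/MP mode grid, the `lambda` sweep, and UMAP embedding of
  fused features;
* a synthetic multi-modal phantom generator (nested deformed-sphere
  regions with per-modality contrast profiles) so that everything above
  runs end to end on one CPU with no data download.

It is aimed at method developers who want a fully testable, dependency
light reference implementation of the fusion + missing-modality scheme,
not at producing clinical-grade segmentations: the tested encoder is a
small trainable one, and an external pretrained foundation encoder is a
pluggable optional component.

## Worked example

```r
library(fuseseg)

spec <- PhantomSpec(seed = 42)
spec
#> PhantomSpec: 4 modalities ( T1, T1gd, T2, FLAIR )
#>   volume 24x32x32  radii 10/6/3  noise sd 0.02  deform 0.6

cohort  <- generateCohort(spec, 12)
records <- buildSliceDataset(cohort, task = "WT",
                             PreprocessConfig(modelSize = 32, seed = 1))
length(records)
#> [1] 244

config <- TrainConfig(lr = 1e-3, epochs = 4, batchSize = 8,
                      model = ModelConfig(encoderChannels = 4,
                                          seReduction = 4,
                                          decoderChannels = 16,
                                          inputSize = 32),
                      preprocess = PreprocessConfig(modelSize = 32, seed = 1),
                      seed = 1)
testIds <- sprintf("sub-%03d", 1:3)
fit <- trainModel(Filter(function(r) !(r@subjectId %in% testIds), records),
                  config)
round(fit$lossCurve, 4)
#> [1] 1.1779 0.4024 0.0915 0.0676

report <- evaluateModel(fit$model,
                        Filter(function(r) r@subjectId %in% testIds, records))
report
#> EvalReport: 62 slices
#>   WT: Dice 0.946 +/- 0.128, HD95 1.67 +/- 5.44 (n=62)
```

The loss curve shows the combined Dice + BCE objective falling over four
epochs; the report aggregates per-slice Dice and HD95 (pixels at model
resolution) over the three held-out subjects. The lone weak slice is a
4-pixel tumor tip whose empty prediction draws the flagged diagonal
penalty — exactly the small-region failure mode the size-stratified
aggregation (`sizeBins(report)`) is there to expose.

The mode grid and sweep reproduce the scheme's qualitative behavior on
phantoms where T1gd exclusively dominates core contrast: losing T1gd under
full-modality training collapses TC accuracy, missing-modality training
recovers most of it, and full-modality prediction improves as `lambda`
grows:

```r
grid <- modeGridEval(cohort, "TC", config, "T1gd")
modeGridTable(grid)
sweep <- lambdaSweep(cohort, "TC", config, "T1gd", lambdas = c(0, 0.5, 1))
```

A thin command-line runner with subcommands `phantom`, `preprocess`,
`train`, `evaluate`, `mode-grid`, `lambda-sweep` and `embed` is installed
at `inst/scripts/fuseseg` and driven by a single YAML config
(`readExperimentConfig()`).

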