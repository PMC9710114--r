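# phasetcn

Frame-level surgical workflow phase recognition with a residual
multi-stage temporal convolutional network, in R.

## What problem this solves

Computer-assisted surgery systems need to know, at every moment, which
phase of the operation is underway — for cataract surgery, which of nine
steps from incision to tonifying/antibiotics the current frame belongs
to. Per-frame classifiers fail where phases look nearly identical
(irrigation/aspiration versus viscous-agent removal share instruments
and background), and recurrent models cannot hold minutes of context.
`phasetcn` is for researchers who want a desk-scale, fully inspectable
implementation of the temporal-convolution approach to this problem:
every component — from the dilated convolution arithmetic to the
training loop — is plain R backed by tests, and a seeded synthetic
generator stands in for clinical video so everything runs anywhere.

## The model

Per-frame feature vectors `X = (x_1 .. x_T)` (from a triple-stream
frontend fusing whole-frame, pupil-patch and instrument-patch encodings)
feed a two-stage temporal convolutional network that predicts a phase
for every frame at full temporal resolution:

* **Stage 1** — `N` *dual dilated layers*: layer `n` runs two parallel
  causal dilated convolutions with opposing schedules, dilation
  `2^(n-1)` and `2^(N-n)`, fused by a 1x1 convolution with per-frame
  LayerNorm and ReLU on a residual connection. One branch grows its
  receptive field with depth (global context), the other shrinks it
  (local detail near transitions).
* **Stage 2** — `N` single dilated layers (dilation `2^(n-1)`) refine
  the stage-1 features; the result is concatenated with `X`, reduced
  1x1, and classified. Both stages carry supervised heads.

Causal left-padding makes every prediction depend only on current and
past frames, so the model can run online; with kernel 3 and `N = 9` one
dual stage spans 1953 frames of context. Training minimizes the mean of
the stage-wise median-frequency-weighted cross-entropies
`L = (1/M) sum_m L_m`,
`L_m = -(1/N) sum_i sum_c omega_c y_ic log p_ic` with
`omega_c = median(freq)/freq_c`, under Adam with poly learning-rate
decay `lr = init_lr (1 - iter/total)^0.9`.

## Worked example

```r
library(phasetcn)

spec <- benchmark_spec("separable")            # 5 phases, D = 32, ~300 frames
ds   <- generate_dataset(spec, 25, c(0.8, 0, 0.2), seed = 1)
cfg  <- default_config(temporal_epochs = 40L, n_layers = 6L,
                       channels = 32L, seed = 1L)
fit  <- train_temporal(ds$train, val = NULL, n_classes = 5, config = cfg)

v    <- ds$test[[1]]
pred <- predict(fit$model, v$features)
met  <- phase_metrics(confusion_counts(pred$labels, v$labels))
str(met[c("accuracy", "precision", "recall", "jaccard")])
#> List of 4
#>  $ accuracy : num 1
#>  $ precision: num 1
#>  $ recall   : num 1
#>  $ jaccard  : num 1
```

This test video is classified perfectly (across whole test sets the
3-seed median accuracy is about 0.99) because the separable
benchmark is a known-recoverable regime: phase means sit 8 noise-SD
apart, so failure here would indicate a defect in the model or
optimizer, not a hard dataset. The interesting regimes are
`benchmark_spec("confusable")` (two phases with identical emissions —
recognition within the pair falls to the ceiling set by the duration
prior while other phases stay above 0.90 recall) and
`benchmark_spec("imbalanced")` (a phase at 5% of frames — median
frequency balancing lifts its recall relative to uniform weights).

`evaluate_run(pred$labels, v$labels, out_dir = "report")` writes
`metrics.json`/`metrics.csv`, a confusion matrix, a transition-deviation
table in seconds, and the color-coded phase ribbon PNG (prediction above
ground truth).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/phasetcn simulate --out data n_videos=25 seed=1
Rscript inst/cli/phasetcn train-temporal --out run data=data temporal_epochs=40 n_layers=6 channels=32
Rscript inst/cli/phasetcn predict --out run checkpoint=run/temporal.ckpt features=data/test/synthetic_021
Rscript inst/cli/phasetcn evaluate --out run/report predictions=run/predictions.csv features=data/test/synthetic_021
```

## Package layout

* `R/temporal_net.R` — dilated causal convolutions, dual dilated layers,
  stages, the full model, receptive-field analysis, backprop
* `R/frontend.R` — detection selection, patch cropping, the small
  convolutional stream encoder, stream fusion, preliminary classifier
* `R/objectives.R` — median frequency balancing, weighted and
  multi-stage cross-entropy, poly learning rate, Adam
* `R/evaluation.R` — confusion counts, macro metrics, segments,
  transition deviations, phase ribbons
* `R/synthetic.R` — the seeded synthetic surgery-video generator
* `R/pipeline.R`, `R/benchmarks.R` — training loops, feature export,
  checkpoints, manifests, frozen benchmark protocols
* `vignettes/phase-recognition-methods.Rmd` — the full methods account
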