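# eegdecode

Single-trial EEG decoding with a compact convolutional network,
Grad-CAM attribution, and binomial-null chance inference — plus a
synthetic evoked-potential generator so the whole pipeline runs and is
tested end-to-end without any data download.

## The scientific problem

When people learn spatial information about a scene — say, that a goal
hides behind one of the open doors of a rendered room — does that
knowledge immediately reshape the early visual response to the same
image? The experimental design this package models answers that with
decoding: participants view rooms with 1–3 open doors (navigational
affordances) and 7–8 wall colors, first in a *scene memory* task
(one-back color matching), then in a *spatial memory* task (retrieving a
goal direction cued by wall color) on identical images. From epoched
EEG (61 electrodes × 251 samples at 250 Hz, 0–1 s post stimulus) a
classifier decodes the task, the goal direction, the door configuration
and the wall color; attribution maps localize the informative
channels/latencies; and cross-task transfer asks whether the neural code
for affordances survives spatial learning (it should not) while the code
for color does.

At its core are:

* a compact CNN of the **EEGNet family** — temporal convolution (F1
  kernels), depthwise spatial convolution across the full electrode axis
  (D filters per temporal filter), pointwise/separable convolutions to
  F2 maps, batch norm + ELU + average pooling + channel-wise dropout,
  dense readout with one logit per class — trained with class-weighted
  cross-entropy, `w_k = N/(K·N_k)`, Adam and early stopping (forward and
  backward passes implemented natively, gradient-checked);
* **Grad-CAM** on the second convolutional block: per-map weights
  `α_m = mean_t ∂y_c/∂A_m(t)`, map `L(t) = ReLU(Σ_m α_m A_m(t))`,
  upsampled to the input grid, re-projected onto electrodes through the
  energy of the depthwise spatial filters, normalized to [0, 1];
* a **binomial null**: chance is 100/k %, the exceedance threshold the
  smallest m with `P(X ≥ m) ≤ α` for `X ~ Binomial(n, 1/k)`, and a
  bootstrap of the mean difference between observed accuracy and
  binomial-null samples yields the 95% CI and one-sided p value;
* a **synthetic-EEG generator**: the full trial schedule (7 door
  configurations × colors, 6 blocks, scene before spatial, 770 trials
  per task by default, color→goal mapping, 93% behavioral accuracy) and
  epochs built from 1/f^β background noise, spatial correlation,
  class-conditional Gaussian-bump components with per-subject gain and
  latency jitter, and injectable amplitude artifacts.

## Worked example

Simulate a reduced cohort with a planted occipitoparietal task effect,
condition it, and run the task-classification experiment:

```r
library(eegdecode)

cfg <- report_config("desk", seed = 11)       # 5 subjects x 200 trials/task
cfg$simulate$scenario <- "task"
data <- build_cohort(cfg)$epochs
data
#> <epoch_set> 1966 trials x 61 channels x 251 samples @ 250 Hz [0.000, 1.000] s
#>   tasks: scene_memory=990, spatial_memory=976

rep <- run_task_classification(data, n_runs = 1, seed = 101,
                               model_args = cfg$model,
                               train_args = cfg$train, n_iter = 10000)
rep
#> <experiment_report> task_classification (2 classes, 1 run): median accuracy 73.0% vs 50.00% chance
tidy(rep)
#> # A tibble: 1 x 7
#>     run mean_accuracy diff_from_chance conf.low conf.high p.value significant
#>   <int>         <dbl>            <dbl>    <dbl>     <dbl>   <dbl> <lgl>
#> 1     1          0.73             23.0     18.1      27.9  0.0001 TRUE

r <- rep$runs[[1]]
r$threshold$accuracy_pct   # binomial exceedance threshold (per-subject n)
#> [1] 60.25641
op <- default_montage()$groups$occipitoparietal
window_mass_ratio(r$gradcam, op, 50, 250)
#> [1] 3.036494
```

Reading: the pooled network classifies held-out single trials at 73%
where 50% is chance and ~60% is the α = 0.05 binomial threshold; the
bootstrap places the accuracy 18–28 points above chance (p = 1e-4); and
the grand-mean Grad-CAM map concentrates 3× more importance in the
planted occipitoparietal 50–250 ms window than its area share — the
pipeline recovers both the effect and its location. The cross-task
dissociation experiments run the same way from
`run_affordance_generalization()` / `run_color_generalization()` on the
`"dissociation"` scenario, and `run_full_report()` executes all four
analyses on one cohort.

The methods vignette (`vignettes/eeg-decoding-methods.Rmd`) documents
the generator, the architecture, the statistics, every tunable default
and the reduced problem sizes.

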