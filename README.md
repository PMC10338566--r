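# lapcensor

Anonymize laparoscopic surgery video by detecting and censoring every frame
recorded **outside** the abdomen.

Surgical video is invaluable for research, quality management and teaching,
but the camera keeps recording while it is outside the patient — capturing
skin, tattoos, staff faces and other identifying content. `lapcensor` is a
toolkit for surgical data scientists that classifies every frame as inside
or outside the abdomen (binary, or a five-way taxonomy: abdominal cavity,
trocar, outside operation site, outside for cleaning, translucent trocar),
post-processes the predictions, and blacks out or blurs the
privacy-critical footage — then quantifies the residual risk in seconds.

## The method

A sequence classifier consumes runs of `L = 32` frames sampled at 1
frame/second, each resized to 224×224 and normalized:

```
frames → frozen conv backbone → dropout + linear (ReLU)
       → stateless LSTM → dropout 50% → linear head (2 or 5 classes)
```

The backbone is frozen (transfer learning); the stateless LSTM exploits the
multi-second persistence of each class without carrying state across
sequences. Training uses Adam on the **focal loss**

$$\mathcal{L} = -\tfrac{1}{L}\textstyle\sum_t \alpha_{y_t}(1 - p_{y_t})^{\gamma}\log p_{y_t}, \qquad \gamma = 2,$$

with inverse-class-frequency weights α, so the rare outside classes
dominate the gradient. Evaluation is a stratified 5-fold cross-validation
split by whole video (never by frame), with per-class one-vs-rest
sensitivity / specificity / F1 and a privacy report: for a video of
duration *D* with outside fraction *q*, the expected footage *at risk*
(outside kept) is *D·q·(1 − sensitivity)* and the footage *lost* (inside
censored) is *D·(1 − q)·(1 − specificity)*. Predictions are smoothed by a
privacy-safe island filter (short runs are absorbed by their surroundings,
but outside is never flipped to inside), expanded to native frame rate and
censored; everything is seeded and exactly reproducible.

Real surgical corpora are not shareable, so the package ships a seeded
synthetic video generator that emulates their structure — class imbalance
(81.4% cavity / 16.1% outside / 2.5% rest), contiguous multi-second
segments, cross-faded transitions, and colour statistics that make inside
and outside separable — letting the whole pipeline run end to end on a
laptop. See the vignette (`vignettes/inside-outside-censoring.Rmd`) for
the full model description and design rationale.

## Worked example

Published confusion counts from a binary inside/outside experiment
(611,061 of 616,113 inside frames and 123,757 of 128,079 outside frames
matched) reproduce the familiar headline metrics:

```r
library(lapcensor)
bin <- confusion_from_counts(
  matrix(c(611061, 5052, 4322, 123757), 2, 2, byrow = TRUE),
  vocab = binary_classes()
)
metrics(bin, "OUTSIDE")
#> # A tibble: 1 × 5
#>   label   sensitivity specificity precision    f1
#>   <chr>         <dbl>       <dbl>     <dbl> <dbl>
#> 1 OUTSIDE       0.966       0.992     0.961 0.964

privacy_report(0.966, 0.992, 3600, 0.172)[, 1:4]
#> # A tibble: 1 × 4
#>   duration_s outside_fraction at_risk_s lost_s
#>        <dbl>            <dbl>     <dbl>  <dbl>
#> 1       3600            0.172        21     24
```

So a one-hour video with 17.2% outside footage keeps about 21 s of outside
video un-censored at that sensitivity — the quantity to minimize.

A small end-to-end run on synthetic video (6 videos of 96–160 s; the
packaged study uses 20 videos of 120–300 s):

```r
st <- synthetic_study(seed = 0, n_videos = 6, duration_range = c(96, 160),
                      redact = FALSE)
st$glance
#> # A tibble: 1 × 7
#>   n_frames accuracy outside_sensitivity outside_specificity outside_f1 at_risk_s
#>      <int>    <dbl>               <dbl>               <dbl>      <dbl>     <dbl>
#> 1      778    0.979               0.948               0.988      0.953         9
```

Each of the 778 held-out frames was classified by a model that never saw
its video in training; 94.8% of outside frames were caught and 98.8% of
inside footage kept. With `redact = TRUE` the held-out videos are also
censored and re-decoded to verify that no predicted-outside frame survives.

A thin command line wraps the same functions:

```sh
inst/cli/lapcensor synth    --out demo                      # synthetic video + truth track
inst/cli/lapcensor predict  --model ckpt.rds --video demo/synth00000.tiff --out l.csv
inst/cli/lapcensor evaluate --pred l.csv --truth demo/synth00000.csv --report rep.json
inst/cli/lapcensor redact   --video demo/synth00000.tiff --labels l.csv --out anon.tiff
```

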