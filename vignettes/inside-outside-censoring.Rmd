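---
title: "Inside-outside discrimination and censoring of laparoscopic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside-outside discrimination and censoring of laparoscopic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A laparoscopic camera spends most of a procedure inside the abdomen, but it
is switched on before the first incision, taken out for lens cleaning, and
left running after closure. The extra-abdominal footage can show the
patient's skin, tattoos, staff faces — anything that identifies people —
and is the reason surgical video cannot simply be shared for research,
quality management or teaching. Once every outside frame is censored, the
remaining video is anonymous, and the goal is to do that *automatically*
while losing as little intra-abdominal footage as possible.

`lapcensor` implements the full pipeline: a frame-class taxonomy and
interval annotation model, a sequence classifier, stratified by-video
cross-validation, evaluation centred on the privacy-critical outside class,
and the censoring step itself. Because real surgical corpora are not
shareable, the package also contains a seeded synthetic video generator
that reproduces the *structure* of such corpora, so that every stage is
testable end to end on a desktop.

## Class taxonomy

Five frame classes, mapped onto a binary outcome:

| class | binary | meaning |
|---|---|---|
| `ABDOMINAL_CAVITY` | INSIDE | cavity fills more than half the frame |
| `TROCAR` | INSIDE | view down a solid trocar |
| `OUTSIDE` | OUTSIDE | operating field, staff, drapes, skin |
| `CLEANING` | OUTSIDE | camera out for lens wiping |
| `TRANSLUCENT_TROCAR` | OUTSIDE | skin visible through a translucent trocar wall |

The mapping is total and fixed; anything extra-abdominal — including skin
glimpsed through a translucent trocar — is OUTSIDE and must be censored.
Unknown class tokens are hard errors everywhere: a privacy pipeline fails
closed, never open.

Annotations are carried as half-open intervals `[start_s, end_s)` in
seconds that exactly tile `[0, duration_s)`. Frame `i` (0-based) at frame
rate `fps` lives at `i / fps`, so half-open tiling counts every frame
exactly once. Adjacent equal-label intervals are merged on load rather
than rejected, because annotation tools cut long videos into fixed-length
sections and split intervals arbitrarily at the cuts. Overlaps and gaps,
by contrast, are validation errors naming the offending span.

## The synthetic corpus generator

`sample_scenario()` draws an ordered list of `(class, duration)` segments.
Classes are drawn with probability proportional to
`fraction / mean_duration` and durations from a shifted gamma distribution
(shape 2, minimum 2 s), so the *expected* per-class time share equals the
requested fractions while each class occupies contiguous multi-second
runs — long cavity episodes, short trocar transits, 1–4 s
translucent-trocar glimpses. The default fractions (81.39% cavity, 1.39%
trocar, 16.07% outside, 1.08% cleaning, 0.07% translucent trocar) mirror
the imbalance of annotated clinical corpora. The default segment-length
means (90 / 4 / 25 / 10 / 2.5 s) are one-time choices of what a surgical
video of this kind plausibly looks like: cavity episodes dominated by long
dissection phases, outside episodes of a few tens of seconds around
insertion and cleaning.

Two details matter for unbiasedness and realism:

* **Stationary start.** A window cut from a segment process
  under-represents long-duration classes if it always opens at a segment
  boundary and truncates the final segment. The generator therefore opens
  the window *mid-segment*: the first class is drawn by time share, its
  total length from the length-biased law, and the window sees a uniform
  residual. Expected time shares then equal the requested fractions in any
  window, which the test suite confirms by Monte-Carlo over 200 scenarios.
* **Hard labels through transitions.** Segment boundaries cross-fade the
  *pixels* over `transition_s` (default 0.5 s) but never the labels: each
  frame keeps the label of the segment owning its timestamp. Transition
  frames are exactly the hard cases a per-frame annotation produces, and
  the classifier must cope with them.

Appearance is deliberately schematic: the cavity is red-dominant with a
bright optical centre; trocar classes draw a dark vignette ring; outside
frames are blue drape with skin-coloured patches; cleaning frames are a
bright, horizontally streaked cloth. Mean colours are chosen so inside and
outside are separable on mean channel statistics (a thresholding
classifier reaches at least 95% frame accuracy — this floor is asserted in
the tests and guarantees the learning task is solvable at desk scale).
Per-frame Gaussian noise (sd 0.02), seeded by scenario seed and frame
index, prevents degenerate constant-frame learning while keeping renders
bit-reproducible. What the generator does **not** emulate: instruments,
smoke, specular highlights, motion, faces, or any photorealistic detail —
so passing tests show the pipeline's machinery works, not that the trained
weights transfer to clinical video.

Videos are written as multi-page 8-bit RGB TIFF stacks (lossless, readable
everywhere); containers that require an external codec are refused with an
error naming the container. The desk-scale render geometry is 160×90 at
5 fps, configurable up to full clinical resolution.

## From video to model input

Classification runs on a subsampled grid, 1 frame/second by default, which
keeps a multi-hour corpus tractable (a 207-hour corpus becomes ~744k
frames). Each sampled frame is bilinearly resized to 224×224 and
normalized per channel with mean `[0.485, 0.456, 0.456]` and sd
`[0.229, 0.224, 0.225]`. The third mean component is kept at the
configured 0.456 — note this differs from the conventional ImageNet blue
mean (0.406); both constants are overridable.

Frames are cut into non-overlapping sequences of `L = 32` consecutive
sampled frames (32 s of video at the default rate). In training mode a
trailing remainder is dropped; in inference mode the last chunk is padded
by repeating its final frame and the pad count recorded, so every frame
receives exactly one prediction.

Cross-validation folds are assigned to whole videos, never frames. The
fold builder is a deterministic greedy rule: within each operation type,
videos sorted by duration descending are assigned to the fold with the
smallest running total duration (ties to the lowest fold index). This is a
reproducible stand-in for manual stratification; on a 100-video synthetic
roster it keeps the max/min fold duration ratio within 1.25.

## The classifier

The architecture is a frozen convolutional feature extractor followed by
trainable upper layers:

```
frames -> [frozen conv backbone] -> dropout + linear (ReLU)
       -> stateless LSTM -> dropout 50% -> linear head (2 or 5 classes)
```

The LSTM is *stateless*: its hidden state is reset for every 32-frame
sequence, so a sequence's output never depends on previously processed
sequences — classification exploits short-range temporal coherence (a
class persists for seconds, not isolated frames) without memorising whole
procedures. Sequence order within a video therefore never affects outputs,
which the tests assert.

Two backbones are registered. The full-scale configuration uses
ImageNet-pretrained AlexNet feature layers (feature dim 9216, FC width
4096, LSTM hidden 512) and requires a locally supplied weights file —
nothing is ever downloaded. For CPU-scale work the default `tiny_conv`
backbone is three 3×3 convolution blocks with frozen random filters
feeding a 64-dimensional pooled feature (16 channels × a 2×2 spatial grid,
so coarse layout such as a vignette ring survives pooling). Frozen random
convolutions are a classical cheap feature extractor; on colour/texture-
separable scenes they are entirely sufficient. Each backbone preset
carries matched upper-layer widths (`tiny_conv`: FC 128, hidden 64), since
a 4096-wide FC is sized to AlexNet's 9216-dimensional features, not to a
64-dimensional toy feature.

Which layers train is explicit: `trainable_set` defaults to
`{fc, recurrent, head}`, and a strict transfer-learning mode trains the
head alone. The backbone is *never* trainable, and the tests assert
bit-identity of all frozen parameters after training. All forward and
backward passes (convolution via im2col, LSTM backpropagation through
time, Adam) are implemented in plain BLAS-backed R and verified against
finite-difference gradients in the test suite.

### Focal loss

Class imbalance (~4:1 inside:outside binary, up to 1000:1 in the five-way
task) makes plain cross-entropy concentrate on the easy majority. The
focal loss scales cross-entropy by a modulating factor:

$$\mathcal{L} = -\frac{1}{L}\sum_{t=1}^{L} \alpha_{y_t}\,(1 - p_{y_t})^{\gamma}\,\log p_{y_t}$$

so confidently correct frames contribute vanishing loss and gradient,
focusing training on hard, rare classes. Defaults: `gamma = 2`, `alpha` =
inverse class frequency normalized to mean 1 over the classes present
(a class absent from the training labels gets weight 0, with a warning).
`gamma = 0` with unit `alpha` reduces *exactly* to cross-entropy, which
the tests verify to 1e-9; probabilities are clamped at 1e-12 so the loss
is never NaN or infinite.

### Prediction

Per-frame labels are the row-wise argmax of the scores, with a fail-closed
tie rule: an exact tie is broken toward the tied class mapping to binary
OUTSIDE (lowest class index first). A frame the model cannot decide is
censored, not kept.

## Training

Adam with learning rate 1e-4, betas (0.9, 0.999), epsilon 1e-8, batches of
8 sequences, 5 epochs, no early stopping, no schedule — deliberately
minimal defaults. One master seed drives fold assignment, initialization,
shuffling and dropout, so two runs with the same seed produce bit-identical
weights. A leakage guard asserts before each fold that no test-fold video
contributes a training sequence.

The packaged synthetic study (`synthetic_study()`) — 20 videos of
120–300 s at 160×90/5 fps, 5-fold CV, 5 epochs, binary task — uses
learning rate 1e-2 as its configuration: with the tiny backbone's widths
and only ~60 Adam steps per fold, a rate an order of magnitude larger than
the full-scale default is the standard choice for the schedule length.
Because the backbone is frozen, per-frame features are extracted once and
reused across epochs and folds, which is what makes CPU training take
seconds rather than hours. These problem sizes (and the 160×90/5 fps
render) are the package's chosen desk-scale study conditions; all of them
are arguments, not constants.

## Evaluation and privacy arithmetic

Confusion matrices are truth × prediction over the canonical vocabulary;
five-way matrices collapse onto the binary task by summing both axes under
the class mapping (confusions within the same binary group — e.g. trocar
frames predicted as cavity — land on the binary diagonal and are not
privacy errors). Per-class metrics are one-vs-rest sensitivity,
specificity, precision and F1; a ratio with zero denominator is reported
as `NA`, never 0. Display rounds percentages and F1 to two decimals; mean
± sd across folds uses the sample (n−1) standard deviation.

For the outside class the two numbers that matter are its sensitivity
(did we catch all outside footage?) and its specificity (how much inside
footage is needlessly censored?). `privacy_report()` converts them into
seconds: for a video of duration $D$ with outside fraction $q$,

* seconds **at risk** (outside kept): $D\,q\,(1 - \text{sensitivity})$
* seconds **lost** (inside censored): $D\,(1-q)\,(1 - \text{specificity})$

e.g. a one-hour video with 17.2% outside footage and sensitivity 96.6%
leaves about 21 s at risk. Both values are rounded to whole seconds for
display, with exact values kept alongside.

## Smoothing, expansion, censoring

Classifier errors on real video are mostly isolated frames or very short
runs. The post-processing filter removes such islands: any maximal run
shorter than `min_island_s` (default 2 s) whose two neighbouring runs
share a label is reassigned to that label. All qualifying runs are flipped
simultaneously per pass, against the pass-start state, and the rule is
iterated to a fixpoint (each active pass strictly reduces the number of
runs, so termination is guaranteed); edge runs are never touched. The
default mode is `privacy_safe`: an OUTSIDE run is *never* reassigned to
INSIDE, because a flipped outside frame is a privacy breach while a
flipped inside frame only loses data. The symmetric variant is available
where data yield matters more.

Classification runs at 1 frame/s but anonymization must cover every native
frame: each sampled label governs all frames of its sampling period, and
trailing frames inherit the last label. Censoring replaces every
OUTSIDE-labelled frame — black (all-zero pixels, the default) or a heavy
box blur (kernel at least 1/8 frame width; weaker anonymization, kept for
reviewer workflows). Black censoring is idempotent; blur is not (re-
blurring changes pixel statistics), which is one more reason black is the
default. A label/frame count mismatch aborts before any output is
written, and the manifest records the censored half-open native frame
ranges. Neither rendition is claimed to be the clinically "correct" one;
the choice is a policy argument.

## Numerical choices and degenerate inputs

* Interval arithmetic uses a 1e-9 tolerance for tiling checks; frame
  counting clamps to `round(duration × fps)` indices so counts are exact.
* Softmax subtracts the row maximum; focal loss clamps probabilities at
  1e-12; argmax ties use a 1e-12 band.
* Empty training sets, videos shorter than one sequence, empty timelines
  and zero-duration tracks raise errors rather than degenerate silently.
* Dropout is inverted (scaled at train time), so evaluation is the
  identity path and repeated eval calls are bit-identical.

## Limitations

* The synthetic generator validates machinery, not clinical performance;
  no claim about real surgical video follows from the packaged study.
* The AlexNet-scale configuration requires externally supplied pretrained
  weights; the package never downloads anything.
* Videos travel as TIFF frame stacks; integrating a codec-backed container
  is deliberately out of scope here.
* Bidirectional recurrence, attention variants, data augmentation and
  multi-annotator adjudication are out of scope.
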