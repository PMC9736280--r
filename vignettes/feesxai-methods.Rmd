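---
title: "Explainable aspiration detection in swallowing endoscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable aspiration detection in swallowing endoscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(feesxai)
```

## The problem

Flexible endoscopic evaluation of swallowing (FEES) produces long videos in
which the clinically critical event — aspiration, i.e. swallowed material
passing the vocal cords into the airway — may occupy only a handful of
frames. `feesxai` implements a pixel-level, frame-by-frame pipeline for this
detection task whose output is deliberately *inspectable*: instead of a
per-video classification, it produces per-frame segmentations of three
anatomical/clinical structures (the glottis as region of interest, the vocal
cords, and the aspirated bolus), a pixel-count timeline over the whole
video, and a short list of "meaningful frames" — runs of consecutive frames
with detected aspiration — that a clinician can verify directly.

Because clinical FEES recordings are protected patient data, the package
ships a synthetic scene generator that emulates the relevant structure of
such footage with exact ground truth. All quantitative claims made by the
test suite and the acceptance script are claims about this synthetic family,
not about clinical data.

## The segmentation model

The segmentation network is a 2D U-Net: an encoder--decoder with skip
connections, zero-padded 3x3 convolutions (output resolution equals input
resolution), batch normalization, PReLU activations, dropout in the decoder,
and a 1x1 convolution head. Filters double at each encoder level from
`base_filters`; the deepest stage has `base_filters * 2^(depth-1)` filters.
The three output channels pass through *independent sigmoids* rather than a
softmax: the classes overlap by construction (an aspirated bolus lies inside
the glottis ROI), so mutually exclusive labeling would be wrong.

Training minimizes the soft Dice loss, `1 - mean_c (2*sum(p*t)+eps) /
(sum(p)+sum(t)+eps)` with `eps = 1` (the evaluation-time Dice uses `eps = 0`
and the exact pixel-count formula), using Adam. Patches are sampled in three
strata: 80% contain the glottis ROI, 25% of those show aspiration, and the
remainder come from frames labeled as not containing the ROI — the negative
stratum is what suppresses false positives when the model is later run over
*all* frames of a video. Every `val_interval` iterations the model is scored
on all validation frames by per-class Jaccard (binarized at 0.5; frames
where both reference and prediction are empty for a class are skipped for
that class; frame scores are averaged per class, then across classes).
Training stops after `patience` validations without a strict improvement of
the mean Jaccard, and the state with the highest mean Jaccard is retained
("early stopping"). Improvement means strictly greater than the best so far;
no minimum delta is applied.

Since no deep-learning framework is available to R in this package's
dependency footprint, the network — forward pass, backpropagation, Adam —
is implemented in the package itself (RcppArmadillo kernels for
convolution via im2col/GEMM, max-pooling, batch-norm and PReLU; R
orchestration for the architecture). Every layer's analytic gradient is
verified against central finite differences in the test suite.

## Preprocessing and augmentation

Frames are downscaled by a factor of two (2x2 block averaging) to remove
comb artifacts of interlaced recording; masks are 2x2 max-pooled so that any
annotated pixel survives. Augmentation is applied online, per sampled patch:
rotation, zoom *in* up to 1.5x (the zoom range is one-sided by design),
left-right mirroring, a contrast factor, and a brightness shift bounded by
25% of the patch mean. Geometric transforms are applied identically to image
(bilinear) and masks (nearest neighbour). Two ranges are not dictated by the
training recipe and are package choices exposed in the configuration:
rotation +/- 30 degrees and contrast in [0.75, 1.25].

## Post-processing

Probability maps are binarized at 0.5 (threshold configurable; `>=` at the
boundary), the *largest connected component* of the glottis channel is kept
(8-connectivity by default, configurable to 4; equal-size ties break to the
component met first in row-major scan order), and the vocal-cord and
aspiration masks are intersected with that selected component. The
restriction uses the post-component-selection glottis mask, so any
aspiration blob outside the surviving glottis component is discarded. No
minimum-size filter is applied to aspiration blobs and no morphological
smoothing or temporal filtering is performed.

## Evaluation conventions

* Segmentation quality is Dice, computed only on frames whose reference
  contains the class; detection quality is frame-level.
* A frame counts as a true positive when aspiration was segmented and its
  Dice overlap with the reference is greater than zero. The degenerate case
  "prediction and reference both non-empty but zero overlap" is counted as
  one false positive *and* one false negative (the detector both raised a
  spurious finding and missed the true one); it is tallied separately as
  `mismatch` so the convention is auditable. The overlap rule defines only
  the TP side; this completion is a package decision.
* Two empty masks score Dice/Jaccard 1.0 (an absent structure correctly
  predicted absent); frame-level absence is handled by the detection
  outcomes and by the false-positive frame rate, not by the Dice scores.
* The false-positive glottis frame rate is the fraction of glottis-absent
  frames with at least one (configurable) falsely segmented glottis pixel —
  the strictest reading of a "false positive frame".
* The bolus-size question ("are larger boluses easier to detect?") is
  answered by a Spearman rank correlation (average ranks on ties, two-sided
  p) between reference aspiration size in pixels and aspiration Dice.

## The synthetic scene family

Each video renders a schematic laryngeal scene: a dark elliptical glottal
opening whose minor axis oscillates (open/close cycle), two bright
vocal-cord bands flanking it, and a tissue-like shaded background with
endoscope-style vignetting. The annotated glottis *ROI* is the enclosing
laryngeal-inlet ellipse containing both the opening and the cord bands —
this is what makes the ROI-restriction step of post-processing coherent:
cords and aspiration both lie inside the annotated ROI, as in the clinical
annotation scheme. Per-frame Bernoulli draws make the glottis invisible in a
configurable fraction of frames (those frames carry no structure masks and
the `glottis_visible = FALSE` label), or shift it so it clips the image
edge (the hard partial-visibility case). Aspiration events are scheduled by
a Poisson draw (rate per 100 frames) with uniform starts and durations,
merged when overlapping; within an event a bolus blob is rendered *inside*
the glottis ROI with a size profile rising and falling over the event.
Three bolus appearance types mirror the clinically annotated consistencies:
slurry (textured, mid-intensity), saliva (small, bright), liquid
(translucent, low contrast). Frames are corrupted with specular
reflections, Gaussian blur and bounded brightness jitter. Frames inside a
scheduled event are always rendered with a visible glottis so the logged
ground-truth intervals are temporally coherent.

The generator makes no photorealism claim. What passing tests show is that
the pipeline's machinery — sampling, optimization, early stopping,
post-processing, metrics, timeline extraction — is correct and that the
model class can learn this controlled family; they do not show clinical
performance, which requires the protected recordings.

## Numerical and design choices

* Coordinates are row-major and 0-based at the frame level; pixel (i, j) is
  (row, column).
* Masks are stored one PNG per class (0/255) because classes overlap; a
  single label map cannot represent them.
* The glottis state (open/closed/obscured) is annotated but collapsed into
  a single ROI class for training; the network has one glottis output.
* Video-level splitting uses `round(fraction * n)` per split with the
  rounding remainder absorbed by the training set; for 92 videos and
  fractions (0.772, 0.065, 0.163) this yields 71/6/15.
* Dice smoothing `eps = 1` in the loss; `eps = 0` in all reported metrics.
* `peak_frame` of an event run is the earliest argmax; equal-size
  connected components break ties by scan order — all tie-breaks are
  deterministic.
* Checkpoints are RDS files with a JSON sidecar; all figure exports are
  ggplot2.

## Desk-scale study conditions

The acceptance study (`scripts/acceptance.R`, mirrored by the end-to-end
acceptance test) runs the full pipeline at a reduced scale chosen once:
eight 96x128-pixel videos of 70 frames (five training, one validation, two
held-out test; bolus types cycling through slurry/saliva/liquid; event rate
6 per 100 frames), a reduced network with 8 base filters and depth 3,
96x96 patches, batch 8, Adam at 1e-3, validation every 100 iterations,
patience 5, at most 800 iterations. The full-scale defaults
(`base_filters = 32`, `depth = 4`, 288x352 patches, batch 16, learning rate
1e-4, validation every 500 iterations, patience 15) remain the package
defaults. On the held-out scenes the study reports the glottis/vocal-cord/
aspiration median Dice, the frame-level detection metrics, the
false-positive glottis frame rate, timeline event recall (fraction of
logged events of >= 3 frames hit by a detected run with default
`min_consecutive = 3`, `min_pixels = 1`), and the size-versus-Dice rank
correlation.

## Known limitations

* Purely 2D: no temporal context; consecutive-frame coherence enters only
  through the timeline post-analysis.
* The synthetic family has far simpler appearance statistics than clinical
  footage; aspiration Dice achievable here is optimistic.
* The run-length rule for "meaningful frames" is a formalization of
  "several consecutive frames"; `min_consecutive = 3` is a default, not a
  claim.
* Timeline pixel counts use post-processed masks (after ROI restriction),
  consistent with the pipeline's output ordering.
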