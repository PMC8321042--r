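---
title: "Methods: a staged multiple-instance cascade for HER2 status from H&E slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a staged multiple-instance cascade for HER2 status from H&E slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2cascade)
```

## Problem and model

HER2 status is a binary, slide-level label, but the evidence for it is
distributed over a gigapixel H&E image. `her2cascade` treats this as a
multiple-instance learning (MIL) problem: the slide is a *bag* of tiles,
only the bag is labelled, and the slide call is assembled from per-tile
predictions. The cascade has five stages, each with a file-based boundary
(CSV manifests, probability tables, feature tables) so any stage can be
run, replaced or tested in isolation.

**Stage 1 — tiling and background filtering.** Tiles of side `tile_size`
(default 512 px) are cut at origins $0, s, 2s, \dots$ for stride $s$
(default: the tile size, i.e. non-overlapping); partial tiles at the
right/bottom borders are discarded, so the count is
$\lfloor (W-t)/s + 1\rfloor \cdot \lfloor (H-t)/s + 1\rfloor$. A tile's
brightness is its mean Rec. 601 luma ($0.299R + 0.587G + 0.114B$) scaled
to $[0,1]$; tiles *strictly* brighter than 0.8 are dropped as background.
Both the luma weights and the threshold are arguments. The threshold is
interpreted on the $[0,1]$ scale — the only reading under which a
"brightness greater than 0.8" rule separates near-white background from
stained tissue.

**Stage 2 — two branches.** 2A passes every surviving tile forward. 2B
first applies a binary cancer/no-cancer tile classifier and keeps tiles
with predicted cancer probability $\ge 0.5$ (a tie counts as cancer,
consistent with the $\ge$ convention used by the indicator $G$ below).
Four-class tile labels are collapsed to binary ones by a total map
(normal, benign → no cancer; in-situ, invasive carcinoma → cancer);
anything else is rejected rather than silently defaulted.

**Stage 3 — weakly supervised tile classifier.** Every tile inherits its
slide's label, and a classifier is trained to emit $p_{ij}$, the
probability that tile $i$ of slide $j$ is HER2-positive. Weak labels are
intrinsically noisy — a positive slide contains many tiles without
HER2-relevant morphology — which is precisely what the slide-level
features are designed to absorb.

**Stage 4 — slide features.** With $T$ tiles and
$G(p) = \mathbf{1}\{p \ge 0.5\}$:

$$P_1^* = \tfrac1T \sum_i p_{ij}, \qquad P_1 = \mathbf{1}\{P_1^* \ge 0.5\}$$
$$P_2 = \mathbf{1}\Big\{\tfrac1T \sum_i p_{ij}\,G(p_{ij}) \ge 0.66\Big\},
\qquad P_3 = \mathbf{1}\Big\{\tfrac1T \sum_i G(p_{ij}) \ge 0.35\Big\}$$
$$F_h = \tfrac1T \sum_i \mathbf{1}\{p_{ij} \in [h, h+0.1)\},
\quad h \in \{0.5, 0.6, 0.7, 0.8, 0.9\}.$$

All comparisons are $\ge$ exactly as written, with no floating-point
tolerance: the features are means of well-scaled numbers and the
thresholds are only attained by exact-decimal inputs. Three deliberate
readings documented here because the defining text admits alternatives:

* $P_2$ divides by $T$, not by the number of super-threshold tiles. The
  accompanying prose ("average of the probabilities for tiles having
  probability ≥ 0.5") suggests the latter; the formula as printed divides
  by $T$, and the formula wins. The prose reading is available as
  `positivity_P2(..., prose_variant = TRUE)`.
* The top histogram bin is closed, $[0.9, 1.0]$: a strictly half-open bin
  would silently lose certain-positive tiles ($p = 1$). Switchable via
  `closed_top = FALSE`. A useful consequence (and a property test):
  $\sum_h F_h$ equals the fraction of tiles with $p \ge 0.5$.
* An empty probability vector (every tile filtered away) is an error
  naming the slide, not a default prediction — fabricating a call for a
  slide with no evidence would be worse than failing loudly.

The thresholds 0.5 / 0.66 / 0.35 are parameters defaulting to these
values; no derivation for 0.66 and 0.35 is available, so they are treated
as given constants.

**Stage 5 — aggregation.** Either the majority vote of $(P_1, P_2, P_3)$
(positive iff at least two indices are 1; three binary voters cannot tie)
or a small fully-connected "tabular learner" on $(P_1^*, F_{0.5},
\dots, F_{0.9})$ with hidden layers 500–250–125 and a sigmoid output,
thresholded at 0.5. The binary indices are excluded from the tabular
feature set by default (they add no information beyond $P_1^*$ and the
$F_h$); `include_indices = TRUE` restores them for experimentation.

## Learners: design choices

No deep-learning framework is part of this package's dependency set; the
two image classifiers and the tabular learner share one hand-written
fully-connected network (`R/mlp.R`): ReLU hidden layers, sigmoid output,
binary cross-entropy, mini-batch Adam (batch 32), He initialisation, and
a one-cycle learning-rate schedule (linear warm-up over the first 30% of
steps to `lr_max`, cosine anneal to `lr_max`/100). Two training phases
are supported — output-layer-only ("head"), then full network — mirroring
standard fine-tuning practice; the cancer filter uses 3 + 3 epochs by
default, the HER2 classifier 3.

The image classifiers are split into a pluggable *backbone* (tile pixels
→ feature vector) and this network as the head. The desk-scale
`"colorstat"` backbone summarises a tile by 13 colour/texture statistics
(channel means and standard deviations, mean luma, dark- and mid-tone
fractions, saturation and value means, circular hue means). That is
sufficient by construction for the synthetic cue (below) and trains in
seconds on a CPU; it is *not* claimed to capture real tumour morphology.
`"densenet201"` / `"resnet152"` name the full-scale presets and require
an external pretrained feature provider, which is out of scope here.

Two monitored-metric conventions deserve a note: "precision as loss"
(Stage 3) and "accuracy as loss" (Stage 5B) are not differentiable, so
optimisation is by cross-entropy with the named metric computed and
logged per epoch — the only trainable reading.

Augmentation flags {flips, rotations, zoom, warp, luminosity, contrast}
are accepted; flips/rotations act on the pixel array and
luminosity/contrast jitter the tile photometrically. Zoom and warp are
no-ops under the colorstat backbone, whose features are invariant to them
by construction.

Defaults left open by the study design and fixed here: mini-batch size 32,
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), `lr_max` 0.02 for tile heads
and 0.01 for the tabular learner, 200 tabular epochs, features
standardised by training-set mean and standard deviation. These are
config fields, not claims of fidelity.

## The synthetic-data module

Real HER2-labelled slide sets are not redistributable, so the package
ships a generator that emulates exactly the properties the cascade relies
on:

* **Slides** (`generate_synthetic_slide()`): a grid of `tile_px` cells;
  background cells near-white (target mean gray `background_brightness`,
  default 0.95 — above the 0.8 drop threshold), tissue cells an
  eosin-pink base with haematoxylin-blue nuclear blobs (mean gray ≈
  0.6–0.7, well below it). The planted positive cue is a hue shift toward
  purple plus roughly doubled nuclear-blob density — a colour/texture
  signal a small classifier can learn in seconds, standing in for cancer
  morphology. The generator records the per-cell ground truth (tissue /
  cue), which tests compare against the Stage-1 filter (≥ 85% agreement
  required) and use as oracle models for Stages 2B–3.
* **Probability bags** (`generate_probability_bags()`): per-tile
  probabilities drawn from two Beta components with configurable means
  (defaults 0.2 and 0.8) and common concentration 10 — any unimodal pair
  on $[0,1]$ would do; Beta makes the variance explicit
  ($m(1-m)/(k+1)$), which the distributional tests use. Negative slides
  draw only from the low component; in positive slides each tile is
  high-component with probability `positive_tile_rate_in_positive_slides`
  (default 0.6), so bag composition is itself stochastic, as in real
  slides.

All randomness flows through a single per-call seed (`withr::with_seed`);
no global random state is read or written, and identical spec + seed is
bit-identical output. Cohort labels are interleaved so contiguous
train/test splits keep the class balance.

What the generator does **not** emulate: stain variability and scanner
artefacts, spatial correlation between neighbouring tiles, tissue-level
morphology (glands, stroma), the weak and *partial* correlation between
cancer presence and HER2 status, or class imbalance. Passing the
synthetic recovery tests therefore demonstrates that the pipeline's
plumbing, features and learners are correct and can extract a planted
MIL signal — not that the method reaches any particular accuracy on real
H&E slides. Note one deliberate conflation: the default cohort uses a
single visual cue for "HER2-positive", so an *oracle* cancer filter would
strip every tile from negative slides; tests of the 2B branch use a
cohort where both classes carry the cue at different rates (0.7 vs 0.3),
which is the realistic situation (cancer is present in HER2-negative
slides too).

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which every planted-signal check is
comfortably stable: 64-px tiles on 512×320 synthetic slides (40 grid
cells each), cohorts of 50 slides split 30/20, probability-bag
experiments with 200 bags of 50 tiles, and the colour-statistic backbone
with a 32–16 head. Full-scale settings (512-px tiles, deep pretrained
backbones) are reachable through the same configuration objects.

Other numerical decisions: probabilities are validated into $[0,1]$ at
every module boundary; the two-class score for a tile is the sigmoid
output $p$ with the negative-class score $1-p$ (class order fixed as
negative = 0, positive = 1 everywhere); undefined evaluation ratios
(zero denominators) are reported as `NA` with a warning; duplicate slide
ids and missing labels/columns are hard errors naming the offender.

## Known limitations

* The desk backbone's colour statistics cannot represent spatial
  arrangement; on real slides a convolutional backbone is required, and
  the package only names those presets.
* Training the MLP is deterministic given a seed, but is a small
  full-precision CPU implementation — it makes no attempt at the
  throughput of a GPU framework.
* The cascade's published operating points (e.g. the 0.66 and 0.35
  thresholds) are taken as given; no re-calibration is performed.
* Pyramidal/tiled TIFF is read at the rasterised level supplied by the
  caller; proprietary scanner formats and magnification resampling are
  out of scope, with `microns_per_pixel` carried as metadata only.
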