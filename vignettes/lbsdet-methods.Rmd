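---
title: "Inside lbsdet: architecture accounting, ripeness grading and synthetic scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside lbsdet: architecture accounting, ripeness grading and synthetic scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lbsdet` re-implements, in plain R, the bespoke components of a lightweight
single-stage strawberry-ripeness detector: an adaptive-weighted downsampling
block, a gated "star" bottleneck, a learnable-weight bidirectional feature
pyramid, the assembled network with its ablation variants and their exact
parameter/FLOP budgets, the five-grade ripeness scoring procedure used to
annotate fruit images, the standard detection metrics, and a synthetic scene
generator that makes the whole pipeline testable at desk scale without the
original photographic dataset. Training is deliberately out of scope; every
network here is an inference-form object whose purpose is exact accounting,
deterministic forward evaluation and gradient-flow checking.

## The detector and its variants

The baseline follows the publicly documented YOLO11 n-scale layout:
stride-2 convolutions to P5, C3k2 split-transform-merge stages, an SPPF
pooling stage and a position-sensitive attention stage at the deepest level,
then a PAN-style neck and an anchor-free decoupled head (distribution-focal
box regression with 16 bins per side) at strides 8/16/32. All convolutions
are stored in inference form: batch normalisation is folded into the kernel
and bias, so a "conv" here owns `k*k*c_in/g*c_out` weights and `c_out`
biases. The fused parameterisation is also the counting convention — it is
what reproduces the published per-variant budgets, and it is the natural
description of a network that is never trained inside this package.

Three switches define the ablation grid (`variant_spec()`):

* **LAWDS** (`use_lawds`) replaces the backbone downsampling convolutions at
  stages 3, 5 and 7. The block keeps its channel count: an attention branch
  (3×3 average pool, stride 1; then a 1×1 convolution `C -> C`) scores the
  input at full resolution; the scores are regrouped into non-overlapping
  2×2 windows (row-major: top-left, top-right, bottom-left, bottom-right)
  and softmax-normalised within each window; a grouped stride-2 3×3
  convolution expands `C -> 4C` with `g = max(1, C/16)` groups, its output
  channels `4(c-1)+1..4(c-1)+4` aligned with the four window slots of
  channel `c`; the normalised weights fuse the four candidates into one
  output pixel. Because the block preserves channels, the stage-7
  replacement leaves P5 at 128 channels and the following C3k2 stage widens
  to 256 — its input convolution simply adapts.
* **C3k2_Star** (`use_c3k2_star`) swaps every C3k2 stage's transform modules
  for chains of star blocks while keeping the outer split-transform-merge
  skeleton (1×1 split convolution, transform chain on one branch,
  concatenation, 1×1 merge convolution). A star block is
  `Y = X + DW2(G(relu6(F1(DW(X))) * F2(DW(X))))`: a 7×7 depthwise
  convolution, two parallel 1×1 expansions by the ratio `mlp_ratio` combined
  by a ReLU6-gated element-wise product, a 1×1 reduction, a second 7×7
  depthwise convolution, and a residual connection with optional stochastic
  depth (rate 0 by default; evaluation mode is always deterministic).
* **BiFPN** (`use_bifpn`) replaces the neck with a bidirectional weighted
  fusion pyramid at a unified width: 1×1 projections bring P3/P4/P5 to the
  neck width, a top-down pass and a bottom-up pass fuse neighbouring levels
  with `O = sum_i relu(w_i) I_i / (sum_j relu(w_j) + 1e-4)` (one learnable
  scalar per edge, initialised to 1), the bottom-up P4 node also receives
  the same-level skip edge, and each fused node feeds a chain of C3k2-style
  transform modules. Neck downsampling is depthwise-separable.

## Calibrated design constants

The published per-variant budgets pin down the free constants of the
improved blocks; `lbs_design()` freezes the calibrated values:

* `mlp_ratio = 19/16` and star-chain depth 2 where the stage previously
  carried a nested-CSP (C3k) transform, depth 1 where it carried a plain
  bottleneck. Star substitution must *shrink* the network by about 0.11 M
  parameters; expansion ratios near the StarNet default of 3 or 4 grow it
  instead, so the ratio is necessarily fractional and close to 1. With
  these values the star-only variant counts 2.47 M parameters against the
  baseline's 2.58 M, exactly matching the published ablation row.
* The fusion neck runs at width 64 with twelve transform modules — five
  after the P3 node (three nested-CSP flavour, two plain), two after the
  top-down P4 node, two after the bottom-up P4 node and three after the P5
  node. This distribution reproduces the neck-only budget (1.92 M), the
  downsampling + neck budget (1.63 M), the fully combined budget (1.60 M),
  and the headline compute cost at 640×640 (6.6 GFLOPs, versus 6.5 for the
  baseline) simultaneously. Width 64 is also the only natural choice that
  keeps every star width an integer multiple of 16, which the fractional
  expansion ratio requires.

One published number is *not* reproducible: the downsampling-only variant is
printed as 2.24 M, yet the same substitution between the neck-only and the
combined rows moves the count by −0.29 M, not −0.34 M. The backbone is
identical in both substitutions, so no context-independent block can satisfy
both deltas; the printed ablation table is internally inconsistent by about
0.05 M. This package's LAWDS follows the block's published parameterisation,
which lands on the −0.29 M side: the downsampling-only variant counts
2.29 M here, and the other five rows are reproduced exactly.

## FLOP accounting

`estimate_flops()` propagates shapes through the layer graph and counts, at
the operator level, one multiply-accumulate per kernel tap per convolution
output element, one op per output element for the (folded) normalisation or
bias and one for a non-trivial activation, `k²` per pooled element, the
attention matrix products and softmax, four ops per upsampled element, one
per residual addition, and `n+1` per element of an `n`-input fusion node.
The total is reported as FLOPs under the 1 MAC = 2 FLOPs convention at
640×640. Counting kernel MACs alone would undercount the baseline by about
3% relative to its published 6.5 G figure; the full operator-level
convention reproduces 6.5 G (baseline) and 6.6 G (full variant) at one
decimal place.

## Ripeness grading

The annotation pipeline mirrors how the five maturity grades are assigned
from imagery:

1. **Segmentation** (`segment_foreground()`): box-initialised iterated graph
   cuts. Pixels outside the box are definite background; the box interior
   starts as foreground. Each of the (default 5) iterations refits
   diagonal-covariance Gaussian colour mixtures (K = 5) to both regions —
   seeded deterministically from luminance quantiles, so the pipeline is
   RNG-free — and solves an s-t minimum cut on the 4-connected pixel lattice
   with mixture negative log-likelihood data terms and contrast-sensitive
   smoothness terms (`gamma * exp(-beta * ||z_p - z_q||²)`, `beta` set from
   the mean neighbour contrast, `gamma = 50`). The cut is computed with
   igraph. The final mask is reduced to its largest connected component,
   because a fruit is a single blob and box-cropped slivers of neighbouring
   fruits would otherwise contaminate the colour statistics. Degenerate
   inputs (constant colour, empty cuts) fall back to the box interior with
   a warning.
2. **Red fraction** (`red_fraction()`): the masked pixels are converted to
   HSV and the red share is the fraction with hue ≤ 20° or ≥ 340°,
   saturation ≥ 0.25 and value ≥ 0.20. The gamut is a configurable
   repository default — chosen to exclude white/green flesh and dark shadow
   — since no published hue bounds exist for this procedure.
3. **Grading** (`grade_maturity()`): unripe below 0.05, breaker in
   [0.05, 0.5), half-ripe in [0.5, 0.8), commercially-ripe in [0.8, 0.9),
   fully-ripe at 0.9 and above. The upper-grade onsets (0.5 / 0.8 / 0.9)
   follow the five-grade agricultural standard's "or more" wording, so the
   boundary values belong to the higher grade; the breaker onset of 0.05 is
   a repository default separating "entirely white or green" from "small
   red areas appearing".
4. **Review flag**: instead of a manual correction pass, a record is flagged
   when the mask-based estimate and a segmentation-free estimate over the
   box's inscribed ellipse disagree by more than 0.2 — the signature of
   occlusion or a failed cut. The inscribed ellipse, not the full rectangle,
   is the comparison region because the rectangle's corners are background
   by construction and would bias the check.

## Synthetic scenes

`generate_scene()` renders ellipsoidal fruits on a noise-textured soil
background. The red region grows as an angular sector from the fruit tip
(the ripening pattern of real strawberries); its size is set by pixel count,
so the rendered red share equals the requested coverage up to rasterisation
(±0.01 by construction, verified in tests). Optional elliptical green
occluders emulate leaves. Fruits are placed so their ellipses never
interpenetrate — a later fruit would repaint an earlier one and silently
corrupt its ground-truth coverage. Scene truth records the tight box, the
requested and rasterised coverage, and the grade implied by the default
thresholds; per-class coverage sampling keeps a safety margin of at least
0.015 from every grade boundary so that rasterisation cannot flip a label.
The generator emulates the geometry and colour statistics that the grading
pipeline consumes; it does not emulate photometric variation, specular
highlights, soft shadows or perspective, so green tests here demonstrate
the pipeline's internal consistency, not field performance.

`generate_dataset()` writes a YOLO-layout tree (`images/`, `labels/`,
`data.yaml` naming the five classes in id order) and can emulate class
imbalance plus flip/±15° rotation augmentation of scenes containing rare
classes. `split_dataset()` shuffles deterministically and apportions 7:2:1
by largest remainder, so 3,100 items split into 2,170/620/310.

## Metrics

Matching is class-aware and greedy in confidence order with best-IoU
tie-breaking and single-use ground truths. AP uses the 11-point
interpolation (mean over recall nodes 0.0, 0.1, …, 1.0 of the maximum
precision at recall ≥ node); mAP50 is the unweighted class mean, mAP50-95
additionally averages over IoU thresholds 0.50–0.95 in steps of 0.05.
Classes without ground truth are excluded from the mean rather than scored
zero. The confusion matrix is row-normalised with a background row (false
positives) and column (missed ground truths); its matching is
class-agnostic so cross-class confusions are visible. The confidence (0.25)
and NMS IoU (0.45) defaults are repository choices; the published
evaluation does not state its thresholds.

## Numerical and testing choices

* Convolution is im2col + BLAS; depthwise convolution uses
  shift-and-accumulate. Block outputs are cross-checked against nested-loop
  oracles to 1e-5 relative tolerance in the test suite.
* Gradient flow is verified by central finite differences of the scalar
  sum-of-outputs objective with respect to sampled parameter entries
  (`gradient_flow()`), at a 32×32 probe input; analytic backpropagation is
  intentionally not implemented.
* Determinism: model building seeds the RNG once; scenes are pure functions
  of their specification; evaluation-mode forwards are bitwise reproducible.
* Problem sizes in the tests are desk-scale by design: block oracles run at
  4×4–8×8 spatial extents, forward checks at 32–416 pixel inputs, grading
  end-to-end on five 160-pixel scenes (about a dozen graph cuts), and the
  architecture accounting — which is exact arithmetic — at the full 640
  evaluation resolution.

## Known limitations

* The attention stage's matrix products are evaluated per batch element and
  head in interpreted R; forwards above ~512² inputs are slow. Accounting
  functions never run a forward pass and are fast at any resolution.
* GrabCut quality depends on colour separability; fruits sharing a box with
  similarly coloured clutter can leak into the mask (the review flag is the
  guard, as in the manual-correction step it replaces).
* The checkpoint format stores the flat name-to-array weight map via R
  serialisation with a JSON sidecar header; it is a runtime artefact, not
  an interchange format.
* Only the n-scale layout is defined; other scale tags are rejected.
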