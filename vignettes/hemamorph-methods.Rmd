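---
title: "Blood smear morphometry and anomaly detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood smear morphometry and anomaly detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemamorph)
```

## Scope and design

`hemamorph` implements a desk-scale pipeline for automated blood cell
analysis on smear microscopy: detect cell instances, measure each cell with
a fixed 50-descriptor morphometric registry, classify erythrocyte (RBC)
shapes with a geometric rule engine (poikilocytosis screening over 15
categories), flag leukocyte (WBC) anomalies, optionally score cells against
an attribute knowledge base (zero-shot), and emit a machine-readable report.
Deep detection and classification networks are deliberately out of scope:
they are represented by *contracts* (a detector plug-in interface returning
box/mask/class triples, and a 2048-dimensional embedding backbone interface)
behind which trained models can be mounted, plus classical baselines that
make every downstream stage testable on a single CPU.

Because no image data ships with the package, a synthetic smear generator
provides the ground truth: every stage of the pipeline is validated against
cells whose geometry, pallor, inclusions and nuclei are known exactly at
render time.

## The synthetic smear generator

Cells are rendered as anti-aliased ellipse-derived shapes on a seeded,
low-frequency textured background (base RGB (0.93, 0.89, 0.91) with
smoothed Gaussian texture, sd 0.012). The generator emulates:

* **RBC shape archetypes** — elongation for elliptocytes/ovals/pencil forms
  (axis ratio set so that moment eccentricity lands on the archetype mean),
  disc-shaped or slit-shaped central pallor, a dark-center/bright-ring
  radial profile for target cells, planted dark inclusions (round central,
  round peripheral, or elongated crystal), concave three-pointed polygons
  for fragments, and a 7-lobed boundary modulation for the irregular
  catch-all form.
* **WBC classes** — a dark basophilic nucleus on a lighter cytoplasm; for
  polymorphonuclear classes the nucleus is drawn as 2–3 disjoint lobes so
  that the lobe count is morphologically recoverable after a one-step
  erosion.
* **Platelets and intrusions** — small purple discs and low-saturation gray
  artifacts.

Defaults were chosen once, from standard hematology ranges: a normal RBC is
a 7 µm disc (radius jitter sd 0.1 µm) with a central pallor covering ~35% of
its area; macrocytes render at 9.8 µm and microcytic round forms at 5 µm;
elliptocytes at eccentricity 0.71 and ovals at 0.45. Every archetype mean
sits at least two rule margins away from the relevant decision thresholds,
so the generator↔rule-engine loop closes: measured morphometry of a rendered
archetype falls in that archetype's acceptance region with per-type recall
≥ 0.95 (verified on 1005 seeded cells in the test suite).

Calibration defaults are 0.1 µm/px for single-cell patches (a normal RBC is
then 70 px across, small enough to render quickly and large enough that
discretization error in perimeter and eccentricity is below 1%) and
0.2 µm/px for multi-cell canvases.

What the generator does **not** emulate: real staining variability,
overlapping/clumped cells beyond a configurable overlap bound, optics (PSF,
vignetting, chromatic effects), and the long-tailed morphology continuum of
real smears. Passing tests on generated data therefore demonstrates the
correctness of the measurement and decision machinery, not clinical
performance.

The five-stage data-preparation pipeline is implemented on top of the
generator: perceptual-hash deduplication (64-bit average hash, default
threshold 0 = exact hash match), minority oversampling by seeded
re-rendering with augmentation, YOLO-dialect annotation serialization
(six decimals; any float text accepted on read), geometric augmentation
(flips; rotations within ±15°; shears within ±0.2 rad; nearest-neighbor
inverse mapping so zero-angle transforms are exact identities; boxes are
always recomputed from transformed masks and cells retaining < 20% of their
mask are dropped), and per-channel min–max normalization (a constant
channel raises an error rather than silently emitting zeros).

## The 50-descriptor registry

The registry (20 geometric, 10 nuclear/cytoplasmic, 8 texture, 6 color, 6
specialized hematology descriptors) is the single source of truth for
feature names, order and units; morphometry vectors, knowledge-base rows
and feature tables are all ordered by it. The field's descriptor
enumerations do not pin an exact 50-item list, so the mapping is
necessarily interpretive; the two additions that complete the groups are
`nuclear_solidity` and `central_pallor_ratio` (the latter is required by
the shape rules). Definitions worth noting:

* Perimeters use the sub-pixel marching-squares contour with a 5-point
  circular moving-average smoothing. Raw marching-squares overestimates a
  digital disk's perimeter by ~6% (pushing circularity down to 0.89); the
  smoothed estimator is within 1% across radii 10–60 px, so rasterized
  disks measure circularity 0.99–1.00.
* Axes, orientation and eccentricity come from the central second moments
  of the mask, with the 1/12 pixel-variance correction; the semi-axes are
  those of the solid ellipse with matching moments.
* Texture statistics are 32-level gray co-occurrence features (symmetric,
  horizontal+vertical offsets) within the cell mask; correlation is defined
  as 0 for degenerate (single-level) cells.
* Nucleus segmentation, when no mask is supplied, is an Otsu threshold on
  darkness within the cell, gated to reject candidates whose mean luminance
  exceeds 0.5 or whose area is below 5% of the cell (so dark RBC bodies do
  not masquerade as nuclei). Ground-truth nucleus masks from the generator
  bypass this.
* The six specialized metrics are defined as: granularity index = variance
  of the 4-neighbor Laplacian over cytoplasm; vacuolation level = bright
  pixel fraction of cytoplasm; inclusion count = dark (luminance below the
  cell median − 0.18) connected components of ≥ 2 px; membrane integrity =
  fraction of boundary pixels with gradient magnitude above 0.05;
  cytoplasmic granularity = co-occurrence energy restricted to cytoplasm;
  central pallor ratio = area fraction of bright central components.

Auxiliary measurements that the rules need but that are not registry
descriptors travel as an attribute of the vector: pallor eccentricity,
radial inversion count, maximum inclusion eccentricity, inclusion
peripherality, and interior intensity. The radial profile uses 8
concentric rings; an "inversion" is a change of direction in the sequence
of significant (> 0.02) ring-to-ring luminance differences, counting the
first significant step — so a normal pallor profile scores 1, a target
cell's dark-center/bright-ring/dark-rim profile scores ≥ 2, and a flat
profile scores 0.

## The RBC shape rule engine

Fifteen prioritized rules classify each measured RBC; the first match wins
and a catch-all guarantees totality. Priorities follow the principle
*inclusion rules → size rules → shape rules → Normal → catch-all*, which
prevents, e.g., a normally-sized cell bearing a nuclear remnant from being
labeled Normal. Published criteria: normal diameter 6–8 µm with
circularity > 0.9; elliptocyte eccentricity > 0.5; stomatocyte
circularity < 0.7. All other thresholds complete the taxonomy and are
user-overridable via `anomaly_rule_params()`:

| priority | label | criterion |
|---|---|---|
| 1 | Hemoglobin-C | inclusion present with inclusion eccentricity > 0.8 (crystal) |
| 2 | Heinz bodies | inclusion with centroid beyond 0.7 of the equivalent radius |
| 3 | Howell-Jolly | exactly one (central, round) inclusion |
| 4 | Target | ≥ 2 radial intensity inversions |
| 5 | Fragments | area < 50% of the normal RBC area (38.48 µm²) and solidity < 0.85 |
| 6 | Pencil | eccentricity > 0.85 and aspect ratio > 3 |
| 7 | Elliptocyte | eccentricity > 0.5 |
| 8 | Oval | 0.35 < eccentricity ≤ 0.5 |
| 9 | Macrocyte | equivalent diameter > 8.5 µm |
| 10 | Microcircle | equivalent diameter < 6 µm and circularity > 0.9 |
| 11 | Hyperchromasia | interior intensity < 0.45 and pallor absent |
| 12 | Stomatocyte | slit pallor (pallor eccentricity > 0.7) or circularity < 0.7 with solidity ≥ 0.9 |
| 13 | Spleen | pallor absent, diameter 6–8 µm, circularity > 0.9 |
| 14 | Normal | diameter 6–8 µm, circularity > 0.9, no inclusions, pallor ratio in [0.05, 0.6] |
| 15 | Pikilocyte | irregular catch-all (always true) |

Two deliberate choices: all inequalities are strict, matching the printed
">" forms (a WBC at eccentricity exactly 0.8 is *not* flagged); and the
low-circularity branch of Stomatocyte additionally requires solidity ≥ 0.9,
because spiculated irregular cells also have low circularity and must be
able to reach the catch-all — without the solidity gate the Pikilocyte
class would be unreachable for smooth-rule inputs. "Spleen" and
"Microcircle" are kept verbatim as taxonomy names (they likely denote
spherocyte- and microcyte-like forms); their semantics here are exactly the
documented rules. WBC anomaly flagging fires on eccentricity > 0.8 or a
boundary intensity-gradient score (the `edge_gradient` descriptor) above a
configurable threshold (default 0.35); the gradient score is a documented
stand-in for an unspecified intensity-gradient assessment.

## Zero-shot attribute scoring

The compatibility model is bilinear: `f(x, y) = (W x)' a_y`, with both the
feature vector `x` and each class attribute vector `a_y` living in the
50-descriptor registry space; a 300-dimensional text-embedding projection
is a possible extension but is off by default because attribute vectors
grounded in measurable morphometry are reconstructible and auditable.
Fitting minimizes softmax cross-entropy over the seen classes with an L2
penalty (λ = 0.01), inverted dropout (0.3) on inputs, minibatch Adam
(lr 0.001, batch 16), and early stopping (patience 5) on a seeded 20%
validation split.

`W` initializes at the identity, not zero. This matters for the zero-shot
property: cross-entropy gradients are linear combinations of outer products
`a_y x'` over *seen* classes, so training moves `W` only within the span of
seen attribute directions. A zero-initialized model scores every class
orthogonal to that span as 0 and cannot rank unseen classes; the identity
component carries those scores, and the L2 decay it suffers during training
is negligible at the default λ and step count. With features generated at
orthogonal attribute vectors plus noise (σ = 0.05), the fitted model
reaches top-1 ≥ 0.95 on seen classes and ≥ 0.9 on held-out unseen classes
(test suite). The default knowledge base is built deterministically by
rendering one noise-free exemplar per class and measuring it; two example
subclasses ("Lymphocyte T", "Promyelocyte-N") ship as unseen entries with
documented, synthetic prototype perturbations of their parent classes.

## Virtual staining objectives

The staining stage exposes the adversarial objective
`E[log D(y)] + E[log(1 − D(G(x)))] + λ E[|G(x) − y|]` with λ = 10,
standardization `(x − μ)/σ` (population σ), per-channel min–max
normalization, and the pixel-wise transform loss `mean |G(x) − y|`.
Discriminator outputs are clipped at 1e-12 before logs because the
objective is undefined at 0/1. The desk-scale trainer fits a per-pixel
colorization generator (a 1×8×3 tone-mapping network, i.e. a 1×1
convolutional generator) against a logistic patch discriminator over
channel statistics, with Adam at the configured learning rate (2e-4, batch
32, default 100 epochs — tests use 30). On a deterministic synthetic
colormap task the 30-epoch model cuts held-out transform loss by well over
50%. The full-resolution encoder–decoder setting is a configuration for
mounted external models, not a default; cross-registration of real slide
pairs is out of scope (synthetic pairs are perfectly aligned by
construction).

## Detection and its evaluation

The baseline detector is classical: Otsu threshold on border-estimated
background-subtracted luminance, hole filling, connected components, and a
distance-transform watershed that splits touching cells (verified on two
cells overlapping 30% by area); classes come from a size/color heuristic.
It exists to exercise the detector contract, not to rival trained networks.

Evaluation conventions, fixed because they are not universal: greedy
matching in descending confidence order with ties broken by higher IoU then
lower index, each truth claimable once; micro-averaged precision/recall/F1;
AP is the all-point interpolated area under the precision–recall curve at
IoU 0.5, mAP averages classes present in the ground truth, and mAP@50:95
averages thresholds 0.5–0.95 in 0.05 steps; with no predictions and
existing truths P = R = F1 = 0, with both sets empty all three are 1. The
normalized confusion matrix matches class-agnostically first (so
off-diagonal confusions are visible), adds a background row/column for
unmatched predictions/truths, and row-normalizes.

## Feature-table classification and the report stage

The harness registers exactly eight families — k-NN, decision tree, random
forest, SVM (RBF), Gaussian naive Bayes, gradient boosting, AdaBoost.M1
(SAMME over depth-1 stumps), and a single-hidden-layer perceptron — trains
each on a seeded stratified 80:20 split with optional preprocessing
(Isolation Forest or Elliptic Envelope outlier removal of training rows;
k-means binning discretization with bins relabeled in centroid order so
binning is monotone), and ranks by macro precision then macro F1, reporting
the top 3. Decision time is recorded but never asserted (hardware-bound).
Outlier filters flag exactly `round(contamination × n)` rows, ties broken
by row order. The report stage fits random forest and gradient boosting
with 100 estimators plus a decision tree, records each model's held-out
precision/F1 and the random forest's empirical mean per-tree
misclassification rate, and tallies anomaly counts over all 15 labels
(zero-filled) and WBC flags; report JSON is byte-deterministic given
identical inputs.

## Evaluation protocol

`stratified_kfold` deals each class's shuffled members into folds by
largest-remainder allocation with remainders sent to the currently smallest
folds, so validation fold sizes differ by at most one and per-fold class
counts are within one of proportionality; with k = 5 each fold is an 80:20
split (8380 labeled items give 6704/1676 per fold). Held-out sizes round
half up, which reproduces both reference benchmark holdouts (108 → 22,
260 → 52). Paired comparisons use the two-sided paired t-test with
Bonferroni adjustment `min(1, m·p)` and the paired (d_z) form of Cohen's d
— mean of differences over their sample standard deviation — chosen because
fold-wise metrics are paired by construction; zero-variance differences are
flagged degenerate instead of reporting a p-value. k is a parameter: 5 is
the default, 10 is available where a protocol calls for it.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately small sizes chosen
as the smallest that make the properties sharp: 101–267 px single-cell
patches; 1005 cells (67 per archetype) for the rule-engine recall
property; 12 cells per archetype for the acceptance survey; 200 training /
100 unseen samples for the zero-shot construction; 120-row tables for the
classifier harness; 30 epochs × 100 steps for the staining descent check.
Randomness is always confined by `local_seed`, which restores the caller's
RNG state, so package functions never perturb user RNG streams. Known
numerical edge cases are errors, not silent results: constant channels in
normalization/standardization, empty masks, degenerate boxes, zero-variance
paired differences, and covariance-degenerate inputs to the Elliptic
Envelope.

## Limitations

Rule thresholds beyond the published four are package definitions —
reasonable, documented, overridable, but not clinically validated. The
synthetic generator's archetypes are idealized; real poikilocytosis grades
continuously and overlaps categories. The embedding backbone is a
fixed random projection honoring the 2048-dimension contract, useful for
pipeline wiring and determinism tests, not a trained representation. The
baseline detector assumes stained, well-separated cells on a light
background. Printed performance figures from GPU-trained detection models
on private datasets are outside what this package can or does reproduce.
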