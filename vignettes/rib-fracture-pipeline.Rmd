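---
title: "Fusing, rib-numbering and evaluating CWIS rib-fracture detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing, rib-numbering and evaluating CWIS rib-fracture detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribcwis)
```

## The problem this package addresses

Rib-fracture pipelines on trauma CT often train one detection network
per CWIS label category — fracture type, displacement, location — so a
single fracture can be reported as three separate scored boxes, one per
network. Clinically useful output is a *single* detection per fracture
carrying the full CWIS triple plus the number of the fractured rib, and
a research-grade assessment needs a reproducible evaluation protocol
and interobserver statistics. `ribcwis` implements that
post-processing and evaluation layer. It deliberately contains no
networks: its inputs are scored boxes, numbered rib segmentations and
annotation tables, and a phantom simulator stands in for CT data so the
whole chain is testable with known ground truth.

All geometry uses 0-based voxel indices and half-open boxes
(`x0 <= x < x1`), with physical millimetres entering only through the
per-axis voxel spacing. This makes voxel counting exact (a box's volume
is the product of its extents) and keeps every operation independent of
scanner orientation conventions.

## Ensemble fusion

Within one model, detections are de-duplicated by greedy non-maximum
suppression: boxes are visited in descending score order and a box is
kept only if its intersection-over-union with every already-kept box
is at most the threshold (default 0.5 — overlap "exceeding 50%" means
suppression). Score ties are broken by lexicographic minimum corner so
results never depend on input order.

Across models, a fracture must be confirmed by at least two of the
three networks. The package builds an overlap graph over all boxes with
edges only between boxes of *different* models and takes its connected
components as candidate fractures. Two boxes of different models count
as overlapping when they share at least one voxel (the default); an
IoU-threshold mode is available. The within-model 50% rule is a
de-duplication criterion, not a consensus criterion, so requiring any
positive overlap across models is the weaker and more natural reading;
components make the grouping deterministic and order-independent even
when overlap is not transitive.

Per surviving component, each model present contributes its
highest-scoring member box; the fused box is the smallest axis-aligned
box containing these representatives (their union hull); a category
whose model is absent from the component is labeled `"unknown"`; and
the fused score is the mean of the representatives' scores (a `max`
option exists — the mean is the default because it damps single-model
overconfidence). A component touching only one model produces no
output.

## Rib numbering

Numbered rib segmentations use labels 1–12 for left ribs 1–12 and
13–24 for the right side; other encodings should be remapped by the
caller. A detection box takes the rib with the largest voxel overlap
inside the box; any positive overlap suffices to keep a detection, and
a box touching no rib voxel is discarded, since a fracture detection
off the rib cage is necessarily spurious. Ties (equal voxel counts) go
to the lower rib number, left before right — an arbitrary but fixed
rule that makes assignment deterministic. Boxes reaching past the grid
are clipped with a warning rather than rejected, because detector edge
effects should not invalidate a whole scan.

`validate_rib_labelmap()` automates the usual segmentation quality
criteria as structural checks: per label it reports voxel count and the
number of 26-connected components (a severely displaced rib may
legitimately split into two fragments *sharing* one label, which is
reported but not flagged), and it flags gaps in the per-side 1–12
sequence, labels fragmenting into more than two pieces, and the
"short cage" case of exactly 11 rib pairs — anatomically legitimate,
hence a flag and never a failure. Connected components are counted by a
small frontier BFS written for 3D integer grids.

## Matching and evaluation

Reference fractures are encoded as spheres of radius 10 mm around the
annotated center. A detection can match a reference iff its box
intersects the sphere, tested via the closest point of the box to the
center with per-axis millimetre scaling (so anisotropic voxels are
handled exactly).

Matching is one-to-one. Detections are processed in descending score
order, each preferring its closest feasible reference, and an
augmenting-path pass (Kuhn's algorithm) completes the assignment to
maximum cardinality. The augmentation matters: a pure greedy pass can
let a high-scoring detection occupy the only reference available to a
lower-scoring one even when both could be satisfied, deflating TP
counts in a way that depends on score noise rather than geometry. With
augmentation the TP count equals the best achievable one-to-one
assignment (verified against exhaustive enumeration in the tests),
while the preference order still resolves the remaining freedom
deterministically. Unmatched detections are false positives — a second
detection of an already-matched fracture counts as a false positive,
which is exactly how a displaced fracture reported as two fractures is
scored — and unmatched references are false negatives.

Metrics are pooled over scans: sensitivity TP/(TP+FN), precision
TP/(TP+FP), F1 their harmonic mean, and FPPS = total FP divided by the
number of scans ("mean false positives per scan"). A macro (per-scan
averaged) variant is exposed as an option, but pooling is the default
because FPPS is defined per scan while sensitivity and precision are
naturally fracture-level quantities. Stored values are exact;
percentages print with 0 decimals and FPPS with 2, and rounding happens
only at presentation.

Classification quality is assessed over true positives only — a missed
fracture cannot be classified — as per-category confusion matrices
(reference label × predicted label, including an `"unknown"` column)
and per-class sensitivity/precision tables with the composition of
missed fractures. Rib-number accuracy is the share of matched,
rib-assigned detections whose rib equals the reference rib; detections
discarded at rib assignment and references without rib numbers leave
the denominator.

The operating point for deployment is chosen on a training set as the
largest score threshold whose post-threshold matching still attains a
target sensitivity (e.g. 82%); thresholding is applied after fusion by
default (the alternative order is a caller choice — thresholds are
plain score filters on either table). If the target is unattainable the
function warns and returns a value below the minimum score.

## Interobserver agreement

Two observers' annotations are matched spatially with the same
maximum-cardinality matcher (preference by distance; two 10 mm spheres
intersect iff centers are within 20 mm). Mutual fractures yield
complete label pairs; solo fractures keep the other side missing.
Cohen's κ = (p_o − p_e)/(1 − p_e) is computed on complete pairs, with
p_e from the product of the raters' marginals; if both raters are
constant with the same value the degenerate p_e = 1 case is reported as
perfect agreement. Krippendorff's α = 1 − D_o/D_e uses the nominal
coincidence matrix, where each unit with m ≥ 2 ratings contributes its
rating pairs with weight 1/(m − 1); units with a single rating
contribute nothing, which is precisely why α complements κ when one
observer missed a fracture.

Confidence intervals are percentile bootstrap over fractures
(units), n = 1000 resamples, seeded; degenerate resamples are redrawn
up to a cap. The bootstrap is distribution-free and matches how such
intervals are usually produced when no analytic form is stated;
fracture-level resampling (rather than scan-level) treats the fracture
as the experimental unit, consistent with the statistics themselves.

Qualitative bands: the default scale maps (0.60, 0.80] to
"Substantial" and (0.80, 0.90] to "Strong", with "Poor"/"Slight"/
"Fair"/"Moderate" below and "Almost perfect" above; the classic
Landis–Koch scale is selectable. The default is the scale observer
studies in this area actually print; it differs from Landis–Koch only
in splitting the top band at 0.9.

## The phantom simulator

The generator emulates the *data contracts* of a CT study — a numbered
rib label map with spacing, disjoint sphere-encoded reference
fractures with complete CWIS triples and rib numbers — not CT
appearance. Ribs are tubes (default radius 4 mm) along elliptical arcs
on a schematic thorax, 12 (or legitimately 11) pairs, parameterized by
arc length from the spine, with a mild caudal droop toward the
sternum. This is sufficient because every downstream consumer sees
only label maps and coordinates. The default grid is 128³ voxels at
2 mm isotropic spacing: large enough that 24 ribs and up to a few
dozen disjoint 10 mm reference spheres fit comfortably, small enough
that a phantom generates in well under a second.

Fracture centers are sampled on rib centerlines with at least 20 mm
between centers (the stored, voxel-rounded centers satisfy this), so
reference spheres never overlap — mirroring how point annotations of
distinct fractures are encoded. The location label follows an
arc-length convention: first third from the spine posterior, middle
third lateral, last third anterior. This is a simulation convention,
not a claim about the anatomical definition used by human annotators;
a fracture's location label and its center position are kept mutually
consistent by sampling the label first and then a position inside the
corresponding third. Type and displacement are drawn from configurable
frequency tables. The defaults (simple 0.70 / wedge 0.20 / complex
0.10; undisplaced 0.55 / offset 0.30 / displaced 0.15; anterior 0.30 /
lateral 0.35 / posterior 0.35) encode a blunt-trauma case mix in which
simple undisplaced fractures dominate and complex fractures are rare —
the regime in which class imbalance makes classification hard. Ribs
carrying a displaced fracture can be split into two fragments sharing
their label (a 12 mm gap, offset along the arc so the reference center
itself stays labeled), which exercises the validator's
fragment-consistency check.

The detector simulator emits, per reference, a box with probability
`sensitivity`, centered on the jittered fracture center (Gaussian,
default SD 2 mm), sized uniformly in 10–18 mm per axis — roughly the
diameter of the reference sphere, and below the 20 mm minimum
inter-fracture spacing so detections of distinct fractures stay
disjoint — and labeled through an optional per-category confusion
matrix. False positives arrive Poisson-distributed per scan (default
rate 1.11), placed on random rib voxels (a configurable fraction
anywhere in the volume), with uniformly random labels. True detections
score Beta(8, 2) and false positives Beta(2, 5), giving overlapping
but separable score distributions so operating-point selection has
something to do. Everything is deterministic given the seed.

What passing tests on phantoms do *not* show: performance on real CT.
The phantom has no soft tissue, no imaging noise, no scatter
artifacts, no anatomical variation in rib shape, and its detector
errors are independent across fractures. Phantom results validate the
*bookkeeping* — fusion logic, rib assignment, matching, metric
arithmetic, statistical recovery — not detector quality.

## Numerical and design choices

* Degenerate boxes (zero volume) are rejected as invalid inputs
  everywhere; IoU of disjoint boxes is exactly 0 and of identical
  boxes exactly 1 by construction.
* All tie-breaks (suppression order, rib ties, matching preference)
  are lexicographic and documented, so every function is a pure
  function of its inputs.
* Sensitivity with zero references, precision with zero detections,
  rib accuracy with no eligible true positives, and α with no pairable
  values are reported as undefined (`NA`), never as 0 or 1.
* Empty inputs produce empty outputs of the right shape rather than
  errors, except where an operation is meaningless (operating-point
  selection on an empty detection set).
* Test problem sizes: suppression is checked against a brute-force
  voxel-enumeration oracle on 1000 instances of up to 8 boxes;
  matching against exhaustive enumeration on instances of up to 6
  objects; statistical recovery uses 100 phantom scans (~800
  fractures) at sensitivity 0.80 and 1.11 false positives per scan,
  with 3-standard-error acceptance bands; agreement convergence uses
  1000 complete paired labels. These sizes give the property checks
  comfortable statistical power while keeping the whole suite fast.

## Known limitations

* The fused score aggregation (mean/max) is a convention; no
  probability calibration is attempted.
* No FROC curve fitting, no bootstrap CIs on detection metrics (only
  agreement CIs), and no significance testing between strata — the
  stratified output is descriptive.
* Rib label maps with 11 pairs are flagged but not renumbered; if the
  segmentation numbered the cage as ribs 1–11 while anatomy says
  2–12, assignments inherit that shift.
* The agreement module treats both observers symmetrically; if one
  observer's labels are the designated ground truth for a category,
  that is a data-provenance fact outside these statistics.
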