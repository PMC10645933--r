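---
title: "Measurement models and analysis decisions in pbmstudy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and analysis decisions in pbmstudy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmstudy)
```

`pbmstudy` implements the measurement chain of a preclinical
photobiomodulation study — simulated raw data, behavioral and histological
metrics, and the statistical decision procedure — as one auditable package.
This vignette records the measurement models and, for every threshold the
underlying laboratory protocol leaves unstated, the choice made here and
why.

## Coordinate conventions

Behavioral trajectories live in centimeters with the origin at the arena
center and y pointing up. Images are matrices with row = y (down),
column = x, and 0-based pixel coordinates in all outputs, so they can be
compared directly with common image-viewer and pose-estimation conventions.
Keypoint CSVs use the three-header-row dialect of pose-estimation exports
(scorer / bodyparts / coords) with parts `nose`, `head_center`,
`body_center`.

## Behavioral measurement models

### Novel object recognition

Exploration of an object is scored per frame when both conditions hold:

* the **nose** keypoint is within 5 cm of the object center, and
* the head is **oriented toward** the object: the angle between the
  head-to-nose vector and the head-to-object vector is at most 45°.

The 5 cm radius is the protocol's stated criterion. The protocol scores
orientation by a human-trained classifier; the 45° half-cone
(`facing_max_deg`) is this package's operationalization — wide enough to
keep natural head wobble during investigation, narrow enough to reject
passing or rearing near the object. It is a parameter, not a constant.
The discrimination index is

$$DI = \frac{t_{novel} - t_{familiar}}{t_{novel} + t_{familiar}},$$

undefined (`NA` with an `undefined` attribute) when total exploration is
zero rather than silently 0.

### Y-maze spontaneous alternation

An arm entry is recorded when the **body** keypoint penetrates beyond half
the arm length (`entry_depth_frac = 0.5`) while within the arm's width;
consecutive duplicates are collapsed. Half-depth makes the detector robust
to mouth-dithering: a criterion at the arm mouth would double-count
hesitant approaches. Alternation is the number of overlapping triplets of
three distinct arms divided by (entries − 2); with fewer than 3 entries the
score is undefined. For sequences drawn iid-uniformly from three arms the
expected score is 2/9 ≈ 22%, the chance reference used in one-sample tests.

### Morris water maze

Training trials end at first platform contact (body within the platform
radius) or at the 120 s timeout; escape latency, pre-escape path length and
mean speed are reported. Probe trials (60 s, platform removed) report
occupancy of the four compass quadrants (split along the diagonals, the
platform quadrant containing the platform center), time-weighted mean
distance to the former platform location, path length and speed. A
trajectory leaving the pool by more than `boundary_tol_cm` (2 cm) raises a
calibration error instead of producing silently wrong metrics.

### Tracking dropouts

`fill_gaps()` linearly interpolates keypoint dropouts (likelihood below
0.6) up to 0.5 s; longer gaps are left `NA` and flagged in an `excluded`
attribute so downstream metrics can censor them. The 0.6 / 0.5 s pair
mirrors common pose-estimation post-processing defaults and is exposed as
parameters.

## Synthetic behavior generators

Trajectories are correlated random walks through paradigm-specific
waypoints, with AR(1) jitter (sd 0.3 cm) and rigid keypoints (body→head
1.5 cm, head→nose 1 cm, nose ahead of the head along the heading). Each
generator takes a single programmed effect parameter with a known mapping
to its metric, making parameter recovery testable:

* `novelty_preference` p: each approach bout targets the novel object with
  probability p, so mean DI ≈ 2p − 1. Wander targets between bouts are
  rejection-sampled at least 10 cm from both objects; without this,
  incidental near-object facing biases DI recovery downward.
* `alternation_bias` b: the next latent arm is the least-recently-visited
  of the other two arms with probability b (uniform between the other two
  otherwise), so the latent sequence has no immediate repeats and expected
  alternation (1 + b)/2. The latent sequence is emitted as ground truth and
  must equal the detected sequence exactly — an oracle the tests enforce.
* `goal_bias` g: per-frame steering blends the heading toward the platform
  with correlated noise; g = 1 yields near-direct escapes.

Generators save and restore the caller's RNG state, so a fixed `seed`
yields bit-identical output without disturbing surrounding code.

## Histology measurement models

Images are simulated at 0.6 µm isotropic pixels: non-overlapping bright
disks (plaque channel), a microglial channel with multiplicative
peri-plaque enrichment (factor f out to 12 µm from the plaque edge, linear
falloff over the next 6 µm, pure baseline beyond — so the far annulus is
uncontaminated by construction), nucleus disks with an instance label mask,
and optional Gaussian or Poisson noise.

* **Segmentation** stands in for an interactively trained classifier: Otsu
  threshold on the included pixels, connected components, minimum area
  20 µm². Threshold method and value are recorded in the result.
* **Plaque edge model.** The annulus distance of a pixel is its distance to
  the plaque centroid minus the plaque's equivalent radius
  $r = \sqrt{area/\pi}$ — a circle model of the edge, matching how plaque
  positions are summarized (centroid + radius). For the near-circular
  plaques produced by the generator this coincides with a mask-boundary
  distance; for real, irregular plaques the circle model is the documented
  choice here.
* **Microglial response.** Mean intensity in the (edge, edge + 12 µm]
  annulus over the mean in the [edge + 18, edge + 60 µm] annulus. Pixels
  inside any plaque and outside the region are excluded from both annuli;
  plaques with an empty annulus (e.g. at a region border) are dropped and
  reported. On a spatially uniform channel every ratio is exactly 1 — the
  built-in calibration the acceptance suite checks to 1e-6.
* **Neuron counts** require instance label masks (binary masks are rejected
  with a pointer to connected-component labeling) and count instances whose
  centroid lies in the region.

Regions are polygon or mask annotations on the pixel grid; polygon
rasterization is even-odd on pixel centers.

## Statistical decision procedure

Every comparison is screened for normality with a Monte-Carlo Lilliefors
test: the Kolmogorov–Smirnov statistic against a normal with estimated
parameters, p-value from a seeded null simulation with the add-one rule
$p = (1 + \#\{D^* \ge D\})/(B+1)$, null distributions cached per sample
size. The authored implementation is cross-checked against an independent
one in the test suite.

* Multi-group: if every group passes the gate (each p ≥ 0.05), one-way
  ANOVA; otherwise Kruskal–Wallis, with the fallback explicitly flagged in
  the report since the original procedure describes only the normal branch.
* Paired: gate on the differences; paired t or Wilcoxon signed rank (exact
  null when n ≤ 25 without ties), reporting the (positive, −negative) rank
  sums.
* Chance-level references: one-sample t against 0 (discrimination index),
  22 (alternation %), 1 (annulus ratio).
* Repeated measures: mixed-design ANOVA (between × within with
  `Error(subject/within)`), Greenhouse–Geisser ε estimated from the pooled
  within-cell covariance via orthonormal polynomial contrasts (ε = 1 for
  two within levels), within-effect dfs multiplied by ε. Post-hocs are
  delegated to `emmeans`: Sidak-adjusted pairwise contrasts or
  Dunnett-style contrasts against a reference level.
* Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.

Gating at α = 0.05 per group keeps the procedure faithful to the study's
published decision rule rather than pooling residuals; the type-I error of
the full gated procedure is verified by simulation in the test suite.

## Blinding and the pipeline

`randomize_groups()` deals shuffled animals round-robin to groups within
each sex (shuffled group order; explicit unequal group sizes supported via
capacity caps), and returns a sealed codebook: group lookups error until
`unblind()` is called, and unblinding is audited. `run_pipeline()` runs the
whole chain with per-animal seeds derived from one master seed; all
intermediate tables are keyed by blinded codes, groups are joined only at
the report stage, and a manifest records the configuration and its MD5.
Identical configurations produce byte-identical outputs.

## Dose arithmetic

`dose_spec()` / `dose_summary()` encode the stimulation conditions: average
irradiance = peak × duty cycle (600 mW/cm² × 0.2 = 120 mW/cm²; 6 mW/cm² ×
0.2 = 1.2 mW/cm²), per-session fluence = average × session duration
(14.4 J/cm² and 0.144 J/cm² for 120 s), cumulative fluence over the course.
`fur_attenuation()` converts paired shaved/unshaved power readings into a
percent transmission and attenuation.

## Problem sizes

Defaults (10-minute NORT/Y-maze sessions at 30 Hz, 120 s training and 60 s
probe trials, 512×512 px sections, 10,000-replicate Monte-Carlo nulls) are
the package's own choices sized for desk-scale reproducibility; all are
parameters.
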