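---
title: "Detecting microaneurysms with PBPSO clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microaneurysms with PBPSO clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madpso)
```

Microaneurysms (MAs) are saccular outpouchings of retinal capillaries, a few
pixels wide on a fundus photograph and dark in the green channel. They are
the earliest clinical sign of diabetic retinopathy, which makes reliable
small-dark-dot detection on low-contrast retinal images a worthwhile target
for automated screening. `madpso` implements a complete detection chain —
contrast enhancement, stochastic clustering segmentation, statistical
cluster merging, texture featurization, and a transparent threshold
classifier — together with a ground-truthed phantom generator so that every
stage is testable without access to clinical data.

## Pipeline overview

`run_pipeline()` executes, in order:

1. resize to 250 × 250 (bilinear) and grayscale conversion (green channel
   by default — red lesions have maximal contrast there);
2. retinal field estimation (threshold at 0.05, largest connected
   component, 2 px erosion) so the black camera aperture never enters the
   clustering;
3. fuzzy-clipped CLAHE contrast enhancement;
4. PBPSO clustering of in-field pixels into k = 4 clusters;
5. statistical cluster merging (kurtosis/skewness equality with a
   normality-test fallback);
6. candidate extraction from the darkest cluster (morphological opening,
   connected components, area/eccentricity/contrast filters);
7. GLCM texture features per candidate and a conjunctive threshold call.

## Fuzzy-clipped CLAHE

Plain CLAHE equalizes each contextual tile's histogram after clipping it at
a fixed multiple of the uniform bin height. The fuzzy-clipped variant makes
the clip limit adaptive: a small Mamdani system maps each tile's mean
intensity and normalized histogram entropy (its *uniformity*) to a clip
multiplier in `[1, base_clip]`. Tiles dominated by very dark or very bright
content (triangular memberships anchored at `fuzzy_low = 0.25` and
`fuzzy_high = 0.75`) and tiles whose histogram is already near-uniform are
clipped hard (multiplier near 1, i.e. almost no amplification — these are
aperture borders, glare, or already well-spread regions where equalization
mostly amplifies noise). Mid-toned, low-uniformity tiles receive up to
`base_clip = 4` times the uniform bin height. Clipped mass is redistributed
uniformly, each tile's mapping is its clipped CDF (monotone by
construction), and pixel values blend the four surrounding tile mappings
bilinearly.

Two properties are worth stating precisely because they are tested:

* a **constant image stays constant** (one occupied bin, heavy clipping,
  near-uniform redistributed histogram, hence a near-identity mapping);
* repeated application approaches a fixed point, but under a *strong* clip
  the per-pass displacement is rate-limited and peaks after a few passes
  before decaying; the textbook "second pass moves less than the first"
  contraction holds only when clipping is weak (`base_clip` large), where
  the first pass already performs most of the equalization.

## The PBPSO clustering model

A particle encodes a hard partition of the N data points into k non-empty
blocks: a permutation of the point indices with k − 1 separators. The swarm
moves in this discrete space as follows.

* **Velocity.** A particle's velocity is a *pool of candidate clusters*
  harvested from itself, its personal best, and the global best,
  deduplicated by set equality.
* **Construction.** Each pool cluster is scored by the aggregate fitness of
  its members and drawn with probability proportional to
  `exp(−fitness)` — better clusters are more likely, every cluster keeps
  positive mass. k clusters are drawn without replacement (sequential
  inverse-CDF sampling); their concatenation in draw order forms a pseudo
  sequence; duplicate occurrences of a point after its first are deleted;
  points the draw missed are appended to the chosen cluster with the
  nearest centroid; a block emptied by deduplication is repaired with the
  farthest member of the largest block.
* **Centroid update.** One Lloyd-style pass (recompute centroids, reassign
  to nearest, re-encode) accepted only if it improves the particle's
  fitness, so this step never worsens a particle. An emptied block is
  re-seeded with the point worst-fitted by its current assignment.
* **Bookkeeping.** Personal bests and the global best update after every
  move; the global-best fitness history is therefore monotone
  non-increasing. The loop stops at `max_iter = 50` iterations or after
  `stagnation_patience = 10` iterations without global-best improvement.

Defaults (`n_particles = 20`, the iteration caps above) are desk-scale
choices for images up to 250 × 250; all are exposed in `swarm_config()`.
One seeded RNG stream drives an entire run — R's generator state is saved
and restored around it — so a run is a pure function of data and
configuration. A conventional continuous-centroid PSO
(`run_baseline_pso()`, inertia 0.72, cognitive/social 1.49) is provided as
the comparison baseline under the identical fitness and reporting contract.

### Fitness

Five statistical measures are available: fuzzy entropy, kurtosis, skewness,
co-occurrence correlation, and variance. A partition is scored by
`aggregate_fitness()` as a weighted sum with default weights
`(1, 0, 0, 0, 1)`:

* **Fuzzy entropy** of the soft assignment: each point gets normalized
  inverse-distance memberships to the k centroids; the N × k membership
  matrix is normalized to total mass 1 and its Shannon entropy (natural
  log) computed, with the sign convention that the value is non-negative
  and *smaller is crisper*. (The raw double sum of `y log y` is ≤ 0; the
  implementation returns its negative so every component of the objective
  is minimized.)
* **Within-cluster variance**: pooled squared residuals to block centroids
  over N − 1.

Skewness and kurtosis (moment conventions, `(1/n)Σ(y−ȳ)^p / s^p` with the
n−1 standard deviation, so kurtosis ≈ 3 for a normal sample) and the GLCM
correlation are computed for reporting; their default weight is zero, and
the correlation slot is structurally zero for point-cloud data since it is
a co-occurrence statistic.

Entropy is scale-free while variance carries squared data units, so
`segment_image()` standardizes the intensity feature to unit variance (and
scales the normalized pixel coordinates to the same unit, weighted by
`spatial_weight = 0.2`) before clustering. Without this, on raw `[0, 1]`
intensities the variance term is numerically negligible and the entropy
term alone favours degenerate partitions that pair one bulk cluster with
far outlier singletons — membership crispness is maximized by centroids far
from the data bulk, not by compact clusters.

### Why k = 4 for fundus images

`swarm_config()` defaults to k = 3, a reasonable generic prior (dark /
mid / bright). The *pipeline* default is k = 4. On enhanced phantoms the
k = 3 objective has two near-degenerate optima that place the dark
threshold at noticeably different levels; the coarser one sweeps enough
dark background into the lesion cluster that dot lesions fuse with large
background components and are lost to the area filter. With k = 4 the extra
cluster absorbs the dark background tail, the darkest cluster stays
specific to vessels and lesions, and the merge step folds redundant
background clusters back together when their shapes agree.

## Cluster merging

After segmentation, cluster pairs are compared most-similar-first on their
pixel-intensity populations. Two clusters merge when their kurtosis and
skewness agree within `merge_tol`, or — failing that — when *both* pass the
D'Agostino–Pearson omnibus normality test at `merge_alpha = 0.05` (two
normal populations differing only in location and scale are treated as one
tissue class; the rule is deliberately location-blind). `should_merge()`
defaults to `tol = 0.5` for generic use at moderate sample sizes, where
sampling noise in the two statistics is of that order. The pipeline default
is `merge_tol = 0.05`: segmentation clusters hold 10^4–10^5 pixels, the
sampling error of kurtosis at that size is about 0.03, and a loose
tolerance was observed to merge distinct tissue classes whose shape
statistics coincide by chance. The omnibus statistic is
`K² = z_skew² + z_kurt²` with the D'Agostino (1970) and Anscombe–Glynn
(1983) normalizing transforms, referred to χ² with 2 degrees of freedom; it
requires n ≥ 8 and undersized clusters are never merged.

## Candidate extraction and classification

The lesion cluster is the one with minimum mean intensity — the standard
red-lesion heuristic. Its mask receives a radius-1 morphological opening
(cross element), which cuts the single-pixel noise bridges that otherwise
fuse a dot lesion with the vessel network or dark background patches, then
8-connected components are labelled in-package (the labeller is tested
against an independent implementation). Components are filtered by area
(`[9, 150]` px at 250 × 250 — discs of radius 2–5 px survive the opening
above 9 px, while residual noise specks stay below), eccentricity (≤ 0.85;
vessel fragments are elongated), and local contrast (region mean vs a 3 px
bounding annulus, ≥ 0.1).

Survivors are featurized with gray-level co-occurrence matrices: 16 gray
levels (small regions leave a 256-level matrix too sparse to carry texture
information), symmetric counting, features averaged over the four standard
offsets (0,1), (1,0), (1,1), (1,−1), with pairs restricted to mask pixels.
The six features are homogeneity `Σ p/(1+(i−j)²)`, maximum probability,
energy `Σ p²`, dissimilarity `Σ |i−j| p`, contrast `Σ (i−j)² p`, and the
mean `Σ p / (N·M)`. The mean is constant (`1/(N·M)`) for a normalized
matrix by construction; it is retained in that literal form, and a
count-based variant sits behind `normalized = FALSE` for users who want the
quantity to carry information. The final call is a conjunctive threshold
rule — microaneurysm iff homogeneity ≥ 0.5, eccentricity ≤ 0.85,
dissimilarity ≤ 3, and local contrast ≥ 0.18 — calibrated on a phantom
candidate study in which true lesions and false candidates separated
cleanly on area and local contrast; every cutoff lives in
`detection_config()` so users can recalibrate against their own ground
truth (`train_test_split()` provides the 80/20 list utility for that
workflow). An empty threshold map deliberately calls every candidate a
microaneurysm (vacuous conjunction).

## The phantom generator

`generate_phantom()` renders what the detector actually needs to be tested
against: a bright circular retinal field with a quadratic radial
illumination falloff (`base_intensity = 0.78`, relative falloff 0.3), dark
curvilinear vessels (random-walk polylines with a Gaussian cross-profile,
depth 0.25–0.4), dot lesions as multiplicative disc dips of depth
`lesion_contrast` with a short cosine rim taper, and additive Gaussian
noise (σ = 0.01) inside the field. Placement guarantees lesions sit fully
inside the field, apart from each other, and overlap vessels by at most 20%
of their area; exhausting the 100 retries per lesion raises an error rather
than silently dropping a lesion. Identical spec and seed give bit-identical
images and masks.

What the phantom does *not* emulate: color, the optic disc and macula,
exudates and hemorrhages, vessel branching and caliber variation, camera
vignetting beyond the radial model, and JPEG-like compression artifacts.
Passing the phantom suite therefore demonstrates that the chain detects
small dark compact structures against a smooth confounded background — not
clinical-grade performance on real fundus photographs, which depends on
annotation protocols and image quality far outside this model.
Vessel-*touching* lesions are a known residual failure mode: the opening
detaches most, but a lesion genuinely embedded in the vessel network can
stay fused with an elongated component and be filtered away.

## Numerical choices and degenerate inputs

* Moment statistics of zero-spread samples are reported as 0 with an
  explicit degenerate flag (`is_degenerate()`) instead of NaN.
* `0 log 0 := 0` throughout; memberships use an ε of 1e−9 on distances.
* Bilinear resampling uses pixel-center alignment with edge clamping;
  resizing to the current shape is an exact identity.
* Intensity quantization to L levels is `min(floor(v·L), L−1)` on clamped
  `[0, 1]` values.
* Ties in nearest-centroid assignment resolve to the lowest index;
  within-block order is canonicalized ascending so set semantics have a
  reproducible encoding.
* Greedy evaluation matching pairs the globally nearest
  candidate–lesion pair first, within `match_radius = 5` px.

## Problem sizes in the test suite

The suite exercises the exhaustive-enumeration oracle on instances of up to
8 points (where all 2-partitions can be enumerated), blob recovery on 90
points across 20 seeds, 10^4 randomized particle move cycles, and an
end-to-end batch of twenty 250 × 250 phantoms with five lesions of contrast
0.4 each — the same conditions `scripts/acceptance.R` recomputes. These
sizes were chosen so the full suite runs comfortably on a single desk CPU
while keeping every stochastic check at 20 replicates or more.

## Known limitations

* k is fixed per run; no model-selection over cluster counts.
* The classifier is a transparent conjunctive rule, not a learned model;
  its defaults are phantom-calibrated and will need recalibration for real
  images.
* The merge rule compares distribution shape only; clusters with equal
  shape but different locations merge by design, which is why the pipeline
  runs it with a tight tolerance.
* JPEG input is not supported (no reader in the dependency set); PNG and
  TIFF are.
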