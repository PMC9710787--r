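---
title: "Detecting MS1 precursor features in 4-D ion-mobility point clouds"
author: "timsDescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MS1 precursor features in 4-D ion-mobility point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timsDescent)
```

## The problem

Trapped-ion-mobility time-of-flight instruments record MS1 survey data as
a sparse four-dimensional point cloud: each detector reading has an m/z,
a mobility scan index (a proxy for collisional cross-section, reported as
1/K0), a retention time (the frame axis), and an intensity. A peptide
precursor appears in this space as a series of isotopic peaks spaced
1.003355/z Th apart in m/z, each peak approximately Gaussian along all
three coordinate axes, and all peaks co-eluting in retention time and
co-migrating in mobility. Typical features on this instrument class are
about 2 ± 0.3 Th wide in m/z (the whole envelope), 44 ± 14 scans through
mobility, and 6.6 ± 2.4 s in retention time. `timsDescent` detects these
features de novo — without prior knowledge of where they are — and reports
each one's monoisotopic m/z, charge state, apexes and extents, intensity,
and quality attributes.

## The detection procedure

1. **Voxel ranking.** The cloud is partitioned into voxels of 0.1 Th ×
   10 scans × 5 s (half-open bins anchored at 0). The m/z width is chosen
   to capture a single isotopic peak; the scan and RT spans sample a peak
   broadly enough to locate its apex. Non-empty voxels are ranked by mean
   point intensity (descending, ties broken by voxel key for
   reproducibility) and consumed in that order until the mean intensity
   falls below `min_voxel_intensity`. This stopping threshold is the
   depth-versus-runtime knob and is deliberately config-required: its
   useful range depends on the detector's counting scale. The ranking
   statistic and the stopping statistic are the same (mean, not total)
   so that the queue is consistent with its own cutoff.
2. **Band scheduling.** The m/z axis is cut into 10 Th bands; each worker
   processes the voxels of one band. Bands schedule voxels only — feature
   building always reads the global cloud — and voxel retirement is kept
   band-local, so results are identical for any worker count; duplicate
   detections across band edges are resolved by the final de-duplication.
3. **Peak profiling.** The seeding voxel's intensity-weighted m/z
   centroid is computed and its peak extent taken as ±3σ, with
   σ = (centroid / resolution) / (2√(2 ln 2)) at a resolving power of
   40,000 (an FWHM-based convention; the instrument reports resolving
   power, not σ, so some convention is required). Points within that m/z
   extent and ±40 scans of the voxel's mobility midpoint (twice the mean
   mobility peak width) are flattened onto the scan axis, smoothed with a
   Savitzky–Golay filter (window 11, order 3 — standard for ~40-scan
   peaks; both configurable), and the apex nearest the voxel midpoint is
   chosen, bounded by the nearest local minima (window edges when no
   interior valley exists). The same procedure runs on the RT axis with a
   ±13.2 s half-window (twice the mean 6.6 s base width); frames more
   than 1 s from the chain containing the apex are then trimmed to avoid
   trailing and leading edges. Local maxima below 5% of the series
   maximum are not apex candidates (noise suppression); an apex sitting
   on the window edge is flagged low-confidence.
4. **Envelope region and intensity descent.** The peak's m/z bounds are
   extended by −0.6 Th (one charge-2 isotope plus margin, in case the
   seed is the base rather than the monoisotopic peak) and +3 Th (up to
   six charge-2 isotopes plus margin). The 3-D region is simplified to a
   2-D spectrum by intensity descent: repeatedly take the most intense
   remaining point, group everything within its ±3σ m/z extent into one
   centroided peak, and remove the group. The procedure conserves total
   intensity exactly and is deterministic (ties break to lower m/z).
5. **Deconvolution.** Every spectrum peak is tried as a candidate
   monoisotopic peak for charges 1–4: peaks are collected at expected
   spacings (nearest peak within 10 ppm, walking upward until the first
   missing isotope). Candidates with ≥ 3 isotopes are scored against the
   averagine-model envelope at the implied neutral mass:
   Σ √I · w_mz · w_height, with w_mz penalizing spacing error and
   w_height penalizing disagreement with the predicted peak-height
   fractions. The √I weighting makes well-populated envelopes outscore
   short misinterpretations (e.g. a charge-1 reading of a charge-2
   envelope's even isotopes matches fewer peaks and scores lower).
   Envelopes must exceed a score threshold (default 20, calibrated on
   the synthetic suite so that noise-only regions essentially never
   produce features while planted features 100× below the brightest are
   retained). The accepted envelope must additionally have its
   monoisotopic **or** base peak within 10 ppm of the seeding voxel's
   centroid, which ties every feature to the voxel that proposed it.
6. **Attributes.** Feature intensity is the sum over the first three
   isotopes of the mean, across the three frames nearest the RT apex, of
   each frame's maximum point intensity in the isotope's m/z extent — the
   three-frame mean damps single-point fluctuations. A per-point
   saturation-correction hook is applied before the maximum; the default
   is the identity, and detector-specific models can be plugged in.
   Coelution and mobility coefficients are the mean cosine similarity of
   each higher isotope's RT and scan profile with the monoisotopic
   profile.
7. **Retirement.** Voxels whose intensity is more than 80% contributed by
   an accepted feature's isotopic-peak points are retired (strictly
   greater than; 800/1000 is kept). Retirement is idempotent and monotone
   in the point set.
8. **Classification and de-duplication.** An optional classifier scores
   each feature's identifiability from four attributes (deconvolution
   score, coelution coefficient, mobility coefficient, number of
   isotopes); features below 0.2 are dropped — a deliberately permissive
   threshold that removes only the least promising detections. Finally,
   features within 10 ppm, 20 scans and 5 s of each other (single-linkage
   connected components; the tolerance relation is not transitive, so
   some grouping convention is needed) are collapsed to the
   highest-scoring member, with ties going to higher intensity and then
   lower m/z. When no classifier is supplied the deconvolution score
   orders duplicates instead.

## The identifiability classifier

The network is a feed-forward architecture: 4 inputs, hidden dense layers
200 units wide (3 by default) each with batch normalisation and 40%
dropout, and a single sigmoid output, trained with Adam (learning rate
1e-3) on binary cross-entropy with an 80/10/10 train/validation/test
split and batch size 512; inputs are z-score standardized with statistics
fitted on the training split only (the four inputs span very different
scales). The default regime is 4000 epochs; the synthetic tasks in the
test suite converge within 80. The implementation is plain R matrix
algebra, which keeps training bit-reproducible under a fixed seed.
Training labels would in practice come from a search-engine run (features
identified at q < 1% versus detected-but-unidentified); the package
trains from any labelled table with the four input columns, and its tests
use synthetic separable tasks — they demonstrate that the classifier
learns, not what accuracy real data would give.

## The synthetic generator

`simulateCloud()` plants features with known ground truth on the
acquisition grid (frames every 0.5 s; integer scans; 1/K0 decreasing
affinely in scan — real instruments need a calibration supplied with the
data). For each feature, grid-node intensities follow the product of
Gaussians in RT and scan scaled so the expected total equals the planted
intensity, with Poisson jitter per node; each point's m/z is drawn from a
Gaussian around its isotope center with σ matching a resolving power of
40,000, and isotope amplitudes follow the averagine envelope at the
feature's neutral mass. Noise is uniform in position with exponential
intensities (mean 30 counts, density 1e-3 points per Th·scan·s) — a
de-noised-instrument ambient model that exercises voxel ranking and the
stopping rule. Sigma values are drawn from the typical base widths above
(σ = width/4).

The standard benchmark (`simulateBenchmark()`) plants 50 features with
charges 2–4 and intensities log-uniform over a 100× span (1e5–1e7 summed
counts) in a 120 Th × 600 scan × 300 s extent, with apexes
rejection-sampled so no two features collide on all three axes at once.
The benchmark cloud is ~370k points and detection at
`min_voxel_intensity = 50` runs in well under a minute on one CPU; the
test suite and acceptance script use these sizes throughout.

What the generator does **not** emulate: chromatographic tailing and
fronting, charge-correlated mobility, overlapping envelopes from
co-eluting peptides, detector saturation nonlinearity (the hook exists
but defaults to identity), and structured chemical noise. Passing the
synthetic benchmark therefore demonstrates the machinery is correct under
the stated geometry — not that real-data recovery will match it.

## Numerical choices and degenerate inputs

- Resolution→σ conversion is FWHM-based (σ = FWHM/2.35482) everywhere.
- Binning uses half-open intervals [k·w, (k+1)·w) with a 1e-9 relative
  epsilon so boundary values land in the upper bin despite floating-point
  representation.
- Voxels with fewer than 3 distinct profile positions, zero-intensity
  centroids, or no points near the RT apex raise typed conditions; the
  pipeline logs and skips such voxels, never aborts.
- The expansion step is not idempotent and is guarded by a single-call
  contract in the pipeline.
- Greedy nearest-in-ppm matching is used for feature-set comparison; on
  adversarial instances it can fall one pair short of the optimal
  bipartite assignment (the tests bound it against an exhaustive oracle
  on small instances).

## Known limitations

- Overlapping isotopic envelopes are not co-deconvolved; the stronger
  envelope wins the shared peaks.
- A seeding voxel on a high isotope of a feature whose monoisotopic peak
  lies below the −0.6 Th expansion can yield an isotope-shifted
  duplicate; de-duplication removes exact duplicates but isotope-shifted
  ones survive as (rare) false positives.
- The mean-intensity interpretation of the stopping threshold is a
  documented choice (consistent with the ranking statistic); a
  total-intensity interpretation would change which sparse voxels are
  processed.
- Vendor raw formats are out of scope: the native input is the delimited
  point table, and converting instrument databases to it is an external
  step.
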