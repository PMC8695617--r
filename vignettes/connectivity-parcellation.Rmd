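---
title: "Connectivity-based parcellation of the olfactory amygdala: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connparc)
```

## The scientific problem

The medial amygdala (MeA), cortical amygdala (CoA) and periamygdaloid
complex (PAC) receive direct olfactory-bulb projections and are believed to
support distinct olfactory functions, but they are small, adjacent, and hard
to separate in human imaging. The method implemented here asks whether their
*whole-brain resting connectivity profiles* alone suffice to delineate them:
if each subregion participates in a distinct distributed network, then
clustering voxels by the similarity of their connectivity profiles should
reproduce the anatomical boundaries — and the same machinery separates the
olfactory subregions as a group from the non-olfactory amygdala (k = 2),
delineates the three subregions from each other (k = 3), and maps the
unique and shared portions of their whole-brain networks.

Because analyses of this kind are usually validated only against anatomy,
`connparc` pairs every stage with a *phantom*: a seeded generative model of
a multi-subject resting-state cohort in which the ground truth is known by
construction. All quantitative claims in the test suite are statements
about this phantom, computed at run time.

## The model, stage by stage

### Preprocessing

A subject's series is cleaned in the conventional order: drop the first
`drop_n = 10` volumes (pre-steady-state), remove linear and quadratic
trends per voxel (`detrend_order = 2`), regress out nuisance time courses
(six motion-like parameters plus mean white-matter and CSF signals, the
tissue means taken after eroding the tissue masks by one voxel so gray
matter is not falsely sampled), scale the whole 4D block so its in-mask
grand mean is 10000, apply an ideal Fourier band-pass, and smooth with a
Gaussian kernel of `sigma_mm = 3` (sigma interpreted in millimeters, so
1.5 voxels on a 2 mm grid; kernel truncated at 4 sigma and renormalized at
the volume boundary so constants are preserved).

Three deliberate choices:

* **Grand-mean scaling factor.** Detrending and nuisance regression remove
  the temporal mean, so the scale factor `10000 / grand mean` is computed
  from the series as it *enters* the pipeline (after volume dropping) and
  applied at the normalization stage. The standalone
  `grand_mean_normalize()` keeps the strict semantics (error on zero-mean
  input).
* **Regressors are detrended with the same polynomial basis** before the
  nuisance fit. By the Frisch–Waugh theorem this makes the sequential
  pipeline exactly equal to a single joint regression containing the
  polynomial columns — a property the test suite checks to 1e-8.
* **The band-pass is an ideal Fourier-domain filter**: bins with
  `low_hz <= f <= high_hz` are kept, everything else (including DC) is
  zeroed. This is exactly testable (the output spectrum is identically zero
  outside the band, and the filter is idempotent). The default band is
  0.008–0.01 Hz, taken verbatim from the preprocessing convention this
  package follows. That band is strikingly narrow — at desk-scale series
  lengths (a few hundred volumes) it retains zero to two Fourier bins — so
  the package treats it purely as configuration: the analyses run by the
  test suite and by `scripts/acceptance.R` compute connectivity on
  detrended, nuisance-regressed series without band-pass or smoothing.
  This keeps signal recovery from being confounded with one contested
  filter setting; the filter itself is tested separately and exhaustively.

### Connectivity profiles

For each voxel in the seed mask, the profile is the vector of Pearson
correlations with every gray-matter voxel outside the seed mask. The
gray-matter analysis mask is a tissue-prior threshold at 100 (inclusive:
voxels exactly at threshold are kept, matching the zero-below semantics of
common thresholding tools). The *entire* seed mask is excluded from the
target space — not just the self-voxel — so every seed voxel has the same
feature dimensionality and no cluster can form around trivial
self-similarity; per-self-voxel exclusion is rejected explicitly by the
API. Group aggregation is `tanh(mean(atanh(r)))` over subjects;
correlations are clipped to ±0.999999 before `atanh` so degenerate
identical-series cases stay finite.

### Parcellation

k-means with the correlation distance `1 − cor(x, c)`, where both the
profile and the centroid (the arithmetic mean of member profiles) are
centered — Pearson, not cosine. k is a design input (2 and 3 for the two
main analyses), never selected automatically. Because the initialization
of "standard k-means" is not specified anywhere, each of `n_replicates`
(default 50) restarts uses k-means++-style seeding from its own
deterministic sub-seed and the lowest-objective solution is returned;
results are reproducible from `(profiles, k, n_replicates, seed)`. Empty
clusters arising during Lloyd iterations are repaired by reseeding the
empty centroid at the voxel farthest from its current centroid, keeping k
fixed. Cluster-to-ROI correspondence is the exact maximum-overlap
one-to-one assignment (exhaustive search over permutations, k ≤ 8; ties
break to the lexicographically first assignment).

### Permutation statistics

Both tests shuffle labels without replacement (pure permutations, label
counts preserved) and summarize the null with a normal fit:
`z = (observed − mean(null)) / sd(null)` (n−1 denominator), two-sided
`p = 2 Φ(−|z|)`.

* **k = 2 separation test**: the statistic is the difference in the
  percentage of olfactory voxels between the two clusters, with the
  clusters ordered once by the *observed* olfactory percentage
  (richer cluster first) and that order held fixed across permutations.
  The orientation makes the signed statistic well-defined; because
  ordering by observed richness makes the observed value the absolute
  difference while the permuted values keep both signs, the two-sided
  normal test remains exactly calibrated (the rejection event
  `|D_obs| > 1.96 sd` is unchanged), which the suite verifies empirically
  (type-I rate 3–8% over 200 null cohorts).
* **k = 3 proportion test**: `P[c, r]` = fraction of cluster c inside
  ROI r; each permutation shuffles ROI labels across seed voxels with
  clusters fixed; per-cell z and two-sided p; Bonferroni over all
  `k × R` cells at alpha 0.05.

The two-sided convention is adopted because it is the one consistent with
the headline z-to-p pair this machinery is meant to reproduce (z = 4.79
gives p = 1.7e-6 two-sided); under the same convention z = 4.27 gives
2.0e-5, so the second printed pair in the source analysis is not
reproducible and is not targeted.

### Network maps

The group-level statistic is a per-voxel one-sample t of subject Fisher-z
maps against zero (sd floored at 1e-12), a declared design choice — the
construction behind a bare "TFCE corrected P < 0.05" is not otherwise
pinned down. TFCE uses the canonical volumetric defaults E = 0.5, H = 2,
100 integration steps (dh = max/100) and 6-connectivity, all configurable;
enhancement is one-sided positive (anticorrelations are not mapped).
Family-wise error is controlled by sign-flip permutation of subject maps
with the max-TFCE statistic; the corrected p is `(1 + #{maxima >= enh}) /
(1 + n_perms)`, which never returns zero and is monotone in the enhanced
value. Binarized maps for MeA, CoA and PAC are partitioned into the 8
mutually exclusive membership categories, and the Venn counts are the
category sizes (they sum to the union of the three maps by construction —
a conservation law the tests check on random map triples).

The TFCE implementation is compiled (union-find over a precomputed
mask-adjacency graph; the whole sign-flip loop runs in C++). An
independent brute-force R implementation — explicit per-threshold BFS
component labeling — lives in the test helpers and must agree to 1e-9
relative on random smoothed maps.

## The phantom

`simulate_cohort()` draws, per subject: one latent band-limited
unit-variance Gaussian time course per subregion, injected (scaled by
`coupling_amplitude`) into that subregion's voxels and its distal target
block; polynomial drift with per-voxel N(0, `drift_coeffs_sd`)
coefficients; motion-like regressors (standardized random walks) with
per-voxel loadings; shared white-matter and CSF signals inside their
tissue compartments; a constant baseline (1000) inside the brain; and
i.i.d. N(0, `noise_sd`) noise. Optional `shared_networks` inject an
additional latent into several subregions and a common target block — the
structure that makes the three olfactory subregions mutually similar and
lets k = 2 separate them from a non-olfactory subregion, and that shows up
as the all-shared category in the network maps. With
`mirror_symmetry = TRUE`, every voxel set is reflected about the
mid-sagittal plane and left/right portions share the subregion's latent,
which is what makes bilateral parcellation group hemispheres together.

Defaults are the study conditions the pipeline emulates: 25 subjects,
TR 0.555 s, 1090 volumes (~10 minutes plus the 10 dropped), 2 mm voxels,
3 subregions of 60 voxels. The coupling default `sqrt(2/3)` with
`noise_sd = 1` gives expected within-network voxelwise r of
`a² / (a² + σ²) = 0.4`. The latent passband (0.01–0.08 Hz) sits inside
the conventional resting-state analysis band so that planted structure
survives band-pass filtering rather than being an artifact of skipping
it. Subject variability enters only through fresh noise and nuisance
draws (no coupling jitter), keeping group-level expectations closed-form.
Simulation is a pure function of the configuration: per-subject streams
are derived deterministically from the master seed, and reruns are
bit-identical.

What the phantom does *not* emulate — hemodynamic response shape, head
motion as image displacement, scanner drift structure, spatial
autocorrelation of noise, anatomical geometry — bounds what passing tests
show: they validate the statistical machinery (recovery, calibration,
conservation, determinism) under the model's assumptions, not performance
on real scanner data.

## Numerical choices and degenerate inputs

* Correlations clipped to ±0.999999 before `atanh`; ROI voxels in seed
  maps are NA, never numeric.
* Zero-variance voxels are reported by flat index rather than silently
  dropped; degenerate (constant) permutation nulls are errors.
* Erosion uses the 6-neighbor structuring element (most conservative;
  volume boundary counts as outside); 18/26 available.
* Voxel bookkeeping uses R's native 1-based column-major flat indices,
  recorded alongside the grid in every sidecar — one unambiguous
  convention across modules and files.
* k-means ties in assignment break to the lowest cluster index
  (`max.col(ties.method = "first")`); replicate comparison prefers the
  earlier replicate unless a later one is better by more than 1e-12.

## Problem sizes in the test suite

The acceptance-style tests run at desk scale, chosen once: recovery uses
3 subregions × 60 voxels, 192 planted target voxels and ~1160 additional
gray voxels on a 20×16×8 grid, 20 subjects × 300 volumes × 20 master
seeds; calibration runs use 200 replicate null cohorts (separation test:
2 subjects × 80 volumes, 500 permutations; FWE: 12 subjects on a 6×6×6
mask, 200 sign-flip permutations); the bilateral analysis uses a mirrored
32×16×8 grid with 8 subjects. The null-distribution check compares
`atanh(r)·sqrt(T−3)` over 10,800 voxel pairs against N(0, 1) with a
Kolmogorov–Smirnov test at alpha 0.01.

## Known limitations

* The permutation p is a normal fit to the null, not an exact permutation
  p; agreement holds near the center of the null but extreme tail values
  (z > ~4) extrapolate beyond what `n_perms` draws can witness.
* Shuffles are spatially unconstrained; smooth real data violates
  exchangeability more than the phantom does, so real-data z values are
  anti-conservative to an unknown degree.
* Registration, segmentation, motion correction and atlas construction are
  out of scope: all inputs are assumed to share one grid.
* Exhaustive ROI matching is exact but limited to 8 clusters; hierarchical
  or spectral alternatives to k-means are intentionally absent (k is a
  design input here).
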