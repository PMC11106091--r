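---
title: "Fractal dimension and lacunarity of OCTA capillary plexus images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal dimension and lacunarity of OCTA capillary plexus images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) renders the retinal
capillary circulation as en-face grayscale slabs, one per vascular layer —
the superficial (SCP) and deep (DCP) capillary plexus. In diabetic macular
edema, capillary dropout degrades the geometry of this network, and two
scale-aggregated descriptors summarise that degradation: the box-counting
**fractal dimension** (FD), which measures how completely the vessel
skeleton fills the plane (bounded by 2), and the gliding-box
**lacunarity** (LAC), which measures the gappiness of the mass
distribution at a given dimension. This package implements the full
measurement chain — binarization, skeletonization, FD, LAC — together with
a calibrated synthetic cohort generator and the two-group/correlation
statistics used to relate macular fractal metrics to the extent of
peripheral non-perfusion (the count of affected peripheral quadrants on
fluorescein angiography, 0–4 per eye).

## Preprocessing: from grayscale slab to skeleton

`binarize()` applies, in order:

1. a **median filter** over a disk of radius 2 px (13 pixels). "Radius"
   is taken literally as a disk, not a square; borders are handled by edge
   replication so the local histogram is not diluted with zeros. The
   radius is configurable (`median_radius_px`).
2. **Otsu's threshold** on the 256-bin histogram of the filtered image:
   the threshold `t` maximises the between-class variance, with ties broken
   towards the smallest `t`. A constant image has no threshold and raises a
   degenerate-input error.
3. the **foreground rule**: a pixel is vessel iff its filtered intensity is
   strictly above `t`. This convention is stated once and fixed; together
   with the tie rule it makes binarization fully deterministic.

Filtering *before* thresholding is the default (`filter_order = "pre"`):
speckle suppression is what makes the histogram cleanly bimodal, so the
filter should inform the threshold. The reverse order remains available as
a configuration switch for sensitivity analyses.

`skeletonize()` thins the vessel mask to unit width by iterative
Zhang–Suen thinning (8-connected foreground), run to a fixed point, which
makes the operation idempotent; since thinning only deletes pixels, the
skeleton is always a subset of the mask. Two degenerate situations need a
stated tie-break:

* Zhang–Suen can leave 2×2 blocks at staircase junctions. A post-rule
  deletes block members whose foreground neighbours remain mutually
  8-connected after deletion. Where two unit-width diagonal lines cross,
  no member satisfies this — a diagonal crossing cannot be both unit-width
  and fully connected under deletion-only thinning — and the unit-width
  guarantee is given priority: the member with the fewest neighbours
  outside the block is removed, opening one diagonal contact by a single
  pixel. The effect on box counts and window masses is at the
  single-pixel level; the no-2×2-block invariant is absolute.
* If thinning annihilates a small compact blob entirely, its first
  foreground pixel is retained, so a non-empty mask always yields a
  non-empty skeleton.

## Fractal dimension: multi-origin box counting

For each box size ε the image is partitioned into an ε×ε grid and the
boxes containing at least one skeleton pixel are counted, N(ε); partial
boxes at the image edge participate. Because counts at a single grid
placement carry grid-phase noise, the grid is re-anchored at
`n_origins = 4` deterministic offsets — the corners of a 2×2 lattice over
[0, ε)², always including (0, 0) — and the counts are averaged.
Averaging (rather than taking the minimum) is the default because it
reduces phase variance without biasing the slope; both the number of
origins and the box ladder are configurable.

The default ladder is dyadic, ε = 2, 4, …, floor(min(H, W)/4), giving six
fit points at 256 px. FD is the slope of the ordinary least-squares fit of
log N(ε) on log(1/ε), clamped to [0, 2] with the raw value preserved, and
reported with the fit's R². Exactness anchors: a filled square yields
FD = 2 with R² = 1 identically; a level-5 Sierpinski carpet measured at
ε = 3^k from origin (0,0) yields its similarity dimension
log 8 / log 3 ≈ 1.8928 exactly, because the construction gives
N(3^k) = 8^(5−k).

## Lacunarity: gliding box

For each window size r, an r×r window slides with step 1 over all fully
contained positions; with M the skeleton mass per window,
Λ(r) = ⟨M²⟩/⟨M⟩² = 1 + CV². Window sizes whose mean mass is zero are
skipped. Both FD and LAC are computed on the *skeleton*, not the filled
mask, so the two descriptors refer to the same object.

The scalar summary is the mean over r of Λn(r) = 1 − 1/Λ(r), which maps
the homogeneous limit to 0 and extreme gappiness towards 1. This
normalisation is a documented package convention (the raw mean Λ and mean
CV² are exposed as alternatives): it produces values on the same [0, 1)
scale as the cohort statistics this pipeline is meant to reproduce, and it
keeps the summary insensitive to the absolute skeleton density that Λ(1)
would otherwise dominate.

## The synthetic cohort generator

No patient images are distributed, so every downstream stage is exercised
on synthetic slabs whose *measured* statistics are calibrated to the
target cohort. The generator emulates three things:

1. **Healthy capillary texture**: a stripe carrier of period 5 px whose
   phase is modulated row-wise by seeded band-limited displacement (three
   harmonics, periods 37/13/7 px, amplitudes 6/4/2 px, random phases).
   This yields dense, wavy, locally parallel unit-calibre vessels with
   uniform coverage and a vessel-area fraction set by the carrier duty
   cycle (0.58 SCP, 0.60 DCP — the deep plexus is slightly denser, so its
   mean FD sits marginally above the superficial one). A purely
   noise-thresholded texture was evaluated first and rejected: across
   isotropic and oriented band-pass variants its through-pipeline FD
   plateaued near 1.8 at 256 px, short of the healthy-eye target; the
   modulated lattice reaches ≈1.86 with low seed-to-seed variance.
2. **The foveal avascular zone**: a cleared central disk of radius 0.10 of
   the image side.
3. **Ischemic dropout**: elliptical patches (semi-axes n/32–n/14, random
   orientation) are cleared until a target fraction of the vessel area is
   removed. Per eye, that fraction is `0.22 × npa_quadrants` plus seeded
   Gaussian jitter (SD 0.05, clamped to [0.02, 0.95]); well-perfused eyes
   get none. Dropout severity is therefore non-decreasing in quadrant
   count by construction.

The binary pattern is rendered to 8-bit grayscale (vessel 180, background
40), with additive Gaussian noise (SD 10) and sparse bright speckle
(0.1%), so the binarization stage has realistic work to do. Clinical
covariates are drawn from group-specific normals truncated to plausible
ranges (BCVA 0–100 letters, CMT 150–900 µm, age 30–95 y); sex counts per
group are assigned exactly.

All constants above are **committed calibration values**, derived once by
a grid search over the generator parameters with the objective evaluated
through the full measurement pipeline (not on the latent masks), and then
frozen. Tests never re-calibrate. Under these defaults, 20-seed default
cohorts measure: well-perfused SCP FD ≈ 1.86, NPA-group SCP FD ≈ 1.38,
cohort SCP FD ≈ 1.57, cohort SCP LAC ≈ 0.40, cohort DCP FD ≈ 1.58, and
corr(SCP FD, quadrant count) ≈ −0.94.

What the generator does **not** emulate: real branching topology and
vessel-calibre heterogeneity, flow/projection artifacts, segmentation
errors, inter-eye texture correlation, or any joint distribution between
fractal metrics and covariates beyond group membership (left at
independence). Passing tests therefore certify the measurement chain and
the statistics stage, not device realism.

## Randomness and determinism

Every stochastic step derives its stream from a single cohort seed via a
documented integer hash (`derive_seed()`), one sub-stream per eye, per
plexus and per purpose; no global RNG state leaks in or out (the caller's
`.Random.seed` is saved and restored). Identical seeds give byte-identical
images, tables and reports; the run manifest written by `run_pipeline()`
(config, config hash, package version) suffices to reproduce a run
bit-for-bit.

## Statistics stage

Group comparisons use **Welch's** unequal-variance t test by default: the
two groups' FD standard deviations differ by more than an order of
magnitude (the well-perfused group is nearly degenerate), which is
exactly the situation pooled-variance t handles badly. Student's variant
is available by flag. Correlations with non-perfusion extent use Pearson's
r against the integer quadrant count (0–4); a binary NPA indicator is
available as an alternative coding. No multiple-testing correction is
applied by default. Both statistics are authored implementations validated
against base R's `t.test()` and `cor.test()` to 10 significant digits in
the test suite.

## Problem sizes

Slabs are generated and analysed at 256×256 px — large enough for a
six-point dyadic ladder and stable group means, small enough that a
50-eye, two-plexus cohort takes a few seconds end-to-end. Cohort-level
properties are evaluated over 20 seeds; estimator/oracle equivalence is
checked exhaustively on images up to 64×64, where brute-force enumeration
is cheap.

## Known limitations

* FD and LAC values depend on resolution, the box ladder and the
  skeletonization convention; absolute values are comparable only within
  a fixed pipeline configuration (which the run manifest records).
* The Otsu stage assumes a roughly bimodal histogram; extremely sparse
  skeletons after heavy dropout push the fit toward its small-count
  regime, where FD estimates are noisy (reflected in the wide NPA-group
  spread).
* The generator's dropout model removes vessels in patches; diffuse
  rarefaction (thinning without patch structure) would trace a different
  FD/LAC path at equal dropout fractions.
* One-pixel background holes inside 2×2 skeleton clumps are sacrificed to
  the unit-width guarantee (see the thinning tie-breaks above).
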