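---
title: "Threshold-based PET tumor volumetry: models, phantom design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based PET tumor volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvseg)
```

## The problem

Quantifying tumor burden on PSMA-ligand PET requires turning a continuous
uptake image into a binary tumor volume. The most widely used approaches are
threshold based: a voxel belongs to the tumor if its standardized uptake
value (SUV) exceeds a cut-off. The cut-off can be

* **fixed** — an absolute SUV (e.g. SUV 4.0), identical for every patient;
* **isocontour** — a fraction of the lesion's own SUVmax (e.g. 40% SUVmax),
  adaptive per lesion;
* **background-relative** — a fraction of a reference tissue's SUVmean
  (liver, parotid gland or spleen), adaptive per patient.

`suvseg` implements all five families, the reference-region measurements
they depend on, a per-lesion *inverse* solver (given a target volume, find
the threshold that reproduces it), and the statistical machinery used to
compare each method's volumes against an independent volumetric reference:
correlation with a Shapiro–Wilk normality gate, coefficient of variation
(CoV), Bland–Altman limits of agreement and Kruskal–Wallis comparisons.

Because clinical images with a CT-based reference standard are not freely
shareable, the package ships a digital phantom generator whose analytic
ground truth plays the role of the manually contoured CT volume. Everything
downstream — segmentation, inverse solve, agreement statistics — is
validated against brute-force oracles and exact analytic expectations on
that phantom.

## Segmentation model

All families reduce to one primitive. For a volume $I$ with voxel volume
$v$ (ml) and a lesion VOI $V$ (an axis-aligned ellipsoid), the segmented
volume at absolute threshold $t$ is

$$\mathrm{vol}(t) = v \cdot \#\{x \in V : I(x) \ge t\}.$$

The threshold rule is *inclusive* ($\ge$), so a 100% isocontour still
contains the SUVmax voxel, and the inverse solve always has a well-defined
finite candidate set. The derived thresholds are

* isocontour: $t = f \cdot \mathrm{SUVmax}_V$, $f \in (0, 1]$;
* background-relative: $t = f \cdot \mathrm{SUVmean}_{\mathrm{ROI}}$, with
  the liver sampled by a 30 mm-diameter single-slice axial disc, the parotid
  by a 10 mm cube and the spleen by a 30 mm cube.

Membership of a voxel in any VOI/ROI is decided by its *centre* point
(no partial-volume weighting). This makes every geometric quantity exactly
reproducible by a three-line triple loop, which is how the test suite
checks it. The voxel count times $v$ then converges to the analytic
geometry volume as spacing shrinks — also asserted in the tests.

All suprathreshold VOI voxels are counted without a connectivity
requirement: the workflow assumes the VOI was drawn to exclude off-target
avid structures, so disconnected suprathreshold voxels inside it are noise
around the boundary, not separate lesions. An optional 26-connectivity mode
(`connected = TRUE` keeps the component containing the VOI maximum) is
provided for VOIs that cannot exclude a nearby hot structure; it is off by
default because it makes small noise-dependent differences in volume and is
not needed on well-placed VOIs.

### Inverse ("backwards") thresholding

Given a target volume $V_T$ (the reference volume of that lesion), the
solver enumerates the unique voxel SUVs inside the VOI — the only points
where $\mathrm{vol}(t)$ changes — and returns the candidate minimizing
$|\mathrm{vol}(t) - V_T|$. Ties are broken toward the *larger* threshold,
i.e. the smaller volume, so the solver never overshoots the target by
choice. Two properties are guaranteed and tested: re-applying the returned
threshold reproduces the achieved volume exactly, and no attainable volume
is closer to the target (verified against exhaustive enumeration).

## Phantom design

Each case is built in three steps: paint, blur, corrupt.

1. **Paint.** A 192 × 192 × 128 mm field of view at 2 mm isotropic spacing
   (PET-like; configurable) is filled with soft-tissue uptake. Three
   rectangular tissue blocks (liver, parotid, spleen) occupy the half of
   the field away from the lesion, separated by soft-tissue gaps wide
   enough that blur cannot carry one tissue's uptake into another's
   reference ROI. The lesion is a homogeneous axis-aligned ellipsoid at
   `peak_suv`.
2. **Blur.** A separable Gaussian point-spread function of 2 mm FWHM —
   the post-reconstruction smoothing typical of modern PET — applied as
   one BLAS matrix product per axis. Kernel rows are renormalized at the
   image border, so constant fields pass through unchanged and the image
   integral is conserved away from the border (tested to 0.1%).
3. **Corrupt.** Additive Gaussian noise (SD 0.3 SUV by default), truncated
   at zero. This is a desk-scale surrogate for post-reconstruction noise,
   not a count-statistics model.

The ground-truth volume is the *analytic* ellipsoid volume
$\tfrac{4}{3}\pi abc$, not a voxelized mask: manual slice-by-slice CT
contouring approximates true morphological volume, and an analytic truth
makes the convergence of voxel counts testable.

### Cohort distributions

The defaults emulate the structure of a 50-lesion lymph-node cohort with a
CT reference standard:

| Parameter | Default | Rationale |
|---|---|---|
| n_cases | 50 | typical single-centre cohort size |
| Ground-truth volume | log-normal, median 3.2 ml, truncated to [1.0, 23.8] ml | matches the reported median and range of CT-derived node volumes |
| Elongation (long/short semi-axis) | uniform [1, 1.8] | nodes are mildly prolate; short axis floored at 5 mm (SAD ≥ 10 mm inclusion criterion) |
| Lesion peak SUV | uniform [8, 40] | spans faint to intensely avid nodes, so fixed, isocontour and background-relative thresholds genuinely differ |
| Parotid SUVmean | log-normal, median 20.1 | reference-tissue uptake medians reported for PSMA PET |
| Liver SUVmean | log-normal, median 11.3 | — |
| Spleen SUVmean | log-normal, median 9.9 | — |
| Soft tissue SUVmean | log-normal, median 1.5 (0.8–2.8) | typical blood-pool/soft-tissue avidity; not reported, chosen once |
| Noise SD | 0.3 SUV | desk-scale reconstruction-noise surrogate |
| PSF FWHM | 2 mm | post-reconstruction Gaussian smoothing |
| VOI margin | +6 mm per semi-axis | 3 × FWHM clearance around the lesion boundary |

Background tissues are sampled **independently** — their uptakes are
uncorrelated across patients, which the tests verify on 10,000 draws
(pairwise |r| < 0.05).

Each log-normal is parameterized by its median (`meanlog = log(median)`,
so the median is exact) and by an `sdlog` chosen so the central 95% span
has the same width on the log scale as the reported range. A two-parameter
log-normal cannot match both endpoints of an asymmetric range exactly;
matching the median and the range *width* was preferred over matching
either endpoint. A degenerate range (`lo == hi`) yields constant draws,
which the tests use to build noise-free phantoms.

Seeds propagate through a deterministic per-case sub-seed, so cohorts are
reproducible case by case and two runs of the pipeline with one config are
byte-identical (tested).

### What the phantom does and does not emulate

The phantom captures the features that threshold-based volumetry is
sensitive to: partial-volume blur at the lesion boundary, lesion-size and
lesion-contrast variation across a cohort, background uptake variability
and reference-ROI sampling. It does **not** model attenuation, scatter,
reconstruction artifacts, respiratory motion, intra-lesional
heterogeneity (uptake is homogeneous before blur) or non-ellipsoidal node
morphology. Passing tests therefore demonstrate the *internal* correctness
of the segmentation and statistics, and qualitative behaviours (an
interior optimum of the fixed-threshold grid; degradation of extreme
thresholds), not clinical performance on patient images — the cohort's
correlation values are not expected to reproduce any particular clinical
study's numbers.

## Evaluation harness

For every family × level the harness correlates PET volumes with the
reference volumes. The correlation type is gated per pair: Pearson iff
*both* variables pass Shapiro–Wilk at α = 0.05, else Spearman — a fixed,
deterministic convention where the clinical literature often leaves the
choice implicit. r² is always computed as r·r. Bland–Altman limits of
agreement are mean(d) ± 1.96 sd(d) with the sample (n−1) standard
deviation; the sample SD is used everywhere (CoV included), another
convention fixed here because reports rarely state it.

Ranking picks the argmax of r within each family, ties toward the lower
level (the less aggressive threshold). The backwards analysis reports
mean ± SD and CoV of the per-lesion inverse thresholds, then re-applies
the single cohort-mean threshold to every lesion and correlates those
volumes with the reference — quantifying how much is lost when a per-lesion
optimal threshold is replaced by one population value. On the default
cohort this reapplied correlation is lower than the best fixed-grid
correlation, mirroring the qualitative clinical finding that backwards-
derived mean thresholds underperform a well-chosen fixed cut-off.

Reports round r and r² to 3 decimals and volumes to 0.1 ml. Significance
is two-sided at 0.05.

### Numerical and degenerate-input choices

* Empty segmentations are valid results (volume 0), not errors; empty
  *geometry* (a VOI covering no voxel centre) is an error.
* Correlation requires n ≥ 4 and nonzero variance in both variables;
  degenerate cases surface as flagged errors rather than NaN.
* Kruskal–Wallis on fully tied data returns H = 0 (the tie-corrected
  statistic is 0/0 there; zero rank variance is the meaningful limit).
* The Gaussian kernel is truncated at 4σ and row-renormalized; blur with
  FWHM 0 is the identity.
* All RNG flows through `set.seed` with integer sub-seeds below 2³¹.

## Worked example

```{r example, eval = FALSE}
library(suvseg)

# one phantom lesion: 11 x 8 x 8 mm semi-axes, peak SUV 14
les <- lesion_spec(center = c(60, 95, 63), semi_axes = c(11, 8, 8),
                   peak_suv = 14)
case <- generate_case(les, seed = 42)
case$ct_reference_volume_ml          # analytic ground truth

# the five families at representative levels
segment_fixed(case$pet, case$voi, 4.0)
segment_isocontour(case$pet, case$voi, 0.40)
liver <- roi_mean(case$pet, case$rois$liver)
segment_background_relative(case$pet, case$voi, liver, 0.60)

# inverse solve against the ground truth
backwards_threshold(case$pet, case$voi, case$ct_reference_volume_ml)

# full cohort pipeline (about a minute)
cohort <- generate_cohort(cohort_config(seed = 1))
sw <- sweep_cohort(cohort$cases, cohort$ground_truth)
rank_methods(sw$agreement)$overall
```

## Problem sizes

The shipped analyses use the 50-case cohort at 2 mm spacing (96 × 96 × 64
voxels per case): simulation ≈ 25 s, the full 43-level sweep ≈ 15 s, and
the oracle-equivalence suite checks 200 randomized grids up to 20³ voxels
against triple-loop counters. These sizes were chosen so that the full
study — cohort, sweep, inverse solves, statistics — reruns from scratch in
about a minute on a laptop while keeping every validation exact.

## Known limitations

* Ellipsoidal, homogeneous lesions only; no visceral or osseous morphology.
* The noise model is additive Gaussian, not Poisson count statistics, so
  SUV-dependent noise scaling is absent.
* Axis-aligned geometry; rotated ellipsoids are not supported.
* The backwards solver assumes the target volume is attainable within the
  VOI; targets outside (0, VOI volume] are contract errors by design.
* Single grid per case: no CT/PET resampling or registration.
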