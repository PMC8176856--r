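# suvseg — threshold-based PET tumor volume delineation

`suvseg` is an R package for volumetric delineation of PSMA-avid lesions on
PET images in SUV units, together with the statistical harness needed to
compare delineation methods against a volumetric reference standard. It is
aimed at nuclear-medicine and imaging-methods researchers who want to study
*which* thresholding rule best recovers true lesion volume — and at anyone
who needs a clean, oracle-tested implementation of the underlying
primitives.

## What it implements

Five threshold families, all reducing to one inclusive-rule primitive
`vol(t) = v · #{x ∈ VOI : SUV(x) ≥ t}`:

| Family | Threshold |
|---|---|
| fixed | absolute SUV t (grid 2.5 … 15.0) |
| isocontour | f · SUVmax of the lesion VOI (10 … 75%) |
| liver-relative | f · SUVmean of a 30 mm axial liver disc ROI (45 … 75%) |
| parotid-relative | f · SUVmean of a 10 mm parotid cube ROI (60 … 90%) |
| spleen-relative | f · SUVmean of a 30 mm spleen cube ROI (40 … 70%) |

plus:

* a **backwards (inverse) threshold solver**: given a lesion's reference
  volume, find the SUV threshold whose segmented volume is closest to it
  (exact over the finite candidate set, ties toward the larger threshold);
* **whole-image** fixed-threshold tumor volume with physiological-uptake
  exclusion masks;
* the **agreement harness**: Pearson/Spearman correlation gated by
  Shapiro–Wilk normality, r² = r·r, coefficient of variation
  (100·sd/mean), Bland–Altman limits of agreement
  (mean(d) ± 1.96 sd(d)), Kruskal–Wallis comparisons, per-family method
  ranking;
* a **digital phantom generator**: ellipsoidal lymph-node lesions with
  analytic ground-truth volumes (log-normal, median 3.2 ml, range
  1.0–23.8 ml), independent log-normal background tissues (parotid median
  20.1, liver 11.3, spleen 9.9 SUV), 2 mm FWHM Gaussian point-spread blur
  and truncated-Gaussian noise — so the whole pipeline can be validated
  against exact truth.

NIfTI-1 I/O is provided via RNifti; cohorts, results and summaries are
plain CSV with a seed/config-hash header comment.

## Worked example

```r
library(suvseg)

# one phantom lesion: 11 x 8 x 8 mm semi-axes, peak SUV 14, default
# acquisition (2 mm FWHM blur, noise SD 0.3)
les  <- lesion_spec(center = c(60, 95, 63), semi_axes = c(11, 8, 8),
                    peak_suv = 14)
case <- generate_case(les, seed = 42)

case$ct_reference_volume_ml
#> [1] 2.948908

segment_fixed(case$pet, case$voi, 4.0)
#>   case_id method level threshold_suv n_voxels volume_ml
#> 1    <NA>  fixed     4             4      388     3.104

segment_isocontour(case$pet, case$voi, 0.40)
#>   case_id     method level threshold_suv n_voxels volume_ml
#> 1    <NA> isocontour   0.4      5.899784      380      3.04

liver <- roi_mean(case$pet, case$rois$liver)   # 8.715354
segment_background_relative(case$pet, case$voi, liver, 0.60)
#>   case_id         method level threshold_suv n_voxels volume_ml
#> 1    <NA> background_rel   0.6      5.229213      380      3.04

backwards_threshold(case$pet, case$voi, case$ct_reference_volume_ml)
#>   case_id threshold_suv achieved_volume_ml target_volume_ml
#> 1    <NA>       11.8314              2.952         2.948908
```

The analytic ground truth is 2.95 ml; a fixed SUV 4.0 reads 3.10 ml and a
40% isocontour 3.04 ml — both slightly above truth because the 2 mm
point-spread blur pushes the apparent boundary outward on a
high-contrast lesion. The inverse solver finds the per-lesion threshold
(SUV 11.8) whose volume lands within one voxel (0.008 ml) of the target.

## The analysis workflow

The study itself is a three-stage pipeline over a 50-case cohort
(defaults; ~1 minute total):

```sh
Rscript analysis/01_simulate.R    # cohort -> results/cohort/
Rscript analysis/02_delineate.R   # 43 levels x 50 cases + inverse solves
Rscript analysis/03_evaluate.R    # agreement tables, ranking, report.md
```

Each stage prints what it found and writes CSVs (and a markdown report
laid out method / r / r² / p) whose headers record the seed and a config
hash; two runs with the same config are byte-identical.

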