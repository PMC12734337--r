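# fetalvm

Automated fetal ventriculomegaly (VM) assessment from brain MRI tissue
segmentations.

Ventriculomegaly — enlargement of the fetal cerebral lateral ventricles — is
among the most common CNS findings in prenatal imaging. It is diagnosed when
the atrial width of a lateral ventricle reaches 10 mm on an axial plane and
graded **mild** (10–12.5 mm), **moderate** (12.5–15 mm) or **severe**
(≥ 15 mm). Measuring that width by hand from volumetric MRI is slow and
observer-dependent. `fetalvm` automates the geometric part of the job for
anyone who already has a tissue segmentation (manual, or from a segmentation
network such as nnU-Net): it finds the measurement plane, measures each
ventricle, grades severity, and emits a structured report — and it ships a
synthetic phantom generator with analytic ground truth so every stage can be
validated without any imaging data.

## Method

Given a multi-class tissue mask (FeTA-style, 7 tissues) with voxel spacing:

1. **Simplify** the mask to background (0), lateral ventricles (1) and deep
   gray matter (2); per-volume intensity normalization (percentile clipping +
   z-score) is available for paired T2w images.
2. **Select the measurement plane**: the axial slice where the
   deep-gray-matter cross-sectional area `A(k) = #\{label 2 in slice k\}·dx·dy`
   is maximal — a proxy for the clinical plane through the thalami and cavum
   septi pellucidi. A ±12-slice window around it gives a standardized
   25-slice 2D stack.
3. **Split** the ventricle mask into left and right adaptively: project onto
   the left–right axis and split at the widest interior run of empty columns
   (a natural separation); if none exists, split the bounding box into equal
   halves.
4. **Measure** each side with a minimum-area bounding rectangle (rotating
   calipers in physical mm); the atrial width is the rectangle's short side,
   transverse to the ventricle's long axis. The reported width is
   `W = max(W_left, W_right)`, and the ventricular volume is
   `V = #\{label 1\}·dx·dy·dz`.
5. **Grade**: Normal `W < 10`, Mild `10 ≤ W < 12.5`, Moderate
   `12.5 ≤ W < 15`, Severe `W ≥ 15` (mm; lower-inclusive, configurable).
6. **Report**: a fixed structured prompt
   (`Slice: [Image]; Severity: <class> VM; Width: <w> mm; Volume: <v> cm^3`)
   plus an offline templated explanation citing the threshold crossed.

Evaluation utilities (Dice/IoU overlap, confusion-matrix classification
metrics with per-class precision/recall/F1 and macro F1) match the reporting
conventions used in segmentation and VM-classification studies.

## Worked example

```r
library(fetalvm)

# a synthetic case: left ventricle 13 mm, right 11 mm, measurement plane at slice 30
ph <- generate_phantom(phantom_spec(left_width_mm = 13, right_width_mm = 11,
                                    dgm_peak_slice = 30, seed = 42))

m <- measure_volume(ph$label)
m
#> <fetalvm measurement>
#>   width (mm): left 13.00, right 11.00, final 13.00
#>   volume: 2.60 cm^3   slice: 30   split: gap

label_case(m, case_id = "phantom_demo")
#> # A tibble: 1 × 8
#>   case_id      left_width_mm right_width_mm width_mm volume_cm3 slice_index
#>   <chr>                <dbl>          <dbl>    <dbl>      <dbl>       <int>
#> 1 phantom_demo            13             11       13       2.60          30
#> # ℹ 2 more variables: split_method <chr>, class <chr>

report <- build_case_report(m, case_id = "phantom_demo")
cat(report$prompt_text)
#> Slice: [Image]; Severity: Moderate VM; Width: 13.0 mm; Volume: 2.6 cm^3
cat(report$explanation_text)
#> The lateral ventricles exceed the 12.5 mm threshold, measuring 13.0 mm,
#> indicating moderate ventriculomegaly. Ventricular volume is 2.6 cm^3.
#> Volume supports abnormal fluid accumulation.
```

The pipeline recovered the measurement plane exactly (slice 30), both
per-side widths to the voxel (13.00 / 11.00 mm against a 13 / 11 mm truth at
0.5 mm spacing), the final width as the larger side, the volume within a
fraction of a percent of the analytic ellipsoid volume, and the moderate
grade that a 13 mm atrial width implies.

### Command line

```sh
exec/fetalvm phantom --n 80 --seed 42 --out cohort/         # NIfTI pairs + truth.csv
exec/fetalvm analyze --input case_mask.nii.gz --out results/
exec/fetalvm label-cohort --input cohort/ --out labels/     # labels.csv + run log
exec/fetalvm metrics --truth labels/labels.csv --pred predicted.csv
```

Exit codes: 0 success, 1 input error, 2 anatomical precondition failure
(no deep gray matter / no ventricle pixels).

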