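# cadeval

Standalone performance evaluation of lesion-detection CAD systems on
chest CT, for the people who validate them: imaging researchers and
medical-device evaluators who have a table of ground-truth nodule
annotations, a table of CAD findings, and need defensible numbers.

A computer-aided detection (CAD) system emits candidate nodules with 3D
masks, confidence scores, and predicted characteristics (texture,
calcification, spiculation, lobe, size). Validating such a system
standalone — no human in the loop — means:

1. **Matching.** A finding hits a ground-truth (GT) nodule when their 3D
   intersection-over-union `|A∩B| / |A∪B|` reaches 10% (the literal
   "10% of the finding's volume" reading is available as
   `criterion = "overlap_over_finding"`). Per scan, cadeval computes the
   exact maximum-cardinality, maximum-total-IoU one-to-one assignment;
   unmatched findings are false positives, unmatched nodules false
   negatives.
2. **Scoring.** Scan-level sensitivity/specificity/precision with Wilson
   score intervals, F1, false positives per image; nodule-level
   sensitivity with a Rao-Scott interval (nodules on one scan are
   correlated — scans are the clusters); ROC and precision-recall curves
   with a DeLong interval for the AUC; an FROC curve (sensitivity vs
   average false positives per scan across confidence thresholds).
3. **Characterization.** Per-class concordance of predicted texture,
   calcification, spiculation and lobe on the matched pairs (Wilson
   intervals); stratified mean absolute size errors; Bland-Altman bias
   and limits of agreement `bias ± 1.96·SD` for diameter and volume.
4. **Reference standard.** An adjudication workflow: report-derived
   nodules vs a blinded reader, discrepancies decided by an arbitrator,
   then a reader-vs-CAD cross-tab (both / only-reader / only-CAD /
   neither) and the second-reader uplift.

Because clinical cohorts cannot be shipped, the package includes a
synthetic world: `generate_cohort()` draws scans, covariates, and
ellipsoid-mask nodules with the marginals of a published 263-scan
validation cohort; `simulate_cad()` and `simulate_reader()` apply a
parameterized imperfect detector and reader; and `build_paper_fixture()`
deterministically reconstructs that study's entire contingency so every
pipeline stage can be verified against printed results.

## Worked example

```r
library(cadeval)

fx <- build_paper_fixture()          # deterministic validation cohort
mt <- build_match_table(fx$cohort)   # 3D-IoU matching at the 10% criterion
mt
#> <match_table> nodule level: 149 TP / 34 FN; FPs: 49 in nodule scans, 23 in non-nodule scans
#>   scan level: 104 TP / 17 FN / 21 FP / 121 TN; mean matched IoU 1.000

detection_summary(mt)
#> <detection_summary>
#>   scan sensitivity:   104/121 = 86.0% (78.6-91.0) [wilson]
#>   scan specificity:   121/142 = 85.2% (78.4-90.1) [wilson]
#>   scan precision:     104/125 = 83.2% (75.7-88.7) [wilson]
#>   F1: 0.846 (clopper_heuristic: 0.769-0.904)
#>   scan FPPI: 0.174; FP findings per nodule scan: 0.405
#>   nodule sensitivity: 149/183 = 81.4% (75.4-86.2) [rao_scott]

concordance(mt, fx$cohort, "texture")
#> <concordance_table> texture (n = 149 matched pairs)
#>      gt_class n_detected n_correct sensitivity     lower     upper
#>         solid         82        81   0.9878049 0.9341066 0.9978440
#>    part_solid         42        16   0.3809524 0.2499973 0.5318596
#>  ground_glass         25        18   0.7200000 0.5242339 0.8571615
#>   overall: 115/149 = 77.2% (69.8-83.2) [wilson]

reader_performance(fx$cohort, fx$r1, mt)
#> <reader_performance>
#>   R1:  165/183 = 90.2% (85.0-93.7) [wilson]
#>   CAD: 149/183 = 81.4% (75.2-86.4) [wilson]
#>   uplift: 12/165 = 7.3%; R1 false positives: 39
```

Reading: of 121 nodule-containing scans the CAD flagged 104; of 183 GT
nodules it found 149 at 0.405 false-positive findings per nodule scan.
Texture is its weak spot (38.1% on part-solid nodules), and a single
reader at 90.2% sensitivity would gain at least 12/165 = 7.3% more
detected nodules by accepting the CAD's extra true detections.

For a synthetic experiment instead of the fixed fixture:

```r
cfg <- synthetic_config(n_scans = 500, seed = 7)
co <- generate_cohort(cfg)
co$findings <- simulate_cad(co, cfg$detector, seed = 8)
bundle <- run_pipeline(cohort = co, out_dir = "out")   # JSON + CSV report
```

## Command line

```sh
Rscript inst/cli/cadeval.R simulate --out cohort_dir --n-scans 263 --seed 17
Rscript inst/cli/cadeval.R evaluate --cohort cohort_dir --out report_dir
Rscript inst/cli/cadeval.R match    --cohort cohort_dir --out match_dir --iou-threshold 0.10
```

(After installation the script lives at
`system.file("cli", "cadeval.R", package = "cadeval")`.)

## Layout

- `R/voxel_mask.R` — masks, rasterization, IoU, size measurement
- `R/cohort.R` — data model, validation, CSV/JSON round-trip I/O
- `R/matching.R` — exact one-to-one IoU assignment, scan labels
- `R/ci.R`, `R/metrics.R` — Wilson / Clopper-Pearson / Rao-Scott,
  detection summaries, ROC/PR/FROC, subgroup and covariate tables
- `R/characterization.R` — concordance, MAE strata, Bland-Altman
- `R/adjudication.R` — reference-standard construction, cross-tab
- `R/synthetic.R`, `R/fixture.R` — generator and deterministic fixture
- `R/report.R` — pipeline orchestration and table rendering
- `vignettes/cad-evaluation-methods.Rmd` — the methods vignette
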