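---
title: "Methods: standalone evaluation of nodule-detection CAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standalone evaluation of nodule-detection CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadeval)
```

This vignette is the package's own account of its statistical methods:
the models and conventions implemented, the parameters that matter, what
the synthetic generator does and does not emulate, and the choices made
where the underlying evaluation procedure leaves room.

## The evaluation model

A cohort is a set of CT scans, each either nodule-containing or not
after reference-standard adjudication. Ground truth is a list of nodule
annotations (3-30 mm lesions by the Fleischner definition) with voxel
masks on the scan grid; CAD output is a list of findings with masks,
confidence scores in [0, 1], and predicted characteristics.

**Matching.** A finding and a nodule are candidates when their 3D
intersection-over-union reaches `iou_threshold` (default 0.10). Two
readings of the 10%-overlap rule coexist in the literature and both are
implemented: IoU (default) and intersection over the finding's own
volume (`criterion = "overlap_over_finding"`). The criterion choice is
logged prominently in reports because it changes the operating point.

Within a scan the assignment is one-to-one: each finding counts for at
most one nodule and vice versa. We compute the *exact*
maximum-cardinality, maximum-total-overlap assignment by dynamic
programming over nodule subsets (the cohort's own exclusion rule of at
most 10 nodules per scan bounds the state space at 2^10). The familiar
greedy sweep in descending IoU order is retained as the tie-breaking
order, so wherever greedy is already optimal — the overwhelming majority
of real configurations — the two coincide. We chose the exact optimum
over pure greedy because greedy is provably not order-independent: when
one finding overlaps two nodules and a second finding overlaps only the
first of them, greedy can pair the wrong couple and even lose a true
positive. In testing on 1000 random geometric instances this happened
about 1% of the time; an evaluation statistic should not depend on such
accidents, and the exact assignment is what the package's own oracle
suite verifies against.

**Scan-level rules.** A nodule-containing scan is TP if at least one
finding matched a nodule on it, else FN. A non-nodule-containing scan is
FP if CAD emitted *anything* on it, else TN. Scan-level FPPI is FP scans
per nodule-containing scan; the nodule-level FP rate is FP findings in
nodule scans per nodule-containing scan. Confidence scores play no role
at the operating point — the shipped output is evaluated as-is — and are
used only for ROC/PR/FROC sweeps.

## Interval methods

- **Wilson score** (no continuity correction) for plain proportions:
  sensitivity, specificity, precision, per-class concordance. This
  reproduces, from the printed counts alone, every category-level
  interval in the validation results the package's tests encode, which
  is how "modified Wilson" was disambiguated.
- **Clopper-Pearson** (exact beta-quantile inversion) where an exact
  interval is called for; verified against an independent binomial-tail
  bisection oracle over the full (k, n) grid to n = 50.
- **Rao-Scott** for the nodule-level sensitivity: nodules on one scan
  are correlated, so the ratio-estimator variance with the
  with-replacement cluster formula and m/(m-1) correction yields a
  design effect d; the sample is deflated to n/d and a Wilson interval
  computed at the effective counts. A design effect below 1 (negative
  intra-cluster correlation, common in small fixtures) is kept as
  computed, with a warning, rather than floored — flooring would
  silently widen intervals.
- **DeLong** placement-value variance for the empirical AUC-ROC.
  AUC-PR is stepwise average precision with no interpolation.
- **F1.** The source procedure applies Clopper-Pearson to F1, which is
  not a binomial proportion. Two strategies are provided and labelled:
  the default heuristic applies Clopper-Pearson to `round(F1 * n)` out
  of `n = TP + (FP + FN) / 2` pseudo-trials (F1 equals TP over that
  quantity), and a percentile bootstrap over scans is available as
  `f1_method = "bootstrap"`. Neither is claimed to reproduce any
  published F1 interval; the construction behind the published one is
  unstated.

A known internal inconsistency in the reference results is worth
recording: the published overall texture concordance count (116/149)
disagrees with its own per-class column sum (81 + 16 + 18 = 115), while
the printed percentage (77.2%) and interval (69.8-83.2%) both match
115/149 exactly under plain Wilson. The package therefore treats 115 as
the true count.

## Size agreement

Differences are **prediction minus ground truth**, so a positive bias
means the detector over-measures; the underlying study does not state
its sign convention, and this choice is ours. Bland-Altman limits of
agreement are `bias ± 1.96·SD` with a t interval for the bias
(SE = SD/√n) and the large-sample SE
`SD·sqrt(1/n + z²/(2(n-1)))` with a t quantile for each limit; the exact
LoA-interval variant is deliberately not implemented. Mean absolute
errors are stratified by ground-truth size (<6 / 6-8 / >8 mm;
<100 / 100-250 / >250 mm³, left-closed bins) with a t interval on the
absolute errors by default and a bootstrap as the alternative. Only
matched pairs enter: missed nodules have no prediction.

## Nodule measurement

Volume is exactly voxel count x voxel volume. "Average diameter" is
operationalized — the convention "average of long and short axes" admits
several readings — as: take the axial slice of largest in-plane area
(ties to the lowest slice); the long axis is the maximum Feret diameter
of that slice's voxel centers plus half an in-plane voxel of boundary
correction; the short axis is the maximal extent perpendicular to the
long-axis direction, same correction. The half-voxel correction centers
the discretization error near zero (full-voxel correction biases +1 at
aligned boundaries). The whole convention is isolated behind
`measure_nodule()` so it can be swapped.

## The synthetic world

`synthetic_config()` states the world once; its defaults are the
published cohort's figures, not tunables:

| parameter | default | origin |
|---|---|---|
| prevalence | 121/263 | nodule-containing scan fraction |
| nodules per scan | zero-truncated Poisson, mu = 0.8898, cap 10 | mean 1.51 nodules per nodule scan |
| texture marginals | 94/47/42 of 183 | GT texture counts |
| calcification, spiculation | 8/183, 9/183 | GT counts |
| lobe marginals | 59/17/36/37/34 of 183 | GT location counts |
| diameter law | log-normal(1.5794, 0.6023) truncated to (3.05, 29.5) mm | fitted so the <6 / 6-8 / >8 mm bins hold 54% / 20% / 26% |
| age by status | 24/121 vs 78/142 under 55 | baseline covariate table |
| detector sensitivity | 0.872 / 0.894 / 0.595 by texture | per-texture detection results |
| FP rate | Poisson(72/263) per scan | total FP count |
| texture confusion diagonal | 0.988 / 0.381 / 0.720 | per-class concordance |
| calc/spic/lobe accuracy | 0.919 / 0.826 / 0.946 | overall concordance |
| size noise | +0.47 ± 1.24 mm; +61.8 ± 392 mm³ | Bland-Altman bias and (LoA - bias)/1.96 |
| reader | sensitivity 0.902, FP Poisson(39/263) | blinded-reader results |

Choices the stated world leaves open, decided once:

- **Geometry.** Nodules are axis-aligned ellipsoids (axial semi-axes
  d/2, z semi-axis log-normally elongated, sdlog 0.15) placed uniformly
  in five schematic per-lobe boxes on a 64³ grid at 1 mm spacing. Lobes
  are synthetic spatial regions, not anatomy.
- **Recorded diameter** is the sampled value (the annotator's number and
  the ellipsoid's axial diameter), not a re-measurement of the
  rasterized mask: re-measuring warps the calibrated bin shares and can
  push a just-above-3 mm nodule below the definition floor at 1 mm
  voxels. Recorded volume *is* the exact mask volume, which is the
  mask-consistency invariant validation enforces.
- **TP jitter** is a random translation by a uniform fraction
  (0.08-0.58) of the diameter, rejection-sampled to keep IoU at or above
  the matching floor; the range was calibrated once so the matched-IoU
  distribution has mean near 0.42, the reported mean overlap quality.
  No dilation/erosion component is modelled.
- **Confidence laws**: Beta(5, 2) for true positives, Beta(2, 5) for
  false positives — arbitrary but documented; only the ordering matters
  for ROC/FROC behaviour.
- **Size noise is additive and unclipped.** Clipping predicted volumes
  at a physical floor would truncate the noise distribution (the volume
  sd, 392 mm³, is large against small synthetic nodules) and bias the
  recovered agreement statistics, which are linear in the differences.
  Occasional nonphysical negative predictions are the honest price of
  the stated additive model at desk scale.
- **Per-scan FP counts are Poisson** — the source reports only totals,
  so the distributional form is an assumption.

What a green test does and does not establish: the generator reproduces
the cohort's *marginals* and the detector's *rates*; it does not emulate
CT intensities, anatomy, inter-nodule correlation of characteristics, or
the joint distribution of characteristics (each is drawn independently).
Parameter-recovery tests therefore establish that the pipeline measures
what was configured — not that the simulation resembles clinical data in
any richer sense.

## The deterministic fixture

`build_paper_fixture()` constructs, with no randomness, a 263-scan
cohort whose matching and evaluation reproduce the published contingency
exactly: the 121/142 scan split, 183 GT nodules, 149 matched / 34
missed, 49 + 23 false positives (the latter on 21 scans), scan-level
104/21/17/121, the detected-vs-missed characteristic marginals, every
per-class concordance count, a reader finding 165/183 with 39 false
positives confined to the 33 discrepant scans, and the conflicting-scan
cross-tab 7/2/12/6. Masks are small ellipsoids at fixed voxel-aligned
positions; true-positive findings reuse the ground-truth masks (IoU 1),
so the fixture verifies counting, not overlap geometry — overlap
geometry is covered by the oracle suite. Characteristics are assigned
independently per attribute in deterministic blocks; joint distributions
across attributes are arbitrary, which is immaterial because every
reproduced table is a marginal.

The fixture's report-derived set includes 15 mask-free "phantom"
mentions on report-positive/reader-negative scans (exercising the
approximate lobe-plus-diameter pairing path) that the arbitrator
rejects, mirroring how discrepant non-nodule scans arise.

## Adjudication conventions

Report-derived nodules often carry no masks; they pair against reader
annotations by identical lobe and nearest diameter within 50% relative
tolerance, flagged `approximate`. The arbitrator is modelled as an
external decision table (accept/reject per candidate), not an algorithm
— arbitration is human judgment. Reader false positives are counted
against the whole cohort, separately from the true-nodule cross-tab.
The second-reader uplift is |CAD-only GT nodules| / |reader-found GT
nodules|: the minimum relative gain from accepting every extra CAD
detection.

## Numerical conventions and degenerate inputs

- Rendered tables round half-up at the published precision (percent
  1 d.p., F1 3 d.p.); JSON keeps full precision.
- Proportions with zero denominators yield an `undefined_metric` flag,
  not an exception; F1 is 0 when TP = 0.
- Rao-Scott requires at least 2 clusters (variance undefined otherwise);
  single-cluster strata fall back to Wilson with a warning; degenerate
  p in {0, 1} uses design effect 1.
- AUC ties take half credit; all-tied scores give AUC 0.5.
- Ellipsoid rasterization includes voxels whose center lies inside *or
  on* the surface; an ellipsoid covering no voxel center is an error,
  not an empty mask.
- FROC with no findings is the single point (0, 0). The FP-denominator
  defaults to all scans, with `denominator_scans = "nodule_containing"`
  matching the 0.405-FP/nodule-scan convention.

## Known limitations

- The published AUC-ROC (0.865) exceeds (sens + spec)/2 from the binary
  operating point, implying continuous per-scan device scores that are
  not available; scan-level ROC here uses the maximum finding confidence
  (0 for empty scans) and reproduces the published value only if fed
  comparable scores. It is not asserted in any test.
- Subgroup intervals depend on the unknown within-scan cluster structure
  of the source data; the package reproduces subgroup *point estimates*
  on its fixture but treats the printed subgroup intervals as
  out of reach.
- Segmentation quality beyond IoU (Dice, surface distances) is out of
  scope, as are DICOM ingestion, lung segmentation, malignancy-risk
  scoring, and inter-reader agreement statistics.
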