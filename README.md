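# vertrel — inter-rater reliability of vertebral landmark annotations

Manual landmark labelling of lumbar spine radiographs — four corner points
(`p1`…`p4`) per vertebral body L1–L5, in anteroposterior (AP) and lateral
(LAT) views — underpins quantitative alignment diagnosis and supplies the
ground truth for automated landmark detectors. But experts never mark the
same pixel, so the labelling process itself must be audited: how far do
raters scatter around the consensus location, how variable are the upper and
lower vertebral endplate line (UVEL/LVEL) angles derived from those points,
and is agreement high enough to treat the mean location as ground truth?

`vertrel` implements that audit for large multi-rater studies in which the
raters work in two groups over overlapping case sets, plus a synthetic-study
simulator with the same statistical structure so every stage is testable
without access to (typically unreleased) annotation data. It is aimed at
researchers running labelling studies and at developers who need a
principled error reference for evaluating landmark-detection algorithms.

## What it computes

* **Consensus landmarks** — per (case, view, vertebra, point), the mean of
  the available raters' locations (≥ 2 raters), the pipeline's ground truth.
* **Deviations** — Euclidean and signed per-axis distances from consensus,
  in mm via the image calibration (default 0.143 mm/pixel).
* **Endplate angles** — UVEL (`p1`–`p2`) and LVEL (`p3`–`p4`) orientations
  in degrees on (−90°, 90°], and each rater's RMSE against the consensus
  angle across cases.
* **ICC(A,1)** — single-rating intraclass correlation, two-way
  random-effects, absolute agreement:

  ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)),

  with 95% percentile-bootstrap confidence intervals (500 case resamples)
  and the standard qualitative bins (poor < 0.50 ≤ moderate < 0.75 ≤ good
  < 0.90 ≤ excellent).
* **Group homogeneity** — per measure, a random-intercept linear mixed model
  `value ~ group + (1 | case)` fitted by REML (variance ratio profiled
  numerically), Wald t with df = cases − 2.
* **Study simulation** — the canonical two-group design (cases 1–600 to
  group A, 401–1000 to group B, 401–600 common; 2 × 6 raters), tilted-
  rectangle lumbar geometry, per-rater bias, (view, vertebra)-specific
  noise with the AP/L5 excess, and case-level missingness.

## Worked example

```r
library(vertrel)

cfg <- study_config(n_cases = 50, seed = 7)   # scaled-down two-group study
st  <- simulate_study(cfg)
st$set
#> <annotation_set> 14200 annotations | 50 cases | 12 raters | 10 missing case/view/rater triples
#>   calibration: 0.143 mm/px (1953 x 3000 px)

report <- run_pipeline(st$set, st$design, n_boot = 100, seed = 1)
tab <- report$point_table
tab[tab$scope == "A" & tab$view == "AP" & tab$label %in%
      c("L1_p1", "L1_p2", "L5_p1", "L5_p2"),
    c("label", "mean", "sd", "icc", "ci_low", "ci_high", "classification")]
#>  label mean    sd   icc ci_low ci_high classification
#>  L1_p1 1.41 0.715 0.980  0.970   0.985      excellent
#>  L1_p2 1.41 0.687 0.983  0.975   0.987      excellent
#>  L5_p1 2.95 1.516 0.924  0.890   0.946      excellent
#>  L5_p2 2.79 1.489 0.935  0.909   0.956      excellent
```

Each row summarises one landmark for group A's raters on the AP view:
`mean`/`sd` are the per-rater-per-case Euclidean deviations from consensus
in mm — L5 scatters about twice as much as L1, the classic sacral-
superposition effect — and `icc` is the absolute-agreement ICC of the
landmark coordinates with its bootstrap CI (lower for L5, as the larger
noise predicts).

```r
subset(report$group_tests, view == "AP" & label %in% c("L3_p1", "L5_UVEL"))
#>    label             measure effect     se     t df p_value
#>    L3_p1  point_deviation_mm -0.120 0.0963 -1.25 48   0.218
#>  L5_UVEL angle_abs_error_deg -0.395 0.2900 -1.36 48   0.180
```

`effect` is the B − A difference (mm, or degrees for angle rows); here the
two rater groups are statistically indistinguishable, as they should be when
both follow the same labelling procedure.

The methods vignette (`vignettes/landmark-reliability.Rmd`) documents the
model, the design decisions and the simulator's scope in full. A thin CLI
over the same functions lives in `inst/scripts/landmark-reliability.R`
(`simulate` and `analyze` subcommands).

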