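---
title: "CCAR methodology: scoring, evaluation statistics, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCAR methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccar)
```

## The measurement model

In thoracic OLF the quantity of interest is the residual cerebrospinal-fluid
space around the cord at the level of maximum compression. It cannot be
contoured directly on MRI (the dura/ossification boundary is indistinct), so
it is derived from two ratios measured on co-localized CT and MRI slices:

- **OCAR** — ossified-mass CSA over the normal bony canal CSA (both CT). The
  canal reference is taken at the pedicle level near the narrowest segment,
  where ossification is usually absent.
- **SCAR** — cord CSA over the reference dural-sac CSA (both MRI). The
  reference sac is the mean of the adjacent upper and lower segment dural-sac
  areas, on the assumption that the uncompressed sac fills the normal canal.
- **CCAR** = 100 − OCAR − SCAR (percent).

All ratios are carried as percents throughout the package — the field's
reporting convention — with `as_fraction()` / `as_percent()` as the explicit
converters, so no silent ×100 factor can enter a formula twice. The identity
`OCAR + SCAR + CCAR = 100` holds exactly by construction and is
property-tested on random inputs.

Each raw area is measured twice by each of two observers; `average_repeats()`
pools the four values. Areas come either from vertex contours
(`polygon_area()`, shoelace formula with the absolute value taken so winding
direction is irrelevant; a freehand ROI is just a dense polygon) or from
binary masks (`mask_area()`, whole-pixel counting). The pixel convention is
fixed package-wide: pixel centres at integer coordinates, origin top-left,
y increasing downward; the phantom writer uses the same convention, so
geometry and synthetic modules agree. Self-intersection of contours is not
detected exhaustively — only the ≥3-distinct-vertex precondition is enforced —
because anatomical canal/cord outlines are convex or nearly so and the check
would cost more than it protects.

## Classification rules and their edges

Under measurement noise CCAR can stray outside [0, 100]; such values are
flagged (`ccar_out_of_range()`, warning, `ccar_flag` column) and retained
unclipped, so QC output and ROC analysis see the raw score.

The recovery rate `RR = 100 (mJOA_fu − mJOA_pre) / (11 − mJOA_pre)` is
undefined at `mJOA_pre = 11` (no headroom); it is returned as `NA` and
excluded from aggregate RR statistics. Grading uses the printed integer
edges applied to the unrounded RR — `[75, 100]` excellent, `[50, 75)` good,
`[25, 50)` fair, below 25 poor — and negative RR (deterioration) falls into
"poor": the printed scale starts at 0, and the worst category is the only
defensible sink for a deteriorating patient. mJOA entries are validated as
integers in [0, 11]; half-point scores are rejected.

Zone edges are parameters with the reference defaults: DO zone CCAR ≤ 14.3%,
non-DO zone ≥ 44.5%; outcome zones ≤ 14.3% (poor-or-fair) and ≥ 45.2%
(good-or-excellent). The outer bounds are closed (the stated "≤"/"≥"), which
fixes the gray zone as the open interval between them. `predict_do()` is
strict at the cut-off — positive iff CCAR < cutoff — matching the ROC sweep's
decision rule; the boundary value itself therefore classifies as non-DO.
These cut-offs are treated as reference parameters, not constants the
package tries to re-derive universally.

## Evaluation statistics

**ROC.** `empirical_roc()` sweeps thresholds over the observed score values
(plus +Inf so the curve reaches both ends) under "positive iff score <
threshold"; the positivity direction is an explicit argument because for
CCAR the *lower* score indicates disease. The AUC is computed from midranks
as the Mann–Whitney probability `P(score_pos < score_neg) + ½P(tie)`, and is
property-tested against an O(n²) pair-counting oracle and for invariance
under strictly monotone transforms. The CI uses DeLong's placement-value
variance (cross-checked against pROC in the test suite), with Hanley–McNeil
as an option. The optimal cut-off maximizes Youden's J over observed values;
ties on J are broken toward higher sensitivity, then the lower threshold,
and the comparison runs on integer counts (`n·TP + m·TN`) so that
mathematically tied J values cannot split on floating-point rounding.
Reporting the cut-off as an observed score value keeps it a realizable
decision rule on the data at hand.

**Diagnostic performance.** `diagnostic_performance()` builds the confusion
matrix at a fixed cut-off and attaches exact Clopper–Pearson CIs (via
`binom.test`) to sensitivity, specificity and accuracy (the "diagnostic
coincidence rate"). At full success the exact lower bound has the closed
form `(α/2)^{1/n}` — 69.2% at n = 10, 79.4% at n = 16 — which the tests use
as the independent oracle. Note the reference summary tables imply CI
denominators (e.g. 100% with floor 69.2% implies n = 10) that are
inconsistent with the stated group sizes of 27/25; this package always
computes CIs from the actual counts rather than reproducing that
discrepancy.

**Group tests.** Welch's t-test is the continuous-variable default (robust
to unequal variances; with similar group SDs it is practically the pooled
test). Categorical tables use Pearson's chi-square without continuity
correction, with an automatic fallback to Fisher's exact test for 2×2
tables with any expected count below 5 — the method actually run is always
reported. On the reference sign tables this rule reproduces all three
printed p-values (tram-track 0.004, comma 0.002, bridge 0.101) via Fisher,
while the Pearson statistic for the tram-track table (8.75) remains
available through the explicit method override.

**ICC.** "Inter-observer reliability" is quantified as the intraclass
correlation ICC(2,1): two-way random effects, absolute agreement, single
rater, computed from the ANOVA mean squares with the McGraw–Wong F-based CI.
Absolute agreement is the right form for interchangeable observers — a
constant offset between observers lowers it, unlike the consistency form —
and the form is recorded in the result's `model` field so outputs are
self-describing. It is applied to the per-observer derived CCAR (each
observer's two repeats averaged first). The implementation is cross-checked
against values frozen from an independent implementation.

## The synthetic cohort generator

No per-patient data accompany the reference summary tables, so
`generate_cohort()` draws cohorts with their statistical structure; its
defaults *are* the study conditions and are not tuning knobs:

- group sizes 27 (DO) / 25 (non-DO);
- true CCAR per group: normal with means 22.2 / 50.0 and SDs back-computed
  from the reported CI half-widths via `sd = hw√n / t_{n−1,.975}`
  (`sd_from_ci_halfwidth()`: 12.13 / 11.75), truncated to [0, 100]. The
  normal family itself is an assumption — only means and CIs are reported —
  recorded here and overridable;
- SCAR uniform on [15, 45]% (a plausible cord-occupancy band; nothing in the
  summary tables constrains its distribution), OCAR = 100 − SCAR − CCAR with
  bounded resampling when the implied OCAR would be negative, so the identity
  holds exactly per patient;
- a sampled canal area (normal, mean 220 mm², SD 30 mm², truncated positive —
  a typical thoracic bony-canal CSA) converts ratios to the five raw areas;
  the reference dural sac is set equal to the canal and split into adjacent
  upper/lower areas with ±5% random asymmetry, which cancels exactly in the
  averaged reference;
- preoperative mJOA: group-wise normal (5.1 ± 3.0 / 5.7 ± 2.2) rounded and
  clamped to [0, 10]; RR: group-wise normal (42.3 ± 32.5 / 72.5 ± 23.0)
  truncated above at 100, negatives (deterioration) permitted — a few
  postoperative deteriorations are part of the reference conditions; the
  follow-up mJOA is back-computed as `pre + RR(11 − pre)/100`, rounded to an
  integer in `[max(0, pre − 1), 11]`;
- signs (tram-track, comma, bridge), Sato type, compression segment, sex and
  age are sampled from the per-group frequencies; zero-count cells stay
  exactly zero. These fields feed no downstream formula and exist for schema
  realism; only group-conditional independence is modelled.

Observer noise (`simulate_observers()`) is multiplicative log-normal with
unit mean at coefficient of variation `cv` (default 3%) per single
measurement, plus an optional fixed relative bias per observer.

**What the generator does and does not show.** Passing tests demonstrate
that the pipeline recovers the group means it was fed (grand means within
±1.5 points over 200 cohorts), that the identity and determinism contracts
hold, and that the observer-noise → ICC chain behaves (ICC ≥ 0.9 at 3% CV).
They do not certify behaviour on real images or real score distributions.
Two consequences of the stated generating model are worth knowing. First,
normal group distributions with the reference moments separate *more*
cleanly than the real cohort did: the simulated DO ROC AUC concentrates
near 0.93–0.95, above the reference 0.835, and the derived-CCAR ICC comes
out near 0.99 rather than 0.947 — real measurements have error sources
beyond i.i.d. 3% area noise. Second, because RR and CCAR are drawn
independently within each group, the outcome ROC on synthetic cohorts
(AUC ≈ 0.7) understates the reference association (0.822); modelling the
within-group CCAR–RR correlation would require a joint parameter the
summary tables do not provide. The Youden cut-off for DO, by contrast, is a
property of where the two group distributions cross and lands near 36% on
simulated cohorts, close to the reference 36.4%. Likewise the realized RR
group means sit a few points below the drawn means (truncation at 100 plus
integer-mJOA quantization), which is the stated mechanism, not a defect to
re-tune away.

## Phantoms and numerical choices

`generate_phantom()` rasterizes a circular canal, a posterior
crescent-shaped mass (canal disc minus an interior tangent disc, so the
crescent's area is exactly π(R² − r²); an offset-*ellipse* difference would
have no closed-form area), a circular dural sac and an elliptical cord, with
ground truths from the closed-form shape formulas. At the default
calibration (0.05 mm/px; canal diameter 320 px) whole-pixel rasterization
error is below 1%, the tested tolerance; containment invariants (mass ⊂
canal, cord ⊂ dural sac) are enforced at construction. Phantoms round-trip
through single-channel 0/255 PNGs plus a JSON sidecar carrying the
calibration and truth.

Other numerical choices: truncated normals are sampled by inverse-CDF (no
rejection, exact); the Youden tie-break is integer-exact as described above;
p-values are displayed to three decimals with a `<0.001` floor; degenerate
inputs (single-class labels, zero-variance correlations, zero
between-subject ICC variance, all-zero contingency tables) raise typed
errors or warnings rather than returning silent NaNs.

## Problem sizes in the test and acceptance runs

The suite exercises the oracle equivalences on 500 random ROC instances at
n ≤ 50, the identity on 10⁴ random score triples, generator calibration on
200 default cohorts, ICC recovery on 200-subject simulations, and the
acceptance script averages 20 freshly drawn cohorts per run — sizes chosen
so every Monte-Carlo estimate is stable to well inside the tolerances it is
compared at.

## Known limitations

- Areas enter as measurements or masks; there is no DICOM ingestion, no
  segmentation of real CT/MRI, and no CT–MRI registration.
- Sato types and CT signs enter as categorical labels, never derived from
  images.
- The generator models group-conditional independence only (see above); no
  multivariable or longitudinal modelling, and no multiple-testing
  correction (none is performed in the reference analysis).
- Cut-offs (36.4 / 14.3 / 44.5 / 45.2, RR dichotomization at 50) are
  parameters with reference defaults, not re-derived constants; whether the
  reference outcome ROC used continuous or dichotomized RR is not stated,
  so dichotomized-at-50 is the default with the threshold exposed.
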