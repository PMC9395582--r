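---
title: "Coronary plaque burden scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary plaque burden scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctascore)
```

## The scoring model

The unit of analysis is one patient's CCTA reading: a coronary
dominance pattern plus, for each diseased segment of the 18-segment
SCCT coronary tree, the maximal luminal diameter stenosis (percent) and
the plaque composition (calcified, non-calcified, or mixed).  Segments
are labels, not geometry: the package carries no centerlines or images,
and a "lesion" is whatever the upstream reader adjudicated as plaque
(the conventional > 1 mm² criterion is assumed to have been applied at
annotation time).

From a lesion set the package computes five scores:

* **SIS** counts diseased segments (0–18), blind to severity.
* **SSS** sums a per-segment grade: 1 below the obstructive cut, 2 from
  the obstructive cut up to and including the severe cut, 3 above it.
  Grade 0 is reserved for absent plaque, so any recorded lesion
  contributes at least 1; consequently SC = SSS/SIS lives in
  {0} ∪ [1, 3].
* **SPP** is positive when a severe (grade-3) lesion sits in the left
  main or a proximal LAD / LCx / RCA segment — the anatomy where a
  severe stenosis carries the worst prognosis.
* **OS** flags any lesion at or above the obstructive cut.
* **CT-LeSc** weights each lesion by where it sits
  (dominance-dependent localization weight), what it is made of
  (calcified 1, otherwise 1.5), and how tight it is (obstructive 1,
  non-obstructive 0.615), and sums the products.

The localization weights ship as a plain-text table so they can be
audited cell by cell.  Two structural properties of that table matter
for interpretation.  First, some segment–dominance cells are
anatomically absent (for instance the posterior descending artery from
the left coronary under right dominance); the package treats a lesion
annotated on such a cell as corrupt input and raises a
`notApplicableSegment` error rather than scoring it with weight 0,
which would silently delete plaque burden.  Under every dominance
pattern exactly 16 of the 18 segments are applicable, and the
applicable weights sum to 23 (right), 23 (left) and 22.5 (balanced) —
frozen as a regression test.  Second, the table contains genuine
*zero* weights (the RCA segments under left dominance), so a patient
whose only lesions sit on zero-weight segments has SIS > 0 but
CT-LeSc = 0; the score quantifies prognostically weighted burden, not
bare plaque presence.  One cell (PDA-from-LCA absent under balanced
dominance while the postero-lateral branch from the LCA is applicable)
looks anatomically debatable; the table is reproduced verbatim rather
than "corrected", because the score is defined by its published
weights.

### Tunable parameters

All thresholds live in `ccta_config()`:

| parameter | default | meaning |
|---|---|---|
| `obstructive_cut` | 50% | lowest stenosis graded 2 / flagged OS |
| `severe_cut` | 70% | stenosis strictly above is grade 3 / SPP-eligible |
| `sis_threshold`, `sss_threshold`, `lesc_threshold` | 3, 5, 8.7 | strict dichotomization cuts |
| `rounding` | `full_precision` | CT-LeSc partial handling (below) |
| `tier_low_max`, `tier_moderate_max` | 7.5, 15 | UKPDS fatal-risk tier bounds (%) |
| `quantile_type` | 7 | percentile rule for IQRs |
| `exact_max_n` | 10 | largest combined n for exact Mann–Whitney |

The grade band for 2 is 50–70% inclusive: the obstructive definition is
"≥ 50%" and the severe definition is "greater than 70%", so 70% itself
is obstructive but not severe, and a 70% left-main lesion does not make
SPP positive.  Whether the historical SSS convention caps grade 2 at
69% or 70% is not settled; the boundaries are configuration, not
constants, so either convention is one argument away.

### Rounding

CT-LeSc partials like 5 × 1.5 × 0.615 = 4.6125 are conventionally
written to two decimals on clinical worksheets, and the patient total is
then the sum of the rounded partials.  The package's default is exact
arithmetic (`full_precision`); `paper_2dp` reproduces the worksheet
convention by rounding each partial *half-up* to two decimals before
summing — half-up, not R's default round-half-even, because a worksheet
turns 0.615 into 0.62.  For the packaged worked example the two modes
give 12.31 and 12.30 respectively; the difference is bounded by half a
cent per lesion and is irrelevant at cohort scale, but the worksheet
mode is what published per-patient values quote.

### Degenerate inputs

Multiple plaques in one segment are collapsed by the *reader* (not the
scorer) to the maximal stenosis and the worst composition
(mixed > non-calcified > calcified, i.e. whichever attracts the 1.5
factor), with a warning — the scores are segment-level by definition.
Conflicting dominance rows for one patient are an error.  Stenosis
values in (0, 1] are rejected as probable fraction-for-percent unit
errors rather than rescaled.  An empty lesion set is valid and scores
(0, 0, 0, negative, 0, no OS).

## Risk tiers and eligibility

The UKPDS risk engine is a published external calculator; its equations
are not reimplemented here.  Its output — the 10-year fatal-CHD risk
percentage — is an input column, and `stratify_risk()` maps it to the
screening tiers low (< 7.5%), moderate (7.5–15%, both endpoints
included, since the band is written "7.5–15%" and high is "> 15%") and
high.  Eligibility screening mirrors study practice: ADA diagnostic
criteria (HbA1c ≥ 6.5%, FBG ≥ 7.0 mmol/L, post-challenge glucose
≥ 11.1 mmol/L, or hypoglycemic treatment), at least one additional
cardiovascular risk factor out of five (hypertension, dyslipidemia,
smoking, obesity-or-inactivity, family history), and exclusion of known
CHD, abnormal resting ECG, prior revascularization, and records with
incomplete risk-factor data.  A criterion with missing inputs counts as
not met but is reported, so exclusion decisions are auditable.

## The comparison battery

Score distributions are skewed counts, so comparisons are
nonparametric throughout and two-sided at α = 0.05.

* **Two groups**: Mann–Whitney U on mid-ranks.  Up to a combined
  n of 10 the p-value is exact by full enumeration of the
  `choose(n1+n2, n1)` group assignments over the pooled mid-ranks,
  with two-sided extremity measured as |U − n1·n2/2| — this handles
  ties exactly, which the classical exact distribution does not.
  Beyond that, the tie-corrected normal approximation with continuity
  correction (`stats::wilcox.test`).
* **k groups**: tie-corrected Kruskal–Wallis omnibus
  (`stats::kruskal.test`); post-hoc, Dunn z-tests on the pooled-rank
  means with the tie correction, Bonferroni-multiplied by k(k−1)/2 and
  capped at 1.  Dunn's procedure (rather than pairwise rank-sum tests)
  is the convention behind "Kruskal–Wallis with Bonferroni post-hoc"
  in mainstream statistical software, and it reuses the pooled ranking
  that the omnibus test already established.
* **Categorical**: Pearson χ² without continuity correction; small
  expected counts trigger a warning, never a silent switch to an exact
  test, so the reported statistic is always the one named.
* **Odds ratios**: `outcome ~ group` logistic regression with
  indicator coding against a chosen reference group; OR, Wald 95% CI
  and Wald p per non-reference group.  With a single binary predictor
  the MLE equals the 2×2 cross-product ratio ad/bc and the Wald CI
  equals exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d)) — both are asserted as
  test oracles.  Complete or quasi-complete separation (degenerate
  fitted probabilities, exploding standard errors) is flagged and the
  OR/CI reported as missing rather than as a huge finite number.

## The synthetic cohort generator

Patient-level data behind published screening cohorts are generally
unavailable, so the generator exists to make the pipeline testable end
to end: four groups (control plus low / moderate / high risk tiers)
with group-specific lesion prevalence, severity and composition mixes.
Within a patient, each applicable segment receives a lesion
independently with the profile's probability; severity is drawn from a
mild / moderate / severe mixture with a uniform percentage inside each
stratum; composition from a three-way mixture; covariates from simple
normal/log-normal distributions; and the UKPDS risk uniformly inside
the profile's tier band, so generated tier labels and `stratify_risk()`
agree by construction.

The default profiles are calibrated once to published group-level
marginals: mean stenotic segments per patient of about 2.1 / 3.3 /
4.9 / 4.9 across control / low / moderate / high (giving per-segment
probabilities 0.134 / 0.206 / 0.306 / 0.309 over the 16 applicable
segments), obstructive fractions 13 / 22 / 46 / 47%, calcified
fractions 13 / 3 / 9 / 11%, and covariate means/SDs matching the
published group summaries (e.g. control age 65 ± 13, high tier
63 ± 8).  Where the marginals do not pin a parameter down, a single
plausible choice was made and kept: the obstructive mass splits
roughly 70:30 into moderate vs severe, the non-calcified:mixed split
follows the group-level composition text, and dominance defaults to
(0.85, 0.08, 0.07) right/left/balanced, a conventional anatomical
prior.

What the generator does *not* emulate: within-patient correlation of
lesions (segments are independent given dominance; an optional
log-normal frailty on the lesion odds can induce clustering),
segment-specific prevalence (a real proximal LAD is diseased far more
often than a distal branch — the generator is exchangeable across
segments), and the exact published medians/IQRs or odds ratios, which
depend on unpublished patient-level data.  Passing pipeline tests on
synthetic cohorts therefore demonstrates that the machinery recovers
configured marginals and detects configured group differences — not
that it reproduces any particular clinical cohort.

## Problem sizes and reproducibility

The test suite exercises the scoring invariants (score bounds,
monotonicity in stenosis, the exact ×1.5 composition and ×1/0.615
obstructive factor steps, and equivalence against a brute-force scorer
that re-reads the packaged weight table) over 10,000 randomized
patients; parameter recovery uses 500 patients per group against
3-sigma binomial bounds; pipeline discrimination (higher median
SIS/SSS/CT-LeSc in moderate/high tiers than control, Kruskal–Wallis
p < 0.05) uses 200 per group.  All randomness is seeded;
`generate_cohort()` is byte-reproducible given its configuration.

## Known limitations

* Scores are segment-level: no per-vessel sub-scores, no Agatston
  calcium scoring, no plaque-volume quantification.
* The comparison battery deliberately stops at group-indicator
  logistic models; covariate-adjusted ORs and propensity matching are
  out of scope.
* The exact Mann–Whitney path enumerates all assignments and is
  therefore capped (default combined n ≤ 10); above the cap the normal
  approximation is used even with heavy ties.
* The generator's exchangeable-segment assumption makes its
  segment-location table flat; analyses that depend on the anatomical
  distribution of lesions should use real data or a custom profile per
  segment.
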