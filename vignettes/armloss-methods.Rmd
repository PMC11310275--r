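---
title: "Quantifying chromosome-arm loss and choosing a prognostic cut-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome-arm loss and choosing a prognostic cut-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Loss of the short arm of chromosome 1 (1p) is an established risk marker
for recurrence in meningioma, and concurrent 1p/22q loss is discussed as a
molecular criterion for identifying higher-risk cases despite benign
histology.  In routine practice the copy-number profile comes from a DNA
methylation array, processed into segmented log2 copy-ratio calls (the
conumee family of pipelines, exported in IGV SEG format).  The clinically
contentious question is *how much* of the arm must be lost before a case
is called "1p loss": proposed cut-offs have ranged from any detectable
loss to 30% of the arm.

`armloss` implements the analysis machinery needed to pose and answer
that question on any cohort with segmented copy-number and
recurrence-free survival (RFS) data:

1. per-sample, per-arm **loss/gain fractions** from segments;
2. **extent classification** (none / segmental / complete) and cohort-level
   **binned distributions**;
3. a **cut-off sweep** scored by Harrell's concordance index per cohort;
4. **Kaplan-Meier stratification** and the **grade-1 concurrent 1p/22q
   rule**;
5. a **synthetic cohort simulator** so every stage is testable end to end
   without patient data.

## Arm-level loss quantification

### Coordinates and arm definitions

All coordinates are 0-based half-open (UCSC convention), so interval
length is simply `end - start`; 1-based SEG input is shifted on read.
Arms come from a UCSC-style cytoband file: an arm spans the min start to
the max end of its bands, centromeric (`acen`) bands belong to the arm
their name starts with, and for any chromosome with both arms the p-arm
end must equal the q-arm start (shared centromere boundary).  Acrocentric
chromosomes whose file lists only one arm keep just that arm; an absent
arm is an error at lookup, never a silent 0/0.  The genome build is not
inferable from the file and is carried along as a provenance label only.
The package bundles a *synthetic* hg19-like cytoband file for chromosomes
1 and 22 (arm boundaries at the familiar hg19 positions, e.g. chr1p =
0-125 Mb); analyses of real data should use the cytoband file matching
the pipeline's build.

### From segments to fractions

A segment is called *loss* when its log2 copy-ratio is strictly below
`loss_log2` and *gain* strictly above `gain_log2`.  The defaults are
±0.15.  This is the one deliberately exposed gap between this
implementation and the clinical pipelines it models: segmentation tools
leave the calling threshold to the analyst, and ±0.15 is a common
heuristic for methylation-array log2 ratios.  The thresholds are
configurable everywhere and recorded as an attribute on every profile
table.

The loss fraction of an arm is the fraction of its bases covered by
loss-called segments; uncovered territory counts as neutral, so loss,
gain and neutral fractions always sum to 1.  Fractions are
base-pair-weighted by default — "95% of the arm" is read as genomic
extent — with a probe-weighted option (`weight = "probe"`) in which each
segment contributes its probe count in proportion to its overlap with the
arm and uncovered territory carries no weight.  Whether the original
clinical percentages were base- or probe-weighted is not documented
anywhere we know of; both are provided and the default is stated so
results are reproducible either way.

Overlapping same-sample segments (some pipelines emit them) are accepted
at I/O and resolved here, per base, in favor of the most extreme log2
ratio (largest absolute value; exact-magnitude ties go to the more
negative, i.e. loss-side, value).  The rule is deterministic and
independent of row order.  The implementation sweeps elementary intervals
between segment breakpoints; the test suite checks it against a literal
per-base labeler on hundreds of randomized toy arms, where agreement is
exact because every quantity is an integer base count divided once.

### Integer percent, classes, cut-off

Downstream rules reason in integer percent, so `loss_percent` is the loss
fraction rounded half away from zero — computed in exact integer
arithmetic (`floor((200 b + L) / 2L)` for `b` loss bases on an arm of `L`
bases) to avoid floating-point drift at `.5` boundaries.  On that scale:

* **complete** loss: `loss_percent > 95`;
* **segmental** loss: `5 < loss_percent <= 95`;
* **none**: `loss_percent <= 5`;
* loss at cut-off `c`: `loss_percent > c` (strict).  The recommended
  clinical cut-off of 5% therefore counts cases with a loss of 6% or
  higher, and cut-off 0 counts any detectable loss.

Cohort distributions are binned with 0% isolated in its own bin and
subsequent bins left-open right-closed (width 5: `0`, `1-5`, `6-10`, ...,
`96-100`), which reproduces the conventional presentation of the strongly
bimodal 1p distribution.  When methylation-class labels are supplied the
per-bin composition over the six classes (Ben-1/2/3, Int-A/B, Mal) is
attached.

## Survival machinery

The three survival tools are implemented from first principles (the
`survival` package is used in the test suite as an independent oracle,
never in the implementation).

**Kaplan-Meier.**  The product-limit estimator with the textbook tie
convention: events precede censorings at the same time, so a subject
censored at *t* is still at risk for events at *t*.  The reported median
is the smallest *event* time with S(t) ≤ 0.5; when the curve plateaus
above 0.5 the median is reported as undefined (`NA`), never as infinity —
honest reporting under heavy censoring.

**Log-rank.**  The standard unweighted two-group test: at each distinct
event time, observed events in group 1 minus the hypergeometric
expectation, squared and scaled by the summed hypergeometric variance;
p-values are upper-tail chi-squared with 1 df, no continuity correction.
Risk sets with a single subject contribute no variance; if the total
variance is zero the test degenerates to statistic 0, p = 1, with a
warning.  Type-I error calibration at the nominal 5% level is verified by
2000-replicate null simulation in the test suite.

**Harrell's c-index.**  A pair is comparable when the subject with the
strictly smaller observed time had an event, or when times are tied and
exactly one subject had an event (the event precedes the censoring).
Tied times with two events, or a censored shorter time, are omitted.
Comparable pairs with tied scores count 1/2.  This is Harrell's original
rule; which concordance variant produced published cut-off sweeps is
typically unstated, so the rule here is pinned by an exhaustive
pair-enumeration oracle in the tests.  One consequence worth knowing when
reading sweep results: a *dichotomous* marker cannot reach c = 1 even
under perfect separation, because comparable within-group pairs are
score-tied and each contributes 1/2; the ceiling is
`(n1 n0 + P_within / 2) / P_total`.

## The cut-off analyses

`sweep_cutoffs()` evaluates integer cut-offs (default 0-30, covering the
historically debated 5%-vs-30% range) by dichotomizing each cohort at
each cut-off and scoring the indicator with the c-index.  Cohorts are
always scored separately — independent cohorts are evidence of
replication, and pooling would let one large cohort dominate.  The score
is the dichotomized indicator itself (the simplest reading of "splitting
cases at a cut-off"), not a Cox linear predictor.  The c-index is
piecewise constant in the cut-off: it can only change at cut-offs where
some sample's call flips, a property the tests assert.  Cut-offs that
leave a cohort with zero loss or zero non-loss calls are reported as
`NA`, and no multiple-testing correction is applied across the sweep —
it is a descriptive profile, not a family of tests; treat the location of
its maximum accordingly.

`stratify_by_cutoff()` produces the two-group KM curves, the log-rank
test and the difference in median RFS at one chosen cut-off.

`grade1_co_loss_analysis()` applies the combined rule: restricted to CNS
WHO grade 1 cases, concurrent 1p *and* 22q loss — both called at the same
cut-off, 5% by default — versus all other grade-1 cases.  The comparison
group deliberately pools zero-loss and single-loss cases into one
two-group contrast (the clinically proposed rule); a four-group breakdown
is available via `four_group = TRUE` for exploration.

## The synthetic cohort generator

`simulate_cohort()` generates SEG-format segments on chromosomes 1 and
22, a clinical table, and the generative truth, deterministically from a
`simulation_config()` (a master seed feeds per-phase sub-streams, so
changing one component's parameters leaves the other phases' draws
intact).  The defaults encode the statistical structure reported for
large meningioma cohorts; they are fixed study conditions, not tuning
knobs:

* **Extent mixture** — 60% of samples with 0% true 1p loss, 30% with
  96-100% ("complete"), 10% segmental: the published distribution is
  dominated by the two extremes, with roughly twice as much mass at 0 as
  at complete loss.
* **Telomere-anchored partial losses** — segmental losses are single
  intervals anchored at the 1p telomere with extent uniform on 6-95% of
  the arm, which reproduces the observed gradient of loss frequency
  rising toward the telomere; an interstitial option exists for
  robustness testing.
* **Artifact rate** `p_artifact = 0.02` — spurious focal measured losses
  of 1-5% of the arm injected into truly intact samples, matching the
  ~2% of real cases found in the 1-5% bin (44/2257 ≈ 1.95%).  These
  artifacts are modelled directly as focal intervals at uniform position
  (mirroring the "too focal to see by eye" failure mode) rather than
  emerging from log2 noise, so their rate is exactly controllable.
* **Log2 levels and noise** — loss segments at a mean of −0.45 (one-copy
  loss attenuated by non-tumor admixture), neutral at 0, Gaussian
  segment-mean noise with sd 0.03.  No noise model for conumee log
  ratios is published; Gaussian segment-mean noise is our choice and is
  surfaced in the configuration.
* **22q co-loss** — whole-arm, with probability 0.80 given true 1p loss
  and 0.35 without (22q loss is the most common meningioma CNV overall).
* **Survival** — exponential RFS with hazard
  `baseline * hr_loss^[1p loss] * hr_co_loss^[1p and 22q loss]` and
  independent exponential censoring.  The exponential default gives
  closed-form medians (`log 2 / λ`) and sharp recovery tests; a Weibull
  option is provided.  Defaults `baseline = 0.04`/yr, `hr_loss = 3`,
  `hr_co_loss = 2`, censoring `0.05`/yr put the no-loss median near 17
  years and the loss-group median near 3-6 years — a median RFS gap on
  the order of a decade, the clinically reported scale.
* **Methylation classes** — drawn from a mixture interpolated linearly in
  loss extent between two anchors: 94% benign classes at 0% loss and 72%
  intermediate/malignant at complete loss, the two compositions reported
  for real cohorts.
* **Grades** — mostly grade 1, with higher grades enriched among
  loss-bearing samples; configurable per stratum.

What the simulator does **not** emulate: probe-level intensities,
segmentation breakpoint error (true and measured loss boundaries
coincide, so recovery at zero noise is exact by construction),
tumor-purity variation between samples, non-proportional hazards, and
cohort-to-cohort heterogeneity (cohorts are i.i.d. replicates).  Passing
recovery tests therefore demonstrates that the pipeline is internally
correct and sensitive under the stated generative model — not that any
particular cut-off is optimal for real patients.

`truth_recovery_report()` closes the loop: the confusion matrix of the
cut-off call against generative truth, observed versus closed-form group
medians, and the observed concordance against the analytic no-censoring
reference `w·h/(1+h) + (1−w)/2` for the two-group exponential model.

## Validation problem sizes

The shipped test suite validates: arm fractions against a per-base
brute-force labeler on 200 randomized toy arms (up to 10^5 bases, up to
100 overlapping segments) with exact equality; the classification and
cut-off rules exhaustively on the 0-100 integer grid; the c-index against
exhaustive pair enumeration on 100 random censored, tied cohorts; KM
against hand-computed product limits and `survival::survfit`; log-rank
type-I error within [0.04, 0.06] over 2000 null replicates; parameter
recovery on a simulated 3-cohort study of 500 subjects per cohort
(call accuracy ≥ 99% at zero noise, c-index within Monte-Carlo tolerance
of an independent brute-force draw, and mean c-index higher for cut-offs
≤ 5 than ≥ 10 when any true loss raises hazard); and grade-1 co-loss
detection at n = 300.  All simulation seeds are fixed in the tests.

## Known limitations

* The log2 call threshold (±0.15) is a heuristic, not derived from any
  published pipeline constant; conclusions near the threshold should be
  checked for sensitivity.
* Harrell's c-index (not Uno's censoring-weighted variant) is
  implemented; under heavy, covariate-dependent censoring the two can
  differ.
* No covariate-adjusted (Cox) modelling: the cut-off sweep scores the
  marginal dichotomy only.
* The sweep is descriptive; its argmax is a noisy statistic, especially
  on flat profiles.
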