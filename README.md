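# armloss

Chromosome-arm copy-number loss quantification and prognostic cut-off
analysis for tumor recurrence, built around the question that matters
clinically in meningioma: **how much 1p loss is enough to call a case
high-risk?**

Methylation-array CNV pipelines (conumee and relatives) export segmented
log2 copy-ratio calls; meningioma risk classification increasingly rests
on whether chromosome arm 1p — and, in histologically benign tumors,
1p *together with* 22q — is lost.  Proposed cut-offs for "1p loss" have
ranged from any detectable loss to 30% of the arm.  `armloss` gives
neuro-oncology analysts the machinery to quantify arm loss and evaluate
such cut-offs against outcome on their own cohorts, plus a synthetic
cohort generator so the whole pipeline is testable without patient data.

## What it computes

For sample *s* and arm *a* of length *L* bases, with segments called loss
when their log2 ratio < −0.15 (configurable, strict):

- **loss fraction** `f = (loss-covered bases of a) / L`, uncovered
  territory neutral, overlaps resolved per base by the most extreme log2
  ratio; `loss_percent = round(100 f)` (half away from zero, exact
  integer arithmetic);
- **extent class**: *complete* if `loss_percent > 95`, *segmental* if
  `5 < loss_percent ≤ 95`, else *none*;
- **cut-off rule**: loss at cut-off *c* iff `loss_percent > c` — at the
  recommended *c* = 5 this counts cases with ≥ 6% loss;
- **survival machinery from first principles**: Kaplan–Meier
  product-limit estimator S(t) = Π(1 − dᵢ/nᵢ) with median and censoring
  ties handled events-first; the unweighted two-group log-rank test
  (χ², 1 df); Harrell's concordance index
  c = (concordant + ½·score-tied) / comparable pairs;
- **cut-off sweep**: c-index of the dichotomized loss call per cohort at
  every integer cut-off (default 0–30), never pooled across cohorts;
- **grade-1 co-loss rule**: among CNS WHO grade 1 cases, concurrent
  1p ∧ 22q loss (both at the same cut-off) versus no-or-single loss.

Input formats are IGV SEG (read/write, 0- or 1-based), a UCSC-style
cytoband file for arm coordinates, and a TSV/CSV clinical table
(`sample_id`, `time` in years, `event`, optional `who_grade`,
`mc_class`, `cohort`).

## Worked example

```r
library(armloss)

cfg   <- simulation_config(n_subjects = 250, n_cohorts = 3, seed = 42)
study <- simulate_cohort(cfg)
arms  <- load_cytobands(cfg$cytoband, genome_build = "hg19-like-synthetic")
prof  <- arm_profiles(study$segments, arms, "chr1p")

head(bin_distribution(prof, bin_width = 5), 4)
#>     bin lower upper count
#> 1     0     0     0   439
#> 2   1-5     1     5     9
#> 3  6-10     6    10     5
#> 4 11-15    11    15    10
```

The simulated loss distribution is bimodal like the real one: 439/750
cases fully intact, a handful of 1–5% (mostly artifact) losses, and a
large complete-loss mode.  Sweeping cut-offs:

```r
sw <- sweep_cutoffs(prof, study$clinical, 0:30)
head(summarize_sweep(sw), 7)
#>   cutoff mean_c_index
#> 1      0    0.7031906
#> 2      1    0.7043880
#> 3      2    0.7062841
#> 4      3    0.7065011
#> 5      4    0.7061858
#> 6      5    0.7061858
#> 7      6    0.7061858
```

Mean concordance across the three cohorts is flat near its maximum for
low cut-offs and (further down the table) decays for large ones — the
signature of a cohort in which any true loss carries risk.  Stratifying
the discovery cohort at the 5% cut-off:

```r
disc <- study$clinical[study$clinical$cohort == "discovery", ]
stratify_by_cutoff(prof[prof$sample_id %in% disc$sample_id, ], disc, 5)
#> Stratified survival analysis: chr1p loss percent > 5 vs <= 5
#>    group   n n_events
#>     loss 105       85
#>  no_loss 145       61
#>   log-rank chi-square = 123.6, p = 1.02e-28
#>   median difference: 15.30 years
```

Loss-called cases recur far earlier (a ~15-year gap in median
recurrence-free time under the generator's default hazards).  The
combined rule for histologically benign cases:

```r
p22 <- arm_profiles(study$segments, arms, "chr22q")
grade1_co_loss_analysis(prof, p22, study$clinical, 5)
#> Stratified survival analysis: WHO grade 1: concurrent chr1p and chr22q loss (> 5%) vs no or single loss
#>         group   n n_events
#>       co_loss 136      111
#>  no_or_single 420      197
#>   log-rank chi-square = 225.6, p = 5.509e-51
#>   median difference: 14.21 years
```

Grade-1 tumors with concurrent 1p/22q loss progress markedly faster than
grade-1 tumors with no or a single loss.

A thin command-line wrapper over the same functions ships in
`inst/cli/armloss.R` (subcommands `validate`, `fractions`, `bins`,
`sweep`, `km`, `grade1`, `simulate`).

See `vignettes/armloss-methods.Rmd` for the full model description,
parameter rationale, numerical conventions and limitations.

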