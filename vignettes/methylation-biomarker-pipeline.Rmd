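---
title: "From paired bisulfite reads to prognostic methylation subgroups: the methmark pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paired bisulfite reads to prognostic methylation subgroups: the methmark pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

# The scientific problem

Colorectal tumors acquire aberrant DNA methylation early and consistently,
which makes methylation a natural substrate for diagnostic and prognostic
biomarkers. The workflow implemented here follows a cohort study design that
has become standard in the field:

1. **Array prescreen.** Genome-wide 450K-style beta values on a modest
   tumor/normal panel select CpG islands (CGIs) whose tumor methylation
   departs from the healthy mean in a meaningful fraction of tumors.
2. **Targeted bisulfite screen.** The surviving CGIs are deep-sequenced in a
   large cohort of *paired* tumor and adjacent-healthy samples; a
   multi-criterion rule distills a Table-1-style list of differentially
   methylated regions (DMRs).
3. **Genomic context.** Each DMR is labelled promoter, intragenic, or
   intergenic. A key observation driving this design is that intragenic
   CGIs — not only promoters — carry strong tumor-specific hypermethylation.
4. **Expression linkage.** RNA-seq fold-change filtering and per-gene
   methylation–expression correlations connect candidate DMRs to
   transcriptional consequences.
5. **qMSP validation.** For clinically usable markers, methylation-specific
   PCR primers are designed on the bisulfite-converted sequence, and the
   quantification-cycle (Cq) difference between the methylated- and
   unmethylated-specific reactions quantifies methylation in independent
   samples.
6. **Prognostic subgrouping.** Hierarchical clustering of patients on marker
   methylation defines a hypermethylated subgroup whose survival, recurrence
   and clinical covariates are compared by log-rank, chi-square and t tests.

`methmark` implements every stage as composable, individually tested
functions, plus a synthetic-cohort generator with planted ground truth so
that the entire pipeline is exercisable and falsifiable without any external
download.

# Data model and coordinate conventions

Internally every interval is **0-based, half-open** — the BED convention,
and the only convention in which widths and overlaps are computable without
±1 bookkeeping. Printed genomic coordinates in the literature are 1-based
inclusive; `parse_region()` and `format_region()` convert at the boundary,
and nothing else in the package ever adjusts a coordinate. Per-CpG data are
read-count records (`chrom`, `pos`, `strand`, `meth_count`, `unmeth_count`)
with beta = meth / (meth + unmeth); aggregation only combines cytosines on
the same strand, because opposite-strand cytosines of one CpG are distinct
measurements that bisulfite protocols report separately.

# The screening rules and their thresholds

## CGI aggregation (`aggregate_to_cgi`)

* **Depth ≥ 10×** per site (`min_cov = 10`): below ~10 reads a beta value
  has a binomial standard error above 0.15 and is noise at the effect sizes
  of interest.
* **Completeness: covered sites must exceed 1/3 of the CGI's CpG sites**
  (`min_site_fraction = 1/3`, strict `>`). A CGI mean computed from a
  handful of its CpGs is not a CGI-level measurement. The strict reading
  matters at small site counts (3 covered of 9 fails; 4 passes) and is
  pinned by tests.

## Array prescreen (`prescreen_array`)

A CGI survives when `|beta_tumor − mean(beta_normal)| ≥ 0.20` in **more
than** 20% of tumors with data. The 0.20 delta is the conventional 450K
threshold separating biological from technical variation; the `> 20%`
fraction discards private (single-patient) events while keeping
subtype-restricted ones.

## DMR screen (`screen_cohort` / `classify_dmr`)

Four criteria, all required (defaults in `screen_params()`):

1. **Paired difference**: `|beta_tumor − beta_normal| > 0.30` within a
   patient pair, in **≥ 50%** of evaluable pairs (`paired_diff_min = 0.30`,
   `paired_fraction_min = 0.50`). The per-pair comparison cancels
   patient-level covariates (age, diet, field effects) that inflate
   unpaired screens. The fraction threshold is *inclusive* (≥): the
   published candidate list contains a marker at exactly 50.0%, which pins
   the boundary reading.
2. **Band rule, healthy side**: cohort mean healthy methylation < 30%
   (`low_band_max = 0.30`) — a usable marker needs a quiet background.
3. **Band rule, tumor side**: cohort mean tumor methylation ≥ 50%
   (`high_band_min = 0.50`) — strong signal in the positive class.
4. **Mean separation**: cohort mean difference > 30%
   (`mean_diff_min = 0.30`).

Hypomethylated DMRs apply the mirrored bands. `classify_dmr()` exposes the
band rule alone (on the percent scale of printed summary tables);
`screen_cohort()` composes all four on raw site records. Pairs are
evaluable only when both members pass depth and completeness — which is why
published patient fractions carry varying denominators (75/90 but 58/83).

### A note on monotonicity

Tightening any of the four *decision* thresholds can only shrink the DMR
set, and the test suite asserts exactly that over 50 random cohorts. The
*coverage* threshold `min_cov` is deliberately excluded: raising it changes
which sites enter each mean and which pairs are evaluable, so a CGI can
*gain* DMR status at higher `min_cov` (e.g. when dropping a low-depth
discordant pair lifts the patient fraction above 50%). Empirically this
occurs in a noticeable minority of random cohorts. It is a real property of
the rule, not a bug, and the suite does not assert monotonicity there.

# Genomic context

`annotate_cgi()` is strand-aware: the promoter window spans 1500 bp
upstream to 500 bp downstream of the transcription start site, which for a
minus-strand gene is the *end* of its interval. A CGI overlapping both a
promoter window and a gene body is called **promoter** (the stronger
regulatory claim); among multiple genes the largest overlap wins, with the
smaller start coordinate as the deterministic tie-break. The window sizes
are conventional, not derived; they only affect the promoter/intragenic
split, never DMR status.

# Expression linkage

Library-size normalization uses median-of-ratios size factors (each sample's
median ratio to the per-gene geometric-mean reference), the standard robust
choice when most genes are non-differential. The fold-change filter is
strict (`ratio > min_fold`, default 2); genes expressed only in tumors give
an infinite ratio, which is retained and logged rather than dropped —
on/off genes are the most interesting case. TPM is recovered from
transcript-level scaled estimates as `scaled_estimate × 1e6`.
`methylation_expression_correlation()` reports Pearson and Spearman
together, since methylation–expression coupling is often monotone but
saturating.

# qMSP primer design

All design happens on the **in-silico bisulfite-converted** top strand:
unmethylated C → T, methylated CpG-C retained (`bisulfite_convert()`).
Conversion of a primer *footprint* takes its CpG context from the full
region sequence, so a footprint-terminal C whose G lies one base outside is
still treated as a CpG cytosine — conversion is chemistry on the genome,
not on the substring.

`enumerate_primer_pairs()` exhaustively scans all forward/reverse
placements and keeps pairs satisfying the design rule: **≥ 6 CpG sites
across the two primers** (the methylation specificity of the assay lives in
these positions), **melting temperature 55–60 °C** per primer, **amplicon
100–160 bp** (efficient qPCR on fragmented clinical DNA), primer length
18–30 nt. Pairs are ranked by the mean planted (or observed) tumor–normal
beta difference over the CpGs their primers cover, so the top-ranked pair
targets the most discriminative cytosines.

Melting temperatures use two-state nearest-neighbor thermodynamics with the
unified Allawi & SantaLucia (1997) parameter set, terminal A·T/G·C
initiation terms, the self-complementarity entropy correction, and the
monovalent-salt entropy correction `0.368·(N−1)·ln[Na⁺]`, at 50 mM Na⁺ and
500 nM oligo. The implementation reproduces an independent reference
implementation of the same table to ~1e-6 °C on non-palindromic sequences
(a fixed reference value is pinned in the tests). The internal
`window_tms()` computes all window temperatures from cumulative
nearest-neighbor sums and is verified numerically identical to the
per-sequence function.

`make_variants()` emits the Met / Unmet / Half-Met primer triple. The
Half-Met variant retains alternate CpG cytosines starting with the 5'-most
(configurable via `half_selector`); any fixed, documented alternation is
equally defensible — the variant exists to probe intermediate methylation,
not a specific haplotype.

# qMSP quantification

Under the exponential amplification model, a template quantity behind a
cycle value is `(1+E)^(−Cq)`, so the methylation level is
`(1+E)^(Cq_unmet − Cq_met)`; replicate wells average on the Cq scale by
default (the conventional treatment; quantity-scale averaging is available
and differs whenever replicates disagree). "nd" (no amplification) wells
follow assay semantics: no methylated signal → level 0; no unmethylated
signal with methylated present → infinite level (fully methylated); both
absent → `NA` with a warning. Tumor-over-normal `relative_level()` flags —
rather than errors on — division by an unmethylated normal.

# Prognostic subgrouping

Patient distances on marker betas are hand-computed Manhattan or Canberra
sums (Canberra skips zero-denominator coordinates; missing values drop
pairwise), feeding complete-linkage `hclust`. Group 1 is, by convention,
the cluster with higher mean methylation — the hypermethylated subgroup.
Survival uses the product-limit estimator and the standard log-rank
chi-square (via the `survival` package, cross-checked in the tests against
a hand-written hypergeometric tally). Clinical covariates use Pearson
chi-square **without continuity correction** — the reading verified to
reproduce published subgroup tables — and two-tailed Welch t tests for age.
Stage-IV patients can be excluded from recurrence analyses via
`subgroup_report(exclude_stage = "IV")`, since metastatic disease makes
"recurrence" ill-defined.

# The synthetic cohort generator

`simulate_cohort()` plants ground truth at the *study's* operating point:
90 tumor/normal pairs (plus optional unpaired samples), ~30× mean depth,
hypermethylated CGIs centered at beta 0.10 in healthy tissue with a +0.45
tumor effect. Per-site betas are drawn from
`Beta(center·c, (1−center)·c)` with concentration `c = 5`, giving realistic
site-to-site heterogeneity within a CGI; depths are Poisson; methylated
read counts binomial. Survival times are exponential with a planted hazard
ratio; the uniform censoring bound is solved numerically so the *realized*
censoring fraction matches the requested rate. `simulate_region_sequence()`
builds design regions whose CpGs carry large planted differences in the
central portion — mirroring markers whose discriminative CpGs cluster —
and guarantees no accidental CpG outside the planted set.

**Realism limits.** Sites within a CGI are conditionally independent given
the island center (no spatial autocorrelation along the island); depth is
Poisson rather than overdispersed; the methylation–expression link is a
fixed fold change rather than a dose–response; survival is exponential
(constant hazard). These simplifications make planted truth exactly
recoverable and keep every acceptance property interpretable; they
understate the between-site correlation of real bisulfite data, so real
cohorts will show somewhat noisier patient fractions than the generator.

# Worked example

```{r example, eval = FALSE}
params <- sim_params(seed = 1, n_cgis = 50, frac_hyper = 0.2,
                     n_pairs = 30, mean_depth = 30, effect = 0.45)
cohort <- simulate_cohort(params)
dmrs <- screen_cohort(cohort$sites, cohort$cgis, cohort$samples)
table(dmrs$call)

region <- simulate_region_sequence(300, 24, seed = 2)
pairs <- enumerate_primer_pairs(region)
make_variants(pairs[1, ], region)

lvl_t <- methylation_level(cq_met = 26.1, cq_unmet = 31.4)
lvl_n <- methylation_level(cq_met = 33.9, cq_unmet = 30.2)
relative_level(lvl_t, lvl_n)
```

# Design decisions, briefly

* Wrap, don't rewrite, the settled statistics (`survival::survfit`,
  `survdiff`, `chisq.test`, `t.test`, `hclust`); every wrapper is checked
  against an independent hand-written oracle in the test suite.
* Hand-write what *is* the contribution: the four-criterion screen, the
  band classifier, bisulfite conversion and primer enumeration, the
  nearest-neighbor Tm, the qMSP level model, the distance kernels.
* Strict vs inclusive threshold readings are each pinned by a boundary
  test, not left to `>=` happenstance.
* All defaults are the study's operating conditions; none were tuned to
  make a test pass.

# Limitations

The screen consumes CGI-level betas and does not model read-level
bisulfite conversion failure; primer design checks thermodynamics and CpG
content but not secondary structure or off-target hits; the prognostic
module implements two-group comparisons, not multivariable Cox adjustment.
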