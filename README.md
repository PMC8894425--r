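# methmark

Discovery and validation of CpG-island methylation biomarkers in colorectal
cancer, as a tested, composable R pipeline.

## The scientific problem

Colorectal tumors acquire recurrent, tumor-specific DNA methylation at CpG
islands (CGIs) — prominently at *intragenic* islands, not only promoters.
Turning that signal into usable biomarkers takes a chain of distinct steps,
each with its own statistics and failure modes:

1. **Array prescreen** — select CGIs whose 450K-style tumor beta values
   depart from the healthy mean by ≥ 0.20 in more than 20% of tumors.
2. **Paired cohort screen** — on targeted bisulfite sequencing of
   tumor/adjacent-healthy pairs, call a CGI a differentially methylated
   region (DMR) when (i) the within-pair beta difference exceeds 0.30 in at
   least 50% of evaluable pairs, (ii) cohort mean healthy methylation < 30%,
   (iii) cohort mean tumor methylation ≥ 50%, and (iv) the means differ by
   more than 30% (mirrored bands for hypomethylation). Sites need ≥ 10×
   depth, same-strand cytosines only, and a CGI mean requires coverage of
   more than a third of its CpG sites.
3. **Genomic context** — promoter / intragenic / intergenic classification
   with a strand-aware promoter window (TSS −1500 / +500).
4. **Expression linkage** — median-of-ratios normalization, strict
   fold-change filtering, Pearson + Spearman methylation–expression
   correlation.
5. **qMSP design and quantification** — exhaustive primer-pair enumeration
   on the in-silico bisulfite-converted strand (≥ 6 CpGs across the pair,
   nearest-neighbor Tm 55–60 °C, amplicon 100–160 bp), Met/Half-Met/Unmet
   variants, and methylation levels `(1+E)^(Cq_unmet − Cq_met)` from
   quantification cycles.
6. **Prognosis** — hierarchical clustering of patients on marker betas
   (Manhattan/Canberra, complete linkage; the hypermethylated cluster is
   group 1), Kaplan–Meier curves, log-rank tests, and a clinical covariate
   report (Pearson chi-square without continuity correction; Welch t for
   age), with optional stage-IV exclusion for recurrence.

A synthetic-cohort generator (`simulate_cohort()`, `simulate_expression()`,
`simulate_survival()`, `simulate_region_sequence()`) plants ground truth at
the study's operating conditions (90 pairs, ~30× depth, +0.45 effect on a
0.10 healthy background), so every stage is testable offline. The bundled
published summary tables (`published_dmr_summary()`,
`published_subgroup_clinical()`) serve as exact regression fixtures.

See the vignette (`vignettes/methylation-biomarker-pipeline.Rmd`) for the
model, threshold rationale, and generator limits.

## Worked example

```r
library(methmark)

params <- sim_params(seed = 1, n_cgis = 50, frac_hyper = 0.2, n_pairs = 30,
                     mean_depth = 30, effect = 0.45)
cohort <- simulate_cohort(params)
dmrs <- screen_cohort(cohort$sites, cohort$cgis, cohort$samples)
print(dmrs, n = 5)
#> # A tibble: 15 × 10
#>   cgi   region gene  numerator denominator frac_patients  mcom  mcam  diff call
#>   <chr> <chr>  <chr>     <int>       <int>         <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 CGI_… chrS:… <NA>         30          30             1  9.47  55.9  46.4 hyper
#> 2 CGI_… chrS:… <NA>         30          30             1 70.3   24.1 -46.3 hypo
#> 3 CGI_… chrS:… <NA>         30          30             1 70.3   24.5 -45.9 hypo
#> 4 CGI_… chrS:… <NA>         30          30             1  9.65  55.4  45.8 hyper
#> 5 CGI_… chrS:… <NA>         30          30             1  9.90  55.4  45.5 hyper
#> # ℹ 10 more rows

region <- simulate_region_sequence(300, 24, seed = 2)
pairs <- enumerate_primer_pairs(region)
pairs[1, c("fwd_seq", "rev_seq", "tm_met_f", "tm_met_r",
           "amplicon_len", "score")]
#> # A tibble: 1 × 6
#>   fwd_seq                        rev_seq    tm_met_f tm_met_r amplicon_len score
#>   <chr>                          <chr>         <dbl>    <dbl>        <int> <dbl>
#> 1 GAGTTAGCGATTAGTTATTAATTTCGTGAT CGAATACGC…     55.7     55.7          126 0.641

lvl_t <- methylation_level(cq_met = 26.1, cq_unmet = 31.4)
lvl_n <- methylation_level(cq_met = 33.9, cq_unmet = 30.2)
c(tumor = lvl_t, normal = lvl_n, relative = relative_level(lvl_t, lvl_n))
#>        tumor       normal     relative
#>  39.39662123   0.07694653 512.00000000
```

A thin command-line interface covering each stage is installed at
`inst/cli/methmark.R` (`Rscript $(Rscript -e 'cat(system.file("cli/methmark.R", package="methmark"))') simulate --help`).

## Layout

- `R/` — one file per stage: `core_io`, `synthetic_data`,
  `methyl_aggregate`, `dmr_screen`, `genomic_context`, `expression_link`,
  `msp_design`, `qmsp_model`, `prognosis_stats`, `published_tables`.
- `inst/extdata/` — transcribed published summary tables (CSV).
- `tests/testthat/` — per-stage suites, shared oracles in
  `helper-oracles.R`, acceptance criteria in `test-acceptance.R`.
- `vignettes/` — methods vignette (source).
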