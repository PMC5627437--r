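# favsig

Combined gene-expression signatures of response to antimetabolite
chemotherapies (5-FU, Gemcitabine and kin), for computational biologists
analyzing tumor cohorts with progression-free survival (PFS) follow-up or
cell-line panels with drug IC-50s.

Single target-enzyme markers (TYMS for 5-FU, RRM1/RRM2 for Gemcitabine)
stratify patients weakly. `favsig` instead builds a *combined* signature:

1. **Screen** — per gene, a univariate Cox proportional-hazards fit of PFS
   on standardized expression (Efron ties); keep genes with p < 0.05.
2. **Confounder filter** — drop hits associated with TP53 status (Wilcoxon)
   or stage/age/grade/nodal status (Spearman), each at per-test α = 0.05.
3. **Favorability scores** — discretize each surviving gene against its own
   threshold med + s/2:
   F = +1 if expression ≥ med + s/2 and the gene/sample anchor is favorable,
   −1 if unfavorable, 0 otherwise.
4. **Stratify** — k-means (k = 2) on the samples × genes score matrix;
   compare subgroup PFS by Cox regression (HR oriented unfavorable vs.
   favorable); validate with 5-fold cross-validation in which thresholds,
   directions and centroids are estimated on training folds only.
5. **Cell-line branch** — the same machinery anchored on IC-50: CV filter,
   Kendall tau-b screen (|τ| > 0.2, p ≤ 0.01), sensitive/resistant classing
   at IC-50 quartiles, Wilcoxon subgroup comparison.
6. **Phenotype branch** — Spearman correlations of proliferation rate (kp),
   cell volume (V0), volume-corrected growth rate kg = V0·kp/ln 2 and
   metabolite consumption/release (CORE) with sensitivity −log10(IC-50),
   BH-FDR per family; pairwise Pearson drug-similarity clustering.
7. **Enrichment** — one-sided Fisher's exact test of signatures against
   GMT gene-set collections.

Synthetic-cohort generators with planted, known structure
(`simulate_tumor_cohort()`, `simulate_cellline_panel()`,
`simulate_phenotype_panel()`) make every stage testable end to end.

## Worked example

```r
library(favsig)

sim <- simulate_tumor_cohort(tumor_sim_config(seed = 3))
wf  <- run_tumor_workflow(sim$expression, sim$survival, n_folds = 5, seed = 3)

wf$manifest
#> # A tibble: 5 x 2
#>   stage             n_genes
#>   <chr>               <int>
#> 1 input                1000
#> 2 low_count_filter     1000
#> 3 survival_screen       103
#> 4 confounder_filter      89
#> 5 signature              89

wf$comparison
#> <subgroup_comparison> cox_lr p = 6.34e-26, HR (unfavorable vs favorable) = 9.43; n = 103/97

glance(wf$cv)
#> # A tibble: 1 x 5
#>   median_train_p sd_train_p median_test_p sd_test_p n_folds_completed
#>            <dbl>      <dbl>         <dbl>     <dbl>             <int>
#> 1       8.61e-22   5.34e-21    0.00000328 0.0000345                 5
```

The funnel reads: 1000 genes in, 103 survive the survival screen, 89
survive the confounder filter and form the signature. The two k-means
subgroups separate PFS at HR ≈ 9.4 (the unfavorable-signature group
progresses ~9× as fast), and the separation holds in held-out folds
(median test p ≈ 3e-6),
i.e. it is not an artifact of fitting and evaluating on the same samples.
`autoplot(wf$comparison)` draws the Kaplan–Meier curves and
`autoplot(wf$favorability)` the score heatmap.

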