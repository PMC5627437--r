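---
title: "Favorability-score signatures of chemotherapy response: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Favorability-score signatures of chemotherapy response: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(favsig)
library(dplyr)
```

Patients treated with antimetabolite chemotherapies such as 5-FU or
Gemcitabine respond very heterogeneously, and single target-enzyme markers
(TYMS, RRM1/RRM2) have weak and contested prognostic value. `favsig`
implements a combined-signature alternative: screen the transcriptome for
genes whose expression is associated with progression-free survival (PFS),
remove genes explained by clinical confounders, discretize the survivors
into per-(gene, sample) *favorability scores*, and cluster samples on that
score matrix into favorable- and unfavorable-signature response subgroups.
A parallel branch does the same in cell-line panels with IC-50 as the
response anchor, and a phenotype branch relates proliferation, cell volume,
growth rate and metabolite exchange rates to drug sensitivity.

This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, what the synthetic-data generators
emulate, and the numerical and design choices that were genuinely open.

## The tumor branch

### Screening model

For each gene $i$ the package fits a univariate Cox proportional-hazards
model of PFS on standardized expression,
$h_j(t) = h_0(t)\exp(\beta_i z_{ij})$, with Efron handling of tied event
times. Standardization to unit SD makes $\beta_i$ a per-SD log-hazard, so
effect sizes are comparable across genes and against the generator's
planted effects. A gene is a *hit* when its Wald p-value is below
`alpha = 0.05`, **uncorrected for multiple testing** — the screen is a
filter, not an inference, and the raw-p convention is recorded in the
result's metadata. A likelihood-ratio p is available via `p_type = "lr"`;
for a single covariate the two agree closely except at extreme effects.

The confounder filter then discards hits whose expression is associated
with clinical covariates: a Wilcoxon rank-sum test across the two levels of
a binary covariate (TP53 mutation status), and a Spearman correlation test
for ordinal or continuous covariates (stage, age, grade, nodal status),
each at a per-test `alpha = 0.05` with no multiplicity correction. With $k$
covariates a null gene is removed with probability about
$1-(1-\alpha)^k$; that cost is deliberate — the filter buys independence
from known prognostic factors at the price of some recall.

### Favorability scores

Each surviving gene is discretized against its own high-expression
threshold, the median plus half the standard deviation of its expression:

$$F_{ji} = \begin{cases} +1 & E_{ij} \ge \mathrm{med}_i + s_i/2
  \text{ and the anchor condition is favorable} \\
  -1 & E_{ij} \ge \mathrm{med}_i + s_i/2
  \text{ and the anchor condition is unfavorable} \\
  0 & \text{otherwise} \end{cases}$$

The anchor condition is ambiguous in the favorability-score tradition: it
can be read per gene (the sign of the gene's Cox coefficient) or per sample
(whether the patient had good or poor survival). Both readings are
implemented behind `mode`:

* `gene_direction` (default): the sign of every nonzero score in a gene
  column is the gene's screened direction — favorable genes contribute only
  $+1$, unfavorable only $-1$. This produces the column-coherent
  favorable/unfavorable blocks seen in favorability heatmaps and avoids the
  circularity of clustering samples on labels derived directly from their
  survival.
* `sample_class`: a sample classed "poor" (event at or before the median
  event time) contributes $-1$, "good" (event-free at least that long)
  $+1$, with insufficient follow-up neutral. For cell lines the classes are
  "sensitive"/"resistant", defined as the quartile extremes of the drug's
  IC-50 distribution (`lower_q`/`upper_q`, type-7 quantiles; the
  discretization is rank-based, so any log transform of IC-50 is
  immaterial).

`score_matrix()` accepts frozen per-gene thresholds so that
cross-validation can estimate them on training folds only.

### Stratification and comparison

Samples are clustered on the rows of $F$ with k-means (k = 2 by default,
Euclidean distance, 50 restarts, seeded); the cluster with the higher mean
score is the favorable-signature group. Subgroup survival is compared with
a binary-covariate Cox fit; the reported hazard ratio is always oriented
unfavorable vs. favorable, and the p-value is the likelihood-ratio test.
The k-means restart count and seeding are fixed only for determinism — with
a two-block score matrix the objective is insensitive to them.

Five-fold cross-validation re-estimates *everything* — screen, confounder
filter, thresholds, directions, centroids — on each training set and
applies them frozen to the held-out fold; test samples are assigned to the
nearest training centroid (the assignment rule for held-out samples was an
open choice; nearest-centroid is the natural k-means companion). Per-fold
train and test p-values are summarized by median and SD. On null cohorts
the median test-fold p behaves like a median of uniforms (≈ 0.5); a test
median far below the train median would indicate leakage, and the package's
tests assert the opposite ordering.

### Single-gene baseline

`optimal_cutpoint()` scans all distinct expression values as candidate
dichotomization thresholds (keeping at least `min_group_frac = 0.1` of
samples per side, a guard against degenerate cuts), maximizing the
two-sample log-rank statistic — the standard "best cutting point" reading.
The maximally selected statistic is anti-conservative for a null gene; the
package documents this rather than correcting it, since the baseline exists
to be compared against the combined signature under identical conventions.
Ties in the scanned statistic resolve to the smallest cut.

## The cell-line branch

Expression is first CV-filtered (coefficient of variation ≤ 0.05 removed;
n−1 SD; zero-mean genes dropped with a warning). Association with drug
response is the tie-corrected Kendall $\tau_b$ between expression and
IC-50, with an exact permutation p-value for n ≤ 8 without ties and the
normal approximation otherwise. A gene passes at $|\tau| > 0.2$ and
$p \le 0.01$. The absolute value is a deliberate reading: both
sensitivity-associated (negative $\tau$: high expression, low IC-50) and
resistance-associated genes are needed to form favorable and unfavorable
signatures. Subgroups are compared on log IC-50 with a two-sided Wilcoxon
rank-sum test.

## The phenotype branch

Proliferation rate $k_p$ and post-division cell volume $V_0$ are coupled
(smaller cells divide faster), so raw correlations between $k_p$ and drug
sensitivity conflate size and division rate. The volume-corrected growth
rate assumes linear volume growth between divisions and division at
$2V_0$: with doubling time $T_d = \ln 2 / k_p$,

$$k_g = \frac{V_0\,k_p}{\ln 2} \quad \text{(volume per unit time).}$$

Sensitivity is $-\log_{10}(\mathrm{IC50})$ (the base is immaterial for
rank correlations, which the tests assert). Per trait, Spearman
correlations across drugs are Benjamini–Hochberg adjusted within the
drug family for that trait; CORE metabolite–drug pairs are adjusted
globally by default (`fdr_scope = "within_metabolite"` switches, since the
convention is not fixed by the tradition this follows). The drug-similarity
matrix is pairwise-complete Pearson correlation over IC-50 profiles,
clustered with average linkage on $1-r$; pair counts are recorded, and the
dendrogram exports as Newick.

## Enrichment

Signatures are tested for over-representation in user-supplied GMT
collections with a one-sided Fisher's exact test (hypergeometric upper
tail) per set, raw p < 0.05 reported without FDR — enrichment here is
descriptive annotation of a signature, not a discovery procedure. The
universe defaults to the genes that survived preprocessing (the screen's
input), conditioning on testability rather than the whole genome; a custom
universe can be supplied.

## What the generators emulate — and what they do not

`simulate_tumor_cohort()` draws per-gene Gaussian log2 expression.
Planted favorable and unfavorable genes load on one latent *program* per
direction with loading $\sqrt{\texttt{program\_cor}}$
(`program_cor = 0.6`): a response signature is a coherent transcriptional
program, not 50 independent markers, and the coherence is what makes the
favorability heatmap's block structure reproducible. The two programs share
a response axis with correlation `-program_anticor` (default 0.5), so
samples enriched for favorable scores are depleted for unfavorable ones —
the structure k-means exploits. The per-sample log hazard is

$$\eta_j = \beta\,\frac{\sum_{i \in U} z_{ij} - \sum_{i \in F} z_{ij}}
  {\sqrt{n_U + n_F}},$$

with $\beta$ = `effect_log_hazard` (0.5), exponential event times at
`baseline_hazard` $\times\, e^{\eta_j}$ and independent exponential
censoring (0.05 and 0.03 per day: a median PFS of roughly a year at null
risk and ~37% censoring, ordinary for adjuvant-therapy cohorts of n ≈
100–200). Confounded genes get a 1-SD mean shift between TP53 levels and
*no* hazard effect, so confounder-filter correctness is measurable as pure
recall/rejection. The planted subgroup labels are the median split of
$\eta_j$. Event times are exponential — the simplest law satisfying the
proportional-hazards assumption the screen fits; the generators do not
model RNA-seq technical artifacts, batch, tumor purity, non-proportional
hazards, or covariate-outcome associations, so passing tests demonstrate
algorithmic correctness under the planted model, not robustness to real
cohort pathology.

`simulate_cellline_panel()` plants expression–IC-50 dependence through a
Gaussian copula: a signal gene with target Kendall $\tau$ gets latent
correlation $r = \sin(\pi\tau/2)$ with log IC-50 (exact for bivariate
normals), signs split evenly between directions.
`simulate_phenotype_panel()` draws log-normal volumes and proliferation
rates with latent correlation −0.6 and builds each drug's sensitivity
latent from $(b-a)/\sqrt{2-2\rho}$ — where $a, b$ are the volume and
proliferation latents — which is exactly orthogonal to $a+b$, hence to log
growth rate: proliferation predicts sensitivity, volume anti-predicts it,
and the volume-corrected growth rate predicts nothing. Three drug families
share family factors (within-family IC-50 correlation ≈ 0.85 vs ≈ 0.36
between), and one metabolite (phosphocholine release) is anti-correlated
with sensitivity to one family. All generators are pure functions of
config + seed.

## Numerical conventions and edge cases

* "Over 80%" and "0.05 or smaller" in the count and CV filters are strict
  `>` and `≤` respectively; the log2 pseudocount is 1 (zeros stay zero).
* Thresholds use `≥` at the boundary; SDs use the n−1 denominator;
  quantiles are type 7.
* Constant genes: flagged p = 1 in the Cox screen, skipped in the tau
  screen, removed by the CV filter. Genes with > 20% missing values are
  dropped with a warning; per-gene statistics otherwise use complete pairs.
* Non-convergent Cox fits are excluded and logged; k-means on a matrix
  with fewer distinct rows than k returns a flagged degenerate assignment
  rather than an error, and downstream comparisons refuse to run on it.
* All randomized steps (generation, fold assignment, k-means restarts)
  take explicit integer seeds, and workflow artifacts carry a hash of the
  full configuration.

## Problem sizes used in the test-suite simulations

Monte-Carlo checks use cohorts of 100–200 samples and 100–1000 genes, 5–20
seeds per property, 44–60 cell lines and 17 drugs — large enough that the
planted effects dominate sampling noise for the asserted margins, small
enough to keep the whole suite inside a normal check run. The acceptance
script reruns the same computations at the same sizes from a caller-chosen
seed.

## Known limitations

* The screen is univariate by design; correlated hit lists overstate the
  number of independent signals (the signature is used collectively, so no
  claim is made per gene).
* Raw-p selection at every stage means signatures are not FDR-controlled
  gene lists.
* The cutpoint baseline's p-value is maximally selected and therefore
  optimistic; compare it qualitatively, not numerically, with the subgroup
  p.
* IC-50s are consumed as given — no dose-response refitting — and the
  enrichment stage never fetches pathway databases; collections are
  supplied as files.
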