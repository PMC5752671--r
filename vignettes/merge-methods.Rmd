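---
title: "Methods: prior-guided gene-drug association discovery with mergeaml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prior-guided gene-drug association discovery with mergeaml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mergeaml)
```

## The problem

In vitro drug-sensitivity screens on primary tumour samples pair a gene
expression matrix $X$ ($p$ genes $\times$ $n$ samples) with a drug response
matrix $Y$ ($q$ drugs $\times$ $n$ samples) of dose-response AUC values
(lower AUC = more sensitive). With $n \approx 30$ and $p \approx 17{,}000$,
univariate gene-drug correlations are plentiful but fragile: many reflect
disease subtypes, sample ascertainment, or assay batch rather than the
drug's mechanism, and they fail to replicate in independent data.

The approach implemented here integrates five per-gene "driver features" —
mutation evidence, expression hubness, known regulator annotation, copy
number variation, and promoter methylation — into a single *marker
potential* score per gene, and learns from the screen itself how much each
feature matters. Genes with high marker potential are prioritized, and
gene-drug pairs are reported only when they are both statistically
significant genome-wide and fall in the prioritized subset.

## The model

For gene $i$ and drug $j$, let $r_{ij}$ be the Pearson correlation between
expression and AUC across samples and
$z_{ij} = \operatorname{atanh}(r_{ij})\sqrt{n-3}$ its Fisher z-score,
approximately $N(0,1)$ when gene and drug are unrelated. The package fits a
two-groups mixture with a gene-level, covariate-dependent prior:

$$z_{ij} \sim (1-\pi_i)\,N(0,1) + \pi_i\,N(0,\,1+\omega^2), \qquad
\operatorname{logit}(\pi_i) = \lambda_0 + \lambda\, m_i, \qquad
m_i = \sum_{k=1}^{5} v_k d_{ik},$$

where $d_{ik}$ are the column-standardized driver features, $v$ the feature
weights, $\lambda \ge 0$ the impact of the score on the odds that a pair is
a true association, and $1+\omega^2$ the variance of true-association
z-scores. The mixture acts on the magnitude of $z$ (a symmetric,
variance-inflated alternative); the direction of each association —
negative $r$ marks a sensitivity marker — is kept in the association table,
not the mixture.

Because $\lambda$ and $\|v\|$ only enter through the product $\lambda v$,
the model is fitted in terms of $\beta = \lambda v$ and reported with
$\lambda = \|\beta\|$ and unit-norm $v$, which also resolves the sign
indeterminacy while allowing individual weights (e.g. methylation) to be
negative.

### Fitting

`fit_merge()` runs EM. The E-step computes per-pair responsibilities; the
M-step maximizes the responsibility-weighted logistic log-likelihood over
$(\lambda_0, \beta)$ by damped Newton steps — a step is accepted only if it
improves the objective, so the marginal log-likelihood never decreases —
and updates $\omega^2$ in closed form from the responsibility-weighted
second moment. Numerical choices that matter:

* **Convergence.** The run stops when the relative log-likelihood change
  falls below `tol` (default `1e-6`). At genome scale the total
  log-likelihood is of order $10^4$–$10^5$, so the default can stop while
  the weights are still drifting along a flat ridge; definitive fits (the
  package's own recovery experiments) pass `tol = 1e-9`.
* **Multi-start.** Mixture likelihoods of this form have near-degenerate
  local optima (observed: basins whose log-likelihoods differ by less than
  one unit but whose heaviest weights differ). By default the flat start
  ($v=0$, $\lambda_0=\operatorname{logit}(0.01)$, $\omega^2=4$) competes
  with 100-iteration short runs started at impact $\pm 2$ on each single
  feature, and the best short-run likelihood continues to convergence.
  `multi_start = FALSE` restores the single flat start.
* **Degeneracies.** An all-zero (constant) feature matrix makes $\lambda$
  unidentifiable; the fit then reduces to a plain two-groups model and
  returns $v = 0$ with a flag. Non-finite z entries are excluded with a
  logged count.

### Prioritized selection

`merge_scores()` ranks genes by $m_i$ (ties broken lexicographically);
`prioritize()` intersects the genome-wide Benjamini-Hochberg selection at
FDR $q = 0.1$ over all $p \times q$ p-values with the top-$N$ genes.
BH is applied *before* subsetting, matching the "genome-wide FDR" reading
of the selection rule; a per-drug variant is available behind a flag. The
default reporting subset is $N = 500$ — the source work never states its
$N$, so this is an explicit package choice, configurable everywhere it is
used.

## Dose-response processing

Raw screens measure viability (fraction of control) at eight concentrations
spanning roughly $10^{-12}$–$10^{-4}$ M, in duplicate. `fit_curve()` fits a
four-parameter logistic on $\log_{10}$ concentration by bounded least
squares (bottom $\in [0,1]$, top $\in [0,1.5]$, Hill slope $\in [0.1,10]$,
EC50 within two decades of the tested range), replicates averaged before
fitting, with a flagged monotone-interpolation fallback on non-convergence.
`compute_auc()` integrates the fitted curve clipped to $[0,1]$ over the
tested $\log_{10}$ range and normalizes by the range width, so AUC is
comparable across drugs with different ranges; a flat curve at viability 1
has AUC exactly 1. The activity filter keeps drugs whose minimum *fitted*
viability is at or below 0.5 in at least half the samples; filtering on raw
viability is available via the minimum of the replicate means. Which of the
two the original screen used is not stated; fitted viability was chosen to
damp replicate noise.

## Expression hubness

`infer_hubness()` estimates a gene network from an expression compendium
and returns each gene's degree as the hubness feature. The default is lasso
neighbourhood selection (each gene regressed on all others over a shared
penalty grid, edge kept if either direction selects it) with the penalty
chosen to hit a target mean degree (default 5); a correlation-threshold
estimator with the same sparsity control is provided for speed. The choice
is logged because the original network construction is not reproduced here:
neighbourhood selection conditions away within-block correlation, so a hub
driving a correlated block is separated from its followers, which a
marginal-correlation network cannot do at dense edge budgets.

## Evaluation statistics

* **Consistency rate** (`consistency_rate()`): among the top $q \times N$
  pairs of a method's ordering that are discovery-significant (genome-wide
  BH at 0.1), the fraction whose validation p-value is below 0.05 *with the
  same association sign*. Both pieces of the replication definition are
  configurable; the source work states neither.
* **Drug-class specificity** (`dcs_score()`,
  `dcs_permutation_test()`): per gene, $-\log_{10}$ of the minimum
  one-sided Fisher's exact p-value over mechanism classes, multi-class
  drugs counted in each class; significance by shuffling the class-label
  assignment across drugs (each drug's label set moves as a unit), with
  add-one-smoothed empirical p-values and a global p comparing the mean
  observed score against permuted means. The exact statistic behind the
  published global p-value is in unpublished supplementary material; this
  implementation is a documented stand-in. Permutation p-values on a
  discrete statistic are conservative under ties; a randomized tie-breaking
  variant (exactly uniform under exchangeability) is provided for
  calibration checks.
* **Cluster enrichment** (`cluster_class_enrichment()`): drugs clustered on
  row-standardized AUC (average linkage, Euclidean — the linkage is not
  stated in the source and is scanned over *all* internal dendrogram nodes
  rather than hand-picked branches), a class counting as clustered if any
  node is Fisher-enriched at $p \le 0.06$.
* **Prediction** (`predict_response()`): per drug, ridge regression (penalty
  by generalized cross-validation) on the highest-scoring genes among those
  passing a training association screen at $p<0.05$, falling back to the
  top genes by training p-value. How the original "prediction from the
  prioritized model" was implemented is not described; this predictor is an
  explicit package decision. Baselines: per-drug elastic net (mixing 0.5,
  seeded CV) and a shared-support approximation to multi-task learning.
  Reports are per-drug Spearman correlations; methods are compared with the
  exact one-sided Wilcoxon signed-rank test.

## The synthetic world

`generate_dataset()` produces expression, AUC, driver features, class
annotation, and the full ground truth. Marker placement follows the model's
own law: $P(\text{gene } i \text{ markers class } c) =
\operatorname{logit}^{-1}(\lambda_0 + \lambda m_i)$ with defaults
$\lambda_0 = \operatorname{logit}(0.02)$, $\lambda = 2$ and the truth
one-hot on hubness; drugs in a class share their marker set exactly.
Expression has planted hub blocks (hub + 10 followers, pairwise correlation
0.8); hub degree feeds the hubness feature. Drug response is a linear
combination of marker expression plus Gaussian noise, with the noise scaled
so the signal fraction is $R^2 = 0.7$, then min-max rescaled to $[0,1]$ per
drug (a linear map, so correlations are unchanged).

Two effect profiles make an unavoidable trade-off explicit. Because a
drug's per-pair correlations satisfy $\sum_i r_{ij}^2 \le 1$, a world
cannot both give *every* true pair a moderate, recoverable correlation and
give *some* pairs the $|r| \approx 0.7$–$0.8$ needed to clear genome-wide
FDR at $n = 30$:

* `"sparse-dominant"` (default): half-Cauchy effect magnitudes, so one or
  two markers dominate each drug — the regime real screens show, used for
  the discovery/replication evaluations. This profile also plants a
  *discovery-only batch factor* loading on 5% of genes and on every drug at
  half its signal sd: it creates genuinely correlated gene-drug pairs in
  the discovery data that are absent from validation replicates. Without
  such a mechanism every significant association replicates equally well
  and no ordering can beat a random one — non-replication driven by
  confounding is precisely what prior-guided prioritization is for.
* `"dense"`: equal-scale magnitudes ($0.5+\operatorname{Exp}(1)$), no
  confounder — the model's own generative assumptions, used for
  parameter-recovery experiments.

`generate_validation_replicate()` draws new samples from the same law with
effect sizes multiplied by an attenuation factor (0.8 mimics a cell-line
panel, 0.4 a refractory cohort; the batch factor is never replicated) and
the noise kept at its discovery scale, so attenuation 0 is a pure null.

What a green test on this world does **not** establish: robustness to
non-Gaussian expression beyond the optional t(3) flag, to probe-level
artefacts, to non-linear dose-response of the signal, or to driver features
measured with error; and the recovery results are specific to a truth
expressible in the five features.

## Known limitations

* The exact likelihood and inference of the original method are in
  unpublished supplementary notes; this package implements the documented
  stand-in above, versioned so an alternative likelihood can replace it
  without touching prioritization or evaluation.
* In finite samples the mixture can genuinely prefer a wrong feature
  direction: on 2 of 20 study-scale recovery replicates the
  maximum-likelihood solution from every tested start puts its heaviest
  weight on a sparse binary covariate other than the true one. This is a
  property of the estimator at $n = 30$, not of the optimizer.
* Spearman p-values use the t approximation (adequate for $n \ge 10$);
  permutation p-values are add-one smoothed and hence conservative at the
  resolution floor $1/(B+1)$.
* The dose-response module does not model plate or edge-well effects, and
  IC50/EC50 are computed but not used as the primary statistic.
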