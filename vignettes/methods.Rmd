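---
title: "Classifying homologous recombination deficiency from RNA-seq counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homologous recombination deficiency from RNA-seq counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdpredict)
```

## The problem

High-grade serous ovarian carcinoma (HGSC) with deficient homologous
recombination (HR) DNA repair responds to PARP inhibitors, so determining a
tumour's HR status is clinically decisive. The genomic gold standard counts
scars — telomeric allelic imbalance, loss of heterozygosity and large-scale
transitions — into an HRD score, with scores of 42 or more called deficient
(HRD) and below 42 proficient (HRP). Those scars also reshape the
transcriptome: recurrent copy-number changes at regions such as 8q24.2
(amplified in HRD), 5q13.2 and 19q12 leave coordinated expression
footprints. `hrdpredict` trains a penalized logistic classifier on exactly
that footprint, so HR status can be predicted from RNA-seq counts alone, for
bulk cohorts, single samples, or pseudobulked single-cell data.

## The training procedure

Training proceeds in five stages, each exposed as its own function and
orchestrated by `run_train()`.

**1. Gene-universe filtering.** Non-coding genes and genes on the
mitochondrial and Y chromosomes are removed
(`remove_excluded_genes()`). Genes are then required to reach 10 counts per
million (CPM, raw library sizes) in at least 70% of the smallest design
group (`filter_low_expression()`); both the CPM threshold and the
proportion are parameters. The rule is implemented literally as stated
rather than through any package's internal heuristic, so its behaviour is
fully determined by the two parameters.

**2. Differential expression.** Composition biases between libraries are
corrected by TMM factors (doubly trimmed — 30% on log-ratios, 5% on
absolute expression — precision-weighted mean of M-values against an
upper-quartile-selected reference; `tmm_norm_factors()`, computed by
edgeR). Counts are transformed to log2-CPM with precision weights from the
fitted mean–variance trend (`voom_transform()`, lowess span 0.5), each gene
is fit by weighted least squares against an intercept + HR-status design —
no other covariates — and the HRD − HRP contrast is moderated by robust
empirical-Bayes variance shrinkage (`moderate_statistics()`): posterior
variance $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with the prior $(d_0,
s_0^2)$ estimated from the across-gene variance distribution and outlier
variances down-weighted by winsorization at the (0.05, 0.10) tails. Genes
with Benjamini–Hochberg adjusted $p < 0.05$ (strict) form the signature.

**3. Standardization.** Signature counts are re-normalized to log2-CPM
using the library size *over the signature genes only* (prior count 0.5,
denominator offset by twice the prior), then z-scaled per gene. The mean
and sample standard deviation ($n-1$ denominator) of every signature gene
are stored in the model bundle and are the single source of truth at
prediction time — they are never recomputed on new data. This makes the
coefficients comparable across genes regardless of abundance, and makes
single-sample scoring well defined.

**4. Hyperparameter search.** The classifier minimizes

$$\frac{1}{N}\sum_i \left[\log(1+e^{\eta_i}) - y_i\eta_i\right] +
\lambda\left[\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
\alpha\lVert\beta\rVert_1\right],\qquad \eta = \beta_0 + X\beta,$$

with HRP coded $y = 1$, so the raw model probability is P(HRP); reported
probabilities are the inversion $P(\mathrm{HRD}) = 1 - P(\mathrm{HRP})$.
The mixing grid is $\alpha \in \{0.00, 0.01, \dots, 1.00\}$; per alpha, a
100-value lambda path descends log-spaced from
$\lambda_{\max} = \max_j |x_j^\top(y-\bar y)| / (N\max(\alpha, 0.001))$ to
$10^{-4}\lambda_{\max}$ (the surrogate 0.001 only keeps the ridge path
finite). Stratified 5-fold cross-validation fits each path per training
fold (warm-started) and scores out-of-fold AUC; each alpha keeps the lambda
maximizing its mean per-fold AUC.

**5. One-SE selection and final fit.** Let $\alpha^\*$ have the best mean
AUC, with per-fold SD $s^\*$. Among alphas whose mean AUC is within $s^\*$
of the best, the one with the smallest per-fold SD wins, ties broken toward
the larger (sparser) alpha. One-SE rules vary in which SD defines the
band; we use the best alpha's SD, with each-alpha's-own SD available via
`select_alpha_one_se(band = "own_sd")`. Per-fold AUCs are averaged rather
than pooling out-of-fold predictions. The final model is refit on the whole cohort at
the selected $(\alpha, \lambda)$ — no second cross-validation — and
exported as a JSON bundle carrying the signature, standardization
statistics, coefficients (zeros retained), intercept, hyperparameters and
the 0.5 default threshold.

## The solver

The elastic-net fit is computed by cyclic coordinate descent on the
IRLS-weighted quadratic approximation with soft thresholding (compiled
code), the standard algorithm for this objective. Numerical choices:

- IRLS weights floored at $10^{-5}$ to keep working responses finite near
  fitted probabilities of 0/1.
- Inner coordinate descent alternates full passes with passes over the
  active set; convergence when no parameter moves more than
  $\min(\text{tol}, 10^{-8})$, with the outer tolerance defaulting to
  $10^{-7}$ (`training_config(convergence_tol = )`).
- An IRLS step that increases the true penalized objective is backtracked
  halfway toward the previous iterate (up to 40 halvings), so the objective
  is non-increasing across outer iterations.
- Convergence is declared only when the stationarity (KKT) residual of the
  true objective falls below $10^{-6}$; fits that exhaust `max_iter`
  return `converged = FALSE` with a warning rather than failing.
- Along a lambda path, once the fitted model explains 99.9% of the null
  binomial deviance the remaining (smaller) lambdas inherit the current
  solution: on separable data the tail of the path adds no discrimination,
  only unbounded coefficients.
- Features are standardized once, up front; the solver never re-scales.

## The prediction contract

`predict_hr_status()` applies a fixed contract to any new count matrix:
subset to the signature in its stored order, zero-filling genes that the
cohort's annotation lacks (warning at any missingness, refusing above 50%
by default — `max_missing_frac`); log2-CPM with the library size summed
over signature genes only and norm factor 1 (no TMM against a reference
cohort, so a single sample can be scored); z-scaling with the stored
statistics; logistic scoring; inversion to P(HRD); thresholding with
`p_hrd >= threshold` called HRD (boundary inclusive). Counts on
non-signature genes can never influence the result.
`optimize_probability_threshold()` sweeps thresholds 0–1 in steps of 0.01
and returns the smallest maximizer of accuracy — smallest, because a lower
HRD threshold is the conservative direction for a treatable condition.

## Benchmark classifiers

Three simpler expression classifiers are included for comparison, each
taking the role of a published signature-based approach: 2-means clustering
of z-scored signature expression with the lower-marker-mean cluster called
HRD (`kmeans_signature_classify()`, 25 restarts, best within-cluster sum of
squares; exact marker ties call cluster 1 HRP); per-sample Pearson
correlation against an HRD centroid with positive correlation called HRD
and zero correlation conservatively HRP (`centroid_correlation_classify()`;
real published centroid values are out of scope, so tests use synthetic
stand-ins); and thresholding of a continuous score at 42 with an exhaustive
integer-grid optimizer (`score_threshold_classify()`,
`optimize_score_threshold()`). Agreement between partitions is quantified
by the adjusted Rand index.

## The synthetic cohort generator

Because the real training cohorts are controlled-access, the package ships
a generator (`simulate_cohort()`) that emulates their structure: ~50% HRD
prevalence; a latent HRD score drawn from truncated normals (HRP: mean 20,
SD 10, truncated to [0, 42); HRD: mean 62, SD 12, truncated to [42, ∞)) so
labels and the 42 cutoff are consistent by construction; library sizes
log-normal with median 6×10^7 reads; tumour purity uniform on 0.30–1.00;
negative-binomial counts with gene-wise log-normal dispersion (median 0.08,
sdlog 0.5); and three planted effect regions — 8q24.2 up in HRD, 5q13.2 and
19q12 down — of 50 genes each with per-gene |log2 fold-changes| uniform on
0.5–1.5. Purity multiplies the effect exponent (tumour fold-changes diluted
against a stromal baseline — simple and monotone), and a coupling fraction
(default 0.7) blends the binary label with the scaled latent score
(score/84) in the per-sample modulation, so expression tracks the
continuous score, not just the label. Expected abundances are renormalized
to proportions before sampling, so region shifts induce the mild
composition bias that TMM exists to remove.

The generator reproduces the *statistical* structure that the pipeline
exploits — regional fold-changes, purity dilution, score coupling,
overdispersion — not the full biology of HGSC: no batch effects, no
gene–gene correlation beyond the regions, no 5′/3′ coverage bias in the
single-cell simulator (plain multinomial sampling), and effect sizes chosen
for testability rather than estimated from tumour data. Tests passing on
synthetic cohorts therefore validate the machinery and its contracts, not
clinical performance.

`simulate_single_cells()` draws cells multinomially from a bulk profile at
log-normal cell library sizes (median 10^4), which is sufficient to test
the pseudobulk aggregation contract (`pseudobulk_counts()`: group sums,
counts conserved, grouping composes).

## Problem sizes used by the test suite

The default study configuration — 240 training and 60 test samples, 3000
genes, 150 effect genes, seed 1 — is the package's reference experiment:
large enough that feature selection, cross-validation and held-out
evaluation are all exercised at realistic signal-to-noise, small enough to
run comfortably on a laptop. Null calibration uses a 5000-gene, 60-sample
cohort with no planted effects. Solver correctness is checked against a
generic numerical minimizer (BFGS on an ε-smoothed |·|) on problems of up
to 6 features and 60 samples, where both routes are exact, and against
glmnet as an independent implementation.

## Known limitations

- The classifier is a linear model on z-scored log2-CPM; it inherits the
  usual failure modes of penalized logistic regression under strong class
  imbalance or covariate shift (e.g. very different library chemistry).
- Zero-filling missing signature genes is faithful to the scoring contract
  but not benign: a zero count scores far below the training mean on the
  z scale (tens of SDs when per-gene variance is small), and when the
  selected model is dense (ridge-like) each missing *weighted* gene shifts
  the linear predictor materially. On the default synthetic cohort, where
  CV selects a dense model, randomly removing even 4% of signature genes
  can flip many calls. Missingness is therefore always reported
  (`n_missing_genes`), the guard refuses above 50% missing, and users with
  systematically missing genes should retrain rather than rely on
  zero-fill.
- Probabilities are not calibrated (no Platt/isotonic step); the 0.5
  threshold is a decision default, not a calibrated posterior cut.
- The one-SE rule's band depends on which SD defines it; both readings are
  implemented, and the default is recorded in the bundle only through the
  selected hyperparameters.
- `hr_status` must be binary; multi-class outputs (e.g. BRCA1-like vs
  BRCA2-like deficiency) are out of scope.
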