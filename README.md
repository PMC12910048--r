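# hrdpredict

Transcriptomic classification of homologous recombination (HR) status in
high-grade serous ovarian carcinoma (HGSC), for computational biologists who
have RNA-seq counts but not the SNP-array or WGS data that genomic HRD
scoring requires.

HR-deficient (HRD) HGSC responds to PARP inhibitors; the clinical gold
standard calls a tumour HRD when its genomic scar score (telomeric allelic
imbalance + loss of heterozygosity + large-scale transitions) is ≥ 42.
Those scars leave a copy-number footprint in expression — 8q24.2
amplification, 5q13.2 and 19q12 loss, among others — and `hrdpredict`
learns that footprint:

1. **Feature selection** — counts are filtered (protein-coding, off
   chrM/chrY, CPM ≥ 10 in ≥ 70% of the smallest group), TMM-normalized and
   tested for differential expression between HRD and HRP with
   precision-weighted (voom) linear models and robust empirical-Bayes
   moderated t-statistics; genes at BH-adjusted p < 0.05 form the signature.
2. **Classifier** — elastic-net penalized logistic regression on z-scored
   subset-library log2-CPM of the signature genes:

   min over (β₀, β) of (1/N) Σᵢ [log(1 + exp(ηᵢ)) − yᵢηᵢ]
     + λ[(1−α)/2‖β‖₂² + α‖β‖₁],  η = β₀ + Xβ

   fit by coordinate descent; α is chosen from the grid 0.00–1.00 (step
   0.01) by stratified 5-fold cross-validation on AUC with a
   one-standard-error rule (most stable alpha within one SD of the best),
   and λ from a 100-value path per alpha.
3. **Prediction** — any cohort (bulk TSV/CSV, or 10x-style MTX pseudobulked
   with `pseudobulk_counts()`) is scored through a fixed contract: subset
   to the signature (zero-fill missing genes, with a report), log2-CPM over
   the signature-gene library only, z-scale with the *stored* training
   statistics, logistic score, and report P(HRD) = 1 − P(HRP) with the
   boundary-inclusive rule P(HRD) ≥ 0.5 → HRD.

Benchmark classifiers (2-means signature clustering, centroid correlation,
score thresholding), evaluation metrics (AUC, confusion metrics, adjusted
Rand index) and a synthetic HGSC cohort generator with known ground truth
are included, so the entire pipeline runs with no external data.

## Worked example

```r
library(hrdpredict)

# a synthetic HGSC-like cohort: 300 samples, 3000 genes, ~50% HRD,
# planted effects at 8q24.2 (up in HRD), 5q13.2 and 19q12 (down)
sim <- simulate_cohort(simulation_config(n_samples = 300, seed = 1))

# train on 240 samples
trained <- run_train(sim$counts[, 1:240], sim$samples, sim$annotation,
                     config = training_config(fold_seed = 1))
trained$bundle
#> HR-status classifier bundle (schema v1)
#>   signature genes: 137 (137 weighted)
#>   alpha = 0, lambda = 0.284, threshold = 0.50

# score the 60 held-out samples
pred <- predict_hr_status(sim$counts[, 241:300], trained$bundle)
truth <- sim$samples$hr_status[241:300]
auc_score(pred$p_hrd, truth)                    # 0.995
mean(pred$status == truth)                      # 0.967
cor(pred$p_hrd, sim$samples$hrd_score[241:300]) # 0.83
```

The trained signature has 137 genes (the differential-expression stage
recovers ~87% of the 150 planted effect genes), the cross-validated one-SE
rule selects ridge-like mixing on this cohort, and the held-out samples are
classified with AUC 0.995 / accuracy 0.967; the predicted probability of
HRD tracks the latent continuous HRD score (r = 0.83), mirroring the fact
that HR deficiency is a continuum that the 42-point cutoff discretizes.

`write_model_bundle()` / `read_model_bundle()` persist the classifier as
schema-versioned JSON with exact float round-trips. A thin command-line
wrapper with `train`, `predict`, `benchmark` and `simulate` subcommands is
installed at `inst/cli/hrdpredict.R`.

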