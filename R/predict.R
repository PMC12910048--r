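#' Preprocess a cohort for prediction
#'
#' Applies the fixed scoring contract of the classifier to raw counts:
#' subset to the bundle's signature genes (zero-filling missing ones),
#' compute log2-CPM with the library size taken over the signature genes
#' only (norm factor 1, prior count 0.5), then z-scale each gene with the
#' *stored* training mean and SD. Counts on non-signature genes can never
#' affect the result.
#'
#' @param counts Gene-by-sample count matrix (any gene universe).
#' @param bundle An `"hr_model_bundle"`.
#' @param max_missing_frac Passed to [subset_with_zero_fill()].
#' @return List with `z` (signature x samples z-score matrix) and
#'   `missing_genes`.
#' @export
preprocess_for_prediction <- function(counts, bundle, max_missing_frac = 0.5) {
  validate_model_bundle(bundle)
  sub <- subset_with_zero_fill(counts, bundle$signature_gene_ids,
                               max_missing_frac = max_missing_frac)
  lib <- colSums(sub)
  if (any(lib == 0)) stop("degenerate library: no counts on signature genes")
  norm <- log2_cpm(sub, lib_sizes = lib, prior_count = 0.5)
  stats_df <- data.frame(gene_id = bundle$signature_gene_ids,
                         mean = bundle$gene_means, sd = bundle$gene_sds,
                         stringsAsFactors = FALSE)
  list(z = apply_standardizer(norm, stats_df),
       missing_genes = attr(sub, "missing_genes"))
}

#' Logistic scoring of z-scaled samples
#'
#' The linear model's raw probability is P(HRP) (HRP is coded 1 in
#' training); the reported probability of interest is its inversion,
#' `p_hrd = 1 - p_hrp`.
#'
#' @param z Signature-by-sample z-score matrix (rows ordered as the
#'   bundle's signature).
#' @param bundle An `"hr_model_bundle"`.
#' @return data.frame with `sample_id`, `p_hrd`, `p_hrp`.
#' @export
predict_probability <- function(z, bundle) {
  validate_model_bundle(bundle)
  if (!identical(rownames(z), bundle$signature_gene_ids))
    z <- z[match(bundle$signature_gene_ids, rownames(z)), , drop = FALSE]
  if (anyNA(z) || any(!is.finite(z))) stop("non-finite z-scores")
  eta <- as.numeric(bundle$intercept + crossprod(z, bundle$coefficients))
  p_hrp <- 1 / (1 + exp(-eta))
  data.frame(sample_id = colnames(z), p_hrd = 1 - p_hrp, p_hrp = p_hrp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold probabilities into discrete HR status
#'
#' A sample is called HRD when `p_hrd >= threshold` (boundary inclusive).
#'
#' @param predictions data.frame from [predict_probability()].
#' @param threshold P(HRD) classification threshold in \[0, 1\].
#' @return The input with `status` (`"HRD"`/`"HRP"`) and `threshold_used`
#'   columns added.
#' @export
classify <- function(predictions, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  predictions$status <- ifelse(predictions$p_hrd >= threshold, "HRD", "HRP")
  predictions$threshold_used <- threshold
  predictions
}

#' Score a cohort with a model bundle
#'
#' End-to-end prediction: [preprocess_for_prediction()],
#' [predict_probability()] and [classify()] at the bundle's threshold
#' (overridable).
#'
#' @inheritParams preprocess_for_prediction
#' @param threshold Optional threshold override (default: the bundle's).
#' @return data.frame with `sample_id`, `p_hrd`, `p_hrp`, `status`,
#'   `threshold_used`, `n_missing_genes`.
#' @export
predict_hr_status <- function(counts, bundle, threshold = NULL,
                              max_missing_frac = 0.5) {
  prep <- preprocess_for_prediction(counts, bundle, max_missing_frac)
  pred <- predict_probability(prep$z, bundle)
  pred <- classify(pred, if (is.null(threshold)) bundle$threshold else threshold)
  pred$n_missing_genes <- length(prep$missing_genes)
  attr(pred, "missing_genes") <- prep$missing_genes
  pred
}

#' Optimize the probability threshold for accuracy
#'
#' Sweeps thresholds 0.00, 0.01, ..., 1.00 and returns the smallest value
#' maximizing accuracy of the rule `p_hrd >= threshold -> HRD` against the
#' given labels.
#'
#' @param p_hrd Predicted P(HRD) per sample.
#' @param truth `"HRD"`/`"HRP"` labels (both classes present).
#' @param step Grid spacing (default 0.01).
#' @return List with `threshold` and `accuracy`.
#' @export
optimize_probability_threshold <- function(p_hrd, truth, step = 0.01) {
  if (length(unique(truth)) < 2)
    stop("degenerate labels: both classes must be present")
  grid <- seq(0, 1, by = step)
  acc <- vapply(grid, function(t)
    mean(ifelse(p_hrd >= t, "HRD", "HRP") == truth), numeric(1))
  best <- which.max(acc)  # which.max returns the first (smallest) maximizer
  list(threshold = grid[best], accuracy = acc[best])
}
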