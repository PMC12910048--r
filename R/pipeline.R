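run_manifest <- function(command, config, seeds) {
  list(command = command,
       config = config,
       seeds = seeds,
       package_version = as.character(utils::packageVersion("hrdpredict")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Train an HR-status classifier end to end
#'
#' The full training workflow on a raw count matrix: annotation-based gene
#' exclusion (protein-coding, off chrM/chrY), low-expression filtering, TMM
#' normalization, precision-weighted moderated differential expression of
#' HRD vs HRP, signature selection at FDR < `alpha_fdr`, subset-library
#' log2-CPM and z-standardization of the signature, cross-validation of the
#' elastic-net mixing grid, one-SE selection, and the final full-cohort
#' fit, exported as a model bundle.
#'
#' @param counts Gene-by-sample count matrix.
#' @param labels data.frame with `sample_id` and `hr_status`
#'   (`"HRD"`/`"HRP"`); see [read_labels()].
#' @param annotation Gene annotation with `gene_id`, `chromosome`,
#'   `biotype` (and `arm` if arm enrichment is wanted downstream).
#' @param config A [training_config()].
#' @param cpm_threshold,min_prop Expression-filter settings.
#' @param alpha_fdr Signature FDR cutoff.
#' @param robust Robust empirical-Bayes moderation.
#' @return List with `bundle`, `cv` (the CV grid), `selection`, `de` (full
#'   DE table), `signature`, `standardizer`, `stages` (gene counts in/out
#'   of each filter) and `manifest`.
#' @export
run_train <- function(counts, labels, annotation, config = training_config(),
                      cpm_threshold = 10, min_prop = 0.7, alpha_fdr = 0.05,
                      robust = TRUE) {
  idx <- match(colnames(counts), labels$sample_id)
  if (anyNA(idx)) stop("missing labels for sample(s): ",
                       paste(utils::head(colnames(counts)[is.na(idx)], 5),
                             collapse = ", "))
  hr <- labels$hr_status[idx]
  stages <- list(input_genes = nrow(counts))

  kept <- remove_excluded_genes(counts, annotation)
  stages$after_annotation_filter <- nrow(kept)

  keep_ids <- filter_low_expression(kept, group_sizes = table(hr),
                                    cpm_threshold = cpm_threshold,
                                    min_prop = min_prop)
  filtered <- kept[keep_ids, , drop = FALSE]
  stages$after_expression_filter <- nrow(filtered)

  nf <- tmm_norm_factors(filtered)
  de <- run_differential_expression(filtered, hr, norm_factors = nf,
                                    robust = robust)
  sig <- select_de_genes(de, alpha_fdr = alpha_fdr)
  stages$signature_genes <- nrow(sig)

  sub <- subset_with_zero_fill(counts, sig$gene_id)
  norm <- log2_cpm(sub, lib_sizes = colSums(sub))
  standardizer <- fit_standardizer(norm)
  X <- t(apply_standardizer(norm, standardizer))
  y <- as.numeric(hr == "HRP")  # raw model probability is P(HRP)

  cv <- cross_validate_alpha_grid(X, y, config)
  sel <- select_alpha_one_se(cv)
  bundle <- train_final_model(X, y, sel$alpha, sel$lambda, standardizer,
                              sig$gene_id, config)
  stages$nonzero_coefficients <- sum(bundle$coefficients != 0)

  list(bundle = bundle, cv = cv, selection = sel, de = de, signature = sig,
       standardizer = standardizer, stages = stages,
       manifest = run_manifest("train",
                               list(cpm_threshold = cpm_threshold,
                                    min_prop = min_prop,
                                    alpha_fdr = alpha_fdr, robust = robust,
                                    training = unclass(config)),
                               seeds = config$fold_seed))
}

#' Score a cohort with a trained bundle
#'
#' Thin orchestration over [predict_hr_status()], returning predictions
#' plus a run manifest.
#'
#' @inheritParams predict_hr_status
#' @return List with `predictions` and `manifest`.
#' @export
run_predict <- function(counts, bundle, threshold = NULL,
                        max_missing_frac = 0.5) {
  pred <- predict_hr_status(counts, bundle, threshold = threshold,
                            max_missing_frac = max_missing_frac)
  list(predictions = pred,
       manifest = run_manifest("predict",
                               list(threshold = if (is.null(threshold))
                                 bundle$threshold else threshold),
                               seeds = NULL))
}

#' Benchmark prediction sets against truth labels
#'
#' Thin orchestration over [benchmark_report()], returning the report plus
#' a run manifest. AUC is reported as `NA` (with a note) when `truth`
#' contains a single class.
#'
#' @inheritParams benchmark_report
#' @return List with `report` and `manifest`.
#' @export
run_benchmark <- function(predictions, truth, scores = NULL) {
  single_class <- length(unique(truth)) < 2
  if (single_class && !is.null(scores)) {
    warning("truth contains a single class; AUC undefined")
    scores <- NULL
  }
  rep <- benchmark_report(predictions, truth, scores)
  out <- list(report = rep,
              manifest = run_manifest("benchmark", list(), seeds = NULL))
  if (single_class) out$note <- "single-class truth: AUC undefined"
  out
}
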