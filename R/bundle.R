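BUNDLE_SCHEMA_VERSION <- 1L

#' Construct a classifier model bundle
#'
#' The bundle is the complete persisted state of a trained HR-status
#' classifier: the DE-selected signature genes (used for subset-library
#' normalization of new samples), the training log2-CPM mean and SD of each
#' signature gene, the elastic-net coefficients (zeros retained), intercept,
#' hyperparameters and decision threshold. The raw linear-model probability
#' is P(HRP); prediction inverts it to report P(HRD).
#'
#' @param signature_gene_ids Ordered character vector of signature genes.
#' @param gene_means,gene_sds Training log2-CPM means and (positive) SDs,
#'   one per signature gene.
#' @param coefficients Coefficient per signature gene (zeros allowed).
#' @param intercept Scalar intercept.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param lambda Positive penalty strength.
#' @param threshold P(HRD) classification threshold (default 0.5).
#' @return A validated object of class `"hr_model_bundle"`.
#' @export
model_bundle <- function(signature_gene_ids, gene_means, gene_sds,
                         coefficients, intercept, alpha, lambda,
                         threshold = 0.5) {
  b <- structure(list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    signature_gene_ids = as.character(signature_gene_ids),
    gene_means = as.numeric(gene_means),
    gene_sds = as.numeric(gene_sds),
    coefficients = as.numeric(coefficients),
    intercept = as.numeric(intercept),
    alpha = as.numeric(alpha),
    lambda = as.numeric(lambda),
    threshold = as.numeric(threshold),
    positive_class_convention = "raw_probability_is_P_HRP"
  ), class = "hr_model_bundle")
  validate_model_bundle(b)
  b
}

#' @rdname model_bundle
#' @param bundle Object to validate.
#' @export
validate_model_bundle <- function(bundle) {
  required <- c("schema_version", "signature_gene_ids", "gene_means",
                "gene_sds", "coefficients", "intercept", "alpha", "lambda",
                "threshold", "positive_class_convention")
  missing <- setdiff(required, names(bundle))
  if (length(missing) > 0)
    stop("model bundle is missing field(s): ", paste(missing, collapse = ", "))
  p <- length(bundle$signature_gene_ids)
  if (p == 0) stop("model bundle has an empty signature")
  if (anyDuplicated(bundle$signature_gene_ids))
    stop("duplicate signature gene identifiers")
  for (f in c("gene_means", "gene_sds", "coefficients"))
    if (length(bundle[[f]]) != p)
      stop(sprintf("%s length (%d) does not match signature length (%d)",
                   f, length(bundle[[f]]), p))
  if (any(!is.finite(bundle$gene_sds)) || any(bundle$gene_sds <= 0))
    stop("gene_sds must all be positive")
  if (length(bundle$intercept) != 1 || !is.finite(bundle$intercept))
    stop("intercept must be a finite scalar")
  if (bundle$alpha < 0 || bundle$alpha > 1) stop("alpha must be in [0, 1]")
  if (bundle$lambda <= 0) stop("lambda must be positive")
  if (bundle$threshold < 0 || bundle$threshold > 1)
    stop("threshold must be in [0, 1]")
  invisible(bundle)
}

#' Serialize / deserialize a model bundle
#'
#' The on-disk format is schema-versioned JSON with doubles written at full
#' round-trip precision, so `read_model_bundle(write_model_bundle(b))`
#' reproduces every field bit-identically.
#'
#' @param bundle An `"hr_model_bundle"` object.
#' @param path Output (input) file path.
#' @return `write_model_bundle` returns `path` invisibly;
#'   `read_model_bundle` returns the validated bundle.
#' @export
write_model_bundle <- function(bundle, path) {
  validate_model_bundle(bundle)
  # digits = I(17): 17 significant digits, enough for exact double round trips
  json <- jsonlite::toJSON(unclass(bundle), digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop("model bundle is missing field(s): schema_version")
  if (obj$schema_version != BUNDLE_SCHEMA_VERSION)
    stop(sprintf("unsupported model bundle schema version %s (supported: %d)",
                 obj$schema_version, BUNDLE_SCHEMA_VERSION))
  b <- structure(obj, class = "hr_model_bundle")
  b$signature_gene_ids <- as.character(b$signature_gene_ids)
  for (f in c("gene_means", "gene_sds", "coefficients", "intercept",
              "alpha", "lambda", "threshold")) {
    if (is.null(b[[f]])) stop("model bundle is missing field(s): ", f)
    b[[f]] <- as.numeric(b[[f]])
  }
  validate_model_bundle(b)
  b
}

#' @export
print.hr_model_bundle <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "HR-status classifier bundle (schema v%d)\n  signature genes: %d (%d weighted)\n  alpha = %.3g, lambda = %.4g, threshold = %.2f\n",
    x$schema_version, length(x$signature_gene_ids), nz, x$alpha, x$lambda,
    x$threshold))
  invisible(x)
}
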