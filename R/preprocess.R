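#' Remove excluded genes before feature selection
#'
#' Training restricts the gene universe to protein-coding genes off the
#' mitochondrial and Y chromosomes, since non-coding and chrM/chrY signal is
#' uninformative for (or confounded with) HR status in tumour cohorts.
#'
#' @param counts Gene-by-sample count matrix.
#' @param annotation data.frame with `gene_id`, `chromosome` and `biotype`
#'   (`"protein_coding"` marks coding genes).
#' @param drop_unannotated Drop genes absent from the annotation (default
#'   TRUE).
#' @return The filtered matrix, with an attribute `"removed"` giving a
#'   per-reason removal count.
#' @export
remove_excluded_genes <- function(counts, annotation, drop_unannotated = TRUE) {
  idx <- match(rownames(counts), annotation$gene_id)
  chrom <- annotation$chromosome[idx]
  biotype <- annotation$biotype[idx]
  unannotated <- is.na(idx)
  on_excluded_chrom <- !unannotated & chrom %in% c("M", "MT", "Y")
  noncoding <- !unannotated & !on_excluded_chrom & biotype != "protein_coding"
  drop <- on_excluded_chrom | noncoding | (unannotated & drop_unannotated)
  removed <- c(non_coding = sum(noncoding),
               chrM_chrY = sum(on_excluded_chrom),
               unannotated = sum(unannotated & drop_unannotated))
  out <- counts[!drop, , drop = FALSE]
  if (nrow(out) == 0) stop("no genes left after annotation filtering")
  attr(out, "removed") <- removed
  out
}

#' Filter genes by minimum expression
#'
#' A gene is retained when its CPM (raw library sizes, no normalization
#' factors, no prior count) reaches `cpm_threshold` in at least
#' `ceil(min_prop * min(group_sizes))` samples, i.e. in at least 70% of the
#' smallest design group at the defaults.
#'
#' @param counts Gene-by-sample count matrix.
#' @param group_sizes Integer vector of per-class sample counts (at least
#'   two groups).
#' @param cpm_threshold CPM cutoff (default 10).
#' @param min_prop Required fraction of the minimum group size (default 0.7).
#' @return Character vector of retained gene identifiers.
#' @export
filter_low_expression <- function(counts, group_sizes, cpm_threshold = 10,
                                  min_prop = 0.7) {
  if (length(group_sizes) < 2) stop("need at least two design groups")
  if (min(group_sizes) < 1) stop("group sizes must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("degenerate library with zero total counts")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- ceiling(min_prop * min(group_sizes))
  keep <- rowSums(cpm >= cpm_threshold) >= need
  if (!any(keep)) stop("no genes pass the expression filter")
  rownames(counts)[keep]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values composition normalization: per-library scaling
#' factors from a doubly trimmed (log-ratio 30%, absolute-expression 5%),
#' precision-weighted mean of gene-wise log ratios against a reference
#' library (the one whose upper-quartile CPM is closest to the mean), then
#' rescaled to geometric mean 1. Computed with edgeR.
#'
#' @param counts Gene-by-sample count matrix with at least two samples.
#' @param logratio_trim,abs_expr_trim Trim fractions for the M and A
#'   components.
#' @return Numeric vector of positive factors, one per sample, product 1.
#' @export
tmm_norm_factors <- function(counts, logratio_trim = 0.30,
                             abs_expr_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stop("degenerate library with zero total counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_expr_trim)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' log2 counts-per-million
#'
#' `log2((count + prior_count) / (lib_size * norm_factor + 2 * prior_count) * 1e6)`.
#' The prior count keeps zero counts finite; the doubled prior in the
#' denominator keeps values bounded above by log2(1e6).
#'
#' @param counts Gene-by-sample count matrix.
#' @param lib_sizes Library sizes (default: column sums).
#' @param norm_factors Normalization factors (default 1).
#' @param prior_count Prior count added to the numerator (default 0.5).
#' @return Real matrix of log2-CPM values, same dimnames as `counts`.
#' @export
log2_cpm <- function(counts, lib_sizes = colSums(counts),
                     norm_factors = rep(1, ncol(counts)), prior_count = 0.5) {
  eff <- lib_sizes * norm_factors
  if (any(eff <= 0)) stop("degenerate library: effective library size <= 0")
  t(log2(t(counts + prior_count) / (eff + 2 * prior_count) * 1e6))
}

#' Fit / apply per-gene standardization
#'
#' `fit_standardizer` records each gene's training mean and sample standard
#' deviation (n - 1 denominator) of log2-CPM; `apply_standardizer` z-scales
#' any matrix with those *stored* statistics, never recomputing them, so
#' that single new samples are scored on the training scale.
#'
#' @param norm Gene-by-sample log2-CPM matrix.
#' @return `fit_standardizer`: data.frame with `gene_id`, `mean`, `sd`.
#' @export
fit_standardizer <- function(norm) {
  if (ncol(norm) < 2) stop("standardization needs at least two samples")
  m <- rowMeans(norm)
  s <- apply(norm, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(norm)[s == 0], 5), collapse = ", "))
  data.frame(gene_id = rownames(norm), mean = m, sd = s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname fit_standardizer
#' @param stats_df Statistics from [fit_standardizer()] (or stored in a
#'   model bundle).
#' @export
apply_standardizer <- function(norm, stats_df) {
  idx <- match(rownames(norm), stats_df$gene_id)
  if (anyNA(idx))
    stop("missing standardization statistics for gene(s): ",
         paste(utils::head(rownames(norm)[is.na(idx)], 5), collapse = ", "))
  (norm - stats_df$mean[idx]) / stats_df$sd[idx]
}

#' Subset a count matrix to required genes, zero-filling the absent ones
#'
#' New cohorts are subset down to the classifier's signature genes in the
#' signature's order. Genes missing from the input (different annotation
#' releases) become all-zero rows, mirroring how cross-annotation cohorts
#' are scored; downstream library sizes are computed over the signature
#' genes only.
#'
#' @param counts Gene-by-sample count matrix.
#' @param required_genes Ordered, unique gene identifiers.
#' @param max_missing_frac Refuse when more than this fraction of required
#'   genes is absent (default 0.5).
#' @return Matrix with exactly `required_genes` as rows; attribute
#'   `"missing_genes"` lists the zero-filled identifiers.
#' @export
subset_with_zero_fill <- function(counts, required_genes,
                                  max_missing_frac = 0.5) {
  if (length(required_genes) == 0) stop("required_genes is empty")
  if (anyDuplicated(required_genes)) stop("required_genes must be unique")
  idx <- match(required_genes, rownames(counts))
  missing <- required_genes[is.na(idx)]
  frac <- length(missing) / length(required_genes)
  if (frac > max_missing_frac)
    stop(sprintf("%.0f%% of required genes missing (limit %.0f%%)",
                 100 * frac, 100 * max_missing_frac))
  if (length(missing) > 0)
    warning(sprintf("%d of %d required genes missing; zero-filled",
                    length(missing), length(required_genes)))
  out <- matrix(0, nrow = length(required_genes), ncol = ncol(counts),
                dimnames = list(required_genes, colnames(counts)))
  present <- !is.na(idx)
  out[present, ] <- counts[idx[present], , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}

#' Pseudobulk single-cell counts
#'
#' Sums cell-level counts within groups (samples, sites or patients),
#' conserving total counts.
#'
#' @param cell_counts Gene-by-cell count matrix.
#' @param grouping Named character/factor vector mapping every cell
#'   (by name, or positionally when unnamed) to a group.
#' @return Gene-by-group count matrix.
#' @export
pseudobulk_counts <- function(cell_counts, grouping) {
  if (!is.null(names(grouping))) {
    if (!all(colnames(cell_counts) %in% names(grouping)))
      stop("unmapped cell(s): ",
           paste(utils::head(setdiff(colnames(cell_counts), names(grouping)), 5),
                 collapse = ", "))
    grouping <- grouping[colnames(cell_counts)]
  } else if (length(grouping) != ncol(cell_counts)) {
    stop("grouping length does not match the number of cells")
  }
  if (anyNA(grouping)) stop("unmapped cell(s): NA group")
  g <- factor(as.character(grouping))
  design <- stats::model.matrix(~ 0 + g)
  out <- cell_counts %*% design
  colnames(out) <- levels(g)
  storage.mode(out) <- "integer"
  out
}
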