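#' Confusion-matrix metrics
#'
#' HRD is the positive class. Precision is reported as `NA` (with a note
#' attribute) when nothing is predicted positive.
#'
#' @param predicted,truth Vectors of `"HRD"`/`"HRP"` calls of equal length.
#' @return List with `n`, `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `misclassification`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  stopifnot(all(predicted %in% c("HRD", "HRP")), all(truth %in% c("HRD", "HRP")))
  tp <- sum(predicted == "HRD" & truth == "HRD")
  fp <- sum(predicted == "HRD" & truth == "HRP")
  fn <- sum(predicted == "HRP" & truth == "HRD")
  tn <- sum(predicted == "HRP" & truth == "HRP")
  n <- length(truth)
  out <- list(n = n, tp = tp, fp = fp, fn = fn, tn = tn,
              accuracy = (tp + tn) / n,
              precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
              recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              misclassification = (fp + fn) / n)
  if (tp + fp == 0) attr(out, "note") <- "no positive predictions; precision undefined"
  out
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random HRD sample scores
#' above a random HRP sample, counting ties as 1/2, computed via the rank
#' formula. Higher scores must indicate HRD.
#'
#' @param scores Numeric score per sample.
#' @param truth `"HRD"`/`"HRP"` (or logical/0-1 with TRUE/1 = HRD) labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth) {
  pos <- if (is.character(truth) || is.factor(truth)) truth == "HRD"
         else as.logical(truth)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' k-means signature classifier
#'
#' z-scored signature expression is clustered with 2-means (multiple random
#' restarts, lowest within-cluster sum of squares kept); the cluster whose
#' centroid has the lower mean over the marker genes (canonical HR genes,
#' whose low expression suggests deficiency) is labelled HRD. Exact marker
#' ties label cluster 1 as HRP.
#'
#' @param z Signature-by-sample z-score matrix.
#' @param marker_genes Genes (subset of rownames of `z`) whose low
#'   expression marks HRD.
#' @param seed RNG seed for the restarts.
#' @param n_init Number of random restarts (default 25).
#' @return Character vector of `"HRD"`/`"HRP"` per sample.
#' @export
kmeans_signature_classify <- function(z, marker_genes, seed = 1L,
                                      n_init = 25L) {
  if (ncol(z) < 2) stop("need at least two samples to cluster")
  if (!all(marker_genes %in% rownames(z)))
    stop("marker genes absent from the signature matrix")
  set.seed(seed)
  km <- stats::kmeans(t(z), centers = 2, nstart = n_init)
  marker_means <- rowMeans(km$centers[, marker_genes, drop = FALSE])
  hrd_cluster <- if (marker_means[1] == marker_means[2]) 2L
                 else which.min(marker_means)
  ifelse(km$cluster == hrd_cluster, "HRD", "HRP")
}

#' Centroid-correlation classifier
#'
#' Each sample's z-scored signature vector is correlated (Pearson) with an
#' HRD class centroid: positive correlation calls HRD, negative (or zero)
#' calls HRP. Constant sample vectors are flagged unclassified (`NA`).
#'
#' @param z Signature-by-sample z-score matrix.
#' @param hrd_centroid Numeric centroid, one value per row of `z` (or a
#'   named vector matched by gene).
#' @return Character vector of `"HRD"`/`"HRP"` (or `NA`) per sample.
#' @export
centroid_correlation_classify <- function(z, hrd_centroid) {
  if (!is.null(names(hrd_centroid)))
    hrd_centroid <- hrd_centroid[rownames(z)]
  if (length(hrd_centroid) != nrow(z))
    stop("centroid length does not match the signature")
  if (stats::sd(hrd_centroid) == 0) stop("constant centroid")
  apply(z, 2, function(v) {
    if (stats::sd(v) == 0) return(NA_character_)
    if (stats::cor(v, hrd_centroid) > 0) "HRD" else "HRP"
  })
}

#' Score-threshold classifier
#'
#' Calls HRD when a continuous HRD-type score reaches the cutoff
#' (clinically, genomic scar scores >= 42).
#'
#' @param scores Numeric scores.
#' @param cutoff Decision cutoff (default 42).
#' @return `"HRD"`/`"HRP"` per sample.
#' @export
score_threshold_classify <- function(scores, cutoff = 42) {
  ifelse(scores >= cutoff, "HRD", "HRP")
}

#' Optimize a score cutoff for accuracy
#'
#' Exhaustive search over an integer grid; the smallest cutoff attaining
#' maximal accuracy of `score >= cutoff -> HRD` is returned.
#'
#' @param scores Numeric scores.
#' @param truth `"HRD"`/`"HRP"` labels (both classes present).
#' @param grid Candidate cutoffs (default 1:114).
#' @return List with `cutoff` and `accuracy`.
#' @export
optimize_score_threshold <- function(scores, truth, grid = 1:114) {
  if (length(unique(truth)) < 2)
    stop("degenerate labels: both classes must be present")
  acc <- vapply(grid, function(ct)
    mean(score_threshold_classify(scores, ct) == truth), numeric(1))
  best <- which.max(acc)
  list(cutoff = grid[best], accuracy = acc[best])
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected by the
#' permutation-model expected index; 1 for identical partitions (up to
#' label swap), about 0 for independent ones.
#'
#' @param a,b Partition labels over the same samples.
#' @return ARI (a real number, at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same samples")
  n <- length(a)
  if (n < 2) stop("need at least two samples")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Benchmark one or more prediction sets against truth
#'
#' @param predictions Named list of `"HRD"`/`"HRP"` prediction vectors (or
#'   a single vector).
#' @param truth `"HRD"`/`"HRP"` labels.
#' @param scores Optional named list of continuous scores (higher = more
#'   HRD) for AUC.
#' @return data.frame, one row per method, with confusion metrics and AUC
#'   where scores were given.
#' @export
benchmark_report <- function(predictions, truth, scores = NULL) {
  if (!is.list(predictions)) predictions <- list(method = predictions)
  rows <- lapply(names(predictions), function(nm) {
    m <- confusion_metrics(predictions[[nm]], truth)
    auc <- if (!is.null(scores) && !is.null(scores[[nm]]))
      auc_score(scores[[nm]], truth) else NA_real_
    data.frame(method = nm, n = m$n, tp = m$tp, fp = m$fp, fn = m$fn,
               tn = m$tn, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, misclassification = m$misclassification,
               auc = auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
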