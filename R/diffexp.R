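#' Build the two-group design matrix
#'
#' Intercept plus an HR-status indicator; no other covariates are modelled.
#'
#' @param hr_status Character vector of `"HRD"`/`"HRP"` per sample.
#' @return Design matrix with columns `(Intercept)`, `HRD` (1 for HRD).
#' @keywords internal
hr_design <- function(hr_status) {
  if (!all(hr_status %in% c("HRD", "HRP")))
    stop("hr_status values must be 'HRD' or 'HRP'")
  if (length(unique(hr_status)) < 2)
    stop("both HR classes must be present")
  cbind(`(Intercept)` = 1, HRD = as.numeric(hr_status == "HRD"))
}

#' Precision-weighted transformation of counts (voom)
#'
#' Transforms counts to log2-CPM (prior count 0.5) and estimates an
#' observation-level precision weight for each value from the fitted
#' mean-variance trend: gene-wise square-root residual standard deviations
#' are smoothed against average log2 counts by lowess, and each
#' observation's weight is the inverse of its predicted variance. This lets
#' heteroskedastic count data be analysed with ordinary weighted linear
#' models.
#'
#' @param counts Filtered gene-by-sample count matrix.
#' @param hr_status `"HRD"`/`"HRP"` per sample.
#' @param norm_factors TMM factors (default 1).
#' @param span Lowess span for the trend (default 0.5).
#' @return List with `logcpm`, `weights` (both gene-by-sample) and `design`.
#' @export
voom_transform <- function(counts, hr_status, norm_factors = rep(1, ncol(counts)),
                           span = 0.5) {
  design <- hr_design(hr_status)
  if (min(table(hr_status)) < 2) stop("need at least 2 samples per group")
  if (length(unique(rowMeans(counts))) < 3)
    stop("cannot fit the mean-variance trend: fewer than 3 distinct gene means")
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * norm_factors, span = span)
  list(logcpm = v$E, weights = v$weights, design = design)
}

#' Gene-wise weighted linear fits and the HRD - HRP contrast
#'
#' Fits each gene's log2-CPM against the design by weighted least squares
#' (voom weights) and extracts the HRD - HRP contrast: log fold-change,
#' residual standard deviation, residual degrees of freedom and the
#' unscaled coefficient standard deviation.
#'
#' @param fit A list from [voom_transform()], or any list with `logcpm`,
#'   `weights` and `design`.
#' @return data.frame with `gene_id`, `logFC`, `sigma`, `df_residual`,
#'   `stdev_unscaled`.
#' @export
fit_gene_linear_models <- function(fit) {
  if (qr(fit$design)$rank < ncol(fit$design))
    stop("design matrix is rank deficient")
  lf <- limma::lmFit(fit$logcpm, design = fit$design, weights = fit$weights)
  cf <- limma::contrasts.fit(lf, contrasts = c(0, 1))
  data.frame(gene_id = rownames(fit$logcpm),
             logFC = as.numeric(cf$coefficients),
             sigma = cf$sigma,
             df_residual = cf$df.residual,
             stdev_unscaled = as.numeric(cf$stdev.unscaled),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moderated t-statistics by empirical-Bayes variance shrinkage
#'
#' Per-gene residual variances are shrunk toward a prior estimated from
#' their across-gene distribution: the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t uses
#' `d0 + d_g` degrees of freedom. With `d0 = 0` the ordinary t-statistic is
#' recovered; with `d0 = Inf` every gene uses the common prior variance.
#' When `d0`/`s0_sq` are not supplied they are estimated by limma's
#' moment matching on the log-variance distribution; `robust = TRUE`
#' down-weights outlier variances (winsorization at the 5%/10% tails)
#' before estimation.
#'
#' @param fits Per-gene fits from [fit_gene_linear_models()].
#' @param d0,s0_sq Optional fixed prior degrees of freedom and variance.
#' @param robust Use outlier-robust prior estimation (default TRUE).
#' @return data.frame with `gene_id`, `logFC`, `t_mod`, `p`, `df_total`,
#'   plus the prior as attributes `"d0"` and `"s0_sq"`.
#' @export
moderate_statistics <- function(fits, d0 = NULL, s0_sq = NULL, robust = TRUE) {
  if (any(fits$df_residual <= 0)) stop("non-positive residual degrees of freedom")
  s2 <- fits$sigma^2
  if (is.null(d0) || is.null(s0_sq)) {
    sq <- tryCatch(
      limma::squeezeVar(s2, df = fits$df_residual, robust = robust,
                        winsor.tail.p = c(0.05, 0.10)),
      error = function(e) NULL)
    if (is.null(sq) || !is.finite(sq$var.prior) || sq$var.prior <= 0) {
      warning("prior estimation degenerate; falling back to d0 = Inf")
      d0 <- Inf; s0_sq <- mean(s2)
      s2_post <- rep(s0_sq, length(s2))
    } else {
      d0 <- sq$df.prior[1]
      s0_sq <- sq$var.prior[1]
      s2_post <- sq$var.post
    }
  } else {
    if (is.infinite(d0)) s2_post <- rep(s0_sq, length(s2))
    else s2_post <- (d0 * s0_sq + fits$df_residual * s2) / (d0 + fits$df_residual)
  }
  df_total <- fits$df_residual + (if (is.infinite(d0)) Inf else d0)
  t_mod <- fits$logFC / (sqrt(s2_post) * fits$stdev_unscaled)
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  out <- data.frame(gene_id = fits$gene_id, logFC = fits$logFC,
                    t_mod = t_mod, p = p, df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full differential-expression feature selection
#'
#' voom transform, gene-wise weighted fits of the HRD - HRP contrast,
#' robust empirical-Bayes moderation and BH adjustment, in one call.
#'
#' @inheritParams voom_transform
#' @param robust Robust prior estimation (default TRUE).
#' @return data.frame with `gene_id`, `logFC`, `t_mod`, `p`, `p_adj`,
#'   `direction` (`"up"`/`"down"` in HRD).
#' @export
run_differential_expression <- function(counts, hr_status,
                                        norm_factors = rep(1, ncol(counts)),
                                        robust = TRUE) {
  v <- voom_transform(counts, hr_status, norm_factors)
  fits <- fit_gene_linear_models(v)
  mod <- moderate_statistics(fits, robust = robust)
  mod$p_adj <- bh_adjust(mod$p)
  mod$direction <- ifelse(mod$logFC >= 0, "up", "down")
  mod
}

#' Select the differential-expression signature
#'
#' @param results DE table from [run_differential_expression()].
#' @param alpha_fdr Strict BH-adjusted significance cutoff (default 0.05).
#' @return data.frame with `gene_id` and `direction` for genes with
#'   `p_adj < alpha_fdr`.
#' @export
select_de_genes <- function(results, alpha_fdr = 0.05) {
  sel <- results[results$p_adj < alpha_fdr, c("gene_id", "direction")]
  if (nrow(sel) == 0)
    stop("empty signature: no genes significant at FDR ", alpha_fdr)
  rownames(sel) <- NULL
  sel
}

#' Chromosome-arm enrichment of DE directions
#'
#' For each arm carrying at least one selected gene, tests whether the
#' up:down split on the arm differs from the split on all other arms, by a
#' Yates-corrected chi-squared test on the 2x2 table, Bonferroni-corrected
#' over arms tested. Concentrations of one direction on an arm are the
#' expression footprint of arm-level copy-number change.
#'
#' @param selected Signature table from [select_de_genes()].
#' @param annotation Gene annotation with `gene_id` and `arm`.
#' @return data.frame per arm: counts, `chi_sq`, `p`, `p_bonf`.
#' @export
arm_enrichment_test <- function(selected, annotation) {
  if (nrow(annotation) == 0) stop("no cytoband annotation available")
  arm <- annotation$arm[match(selected$gene_id, annotation$gene_id)]
  if (all(is.na(arm))) stop("no selected gene maps to any chromosome arm")
  keep <- !is.na(arm)
  up <- selected$direction[keep] == "up"
  arm <- arm[keep]
  arms <- sort(unique(arm))
  rows <- lapply(arms, function(a) {
    on <- arm == a
    tab <- matrix(c(sum(up & on), sum(!up & on),
                    sum(up & !on), sum(!up & !on)), nrow = 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    data.frame(arm = a, up_on_arm = tab[1, 1], down_on_arm = tab[2, 1],
               up_elsewhere = tab[1, 2], down_elsewhere = tab[2, 2],
               chi_sq = unname(ct$statistic), p = unname(ct$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y Equal-length numeric vectors (length >= 3), both non-constant.
#' @return List with `r` and two-sided `p` (t transform, n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
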