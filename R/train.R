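#' Training configuration
#'
#' Defaults define the reference training recipe: the full elastic-net
#' mixing grid 0.00-1.00 in steps of 0.01, a 100-value log-spaced lambda
#' path per alpha, stratified 5-fold cross-validation scored by AUC, and a
#' one-standard-error alpha selection rule.
#'
#' @param alpha_grid Mixing parameters to search (101 values by default).
#' @param n_lambda Path length per alpha.
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param n_folds Cross-validation folds.
#' @param fold_seed Seed for the stratified fold assignment.
#' @param convergence_tol Coordinate-descent convergence tolerance.
#' @param max_iter Maximum outer (IRLS) iterations per fit.
#' @return List of class `"hr_training_config"`.
#' @export
training_config <- function(alpha_grid = seq(0, 1, by = 0.01),
                            n_lambda = 100, lambda_min_ratio = 1e-4,
                            n_folds = 5, fold_seed = 1L,
                            convergence_tol = 1e-7, max_iter = 250L) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), n_folds >= 2,
            n_lambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(alpha_grid = alpha_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, n_folds = n_folds,
                 fold_seed = as.integer(fold_seed),
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter)),
            class = "hr_training_config")
}

#' Lambda path for the elastic net
#'
#' `lambda_max = max_j |x_j' (y - ybar)| / (N * max(alpha, 0.001))` — the
#' smallest penalty at which the lasso-weighted fit is fully sparse — then
#' `n_lambda` log-spaced values down to `lambda_max * lambda_min_ratio`.
#' Ridge (`alpha = 0`) has no finite sparsity point, so a small surrogate
#' alpha is used for path construction only.
#'
#' @param X Standardized feature matrix (samples x genes).
#' @param y Binary labels (0/1).
#' @param alpha Mixing parameter.
#' @param n_lambda,lambda_min_ratio Path shape.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
make_lambda_path <- function(X, y, alpha, n_lambda = 100,
                             lambda_min_ratio = 1e-4) {
  if (length(unique(y)) < 2) stop("degenerate labels: both classes must be present")
  lam_max <- max(abs(crossprod(X, y - mean(y)))) /
    (nrow(X) * max(alpha, 0.001))
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Fit elastic-net penalized logistic regression
#'
#' Minimizes the average binomial deviance plus the elastic-net penalty
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)` with an
#' unpenalized intercept, by cyclic coordinate descent on the IRLS-weighted
#' quadratic approximation with soft thresholding. `X` must be
#' pre-standardized; no internal re-standardization is performed, so stored
#' standardization statistics remain the single source of truth.
#'
#' @param X Standardized feature matrix (samples x genes).
#' @param y Binary 0/1 labels (both classes present).
#' @param alpha Mixing parameter in \[0, 1\].
#' @param lambda Positive penalty, or a decreasing path of penalties
#'   (warm-started in order).
#' @param tol,max_iter Convergence controls.
#' @return For scalar `lambda`: list with `beta`, `intercept`, `alpha`,
#'   `lambda`, `objective_value`, `kkt_residual`, `converged`. For a path:
#'   list with `betas` (genes x lambdas), `intercepts`, `objectives`,
#'   `converged`, `lambdas`.
#' @export
fit_elastic_net_logistic <- function(X, y, alpha, lambda, tol = 1e-7,
                                     max_iter = 250L) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("degenerate labels: both classes must be present")
  if (any(diff(lambda) > 0)) stop("lambda path must be decreasing")
  res <- cpp_elnet_logistic_path(X, as.numeric(y), alpha,
                                 as.numeric(lambda), tol = tol,
                                 max_outer = max_iter)
  if (!all(res$converged))
    warning("elastic-net fit did not fully converge at ",
            sum(!res$converged), " lambda value(s)")
  rownames(res$betas) <- colnames(X)
  if (length(lambda) == 1) {
    beta <- res$betas[, 1]
    return(list(beta = beta, intercept = res$intercepts[1], alpha = alpha,
                lambda = lambda, objective_value = res$objectives[1],
                kkt_residual = cpp_elnet_kkt(X, as.numeric(y),
                                             res$intercepts[1], beta,
                                             alpha, lambda),
                converged = res$converged[1]))
  }
  list(betas = res$betas, intercepts = res$intercepts,
       objectives = res$objectives, converged = res$converged,
       lambdas = lambda, alpha = alpha)
}

#' Stratified fold assignment
#'
#' Partitions samples into folds of near-equal size (differing by at most
#' one) while balancing classes, from a fixed seed.
#'
#' @param y Binary labels.
#' @param n_folds Number of folds.
#' @param seed Seed for the shuffling.
#' @return Integer fold index per sample.
#' @export
make_stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  start <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- ((seq_along(idx) + start - 1L) %% n_folds) + 1L
    start <- start + length(idx)
  }
  if (any(tabulate(fold, n_folds) == 0) ||
      any(vapply(seq_len(n_folds), function(f)
        length(unique(y[fold == f])), 1L) < 2))
    stop("stratification failure: a fold is missing a class")
  fold
}

#' Cross-validate the elastic-net mixing grid
#'
#' For each alpha on the grid: build the lambda path on the full data, fit
#' the path on each training fold (warm-started), score out-of-fold AUC at
#' every lambda, and keep the lambda maximizing the mean per-fold AUC,
#' recording the per-fold AUCs at that lambda and their mean and SD.
#'
#' @param X Standardized feature matrix (samples x genes).
#' @param y Binary 0/1 labels (1 = HRP under the internal coding).
#' @param config A [training_config()].
#' @return List of class `"hr_cv_grid"`: `grid` (data.frame with `alpha`,
#'   `lambda`, `mean_auc`, `sd_auc`, `fold1..K`), `folds` (assignment),
#'   `config`.
#' @export
cross_validate_alpha_grid <- function(X, y, config = training_config()) {
  X <- as.matrix(X)
  folds <- make_stratified_folds(y, config$n_folds, config$fold_seed)
  K <- config$n_folds
  rows <- vector("list", length(config$alpha_grid))
  for (a in seq_along(config$alpha_grid)) {
    alpha <- config$alpha_grid[a]
    lambdas <- make_lambda_path(X, y, alpha, config$n_lambda,
                                config$lambda_min_ratio)
    aucs <- matrix(NA_real_, nrow = K, ncol = length(lambdas))
    for (f in seq_len(K)) {
      tr <- folds != f
      fit <- suppressWarnings(fit_elastic_net_logistic(
        X[tr, , drop = FALSE], y[tr], alpha, lambdas,
        tol = config$convergence_tol, max_iter = config$max_iter))
      eta <- X[!tr, , drop = FALSE] %*% fit$betas
      eta <- sweep(eta, 2, fit$intercepts, "+")
      aucs[f, ] <- apply(eta, 2, auc_score, truth = y[!tr])
    }
    mean_auc <- colMeans(aucs)
    best <- which.max(mean_auc)
    rows[[a]] <- data.frame(
      alpha = alpha, lambda = lambdas[best], mean_auc = mean_auc[best],
      sd_auc = stats::sd(aucs[, best]),
      t(stats::setNames(aucs[, best], paste0("fold", seq_len(K)))))
  }
  structure(list(grid = do.call(rbind, rows), folds = folds,
                 config = config), class = "hr_cv_grid")
}

#' One-standard-error alpha selection
#'
#' Let `alpha*` be the grid point with the highest mean cross-validated
#' AUC, with per-fold SD `s*`. Among all alphas whose mean AUC is within
#' `s*` of the best, the one with the smallest per-fold SD is selected
#' (ties broken toward the larger, sparser alpha). With
#' `band = "own_sd"` the candidate band instead uses each alpha's own SD.
#'
#' @param cv An `"hr_cv_grid"` (or its `grid` data.frame).
#' @param band Which SD defines the one-SE band: that of the best alpha
#'   (default) or each alpha's own.
#' @return List with `alpha`, `lambda`, `mean_auc`, `sd_auc`.
#' @export
select_alpha_one_se <- function(cv, band = c("best_sd", "own_sd")) {
  band <- match.arg(band)
  grid <- if (inherits(cv, "hr_cv_grid")) cv$grid else cv
  if (is.null(grid) || nrow(grid) == 0) stop("empty cross-validation grid")
  best <- which.max(grid$mean_auc)
  lo <- if (band == "best_sd") rep(grid$mean_auc[best] - grid$sd_auc[best], nrow(grid))
        else grid$mean_auc[best] - grid$sd_auc
  cand <- which(grid$mean_auc >= lo)
  cand <- cand[order(grid$sd_auc[cand], -grid$alpha[cand])]
  pick <- cand[1]
  list(alpha = grid$alpha[pick], lambda = grid$lambda[pick],
       mean_auc = grid$mean_auc[pick], sd_auc = grid$sd_auc[pick])
}

#' Train the final model and export the bundle
#'
#' Refits the elastic net at the selected `(alpha, lambda)` on the entire
#' training cohort and packages the classifier: signature genes, stored
#' standardization statistics, full coefficient vector (zeros retained),
#' intercept, hyperparameters and the default 0.5 threshold. The linear
#' model is fit with HRP coded 1, so its raw probability is P(HRP);
#' prediction inverts this to report P(HRD).
#'
#' @param X Standardized signature matrix for the full training cohort
#'   (samples x genes, columns ordered as `signature`).
#' @param y Binary 0/1 labels (1 = HRP).
#' @param alpha,lambda Selected hyperparameters.
#' @param stats_df Standardization statistics from [fit_standardizer()].
#' @param signature Ordered signature gene identifiers.
#' @param config A [training_config()].
#' @return An `"hr_model_bundle"`.
#' @export
train_final_model <- function(X, y, alpha, lambda, stats_df, signature,
                              config = training_config()) {
  stopifnot(identical(colnames(X), signature))
  idx <- match(signature, stats_df$gene_id)
  if (anyNA(idx)) stop("standardization statistics missing for signature gene(s)")
  fit <- fit_elastic_net_logistic(X, y, alpha, lambda,
                                  tol = config$convergence_tol,
                                  max_iter = config$max_iter)
  model_bundle(signature_gene_ids = signature,
               gene_means = stats_df$mean[idx],
               gene_sds = stats_df$sd[idx],
               coefficients = fit$beta,
               intercept = fit$intercept,
               alpha = alpha, lambda = lambda, threshold = 0.5)
}
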