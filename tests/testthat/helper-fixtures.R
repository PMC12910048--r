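# Shared fixture builders. All fixtures are generated in code.

toy_counts <- function() {
  m <- matrix(c(10L, 0L, 5L,
                3L, 7L, 2L), nrow = 3,
              dimnames = list(c("ENSG00000000001", "ENSG00000000002",
                                "ENSG00000000003"),
                              c("S1", "S2")))
  m
}

toy_annotation <- function(gene_ids, chromosome = "1",
                           biotype = "protein_coding", arm = "1q") {
  data.frame(gene_id = gene_ids,
             chromosome = rep_len(chromosome, length(gene_ids)),
             arm = rep_len(arm, length(gene_ids)),
             biotype = rep_len(biotype, length(gene_ids)),
             stringsAsFactors = FALSE)
}

# a quick low-cost cohort for pipeline-level tests
small_sim <- function(seed = 11, n_samples = 80, n_genes = 400) {
  cfg <- simulation_config(
    n_samples = n_samples, n_genes = n_genes,
    region_sizes = c("8q24.2" = 20, "5q13.2" = 20, "19q12" = 20),
    region_signs = c("8q24.2" = 1, "5q13.2" = -1, "19q12" = -1),
    effect_range = c(1.0, 1.5),
    libsize_meanlog = log(2e6), libsize_sdlog = 0.3,
    seed = seed)
  simulate_cohort(cfg)
}

# coarse but fast training configuration for pipeline tests
fast_config <- function(seed = 1) {
  training_config(alpha_grid = c(0, 0.5, 1), n_lambda = 30,
                  n_folds = 3, fold_seed = seed)
}

# random standardized logistic test problem
random_problem <- function(seed, n = 60, p = 6, strength = 1.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("g", seq_len(p))
  truebeta <- rnorm(p) * strength * rbinom(p, 1, 0.6)
  y <- rbinom(n, 1, stats::plogis(X %*% truebeta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}

# generic numerical minimizer of the penalized logistic objective:
# BFGS on an epsilon-smoothed |.|, evaluated with the true objective.
oracle_elnet_objective <- function(X, y, alpha, lambda, eps = 1e-12) {
  n <- nrow(X)
  smooth_obj <- function(par) {
    b0 <- par[1]; beta <- par[-1]
    eta <- b0 + X %*% beta
    loss <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
    loss + lambda * ((1 - alpha) / 2 * sum(beta^2) +
                       alpha * sum(sqrt(beta^2 + eps)))
  }
  true_obj <- function(par) {
    b0 <- par[1]; beta <- par[-1]
    eta <- b0 + X %*% beta
    mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
  }
  par <- rep(0, ncol(X) + 1)
  best <- Inf
  for (round in 1:3) {
    fit <- stats::optim(par, smooth_obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
    polish <- stats::optim(fit$par, smooth_obj, method = "Nelder-Mead",
                           control = list(maxit = 5000, reltol = 1e-15))
    par <- polish$par
    val <- true_obj(par)
    if (val > best - 1e-12) { best <- min(best, val); break }
    best <- val
  }
  best
}

# brute-force TMM oracle: doubly trimmed, precision-weighted mean of
# M-values against the upper-quartile-selected reference library
oracle_tmm <- function(counts, logratio_trim = 0.30, abs_expr_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    obs <- counts[, s]; rf <- counts[, ref]
    nO <- lib[s]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    keep <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[keep]; absE <- absE[keep]; v <- v[keep]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_expr_trim) + 1; hiS <- n + 1 - loS
    rL <- rank(logR); rS <- rank(absE)
    sel <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
    f <- 2^(sum(logR[sel] / v[sel]) / sum(1 / v[sel]))
    if (!is.finite(f)) f <- 1
    f
  }, numeric(1))
  f / exp(mean(log(f)))
}

# brute-force step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    o <- order(p)
    rankpos <- which(o == i)
    min(1, min(p[o][rankpos:m] * m / (rankpos:m)))
  }, numeric(1))
}

# brute-force AUC by pair enumeration (ties count 1/2)
oracle_auc <- function(scores, truth_is_pos) {
  pos <- scores[truth_is_pos]; neg <- scores[!truth_is_pos]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force ARI from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2)); sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (sij - e) / ((sa + sb) / 2 - e)
}
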