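make_group_counts <- function(seed = 21, G = 300, n_per_group = 6,
                              lib = 1e6, sdlog = 0) {
  set.seed(seed)
  mu <- exp(runif(G, 1, 8))
  m <- matrix(rnbinom(G * 2 * n_per_group, mu = mu, size = 10),
              G, 2 * n_per_group,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(2 * n_per_group))))
  list(counts = m, hr = rep(c("HRD", "HRP"), each = n_per_group))
}

test_that("voom weights are positive, finite, and flat when variance is constant", {
  d <- make_group_counts()
  v <- voom_transform(d$counts, d$hr)
  expect_true(all(is.finite(v$weights)))
  expect_true(all(v$weights > 0))

  # counts built so that log-expression has the same residual SD at every
  # abundance: the fitted trend is flat and weights near-constant
  set.seed(4)
  G <- 500; n <- 16
  mu_log <- runif(G, 6, 13)
  vals <- matrix(2^(mu_log + rnorm(G * n, sd = 0.25)), G, n)
  counts <- matrix(as.integer(round(vals)), G, n,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  hr <- rep(c("HRD", "HRP"), each = n / 2)
  vflat <- voom_transform(counts, hr)
  spread <- (max(vflat$weights) - min(vflat$weights)) / mean(vflat$weights)
  expect_lt(spread, 0.35)

  # Poisson counts: sqrt-SD of log-CPM falls with abundance, so weights rise
  set.seed(6)
  mu_p <- exp(runif(G, 1, 6))
  pois <- matrix(rpois(G * n, mu_p), G, n,
                 dimnames = dimnames(counts))
  pois <- pois[rowSums(pois) > 0, ]
  vp <- voom_transform(pois, hr)
  mean_w <- rowMeans(vp$weights)
  abundance <- rowMeans(vp$logcpm)
  expect_gt(cor(abundance, mean_w, method = "spearman"), 0.8)
})

test_that("gene-wise fits recover group-mean differences and match weighted normal equations", {
  # unit weights: logFC is the difference of group means
  hr <- rep(c("HRD", "HRP"), each = 3)
  logcpm <- rbind(g1 = c(5, 5, 5, 3, 3, 3),
                  g2 = c(1, 2, 3, 1, 2, 3))
  fit <- list(logcpm = logcpm, weights = matrix(1, 2, 6),
              design = cbind(`(Intercept)` = 1, HRD = as.numeric(hr == "HRD")))
  res <- fit_gene_linear_models(fit)
  expect_equal(res$logFC, c(2, 0), tolerance = 1e-12)
  expect_equal(res$df_residual, c(4, 4))

  # weights are scale-invariant
  fit10 <- fit
  fit10$weights <- fit$weights * 10
  expect_equal(fit_gene_linear_models(fit10)$logFC, res$logFC,
               tolerance = 1e-12)

  # weighted toy problem vs brute-force solve of the normal equations
  set.seed(31)
  W <- matrix(runif(12, 0.2, 3), 2, 6)
  fitw <- list(logcpm = logcpm + matrix(rnorm(12), 2), weights = W,
               design = fit$design)
  resw <- fit_gene_linear_models(fitw)
  for (g in 1:2) {
    Wg <- diag(W[g, ])
    Xd <- fitw$design
    beta <- solve(t(Xd) %*% Wg %*% Xd, t(Xd) %*% Wg %*% fitw$logcpm[g, ])
    expect_equal(resw$logFC[g], beta[2], tolerance = 1e-10)
  }
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and under equal variances", {
  d <- make_group_counts(seed = 77)
  v <- voom_transform(d$counts, d$hr)
  fits <- fit_gene_linear_models(v)
  ordinary_t <- fits$logFC / (fits$sigma * fits$stdev_unscaled)

  mod0 <- moderate_statistics(fits, d0 = 0, s0_sq = 1)
  expect_equal(mod0$t_mod, ordinary_t, tolerance = 1e-12)

  # equal variances: the prior collapses onto the common value
  fits_eq <- fits
  fits_eq$sigma <- rep(0.8, nrow(fits))
  mod_eq <- moderate_statistics(fits_eq, robust = FALSE)
  t_eq <- fits_eq$logFC / (0.8 * fits_eq$stdev_unscaled)
  expect_equal(mod_eq$t_mod, t_eq, tolerance = 1e-6)
})

test_that("the variance prior is recovered from scaled inverse-chi-square simulations", {
  set.seed(123)
  G <- 5000; dg <- 10; d0_true <- 4; s0_sq_true <- 0.05
  sigma2 <- d0_true * s0_sq_true / rchisq(G, d0_true)
  s2 <- sigma2 * rchisq(G, dg) / dg
  fits <- data.frame(gene_id = paste0("g", 1:G), logFC = rnorm(G),
                     sigma = sqrt(s2), df_residual = dg,
                     stdev_unscaled = 1)
  mod <- moderate_statistics(fits, robust = FALSE)
  expect_lt(abs(attr(mod, "d0") - d0_true) / d0_true, 0.2)
  expect_lt(abs(attr(mod, "s0_sq") - s0_sq_true) / s0_sq_true, 0.2)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(10)
  p <- runif(100)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  # re-adjusting preserves order and never decreases any value
  q <- bh_adjust(p)
  expect_true(all(diff(bh_adjust(q)[order(q)]) >= -1e-12))
  expect_true(all(bh_adjust(q) >= q))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature selection is strict at the FDR boundary", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    p_adj = c(0.049, 0.05, 0.2),
                    direction = c("up", "down", "up"))
  sel <- select_de_genes(res)
  expect_equal(sel$gene_id, "a")
  expect_error(select_de_genes(data.frame(gene_id = "a", p_adj = 0.9,
                                          direction = "up")),
               "empty signature")
})

test_that("arm enrichment reproduces the Yates chi-square closed form", {
  selected <- data.frame(
    gene_id = paste0("g", 1:40),
    direction = c(rep("up", 10), rep("down", 10), rep("down", 10), rep("up", 10)))
  ann <- data.frame(gene_id = paste0("g", 1:40),
                    arm = rep(c("8q", "5q"), each = 20))
  # 8q: 10 up 10 down on arm; elsewhere 10 down 10 up -> no enrichment
  res <- arm_enrichment_test(selected, ann)
  expect_lt(res$chi_sq[res$arm == "8q"], 0.01)
  expect_gt(res$p[res$arm == "8q"], 0.9)

  # [[10,0],[0,10]] table: chi = 20 * (|100 - 0| - 10)^2 / 10^4 = 16.2
  sel2 <- data.frame(gene_id = paste0("g", 1:20),
                     direction = rep(c("up", "down"), each = 10))
  ann2 <- data.frame(gene_id = paste0("g", 1:20),
                     arm = rep(c("8q", "5q"), each = 10))
  res2 <- arm_enrichment_test(sel2, ann2)
  row8 <- res2[res2$arm == "8q", ]
  expect_equal(row8$chi_sq, 16.2, tolerance = 1e-10)
  expect_equal(row8$p, pchisq(16.2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res2$p_bonf, pmin(1, res2$p * nrow(res2)))

  # totals are consistent with the signature
  expect_equal(res2$up_on_arm + res2$up_elsewhere,
               rep(sum(sel2$direction == "up"), nrow(res2)))
})

test_that("Pearson correlation matches its closed form and flags degenerate input", {
  x <- rnorm(20)
  expect_equal(pearson_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -2 * x + 7)$r, -1, tolerance = 1e-12)
  set.seed(33)
  y <- rnorm(20)
  pc <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_direct, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("swapping HRD and HRP labels negates effects and preserves p-values", {
  d <- make_group_counts(seed = 55, G = 200)
  de1 <- run_differential_expression(d$counts, d$hr, robust = FALSE)
  swapped <- ifelse(d$hr == "HRD", "HRP", "HRD")
  de2 <- run_differential_expression(d$counts, swapped, robust = FALSE)
  expect_equal(de1$logFC, -de2$logFC, tolerance = 1e-8)
  expect_equal(de1$t_mod, -de2$t_mod, tolerance = 1e-8)
  expect_equal(de1$p, de2$p, tolerance = 1e-8)
})
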