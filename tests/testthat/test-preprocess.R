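test_that("annotation filtering removes non-coding, chrY and chrM genes only", {
  m <- matrix(5L, 4, 2, dimnames = list(c("Gcoding", "GchrY", "Gnc", "Gauto"),
                                        c("S1", "S2")))
  ann <- data.frame(gene_id = rownames(m),
                    chromosome = c("1", "Y", "8", "2"),
                    biotype = c("protein_coding", "protein_coding",
                                "lincRNA", "protein_coding"))
  out <- remove_excluded_genes(m, ann)
  expect_setequal(rownames(out), c("Gcoding", "Gauto"))
  expect_equal(attr(out, "removed")[["chrM_chrY"]], 1)
  expect_equal(attr(out, "removed")[["non_coding"]], 1)

  clean <- m[c("Gcoding", "Gauto"), ]
  expect_equal(remove_excluded_genes(clean, ann), clean,
               ignore_attr = "removed")
})

test_that("expression filter applies the CPM rule against the minimum group size", {
  lib <- rep(1e6, 4)
  m <- rbind(gA = c(12L, 11L, 0L, 0L),
             gB = c(9L, 9L, 9L, 9L),
             gC = c(0L, 0L, 0L, 0L),
             gD = c(100L, 100L, 100L, 100L))
  colnames(m) <- paste0("S", 1:4)
  # pad library to exactly 1e6 with a filler gene so CPM == count
  filler <- matrix(as.integer(lib - colSums(m)), 1,
                   dimnames = list("filler", colnames(m)))
  m2 <- rbind(m, filler)
  kept <- filter_low_expression(m2, group_sizes = c(2, 2))
  # need >= ceil(0.7 * 2) = 2 samples at CPM >= 10
  expect_true("gA" %in% kept)     # CPM {12, 11, 0, 0}: 2 samples pass
  expect_false("gB" %in% kept)    # CPM 9 everywhere
  expect_false("gC" %in% kept)    # all zero
  expect_true("gD" %in% kept)

  # retained set shrinks (weakly) as the threshold rises
  sets <- lapply(c(5, 10, 50, 101), function(thr)
    tryCatch(filter_low_expression(m2, c(2, 2), cpm_threshold = thr),
             error = function(e) character()))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("TMM factors are depth-invariant, symmetric and match the brute-force oracle", {
  set.seed(3)
  base <- matrix(rnbinom(100, mu = 50, size = 5) + 1L, 50, 2,
                 dimnames = list(paste0("g", 1:50), c("A", "B")))
  same <- cbind(A = base[, 1], B = base[, 1])
  expect_equal(unname(tmm_norm_factors(same)), c(1, 1), tolerance = 1e-12)

  doubled <- cbind(A = base[, 1], B = 2L * base[, 1])
  expect_equal(unname(tmm_norm_factors(doubled)), c(1, 1), tolerance = 1e-12)

  set.seed(17)
  m <- matrix(rnbinom(150, mu = exp(runif(150, 2, 7)), size = 3) + 1L, 50, 3,
              dimnames = list(paste0("g", 1:50), c("A", "B", "C")))
  expect_equal(unname(tmm_norm_factors(m)), unname(oracle_tmm(m)),
               tolerance = 1e-8)
  expect_equal(prod(tmm_norm_factors(m)), 1, tolerance = 1e-12)
})

test_that("log2-CPM follows the stated closed form and its invariances", {
  m <- matrix(c(0L, 10L), 1, 2, dimnames = list("g1", c("S1", "S2")))
  v <- log2_cpm(m, lib_sizes = c(999999, 999999), prior_count = 0.5)
  expect_equal(v["g1", "S1"], -1)  # log2(0.5 / 1e6 * 1e6)

  set.seed(5)
  m4 <- matrix(rpois(8, 40) + 1L, 4, 2,
               dimnames = list(paste0("g", 1:4), c("a", "b")))
  lib <- colSums(m4); nf <- c(1.2, 0.9)
  direct <- t(log2(t(m4 + 0.5) / (lib * nf + 1) * 1e6))
  expect_equal(log2_cpm(m4, lib, nf), direct, tolerance = 1e-12)

  # prior 0: doubling counts and library together changes nothing
  v1 <- log2_cpm(m4, lib, prior_count = 0)
  v2 <- log2_cpm(2L * m4, 2 * lib, prior_count = 0)
  expect_equal(v1, v2, tolerance = 1e-12)

  # strictly monotone in the count at fixed library
  inc <- log2_cpm(matrix(0:5, 6, 1, dimnames = list(paste0("g", 0:5), "S")),
                  lib_sizes = 1e6)
  expect_true(all(diff(inc[, 1]) > 0))
})

test_that("standardization uses stored statistics and self-standardizes to mean 0, SD 1", {
  m <- matrix(c(4, 6), 1, 2, dimnames = list("g1", c("S1", "S2")))
  st <- fit_standardizer(m)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)
  z <- apply_standardizer(matrix(6, 1, 1, dimnames = list("g1", "S")), st)
  expect_equal(z[1, 1], 1 / sqrt(2), tolerance = 1e-6)

  set.seed(8)
  big <- matrix(rnorm(200, 8), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  stats_df <- fit_standardizer(big)
  zz <- apply_standardizer(big, stats_df)
  expect_lt(max(abs(rowMeans(zz))), 1e-10)
  expect_lt(max(abs(apply(zz, 1, sd) - 1)), 1e-10)

  # row order of the new data does not matter
  perm <- sample(nrow(big))
  expect_equal(apply_standardizer(big[perm, ], stats_df), zz[perm, ])

  expect_error(fit_standardizer(matrix(3, 2, 3,
    dimnames = list(c("a", "b"), c("x", "y", "z")))), "zero-variance")
  expect_error(apply_standardizer(
    matrix(0, 1, 1, dimnames = list("unknown", "S")), stats_df),
    "missing standardization")
})

test_that("signature subsetting zero-fills missing genes and guards gross mismatch", {
  set.seed(2)
  required <- paste0("G", 1:209)
  present <- required[-(1:8)]
  m <- matrix(rpois(length(present) * 3, 30), length(present), 3,
              dimnames = list(present, paste0("S", 1:3)))
  expect_warning(sub <- subset_with_zero_fill(m, required), "8 of 209")
  expect_identical(rownames(sub), required)
  expect_identical(attr(sub, "missing_genes"), required[1:8])
  expect_true(all(sub[1:8, ] == 0))
  expect_equal(sub[present, ], m[present, ])

  # all present: exact reordered submatrix, empty report
  sub2 <- subset_with_zero_fill(m, rev(present))
  expect_identical(rownames(sub2), rev(present))
  expect_length(attr(sub2, "missing_genes"), 0)

  expect_error(subset_with_zero_fill(m[1:80, ], required),
               "missing")
})

test_that("pseudobulk aggregation conserves counts and composes across groupings", {
  set.seed(9)
  cells <- matrix(rpois(60, 5), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  site <- rep(c("s1", "s2", "s3", "s4", "s5"), each = 2)
  patient <- rep(c("p1", "p2"), c(4, 6))  # sites nest in patients

  one_per_group <- pseudobulk_counts(cells, paste0("grp", 1:10))
  expect_equal(unname(one_per_group[, order(as.integer(sub("grp", "", colnames(one_per_group))))]),
               unname(cells))

  by_site <- pseudobulk_counts(cells, site)
  expect_equal(sum(by_site), sum(cells))

  by_patient <- pseudobulk_counts(cells, patient)
  site_to_patient <- pseudobulk_counts(by_site, rep(c("p1", "p2"), c(2, 3)))
  expect_equal(by_patient, site_to_patient)

  named <- stats::setNames(site, colnames(cells))
  expect_equal(pseudobulk_counts(cells, named), by_site)
  expect_error(pseudobulk_counts(cells, named[-1]), "unmapped")
})
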