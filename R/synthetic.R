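#' Configuration for the synthetic HGSC cohort generator
#'
#' The generator emulates a two-class bulk RNA-seq cohort of high-grade
#' serous ovarian carcinoma: roughly half the samples are HR-deficient, a
#' continuous latent HRD scar score is thresholded at 42 to give the binary
#' label, and three cytoband-sized regions carry coordinated expression
#' shifts (8q24.2 up in HRD; 5q13.2 and 19q12 down in HRD), attenuated by
#' tumour purity and coupled to the latent score. Library sizes are on the
#' order of tens of millions of reads and counts are negative-binomial with
#' gene-wise log-normal dispersion.
#'
#' @param n_samples Number of samples (default 300).
#' @param n_genes Number of genes (default 3000).
#' @param prevalence HRD fraction (default 0.5).
#' @param score_hrp_mean,score_hrp_sd HRP latent-score normal, truncated to
#'   \[0, cutoff).
#' @param score_hrd_mean,score_hrd_sd HRD latent-score normal, truncated to
#'   \[cutoff, Inf).
#' @param score_cutoff HRD-score label cutoff (default 42).
#' @param region_sizes Genes per effect region, named by cytoband; signs of
#'   `region_signs` give each region's direction in HRD.
#' @param region_signs +1 (up in HRD) or -1 per region.
#' @param effect_range Range of per-gene |log2 fold-change| at full purity
#'   in a pure-label model (default 0.5-1.5).
#' @param coupling Fraction in \[0, 1\] replacing the binary label with the
#'   scaled latent score in the per-sample effect modulation (default 0.7).
#' @param purity_range Tumour purity uniform range (default 0.30-1.00).
#' @param libsize_meanlog,libsize_sdlog Log-normal library size (median
#'   ~6e7 reads).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal NB dispersion.
#' @param baseline_sdlog Spread of log-normal baseline gene abundance.
#' @param seed Mandatory RNG seed.
#' @return List of class `"hr_sim_config"`.
#' @export
simulation_config <- function(n_samples = 300, n_genes = 3000,
                              prevalence = 0.5,
                              score_hrp_mean = 20, score_hrp_sd = 10,
                              score_hrd_mean = 62, score_hrd_sd = 12,
                              score_cutoff = 42,
                              region_sizes = c("8q24.2" = 50, "5q13.2" = 50,
                                               "19q12" = 50),
                              region_signs = c("8q24.2" = 1, "5q13.2" = -1,
                                               "19q12" = -1),
                              effect_range = c(0.5, 1.5),
                              coupling = 0.7,
                              purity_range = c(0.30, 1.00),
                              libsize_meanlog = log(6e7), libsize_sdlog = 0.35,
                              dispersion_meanlog = log(0.08),
                              dispersion_sdlog = 0.5,
                              baseline_sdlog = 1.5,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_samples >= 2, n_genes > sum(region_sizes),
            prevalence > 0, prevalence < 1,
            identical(names(region_sizes), names(region_signs)),
            coupling >= 0, coupling <= 1,
            all(effect_range > 0), diff(effect_range) >= 0,
            purity_range[1] > 0, purity_range[2] <= 1,
            libsize_sdlog > 0, dispersion_sdlog > 0)
  structure(as.list(environment()), class = "hr_sim_config")
}

#' Binary HR label from a continuous HRD score
#'
#' @param score Numeric HRD score(s).
#' @param cutoff Deficiency cutoff (default 42; `score >= cutoff` is HRD).
#' @return `"HRD"`/`"HRP"` per score.
#' @export
label_from_hrd_score <- function(score, cutoff = 42) {
  stopifnot(all(is.finite(score)))
  ifelse(score >= cutoff, "HRD", "HRP")
}

#' Promoter-methylation summary
#'
#' Mean beta value over the promoter's probes, flagged as silenced when the
#' mean exceeds the threshold (strictly).
#'
#' @param betas Probe beta values in \[0, 1\].
#' @param threshold Silencing flag threshold (default 0.15).
#' @return List with `mean_beta` and `silenced`.
#' @export
summarize_promoter_methylation <- function(betas, threshold = 0.15) {
  if (length(betas) == 0) stop("no probes")
  stopifnot(all(betas >= 0 & betas <= 1))
  m <- mean(betas)
  list(mean_beta = m, silenced = m > threshold)
}

# inverse-CDF sampling from a truncated normal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a bulk HGSC expression cohort with known HR ground truth
#'
#' Per sample: an HR label is drawn at the configured prevalence, a latent
#' HRD score from the label's truncated normal (so label and the 42 cutoff
#' are always consistent), a tumour purity and a library size. Per gene: a
#' baseline relative abundance and an NB dispersion; genes in effect
#' regions carry a signed log2 fold-change. The expected abundance of a
#' region gene in sample `i` is shifted by
#' `2^(purity_i * m_i * effect_g)` where the modulation
#' `m_i = (1 - coupling) * label_i + coupling * score_i / 84` blends the
#' binary label with the scaled latent score; abundances are renormalized
#' to proportions and counts drawn negative-binomially at the sample's
#' library size. Non-region genes are null.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (genes x samples), `samples` (per-sample
#'   truth: `sample_id`, `hrd_score`, `hr_status`, `purity`, `lib_size`),
#'   `genes` (per-gene truth: `gene_id`, `baseline`, `dispersion`,
#'   `region`, `effect`), `annotation` (gene_id, chromosome, arm, band,
#'   biotype).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "hr_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  G <- config$n_genes

  ## per-sample truth
  label <- stats::rbinom(n, 1, config$prevalence)  # 1 = HRD
  score <- numeric(n)
  score[label == 1] <- rtruncnorm(sum(label == 1), config$score_hrd_mean,
                                  config$score_hrd_sd,
                                  lower = config$score_cutoff)
  score[label == 0] <- rtruncnorm(sum(label == 0), config$score_hrp_mean,
                                  config$score_hrp_sd, lower = 0,
                                  upper = config$score_cutoff - 1e-9)
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  lib <- stats::rlnorm(n, config$libsize_meanlog, config$libsize_sdlog)
  sample_id <- sprintf("S%03d", seq_len(n))

  ## per-gene truth
  gene_id <- sprintf("SYNG%08d", seq_len(G))
  baseline <- stats::rlnorm(G, meanlog = 0, sdlog = config$baseline_sdlog)
  dispersion <- stats::rlnorm(G, config$dispersion_meanlog,
                              config$dispersion_sdlog)
  region <- rep(NA_character_, G)
  effect <- numeric(G)
  offset <- 0L
  for (rg in names(config$region_sizes)) {
    idx <- offset + seq_len(config$region_sizes[[rg]])
    region[idx] <- rg
    effect[idx] <- config$region_signs[[rg]] *
      stats::runif(length(idx), config$effect_range[1], config$effect_range[2])
    offset <- offset + config$region_sizes[[rg]]
  }

  ## annotation: effect regions live on their nominal arms; null genes are
  ## spread over the remaining autosomal arms
  chromosome <- arm <- band <- character(G)
  for (rg in names(config$region_sizes)) {
    in_rg <- which(!is.na(region) & region == rg)
    chromosome[in_rg] <- sub("[pq].*$", "", rg)
    arm[in_rg] <- sub("^([0-9XY]+[pq]).*$", "\\1", rg)
    band[in_rg] <- rg
  }
  null_idx <- which(is.na(region))
  other_arms <- setdiff(
    as.vector(outer(as.character(1:22), c("p", "q"), paste0)),
    sub("^([0-9XY]+[pq]).*$", "\\1", names(config$region_sizes)))
  arm_assign <- rep_len(other_arms, length(null_idx))
  chromosome[null_idx] <- sub("[pq]$", "", arm_assign)
  arm[null_idx] <- arm_assign
  band[null_idx] <- paste0(arm_assign, "11")
  annotation <- data.frame(gene_id = gene_id, chromosome = chromosome,
                           arm = arm, band = band,
                           biotype = "protein_coding",
                           stringsAsFactors = FALSE)

  ## expected proportions and NB counts
  modulation <- (1 - config$coupling) * label +
    config$coupling * score / 84
  lfc <- outer(effect, purity * modulation)        # genes x samples
  w <- baseline * 2^lfc
  props <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(props, 2, lib, "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / dispersion, n)),
                   nrow = G, dimnames = list(gene_id, sample_id))
  storage.mode(counts) <- "integer"

  list(counts = counts,
       samples = data.frame(sample_id = sample_id, hrd_score = score,
                            hr_status = ifelse(label == 1, "HRD", "HRP"),
                            purity = purity, lib_size = lib,
                            stringsAsFactors = FALSE),
       genes = data.frame(gene_id = gene_id, baseline = baseline,
                          dispersion = dispersion, region = region,
                          effect = effect, stringsAsFactors = FALSE),
       annotation = annotation)
}

#' Simulate single cells from a bulk expression profile
#'
#' Each cell's counts are a multinomial draw from the profile's gene
#' proportions at the cell's own library size (log-normal), so the
#' pseudobulk of many cells converges to the parent profile.
#'
#' @param profile Non-negative count (or proportion) vector with names.
#' @param n_cells Number of cells.
#' @param libsize_meanlog,libsize_sdlog Cell library-size log-normal
#'   (median ~10k).
#' @param seed RNG seed.
#' @return Gene-by-cell integer count matrix.
#' @export
simulate_single_cells <- function(profile, n_cells,
                                  libsize_meanlog = log(1e4),
                                  libsize_sdlog = 0.5, seed = 1L) {
  if (sum(profile) <= 0) stop("profile has zero total")
  set.seed(seed)
  p <- profile / sum(profile)
  sizes <- pmax(1, round(stats::rlnorm(n_cells, libsize_meanlog,
                                       libsize_sdlog)))
  cells <- vapply(sizes, function(s)
    as.numeric(stats::rmultinom(1, size = s, prob = p)),
    numeric(length(p)))
  dimnames(cells) <- list(names(profile),
                          sprintf("CELL%05d", seq_len(n_cells)))
  storage.mode(cells) <- "integer"
  cells
}
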