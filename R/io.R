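#' Strip a numeric version suffix from a gene identifier
#'
#' Ensembl/GENCODE annotations attach a version to stable gene identifiers
#' (e.g. `ENSG00000012048.21`). Cohorts quantified against different
#' annotation releases only match after the version is removed, so every
#' reader in this package strips versions at load time.
#'
#' @param gene_id Character vector of gene identifiers.
#' @return Character vector with the suffix after the final `"."` removed
#'   whenever that suffix is purely numeric; other identifiers are returned
#'   unchanged. Idempotent.
#' @examples
#' strip_gene_version(c("ENSG00000012048.21", "ENSG00000012048"))
#' @export
strip_gene_version <- function(gene_id) {
  stopifnot(is.character(gene_id), all(nzchar(gene_id)))
  sub("\\.[0-9]+$", "", gene_id)
}

#' Validate a gene-by-sample count matrix
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @return The matrix, invisibly, after validation.
#' @keywords internal
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyNA(counts))
    stop("counts contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "malformed count at gene '%s', sample '%s': %s (must be a non-negative integer)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])
    ))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifier after version stripping: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifier: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  invisible(counts)
}

#' Read a gene-by-sample count matrix
#'
#' Two on-disk layouts are supported: a dense delimited table (first column
#' gene identifiers, header row sample identifiers, genes as rows unless
#' `transposed = TRUE`) and 10x-style MatrixMarket triplets, where `path` is
#' the `.mtx` file and `features.tsv` / `barcodes.tsv` sidecars sit next to
#' it (or are given explicitly).
#'
#' Gene identifiers are version-stripped on load; counts are validated to be
#' non-negative integers with unique gene and sample identifiers.
#'
#' @param path Path to the count table or `.mtx` file.
#' @param format `"dense"` or `"mtx"`. Guessed from the file extension when
#'   missing.
#' @param sep Field separator for dense tables (default tab; `","` for CSV).
#' @param transposed Set `TRUE` when a dense table stores samples as rows.
#' @param features,barcodes Optional explicit sidecar paths for MTX input.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path, format = c("auto", "dense", "mtx"), sep = "\t",
                        transposed = FALSE, features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    dirn <- dirname(path)
    if (is.null(features)) features <- file.path(dirn, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(features)) stop("features sidecar not found: ", features)
    if (!file.exists(barcodes)) stop("barcodes sidecar not found: ", barcodes)
    m <- as.matrix(Matrix::readMM(path))
    feat <- utils::read.table(features, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    bc <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(feat) != nrow(m)) stop("features sidecar length does not match matrix rows")
    if (nrow(bc) != ncol(m)) stop("barcodes sidecar length does not match matrix columns")
    rownames(m) <- strip_gene_version(as.character(feat[[1]]))
    colnames(m) <- as.character(bc[[1]])
  } else {
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (transposed) m <- t(m)
    rownames(m) <- strip_gene_version(rownames(m))
  }
  storage.mode(m) <- "double"
  validate_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a dense count table
#'
#' Inverse of [read_counts()] for the dense layout: first column `gene_id`,
#' header row of sample identifiers.
#'
#' @param counts Gene-by-sample integer matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_counts <- function(counts, path, sep = "\t") {
  validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' Expects a delimited table with a `sample_id` column and at least one of
#' `hr_status` (values `"HRD"`/`"HRP"`) or `hrd_score` (non-negative real).
#' When `hr_status` is absent it is derived from the HRD score with the
#' clinical cutoff (score >= 42 is HRD).
#'
#' @param path Path to the table.
#' @param sep Field separator.
#' @param cutoff HRD-score cutoff used to derive missing statuses.
#' @return data.frame with columns `sample_id`, `hr_status` and, when
#'   present, `hrd_score`.
#' @export
read_labels <- function(path, sep = "\t", cutoff = 42) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("label table needs a 'sample_id' column")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in label table")
  if (!"hr_status" %in% names(tab)) {
    if (!"hrd_score" %in% names(tab))
      stop("label table needs 'hr_status' or 'hrd_score'")
    tab$hr_status <- label_from_hrd_score(tab$hrd_score, cutoff = cutoff)
  }
  if (!all(tab$hr_status %in% c("HRD", "HRP")))
    stop("hr_status values must be 'HRD' or 'HRP'")
  tab
}

#' Read a UCSC cytoband annotation file
#'
#' Parses the `cytoBand.txt` dialect: tab-separated chrom, start, end, band
#' name, Giemsa stain, with 0-based half-open intervals. The chromosome arm
#' is taken from the leading p/q of the band name.
#'
#' @param path Path to the cytoband file (plain text).
#' @return data.frame with columns `chrom` (the `"chr"` prefix removed),
#'   `start`, `end`, `band` (e.g. `"8q24.3"`), `arm` (`"8q"`).
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "name", "stain"),
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), stain = character())
      else stop(e)
    })
  if (nrow(tab) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      band = character(), arm = character()))
  chrom <- sub("^chr", "", tab$chrom)
  armletter <- substr(tab$name, 1, 1)
  if (!all(armletter %in% c("p", "q")))
    stop("malformed band name (must start with p or q): ",
         tab$name[which(!armletter %in% c("p", "q"))[1]])
  out <- data.frame(chrom = chrom, start = tab$start, end = tab$end,
                    band = paste0(chrom, tab$name),
                    arm = paste0(chrom, armletter),
                    stringsAsFactors = FALSE)
  # half-open intervals must tile each chromosome without overlap
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (any(sub$end[-nrow(sub)] > sub$start[-1]))
      stop("overlapping cytobands on chromosome ", ch)
  }
  out
}

#' Assign genes to cytobands by position
#'
#' Each gene is placed at a single reference position (its transcription
#' start site if supplied, otherwise its interval midpoint) and assigned to
#' the band whose half-open interval `[start, end)` contains that position.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `tss`; optionally `biotype`.
#' @param cytobands Band table from [read_cytobands()].
#' @return data.frame with columns `gene_id`, `chrom` (as `chromosome`),
#'   `arm`, `band` and, when present in `genes`, `biotype`. Genes whose
#'   position falls outside every band get `NA` arm/band.
#' @export
annotate_genes_cytobands <- function(genes, cytobands) {
  if (nrow(cytobands) == 0) stop("no cytoband annotation available")
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  pos <- if ("tss" %in% names(genes)) genes$tss
         else floor((genes$start + genes$end) / 2)
  arm <- band <- rep(NA_character_, nrow(genes))
  chrom <- sub("^chr", "", as.character(genes$chrom))
  for (ch in unique(chrom)) {
    gi <- which(chrom == ch)
    bi <- which(cytobands$chrom == ch)
    if (length(bi) == 0) next
    bands <- cytobands[bi, ][order(cytobands$start[bi]), ]
    idx <- findInterval(pos[gi], bands$start)
    inside <- idx >= 1 & pos[gi] < bands$end[pmax(idx, 1)]
    arm[gi[inside]] <- bands$arm[idx[inside]]
    band[gi[inside]] <- bands$band[idx[inside]]
  }
  out <- data.frame(gene_id = genes$gene_id, chromosome = chrom,
                    arm = arm, band = band, stringsAsFactors = FALSE)
  if ("biotype" %in% names(genes)) out$biotype <- genes$biotype
  out
}
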