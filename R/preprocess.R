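#' Load an omics matrix from a TSV file
#'
#' Accepts the two tab-separated dialects in common use for gene-level
#' omics tables: `genes_as_rows` (Xena style; first column the gene ID,
#' remaining columns one sample each) and `samples_as_rows` (first column
#' the sample ID, remaining columns one gene each). Either dialect is
#' converted to the canonical samples-by-genes orientation on load.
#'
#' Blank cells are read as `NA` and tolerated here so that
#' [audit_missing()] can report them; any other non-numeric cell is a
#' parse error naming its row and column.
#'
#' @param path TSV file with a header row and an ID column.
#' @param dialect `"genes_as_rows"` or `"samples_as_rows"`.
#' @param modality Modality tag for the result (`"RNA"` or `"CNV"`).
#' @return An [omics_matrix()].
#' @export
load_matrix <- function(path, dialect = c("genes_as_rows", "samples_as_rows"),
                        modality = c("RNA", "CNV")) {
  dialect <- match.arg(dialect)
  modality <- match.arg(modality)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 1) stop("file has no columns: ", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 row_ids[bad[1, 1]], col_ids[bad[1, 2]], path))
  }
  if (dialect == "genes_as_rows") {
    vals <- t(num)
    sample_ids <- col_ids
    gene_ids <- row_ids
  } else {
    vals <- num
    sample_ids <- row_ids
    gene_ids <- col_ids
  }
  # degenerate empty matrix (header-only file or no data columns)
  if (length(sample_ids) == 0 || length(gene_ids) == 0) {
    vals <- matrix(numeric(0), length(sample_ids), length(gene_ids))
  }
  omics_matrix(vals, modality, sample_ids = sample_ids, gene_ids = gene_ids)
}

#' Load a sample label table
#'
#' @param path Two-column TSV with header `sample_id`, `label` and binary
#'   0/1 labels.
#' @return Named integer vector of labels.
#' @export
load_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    stop("label table must have columns 'sample_id' and 'label'")
  }
  labels <- as.integer(df$label)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  names(labels) <- df$sample_id
  labels
}

#' Parse a TCGA-style hyphenated sample barcode
#'
#' Sample identifiers are hierarchical hyphen-delimited barcodes of the
#' form `PROJECT-TSS-PARTICIPANT-SAMPLE` (e.g. `TCGA-05-4244-01`). The
#' first three fields map positionally; any additional trailing fields are
#' kept as part of the sample field so that re-joining with `-`
#' reproduces the original identifier.
#'
#' @param id Barcode string with at least four hyphen-separated fields.
#' @return A list of class `sample_barcode` with elements `project`,
#'   `tss`, `participant`, `sample`.
#' @export
parse_barcode <- function(id) {
  stopifnot(is.character(id), length(id) == 1)
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(parts) < 4) {
    stop(sprintf("barcode '%s' has %d field(s); at least 4 required",
                 id, length(parts)))
  }
  structure(
    list(project = parts[1], tss = parts[2], participant = parts[3],
         sample = paste(parts[-(1:3)], collapse = "-")),
    class = "sample_barcode"
  )
}

#' @export
format.sample_barcode <- function(x, ...) {
  paste(x$project, x$tss, x$participant, x$sample, sep = "-")
}

#' @export
print.sample_barcode <- function(x, ...) {
  cat("<sample_barcode>", format(x), "\n")
  invisible(x)
}

#' Samples present in both modalities
#'
#' Exact full-barcode intersection of the two sample-ID sets, ordered by
#' first appearance in `a`. Decision-level fusion needs per-sample
#' probability pairs from both modalities, so an empty intersection is a
#' hard error.
#'
#' @param a,b [omics_matrix()] objects.
#' @return Character vector of common sample IDs.
#' @export
find_common_samples <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  common <- a$sample_ids[a$sample_ids %in% b$sample_ids]
  if (!length(common)) {
    stop("no common samples between the two modalities; fusion impossible")
  }
  common
}

#' Sample-wise z-score normalization
#'
#' Centers and scales every sample (row) to mean 0 and standard deviation
#' 1, using the population (divide-by-n) convention. Constant rows carry
#' no information and are mapped to all zeros rather than raising.
#'
#' @param m An [omics_matrix()] with finite values.
#' @return The normalized [omics_matrix()].
#' @export
zscore_by_sample <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  if (!all(is.finite(v))) stop("matrix contains non-finite values; run audit_missing() first")
  mu <- rowMeans(v)
  centered <- v - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  scale <- ifelse(sd_pop > 0, 1 / sd_pop, 0)
  omics_matrix(centered * scale, m$modality,
               sample_ids = m$sample_ids, gene_ids = m$gene_ids)
}

#' Audit a matrix for missing values
#'
#' Counts missing (NA / non-finite) cells and reports the first few
#' locations by sample and gene ID. Downstream steps refuse matrices with
#' a nonzero missing count.
#'
#' @param m An [omics_matrix()].
#' @param max_locations Number of cell addresses to include in the report.
#' @return A list of class `missing_audit` with elements `n_missing`,
#'   `locations` (data frame of `sample_id`, `gene_id`) and `clean`.
#' @export
audit_missing <- function(m, max_locations = 10L) {
  stopifnot(inherits(m, "omics_matrix"))
  miss <- which(!is.finite(m$values), arr.ind = TRUE)
  n_missing <- nrow(miss)
  head_idx <- seq_len(min(n_missing, max_locations))
  locations <- data.frame(
    sample_id = m$sample_ids[miss[head_idx, 1]],
    gene_id = m$gene_ids[miss[head_idx, 2]],
    stringsAsFactors = FALSE
  )
  structure(list(n_missing = n_missing, locations = locations,
                 clean = n_missing == 0L),
            class = "missing_audit")
}

#' @export
print.missing_audit <- function(x, ...) {
  cat(sprintf("<missing_audit> %d missing cell(s)\n", x$n_missing))
  if (x$n_missing > 0) print(x$locations)
  invisible(x)
}

#' Harmonize two modalities into a labeled cohort
#'
#' Restricts both matrices to their common samples (exact barcode
#' identity) in identical order, attaches the binary labels, and
#' optionally applies sample-wise z-score normalization to each modality.
#' Normalization runs after the common-sample restriction so it sees
#' exactly the analyzed samples.
#'
#' @param rna,cnv [omics_matrix()] objects for the two modalities.
#' @param labels Named 0/1 vector (or two-column data frame with
#'   `sample_id`, `label`) covering every common sample.
#' @param normalize Apply [zscore_by_sample()] to each modality.
#' @return A list of class `labeled_cohort` with elements `rna`, `cnv`,
#'   `labels` (named, over common samples) and `common_sample_ids`.
#' @export
build_cohort <- function(rna, cnv, labels, normalize = TRUE) {
  stopifnot(inherits(rna, "omics_matrix"), inherits(cnv, "omics_matrix"))
  if (is.data.frame(labels)) {
    lab <- as.integer(labels$label)
    names(lab) <- labels$sample_id
    labels <- lab
  }
  if (is.null(names(labels))) stop("labels must be named by sample ID")
  common <- find_common_samples(rna, cnv)
  unlabeled <- setdiff(common, names(labels))
  if (length(unlabeled)) {
    stop("common sample(s) without a label: ",
         paste(unlabeled, collapse = ", "))
  }
  labels <- as.integer(labels[common])
  names(labels) <- common
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  rna <- subset_omics(rna, samples = common)
  cnv <- subset_omics(cnv, samples = common)
  for (m in list(rna, cnv)) {
    audit <- audit_missing(m)
    if (!audit$clean) {
      stop(sprintf("%s matrix has %d missing cell(s); refusing to build cohort",
                   m$modality, audit$n_missing))
    }
  }
  if (normalize) {
    rna <- zscore_by_sample(rna)
    cnv <- zscore_by_sample(cnv)
  }
  structure(list(rna = rna, cnv = cnv, labels = labels,
                 common_sample_ids = common),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d common samples (%d/%d per class); RNA %d genes, CNV %d genes\n",
              length(x$common_sample_ids), sum(x$labels == 0L),
              sum(x$labels == 1L), length(x$rna$gene_ids),
              length(x$cnv$gene_ids)))
  invisible(x)
}
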