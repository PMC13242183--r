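#' Construct an omics matrix
#'
#' The canonical in-memory container for one modality: a numeric
#' samples-by-genes matrix with unique sample and gene identifiers and a
#' modality tag. All file dialects are converted to this orientation on
#' load.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param modality Modality tag, one of `"RNA"`, `"CNV"` or `"joint"`.
#' @param sample_ids,gene_ids Optional character vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `modality`, `sample_ids`, `gene_ids` and `values`.
#' @export
omics_matrix <- function(values, modality = c("RNA", "CNV", "joint"),
                         sample_ids = rownames(values),
                         gene_ids = colnames(values)) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x genes)")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of 'sample_ids' does not match nrow(values)")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length of 'gene_ids' does not match ncol(values)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(modality = modality, sample_ids = sample_ids,
         gene_ids = gene_ids, values = values),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> modality=%s: %d samples x %d genes\n",
              x$modality, length(x$sample_ids), length(x$gene_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by sample and/or gene identifiers
#'
#' @param m An `omics_matrix`.
#' @param samples,genes Character vectors of IDs to keep, in the requested
#'   order; `NULL` keeps everything.
#' @return An `omics_matrix` restricted (and reordered) accordingly.
#' @export
subset_omics <- function(m, samples = NULL, genes = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.null(samples)) samples <- m$sample_ids
  if (is.null(genes)) genes <- m$gene_ids
  missing_s <- setdiff(samples, m$sample_ids)
  if (length(missing_s)) {
    stop("unknown sample IDs: ", paste(missing_s, collapse = ", "))
  }
  missing_g <- setdiff(genes, m$gene_ids)
  if (length(missing_g)) {
    stop("unknown gene IDs: ", paste(missing_g, collapse = ", "))
  }
  omics_matrix(m$values[samples, genes, drop = FALSE], m$modality,
               sample_ids = samples, gene_ids = genes)
}
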