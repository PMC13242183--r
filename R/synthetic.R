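#' Configuration for the paired-multiomics simulator
#'
#' Defines the study conditions a generated cohort emulates: two omics
#' modalities (an expression-like "RNA" matrix and a gene-level copy-number
#' "CNV" matrix) over mostly overlapping samples with TCGA-barcode-like
#' identifiers, near-balanced binary subtype labels, a
#' high-dimension-low-sample-size shape, and planted class-discriminative
#' genes that are either shared across modalities or modality-specific.
#'
#' Defaults mirror the cohort shape the pipeline is designed for: 505 vs
#' 483 samples per class (the size of a paired NSCLC ADC/SCC cohort after
#' cross-modality sample matching), 1000 genes per modality with 30 shared
#' plus 10 + 10 modality-specific informative genes, and a stronger
#' expression signal (1.5 sigma) than copy-number signal (1.0 sigma) so the
#' two modalities deliberately disagree in difficulty.
#'
#' @param n_class0,n_class1 Samples per class (label 0 / label 1) before
#'   modality dropout.
#' @param n_genes_rna,n_genes_cnv Genes per modality.
#' @param n_shared_informative Planted discriminative genes carrying the
#'   same gene ID, and a class signal, in both modalities.
#' @param n_rna_only_informative,n_cnv_only_informative Planted genes
#'   discriminative in one modality only (pure noise in the other).
#' @param effect_size_rna,effect_size_cnv Standardized class-1 mean shift
#'   (sigma units) of informative genes in each modality.
#' @param block_size Number of genes per equicorrelated block.
#' @param block_rho Within-block equicorrelation, in `[0, 1)`.
#' @param dropout_fraction_rna,dropout_fraction_cnv Fraction of samples
#'   present only in the *other* modality (i.e. missing from this one).
#' @param seed Integer seed; the generated cohort is a pure function of
#'   the configuration including this seed.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_class0 = 505L, n_class1 = 483L,
                       n_genes_rna = 1000L, n_genes_cnv = 1000L,
                       n_shared_informative = 30L,
                       n_rna_only_informative = 10L,
                       n_cnv_only_informative = 10L,
                       effect_size_rna = 1.5, effect_size_cnv = 1.0,
                       block_size = 10L, block_rho = 0.3,
                       dropout_fraction_rna = 0.05,
                       dropout_fraction_cnv = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
    n_genes_rna = as.integer(n_genes_rna),
    n_genes_cnv = as.integer(n_genes_cnv),
    n_shared_informative = as.integer(n_shared_informative),
    n_rna_only_informative = as.integer(n_rna_only_informative),
    n_cnv_only_informative = as.integer(n_cnv_only_informative),
    effect_size_rna = effect_size_rna, effect_size_cnv = effect_size_cnv,
    block_size = as.integer(block_size), block_rho = block_rho,
    dropout_fraction_rna = dropout_fraction_rna,
    dropout_fraction_cnv = dropout_fraction_cnv,
    seed = as.integer(seed)
  )
  counts <- with(cfg, c(n_class0, n_class1, n_genes_rna, n_genes_cnv,
                        n_shared_informative, n_rna_only_informative,
                        n_cnv_only_informative, block_size))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (cfg$block_size < 1) stop("block_size must be >= 1")
  n_inf <- with(cfg, n_shared_informative + n_rna_only_informative +
                  n_cnv_only_informative)
  if (n_inf > min(cfg$n_genes_rna, cfg$n_genes_cnv)) {
    stop("informative gene counts exceed the per-modality gene counts")
  }
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) {
    stop("block_rho must lie in [0, 1)")
  }
  for (f in c("dropout_fraction_rna", "dropout_fraction_cnv")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) stop(f, " must lie in [0, 1)")
  }
  if (cfg$dropout_fraction_rna + cfg$dropout_fraction_cnv >= 1) {
    stop("dropout fractions must sum to less than 1")
  }
  structure(cfg, class = "sim_config")
}

barcode_ids <- function(n) {
  sprintf("SYN-AA-%04d-01", seq_len(n))
}

# One modality's samples x genes draw: standard-normal background with
# equicorrelated blocks (shared Gaussian factor per block) and a
# class-1 mean shift on the informative columns. Blocks are formed within
# each gene segment so they never straddle an informative/noise boundary.
simulate_modality <- function(n_samples, labels, gene_ids, segments,
                              informative, effect_size, block_size,
                              block_rho) {
  m <- length(gene_ids)
  x <- matrix(0, n_samples, m)
  for (seg in segments) {
    if (!length(seg)) next
    blocks <- split(seg, ceiling(seq_along(seg) / block_size))
    for (b in blocks) {
      z <- rnorm(n_samples)
      eps <- matrix(rnorm(n_samples * length(b)), n_samples, length(b))
      x[, b] <- sqrt(block_rho) * z + sqrt(1 - block_rho) * eps
    }
  }
  if (length(informative)) {
    x[labels == 1L, informative] <- x[labels == 1L, informative] + effect_size
  }
  dimnames(x) <- list(NULL, gene_ids)
  x
}

#' Generate a paired two-modality labeled cohort with planted signal
#'
#' Draws the two modality matrices described by a [sim_config()]:
#' per-gene standard-normal background, equicorrelated gene blocks, a
#' class-conditional mean shift on the planted informative genes, and
#' per-modality sample dropout (disjoint between modalities, so dropped
#' samples are present in exactly one matrix). Gene IDs live in a shared
#' namespace: shared informative genes carry the same ID in both
#' modalities, so the downstream cross-omics intersection is meaningful.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{rna, cnv}{[omics_matrix()] objects, after dropout.}
#'     \item{labels}{Named integer vector (0/1) over all generated
#'       samples, named by barcode-like sample ID.}
#'     \item{truth}{A `synthetic_ground_truth` list: `shared_informative`,
#'       `rna_only_informative`, `cnv_only_informative`, `noise_genes`
#'       (per modality), and `common_sample_ids` (samples surviving in
#'       both modalities).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_class0 + config$n_class1
    ids <- barcode_ids(n)
    labels <- c(rep(0L, config$n_class0), rep(1L, config$n_class1))
    names(labels) <- ids

    n_max <- max(config$n_genes_rna, config$n_genes_cnv)
    universe <- sprintf("G%05d", seq_len(n_max))
    s <- config$n_shared_informative
    r <- config$n_rna_only_informative
    cc <- config$n_cnv_only_informative
    shared_idx <- seq_len(s)
    rna_only_idx <- seq_len(r) + s
    cnv_only_idx <- seq_len(cc) + s + r

    seg_rna <- list(shared_idx, rna_only_idx, cnv_only_idx,
                    setdiff(seq_len(config$n_genes_rna), seq_len(s + r + cc)))
    seg_cnv <- list(shared_idx, rna_only_idx, cnv_only_idx,
                    setdiff(seq_len(config$n_genes_cnv), seq_len(s + r + cc)))

    rna_vals <- simulate_modality(
      n, labels, universe[seq_len(config$n_genes_rna)], seg_rna,
      informative = c(shared_idx, rna_only_idx),
      effect_size = config$effect_size_rna,
      block_size = config$block_size, block_rho = config$block_rho)
    cnv_vals <- simulate_modality(
      n, labels, universe[seq_len(config$n_genes_cnv)], seg_cnv,
      informative = c(shared_idx, cnv_only_idx),
      effect_size = config$effect_size_cnv,
      block_size = config$block_size, block_rho = config$block_rho)
    rownames(rna_vals) <- ids
    rownames(cnv_vals) <- ids

    # dropout: disjoint sample sets, each removed from exactly one modality
    n_drop_rna <- round(config$dropout_fraction_rna * n)
    n_drop_cnv <- round(config$dropout_fraction_cnv * n)
    shuffled <- sample(ids)
    drop_rna <- shuffled[seq_len(n_drop_rna)]
    drop_cnv <- shuffled[seq_len(n_drop_cnv) + n_drop_rna]
    keep_rna <- setdiff(ids, drop_rna)
    keep_cnv <- setdiff(ids, drop_cnv)

    rna <- omics_matrix(rna_vals[keep_rna, , drop = FALSE], "RNA")
    cnv <- omics_matrix(cnv_vals[keep_cnv, , drop = FALSE], "CNV")

    gid <- function(i) universe[i]
    truth <- structure(list(
      shared_informative = gid(shared_idx),
      rna_only_informative = gid(rna_only_idx),
      cnv_only_informative = gid(cnv_only_idx),
      noise_genes = list(
        rna = setdiff(rna$gene_ids, gid(c(shared_idx, rna_only_idx))),
        cnv = setdiff(cnv$gene_ids, gid(c(shared_idx, cnv_only_idx)))
      ),
      common_sample_ids = intersect(keep_rna, keep_cnv)
    ), class = "synthetic_ground_truth")

    list(rna = rna, cnv = cnv, labels = labels, truth = truth)
  })
}

#' Write a generated cohort to disk as plain-text tables
#'
#' Emits one genes-as-rows TSV per modality (first column `gene_id`,
#' remaining columns the sample IDs), a two-column label table, and, when
#' ground truth is available, a JSON record of the planted gene sets. The
#' files round-trip losslessly through [load_matrix()].
#'
#' @param cohort A list as returned by [generate_cohort()] (elements
#'   `rna`, `cnv`, `labels`, optionally `truth`).
#' @param dir Output directory; created if absent.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (mod in c("rna", "cnv")) {
    m <- cohort[[mod]]
    stopifnot(inherits(m, "omics_matrix"))
    path <- file.path(dir, paste0(mod, ".tsv"))
    df <- data.frame(gene_id = m$gene_ids,
                     t(m$values), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(sample_id = names(cohort$labels),
               label = as.integer(cohort$labels)),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, lab_path)
  if (!is.null(cohort$truth)) {
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(unclass(cohort$truth), truth_path,
                         auto_unbox = FALSE, pretty = TRUE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}
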