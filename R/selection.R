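#' Per-fold, per-modality ReliefF importance lists
#'
#' Runs ReliefF on each fold's *training split only* (never the
#' validation samples — feature selection inside the cross-validation
#' loop avoids leaking validation data into the ranking), separately for
#' each modality. With `k = 5` folds this yields 10 importance lists:
#' five for the expression modality and five for copy number.
#'
#' @param cohort A [build_cohort()] result.
#' @param plan A [make_fold_plan()] over the cohort's labels.
#' @param config A [relieff_config()].
#' @return List with elements `rna` and `cnv`, each a list (one per
#'   fold) of named weight vectors.
#' @export
run_fold_selection <- function(cohort, plan, config = relieff_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(plan, "fold_plan"))
  out <- lapply(list(cohort$rna, cohort$cnv), function(m) {
    lapply(plan$folds, function(fold) {
      xt <- m$values[fold$train_ids, , drop = FALSE]
      yt <- cohort$labels[fold$train_ids]
      relieff_weights(xt, yt, config)
    })
  })
  names(out) <- c("rna", "cnv")
  out
}

#' Aggregate per-fold importance lists into one ranked list
#'
#' Cumulative importance: per-gene sum of the per-fold ReliefF weights,
#' sorted descending; ties are broken lexicographically by gene ID so
#' the ranking is stable across runs. A rank-sum mode (`mode =
#' "rank_sum"`, smaller is better) is available for sensitivity
#' analysis.
#'
#' @param lists List of named weight vectors over an identical gene
#'   universe.
#' @param mode `"score_sum"` (default, cumulative raw weights) or
#'   `"rank_sum"`.
#' @return Data frame with columns `gene_id`, `score`, ordered best
#'   first.
#' @export
rank_and_aggregate_folds <- function(lists, mode = c("score_sum", "rank_sum")) {
  mode <- match.arg(mode)
  if (!length(lists)) stop("need at least one importance list")
  genes <- names(lists[[1]])
  for (l in lists) {
    if (!identical(sort(names(l)), sort(genes))) {
      stop("importance lists cover different gene universes")
    }
  }
  if (mode == "score_sum") {
    score <- Reduce(`+`, lapply(lists, function(l) l[genes]))
    ord <- order(-score, genes)
  } else {
    # rank 1 = best (largest weight) within each fold; smaller sum is better
    score <- Reduce(`+`, lapply(lists, function(l) {
      rank(-l[genes], ties.method = "min")
    }))
    ord <- order(score, genes)
  }
  data.frame(gene_id = genes[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Top-n genes of an aggregated ranking
#'
#' @param ranked Data frame from [rank_and_aggregate_folds()].
#' @param n Number of genes to keep (default 500).
#' @return Character vector of the first `n` gene IDs.
#' @export
select_top_n <- function(ranked, n = 500L) {
  n <- as.integer(n)
  if (n < 0) stop("n must be nonnegative")
  if (n > nrow(ranked)) {
    stop(sprintf("n = %d exceeds the ranked list length %d", n, nrow(ranked)))
  }
  ranked$gene_id[seq_len(n)]
}

#' Within-omics stable gene set
#'
#' Intersection of the per-seed top-n sets for one modality: genes that
#' rank highly regardless of how the cross-validation folds were drawn.
#'
#' @param sets List of character vectors (one per seed).
#' @return Character vector; a warning is logged when the intersection
#'   is empty.
#' @export
stable_gene_set <- function(sets) {
  if (!length(sets)) stop("need at least one gene set")
  out <- Reduce(intersect, sets)
  if (!length(out)) warning("stable gene set is empty: no gene survived all seeds")
  out
}

#' Cross-omics intersection of the two stable sets
#'
#' Genes consistently top-ranked in *both* modalities: the final
#' discriminative gene set of the selection workflow.
#'
#' @param stable_rna,stable_cnv Character vectors over a shared gene-ID
#'   space.
#' @return Character vector.
#' @export
cross_omics_intersection <- function(stable_rna, stable_cnv) {
  intersect(stable_rna, stable_cnv)
}

#' Cross-omics union of the two stable sets
#'
#' The permissive counterpart of [cross_omics_intersection()], used for
#' the union-vs-intersection comparison workflow.
#'
#' @inheritParams cross_omics_intersection
#' @return Character vector.
#' @export
union_gene_set <- function(stable_rna, stable_cnv) {
  union(stable_rna, stable_cnv)
}

#' End-to-end stable gene discovery
#'
#' The full stability-selection workflow: for each seed, build a
#' stratified fold plan, run per-fold ReliefF on each modality's training
#' splits, aggregate the five fold lists into one cumulative ranking per
#' modality, and take its top `n`. Per-seed top-n sets are then
#' intersected within each modality (stable sets), and the two stable
#' sets intersected across modalities for the final gene set (their
#' union is also reported). Sizes are monotonically non-increasing along
#' the intersection chain.
#'
#' @param cohort A [build_cohort()] result.
#' @param k Folds per seed.
#' @param seeds Distinct integer seeds.
#' @param top_n Genes kept from each per-seed aggregated ranking.
#' @param config A [relieff_config()].
#' @return A list of class `gene_selection_result`: `ranked` (per
#'   modality, per seed aggregated rankings), `top_sets` (per modality,
#'   per seed), `stable` (per modality), `final_genes`, `union_genes`,
#'   and a `provenance` record (seeds, k, top_n, config hash).
#' @export
discover_genes <- function(cohort, k = 5L, seeds = 1:5, top_n = 500L,
                           config = relieff_config()) {
  if (anyDuplicated(seeds)) stop("duplicate seeds")
  ranked <- list(rna = list(), cnv = list())
  top_sets <- list(rna = list(), cnv = list())
  for (s in seeds) {
    plan <- make_fold_plan(cohort$labels, k = k, seed = s)
    lists <- run_fold_selection(cohort, plan, config)
    for (mod in c("rna", "cnv")) {
      agg <- rank_and_aggregate_folds(lists[[mod]])
      ranked[[mod]][[as.character(s)]] <- agg
      top_sets[[mod]][[as.character(s)]] <- select_top_n(agg, top_n)
    }
  }
  stable <- lapply(top_sets, stable_gene_set)
  final_genes <- cross_omics_intersection(stable$rna, stable$cnv)
  scores <- lapply(c(rna = "rna", cnv = "cnv"), function(mod) {
    if (!length(final_genes)) return(numeric(0))
    per_seed <- vapply(ranked[[mod]], function(r) {
      stats::setNames(r$score, r$gene_id)[final_genes]
    }, numeric(length(final_genes)))
    if (length(final_genes) == 1L) sum(per_seed) else rowSums(per_seed)
  })
  structure(list(
    ranked = ranked, top_sets = top_sets, stable = stable,
    final_genes = final_genes,
    union_genes = union_gene_set(stable$rna, stable$cnv),
    final_scores = data.frame(gene_id = final_genes,
                              score_rna = unname(scores$rna),
                              score_cnv = unname(scores$cnv),
                              stringsAsFactors = FALSE),
    provenance = list(seeds = as.integer(seeds), k = as.integer(k),
                      top_n = as.integer(top_n),
                      k_neighbors = config$k_neighbors,
                      config_hash = config_hash(list(seeds, k, top_n, config)))
  ), class = "gene_selection_result")
}

#' @export
print.gene_selection_result <- function(x, ...) {
  cat(sprintf("<gene_selection_result> stable RNA %d, stable CNV %d, final %d, union %d genes\n",
              length(x$stable$rna), length(x$stable$cnv),
              length(x$final_genes), length(x$union_genes)))
  invisible(x)
}
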