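#' Confusion-matrix cell counts
#'
#' @param y_true,y_pred Equal-length 0/1 label vectors.
#' @param positive Which label counts as the positive class (default 1).
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1L) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  structure(list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
                 tn = sum(!pos_t & !pos_p), fn = sum(pos_t & !pos_p)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, undefined = TRUE)
  else list(value = num / den, undefined = FALSE)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision (PPV), recall (sensitivity), specificity,
#' F1-score and NPV. Ratios with a zero denominator are reported as 0
#' and listed in the `undefined` flag vector rather than dropped, so
#' aggregation over seeds stays well-defined.
#'
#' @param counts A [confusion_counts()] result.
#' @return List of class `metrics_entry` with the six metrics, the
#'   counts, and `undefined` (character vector of flagged metrics).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- with(counts, tp + fp + tn + fn)
  if (total == 0) stop("no samples")
  precision <- with(counts, safe_ratio(tp, tp + fp))
  recall <- with(counts, safe_ratio(tp, tp + fn))
  specificity <- with(counts, safe_ratio(tn, tn + fp))
  npv <- with(counts, safe_ratio(tn, tn + fn))
  f1 <- safe_ratio(2 * precision$value * recall$value,
                   precision$value + recall$value)
  vals <- list(accuracy = (counts$tp + counts$tn) / total,
               precision = precision, recall = recall,
               specificity = specificity, f1 = f1, npv = npv)
  undefined <- names(vals)[vapply(vals, function(v)
    is.list(v) && v$undefined, logical(1))]
  structure(list(
    accuracy = vals$accuracy, precision = precision$value,
    recall = recall$value, specificity = specificity$value,
    f1 = f1$value, npv = npv$value, counts = counts,
    undefined = undefined
  ), class = "metrics_entry")
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive sample outranks a
#' randomly chosen negative one, with ties counted one half — computed
#' from the Mann–Whitney rank statistic
#' \eqn{AUROC = U / (n_{pos} \cdot n_{neg})}.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores Positive-class scores (probabilities or any monotone
#'   score).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC requires both classes present")
  }
  r <- rank(scores, ties.method = "average")
  u <- sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Aggregate per-seed metric entries into mean and standard deviation
#'
#' Element-wise mean and population (divide-by-n) standard deviation per
#' metric, matching the "mean +/- sd" convention of benchmark tables.
#'
#' @param entries List of named numeric vectors (or `metrics_entry`
#'   objects), one per seed, with identical metric names.
#' @return List of class `metrics_report` with `per_seed` (data frame),
#'   `mean` and `sd` (named vectors).
#' @export
aggregate_over_seeds <- function(entries) {
  if (!length(entries)) stop("need at least one entry")
  rows <- lapply(entries, function(e) {
    if (inherits(e, "metrics_entry")) {
      unlist(e[c("accuracy", "precision", "recall", "specificity",
                 "f1", "npv")])
    } else unlist(e)
  })
  mat <- do.call(rbind, rows)
  mu <- colMeans(mat)
  sd_pop <- sqrt(colMeans(sweep(mat, 2, mu)^2))
  structure(list(per_seed = as.data.frame(mat), mean = mu, sd = sd_pop),
            class = "metrics_report")
}

#' Mann–Whitney U comparison with rank-biserial effect size
#'
#' Two-sided Mann–Whitney U test between two groups of metric values
#' (e.g. per-seed accuracies of two approaches): exact when both groups
#' have at most 8 tie-free values — the typical 5-seed case — and the
#' normal approximation otherwise. The effect size is the rank-biserial
#' correlation \eqn{1 - 2U/(n_A n_B)}, in `[-1, 1]`, where `U` counts
#' the pairs won by group A.
#'
#' @param a,b Numeric vectors of metric values.
#' @return List of class `comparison_result` with `u_statistic`,
#'   `p_value`, `effect_size`, `exact`.
#' @export
mann_whitney_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  no_ties <- !anyDuplicated(c(a, b))
  exact <- length(a) <= 8 && length(b) <= 8 && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  u <- unname(wt$statistic)
  structure(list(u_statistic = u, p_value = wt$p.value,
                 effect_size = 1 - 2 * u / (length(a) * length(b)),
                 exact = exact),
            class = "comparison_result")
}

#' Pairwise Pearson correlations over a gene set
#'
#' Symmetric correlation matrix with unit diagonal for the selected
#' genes' columns. Constant genes have undefined correlations; these are
#' reported as 0 and flagged.
#'
#' @param m An [omics_matrix()] (or plain samples-by-genes matrix with
#'   column names).
#' @param genes Character vector of gene IDs to correlate.
#' @return Correlation matrix with attribute `flagged_genes` listing
#'   constant genes.
#' @export
pairwise_pearson <- function(m, genes) {
  if (inherits(m, "omics_matrix")) m <- m$values
  if (!length(genes)) stop("gene set must be non-empty")
  if (nrow(m) < 2) stop("need at least 2 samples")
  missing <- setdiff(genes, colnames(m))
  if (length(missing)) {
    stop("unknown gene ID(s): ", paste(missing, collapse = ", "))
  }
  x <- m[, genes, drop = FALSE]
  constant <- genes[apply(x, 2, stats::sd) == 0]
  cc <- suppressWarnings(stats::cor(x))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "flagged_genes") <- constant
  cc
}

seed_metrics <- function(labels, pooled) {
  # pooled: list(ids, label, score) over all validation samples of one seed
  y <- labels[pooled$ids]
  entry <- classification_metrics(confusion_counts(y, pooled$label))
  c(accuracy = entry$accuracy, auroc = auroc(y, pooled$score),
    precision = entry$precision, recall = entry$recall,
    specificity = entry$specificity, f1 = entry$f1, npv = entry$npv)
}

#' Benchmark and fuse, reporting per-approach metrics over seeds
#'
#' Runs the cross-validated benchmark for each seed and computes pooled
#' validation metrics (every sample is validated exactly once per seed)
#' for the three approaches: expression only, copy number only, and
#' decision-level fusion. The fused AUROC uses the continuous fused
#' positive-class probability.
#'
#' @param cohort A [build_cohort()] result.
#' @param spec A [classifier_spec()].
#' @param k Folds.
#' @param seeds Distinct seeds.
#' @param k_scale Fusion scaling factor.
#' @return List of class `approach_report`: per approach (`rna`, `cnv`,
#'   `fused`) a [aggregate_over_seeds()] report; plus `fold_weights`, a
#'   data frame of per-seed per-fold fusion weights.
#' @export
benchmark_with_fusion <- function(cohort, spec, k = 5L, seeds = 1:5,
                                  k_scale = 10) {
  runs <- repeat_over_seeds(cohort, spec, k = k, seeds = seeds)
  per_seed <- list(rna = list(), cnv = list(), fused = list())
  weights <- list()
  for (s in names(runs)) {
    bench <- runs[[s]]$bench
    pooled <- list(
      rna = list(ids = character(0), label = integer(0), score = numeric(0)),
      cnv = list(ids = character(0), label = integer(0), score = numeric(0)),
      fused = list(ids = character(0), label = integer(0), score = numeric(0))
    )
    for (i in seq_len(k)) {
      pr <- bench$rna[[i]]
      pc <- bench$cnv[[i]]
      fused <- fuse_fold(pr, pc, k_scale = k_scale)
      w <- attr(fused, "weights")
      weights[[length(weights) + 1L]] <- data.frame(
        seed = as.integer(s), fold = i, alpha = w$alpha,
        w_rna = w$w_rna, w_cnv = w$w_cnv,
        acc_rna = pr$train_accuracy, acc_cnv = pc$train_accuracy)
      add <- function(acc, ids, label, score) {
        list(ids = c(acc$ids, ids), label = c(acc$label, label),
             score = c(acc$score, score))
      }
      pooled$rna <- add(pooled$rna, pr$validation_ids,
                        as.integer(pr$proba[, 2] > pr$proba[, 1]),
                        pr$proba[, 2])
      pooled$cnv <- add(pooled$cnv, pc$validation_ids,
                        as.integer(pc$proba[, 2] > pc$proba[, 1]),
                        pc$proba[, 2])
      pooled$fused <- add(pooled$fused, fused$sample_id, fused$label,
                          fused$p1)
    }
    for (ap in names(pooled)) {
      per_seed[[ap]][[s]] <- seed_metrics(cohort$labels, pooled[[ap]])
    }
  }
  structure(list(
    rna = aggregate_over_seeds(per_seed$rna),
    cnv = aggregate_over_seeds(per_seed$cnv),
    fused = aggregate_over_seeds(per_seed$fused),
    fold_weights = do.call(rbind, weights),
    seeds = as.integer(seeds), k = as.integer(k), k_scale = k_scale,
    spec_name = spec$name
  ), class = "approach_report")
}

#' Re-evaluate the pipeline on a selected gene set
#'
#' Restricts both modalities to the given genes (erroring with the list
#' of missing IDs if any gene is absent from a modality) and reruns the
#' benchmark-plus-fusion evaluation. With the full gene set this
#' reproduces the unrestricted pipeline exactly, given identical seeds.
#'
#' @param cohort A [build_cohort()] result.
#' @param genes Non-empty character vector of gene IDs present in both
#'   modalities.
#' @inheritParams benchmark_with_fusion
#' @return An `approach_report` (see [benchmark_with_fusion()]).
#' @export
evaluate_selected_genes <- function(cohort, genes, spec, k = 5L,
                                    seeds = 1:5, k_scale = 10) {
  if (!length(genes)) stop("gene set must be non-empty")
  for (mod in c("rna", "cnv")) {
    missing <- setdiff(genes, cohort[[mod]]$gene_ids)
    if (length(missing)) {
      stop(sprintf("gene(s) absent from %s modality: %s",
                   toupper(mod), paste(missing, collapse = ", ")))
    }
  }
  restricted <- structure(list(
    rna = subset_omics(cohort$rna, genes = genes),
    cnv = subset_omics(cohort$cnv, genes = genes),
    labels = cohort$labels,
    common_sample_ids = cohort$common_sample_ids
  ), class = "labeled_cohort")
  benchmark_with_fusion(restricted, spec, k = k, seeds = seeds,
                        k_scale = k_scale)
}
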