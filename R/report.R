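fmt_mean_sd <- function(mu, sd) sprintf("%.3f±%.3f", mu, sd)

#' Render pipeline results as text and machine-readable JSON
#'
#' Produces a deterministic summary of an evaluation run: per-approach
#' metric tables in `mean+/-sd` form (3 decimals), per-fold fusion
#' weights, selection provenance if a gene-selection result is supplied,
#' and any comparison statistics. The same content is written as JSON
#' with a fixed field order so reports round-trip to the in-memory
#' results.
#'
#' @param report An `approach_report` from [benchmark_with_fusion()] or
#'   [evaluate_selected_genes()].
#' @param selection Optional [discover_genes()] result.
#' @param comparisons Optional named list of `comparison_result` objects.
#' @param json_path Optional path; when given the JSON document is
#'   written there.
#' @return Invisibly, a list with `text` (character lines) and `json`
#'   (the JSON string).
#' @export
render_report <- function(report, selection = NULL, comparisons = NULL,
                          json_path = NULL) {
  stopifnot(inherits(report, "approach_report"))
  lines <- c(
    sprintf("model: %s | k = %d folds | seeds: %s | k_scale = %g",
            report$spec_name, report$k,
            paste(report$seeds, collapse = ","), report$k_scale),
    sprintf("config hash: %s",
            config_hash(list(report$spec_name, report$k, report$seeds,
                             report$k_scale))),
    "", "approach          " %+% paste(sprintf("%-14s",
        names(report$rna$mean)), collapse = ""))
  for (ap in c("rna", "cnv", "fused")) {
    r <- report[[ap]]
    lines <- c(lines, sprintf("%-18s%s", toupper(ap),
      paste(sprintf("%-14s", fmt_mean_sd(r$mean, r$sd)), collapse = "")))
  }
  if (!is.null(selection)) {
    lines <- c(lines, "",
      sprintf("gene selection: %d stable RNA, %d stable CNV, %d final, %d union",
              length(selection$stable$rna), length(selection$stable$cnv),
              length(selection$final_genes), length(selection$union_genes)),
      sprintf("selection config hash: %s", selection$provenance$config_hash))
  }
  if (!is.null(comparisons)) {
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      lines <- c(lines, sprintf(
        "%s: U = %g, p = %.4g, rank-biserial effect = %.3f%s",
        nm, cmp$u_statistic, cmp$p_value, cmp$effect_size,
        if (cmp$exact) " (exact)" else " (normal approx.)"))
    }
  }
  doc <- list(
    config = list(model = report$spec_name, k = report$k,
                  seeds = report$seeds, k_scale = report$k_scale,
                  config_hash = config_hash(list(report$spec_name, report$k,
                                                 report$seeds,
                                                 report$k_scale))),
    metrics = lapply(stats::setNames(nm = c("rna", "cnv", "fused")),
      function(ap) list(mean = as.list(report[[ap]]$mean),
                        sd = as.list(report[[ap]]$sd),
                        per_seed = report[[ap]]$per_seed)),
    fold_weights = report$fold_weights
  )
  if (!is.null(selection)) {
    doc$selection <- list(
      stable_rna = selection$stable$rna, stable_cnv = selection$stable$cnv,
      final_genes = selection$final_genes,
      union_genes = selection$union_genes,
      provenance = selection$provenance)
  }
  if (!is.null(comparisons)) {
    doc$comparisons <- lapply(comparisons, function(cmp)
      list(u_statistic = cmp$u_statistic, p_value = cmp$p_value,
           effect_size = cmp$effect_size, exact = cmp$exact))
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
  if (!is.null(json_path)) writeLines(json, json_path)
  invisible(list(text = lines, json = json))
}

`%+%` <- function(a, b) paste0(a, b)
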