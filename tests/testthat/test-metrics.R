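test_that("confusion counts fill the four cells correctly", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  cc2 <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(with(cc2, c(tp, fp, fn, tn)), c(0L, 1L, 1L, 0L))
  cc3 <- confusion_counts(c(1, 1, 0), c(0, 0, 0))
  expect_equal(with(cc3, c(tp, fn, tn, fp)), c(0L, 2L, 1L, 0L))
  expect_error(confusion_counts(c(1, 2), c(0, 1)), "0 or 1")
})

test_that("classification metrics reproduce the hand-computed example", {
  cc <- structure(list(tp = 9L, fp = 1L, tn = 8L, fn = 2L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11, tolerance = 1e-12)
  expect_equal(m$specificity, 8 / 9, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11), tolerance = 1e-12)
  expect_equal(m$npv, 0.8)
  expect_length(m$undefined, 0L)
  perfect <- classification_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "specificity", "f1", "npv")]) == 1))
  # degenerate: no positive predictions -> precision flagged 0
  deg <- classification_metrics(confusion_counts(c(1, 1, 0), c(0, 0, 0)))
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% deg$undefined)
  expect_equal(deg$accuracy, 1 / 3, tolerance = 1e-12)
})

test_that("metrics swap consistently when the positive class flips", {
  y <- c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1)
  yhat <- c(1, 0, 0, 1, 1, 0, 0, 0, 1, 1)
  m_pos1 <- classification_metrics(confusion_counts(y, yhat, positive = 1))
  m_pos0 <- classification_metrics(confusion_counts(y, yhat, positive = 0))
  expect_equal(m_pos1$precision, m_pos0$npv)
  expect_equal(m_pos1$recall, m_pos0$specificity)
  expect_equal(m_pos1$accuracy, m_pos0$accuracy)
})

test_that("AUROC matches worked examples and the pair-enumeration oracle", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "both classes")
  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # rounding induces ties
    expect_equal(auroc(y, s), auroc_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  y[1:2] <- 0:1
  s <- rnorm(60) + y
  expect_equal(auroc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("seed aggregation reports mean and population sd", {
  entries <- lapply(c(0.9, 0.9, 0.9, 0.9, 1.0), function(a) c(accuracy = a))
  agg <- aggregate_over_seeds(entries)
  expect_equal(unname(agg$mean["accuracy"]), 0.92)
  expect_equal(unname(agg$sd["accuracy"]), 0.04, tolerance = 1e-12)
  same <- aggregate_over_seeds(rep(list(c(accuracy = 0.8, auroc = 0.9)), 3))
  expect_equal(unname(same$sd), c(0, 0))
  single <- aggregate_over_seeds(list(c(accuracy = 0.7)))
  expect_equal(unname(single$mean["accuracy"]), 0.7)
  expect_equal(unname(single$sd["accuracy"]), 0)
  # mean lies within [min, max] of inputs
  set.seed(3)
  vals <- runif(7)
  agg2 <- aggregate_over_seeds(lapply(vals, function(v) c(m = v)))
  expect_gte(agg2$mean["m"], min(vals))
  expect_lte(agg2$mean["m"], max(vals))
})

test_that("Mann-Whitney comparison matches enumeration and effect-size algebra", {
  res <- mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$u_statistic), 0)
  expect_equal(res$effect_size, 1.0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_true(res$exact)
  # identical multisets: U = n^2/2, effect size 0 (ties force approximation)
  same <- mann_whitney_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$effect_size, 0)
  # exact p matches brute-force enumeration on random tie-free groups
  set.seed(29)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1)), 6)
    got <- mann_whitney_compare(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, mann_whitney_exact_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_compare(numeric(0), 1), "non-empty")
})

test_that("AUROC is definitionally the normalized U statistic", {
  set.seed(37)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    s <- rnorm(n)
    u <- unname(suppressWarnings(
      stats::wilcox.test(s[y == 1], s[y == 0])$statistic))
    expect_equal(auroc(y, s), u / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
})

test_that("pairwise Pearson matches the definition oracle and flags constants", {
  set.seed(41)
  x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("g", 1:5)))
  cc <- pairwise_pearson(x, paste0("g", 1:5))
  expect_equal(matrix(cc, 5, 5), pearson_oracle(x[, 1:5]), tolerance = 1e-12)
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_equal(cc, t(cc))
  # exact anti-correlation
  x2 <- cbind(g1 = rnorm(10))
  x2 <- cbind(x2, g2 = -x2[, "g1"])
  cc2 <- pairwise_pearson(x2, c("g1", "g2"))
  expect_equal(cc2["g1", "g2"], -1)
  # constant gene: flagged, reported 0
  x3 <- cbind(g1 = rnorm(10), g2 = rep(2, 10))
  cc3 <- pairwise_pearson(x3, c("g1", "g2"))
  expect_equal(cc3["g1", "g2"], 0)
  expect_equal(attr(cc3, "flagged_genes"), "g2")
  expect_error(pairwise_pearson(x, c("g1", "nope")), "unknown gene")
})

test_that("restricting to the full gene set reproduces the unrestricted run", {
  tc <- tiny_cohort(seed = 81L, n_class0 = 15L, n_class1 = 15L,
                    n_genes_rna = 30L, n_genes_cnv = 30L)
  spec <- centroid_spec()
  full <- benchmark_with_fusion(tc$cohort, spec, k = 3, seeds = 1:2)
  again <- evaluate_selected_genes(tc$cohort, tc$cohort$rna$gene_ids, spec,
                                   k = 3, seeds = 1:2)
  expect_identical(full$fused$per_seed, again$fused$per_seed)
  expect_identical(full$fold_weights, again$fold_weights)
  expect_error(evaluate_selected_genes(tc$cohort, character(0), spec),
               "non-empty")
  expect_error(evaluate_selected_genes(tc$cohort, "NOPE", spec),
               "absent from RNA")
})

test_that("reports round-trip through JSON with provenance fields", {
  tc <- tiny_cohort(seed = 83L, n_class0 = 12L, n_class1 = 12L,
                    n_genes_rna = 20L, n_genes_cnv = 20L)
  rep <- benchmark_with_fusion(tc$cohort, centroid_spec(), k = 3, seeds = 1:2)
  out <- render_report(rep)
  parsed <- jsonlite::fromJSON(out$json)
  expect_equal(parsed$config$seeds, 1:2)
  expect_type(parsed$config$config_hash, "character")
  expect_equal(parsed$metrics$fused$mean$accuracy,
               unname(rep$fused$mean["accuracy"]), tolerance = 1e-12)
  expect_equal(as.data.frame(parsed$fold_weights), rep$fold_weights,
               tolerance = 1e-12)
  # mean±sd formatting with 3 decimals in the text table
  expect_true(any(grepl("\\d\\.\\d{3}±\\d\\.\\d{3}", out$text)))
})
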