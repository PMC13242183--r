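# Worked values frozen from a 50-digit arbitrary-precision evaluation of
# the weight formulas (scripts/fusion_oracle.py).
ALPHA_0954_0892_K10 <- 1.5606842713866967
W_RNA_0954_0892 <- 0.5241717492083593
ALPHA_10_05_K10 <- 10.695605577589171
W_RNA_10_05 <- 0.9952639418237105

test_that("alpha matches the arbitrary-precision worked values", {
  expect_equal(compute_alpha(0.9, 0.9, 10), 0)
  expect_equal(compute_alpha(0.954, 0.892, 10), ALPHA_0954_0892_K10,
               tolerance = 1e-12)
  expect_equal(compute_alpha(1.0, 0.5, 10), ALPHA_10_05_K10,
               tolerance = 1e-12)
  expect_error(compute_alpha(1.2, 0.5, 10), "\\[0, 1\\]")
  expect_error(compute_alpha(0.9, 0.5, 0), "positive")
})

test_that("weights match the worked values and sum to one", {
  w <- compute_weights(0.954, 0.892, ALPHA_0954_0892_K10)
  expect_equal(unname(w["w_rna"]), W_RNA_0954_0892, tolerance = 1e-6)
  expect_equal(unname(sum(w)), 1, tolerance = 1e-12)
  w2 <- compute_weights(1.0, 0.5, ALPHA_10_05_K10)
  expect_equal(unname(w2["w_rna"]), W_RNA_10_05, tolerance = 1e-6)
  expect_equal(unname(compute_weights(0.7, 0.3, 0)), c(0.5, 0.5))
  expect_error(compute_weights(0.5, 0.5, -1), "nonnegative")
})

test_that("weight algebra holds over a random accuracy grid", {
  set.seed(42)
  n <- 2000
  acc_r <- runif(n)
  acc_c <- runif(n)
  k <- sample(2:30, n, replace = TRUE)
  for (i in seq_len(n)) {
    a <- compute_alpha(acc_r[i], acc_c[i], k[i])
    w <- compute_weights(acc_r[i], acc_c[i], a)
    expect_true(abs(sum(w) - 1) < 1e-12)
    if (acc_r[i] > acc_c[i]) expect_gt(w["w_rna"], 0.5)
    if (acc_r[i] < acc_c[i]) expect_lt(w["w_rna"], 0.5)
  }
  # monotone: w_rna non-decreasing in acc_rna at fixed acc_cnv and k
  grid <- seq(0, 1, by = 0.05)
  w_seq <- vapply(grid, function(a) {
    compute_weights(a, 0.6, compute_alpha(a, 0.6, 10))["w_rna"]
  }, numeric(1))
  expect_true(all(diff(w_seq) >= -1e-12))
})

test_that("weights stay finite for extreme scaling factors", {
  w <- compute_weights(1, 0, compute_alpha(1, 0, 1e6))
  expect_true(all(is.finite(w)))
  expect_equal(unname(w["w_rna"]), 1, tolerance = 1e-12)
})

test_that("probability fusion is a convex per-class combination", {
  fused <- fuse_probabilities(c(0.8, 0.2), c(0.6, 0.4),
                              list(w_rna = 0.5, w_cnv = 0.5))
  expect_equal(fused$p0, 0.7)
  expect_equal(fused$p1, 0.3)
  expect_equal(fused$label, 0L)
  # degenerate weight reduces exactly to one modality
  only_rna <- fuse_probabilities(c(0.2, 0.8), c(0.6, 0.4),
                                 list(w_rna = 1, w_cnv = 0))
  expect_equal(c(only_rna$p0, only_rna$p1), c(0.2, 0.8))
  # worked value
  f <- fuse_probabilities(c(0.2, 0.8), c(0.6, 0.4),
                          list(w_rna = 0.5242, w_cnv = 0.4758))
  expect_equal(f$p0, 0.39032, tolerance = 1e-9)
  expect_equal(f$p1, 0.60968, tolerance = 1e-9)
  expect_equal(f$label, 1L)
  # convexity + normalization on random pairs
  set.seed(7)
  for (i in 1:200) {
    pr <- runif(1); pc <- runif(1); wr <- runif(1)
    out <- fuse_probabilities(c(1 - pr, pr), c(1 - pc, pc),
                              list(w_rna = wr, w_cnv = 1 - wr))
    expect_true(out$p1 >= min(pr, pc) - 1e-12 && out$p1 <= max(pr, pc) + 1e-12)
    expect_equal(out$p0 + out$p1, 1, tolerance = 1e-12)
  }
  expect_error(fuse_probabilities(c(0.9, 0.3), c(0.5, 0.5),
                                  list(w_rna = 0.5, w_cnv = 0.5)),
               "summing to 1")
})

make_fold_pred <- function(modality, acc, proba, ids) {
  omicsfusion:::fold_prediction(modality, 1L, acc, ids, proba)
}

test_that("fold fusion computes weights once per fold and checks alignment", {
  ids <- paste0("s", 1:4)
  pr <- make_fold_pred("RNA", 1.0,
                       cbind(c(0.9, 0.2, 0.7, 0.4), c(0.1, 0.8, 0.3, 0.6)), ids)
  pc <- make_fold_pred("CNV", 0.5,
                       cbind(c(0.4, 0.6, 0.5, 0.5), c(0.6, 0.4, 0.5, 0.5)), ids)
  fused <- fuse_fold(pr, pc, k_scale = 1000)
  # with a huge scaling factor the stronger modality dominates
  expect_equal(fused$p1, unname(pr$proba[, 2]), tolerance = 1e-6)
  w <- attr(fused, "weights")
  expect_gt(w$w_rna, 0.999)
  # equal accuracies reduce exactly to soft voting
  pc_eq <- make_fold_pred("CNV", 1.0, pc$proba, ids)
  fused_eq <- fuse_fold(pr, pc_eq, k_scale = 10)
  soft <- soft_vote(pr$proba, pc_eq$proba)
  expect_identical(fused_eq$p1, soft$p1)
  expect_identical(fused_eq$label, soft$label)
  # misaligned validation ids are an error
  pc_bad <- make_fold_pred("CNV", 0.5, pc$proba, rev(ids))
  expect_error(fuse_fold(pr, pc_bad), "not aligned")
})

test_that("hard voting is majority with soft-vote tie-breaking", {
  expect_equal(hard_vote(1L, 1L, c(0.1, 0.9), c(0.4, 0.6)), 1L)
  expect_equal(hard_vote(0L, 0L, c(0.9, 0.1), c(0.6, 0.4)), 0L)
  # disagreement: soft vote decides — pF = (0.65, 0.35) -> 0
  expect_equal(hard_vote(0L, 1L, c(0.9, 0.1), c(0.4, 0.6)), 0L)
  # soft voting is definitionally fusion with equal weights
  set.seed(11)
  p1r <- runif(20); p1c <- runif(20)
  sv <- soft_vote(cbind(1 - p1r, p1r), cbind(1 - p1c, p1c))
  fp <- fuse_probabilities(cbind(1 - p1r, p1r), cbind(1 - p1c, p1c),
                           list(w_rna = 0.5, w_cnv = 0.5))
  expect_identical(sv, fp)
})

test_that("ties in fused probability resolve to class 0", {
  out <- fuse_probabilities(c(0.5, 0.5), c(0.5, 0.5),
                            list(w_rna = 0.5, w_cnv = 0.5))
  expect_equal(out$label, 0L)
})

test_that("scaling-factor sweep is consistent and flat at equal accuracies", {
  tc <- tiny_cohort(seed = 65L)
  plan <- make_fold_plan(tc$cohort$labels, k = 4, seed = 1)
  bench <- run_benchmark(tc$cohort, centroid_spec(), plan)
  curve <- sweep_k(bench$rna, bench$cnv, tc$cohort$labels, k_grid = c(2, 10, 20))
  expect_equal(nrow(curve), 3L)
  # single point equals direct fold fusion at the same k
  fused10 <- do.call(rbind, lapply(seq_along(bench$rna), function(i)
    fuse_fold(bench$rna[[i]], bench$cnv[[i]], k_scale = 10)))
  acc10 <- mean(fused10$label == tc$cohort$labels[fused10$sample_id])
  expect_equal(curve$accuracy[curve$k_scale == 10], acc10)
  # equal train accuracies: alpha = 0 for all k, curve constant
  bench_eq <- bench
  for (i in seq_along(bench_eq$cnv)) {
    bench_eq$cnv[[i]]$train_accuracy <- bench_eq$rna[[i]]$train_accuracy
  }
  flat <- sweep_k(bench_eq$rna, bench_eq$cnv, tc$cohort$labels,
                  k_grid = c(2, 5, 10, 30))
  expect_equal(length(unique(flat$accuracy)), 1L)
})
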