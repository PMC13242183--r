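#' Build a stratified k-fold cross-validation plan
#'
#' Partitions the cohort's samples into `k` validation folds with class
#' proportions preserved to within one sample per fold. Within each class
#' the sample IDs are shuffled by the seed and dealt round-robin, so
#' surplus samples land deterministically in the earlier folds. The plan
#' is a pure function of `(labels, k, seed)`, and the same plan is reused
#' for both modalities downstream so fold membership is aligned across
#' omics types.
#'
#' @param labels Named 0/1 vector over sample IDs.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return A list of class `fold_plan` with elements `seed`, `k` and
#'   `folds`, a list of `k` lists each holding `train_ids` and
#'   `validation_ids`.
#' @export
make_fold_plan <- function(labels, k = 5L, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by sample ID")
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  ids <- names(labels)
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k) {
      stop(sprintf("class %d has %d sample(s), fewer than k = %d folds",
                   cls, sum(labels == cls), k))
    }
  }
  fold_of <- integer(length(ids))
  names(fold_of) <- ids
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      cls_ids <- sample(ids[labels == cls])
      fold_of[cls_ids] <- rep_len(seq_len(k), length(cls_ids))
    }
  })
  folds <- lapply(seq_len(k), function(i) {
    list(train_ids = ids[fold_of[ids] != i],
         validation_ids = ids[fold_of[ids] == i])
  })
  structure(list(seed = as.integer(seed), k = k, folds = folds),
            class = "fold_plan")
}

#' Specify a probabilistic binary classifier adapter
#'
#' Classifiers are adapters over established implementations — the
#' bespoke contribution of this package is the cross-validation harness,
#' the decision-level fusion and the gene selection, not the models.
#' Built-in adapters:
#' \describe{
#'   \item{`gradient_boosting`}{[xgboost::xgboost()] with the library's
#'     stock tree-booster settings (`eta = 0.3`, `gamma = 0`,
#'     `lambda = 1`, `alpha = 0`), 100 boosting rounds, single-threaded
#'     for reproducibility.}
#'   \item{`kernel_svm`}{[e1071::svm()], RBF kernel, `cost = 1`, with
#'     Platt-scaled probabilities.}
#'   \item{`mlp`}{[nnet::nnet()], one hidden layer (default 16 units,
#'     smaller than a dense-data default because the intended inputs are
#'     gene matrices with far more features than samples), logistic
#'     output, up to 200 iterations.}
#' }
#' A custom adapter can be supplied via `fit` and `predict_proba`:
#' `fit(x, y, seed, hyperparameters)` must return a model object and
#' `predict_proba(model, x)` an `n x 2` matrix of class probabilities
#' (columns class 0, class 1) with rows summing to 1.
#'
#' @param name Adapter name.
#' @param hyperparameters Named list overriding adapter defaults.
#' @param fit,predict_proba Optional custom adapter functions.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("gradient_boosting", "kernel_svm", "mlp"),
                            hyperparameters = list(),
                            fit = NULL, predict_proba = NULL) {
  if (is.null(fit) != is.null(predict_proba)) {
    stop("supply both 'fit' and 'predict_proba' for a custom adapter, or neither")
  }
  if (is.null(fit)) {
    name <- match.arg(name)
    adapter <- builtin_adapters[[name]]
    fit <- adapter$fit
    predict_proba <- adapter$predict_proba
  } else {
    name <- as.character(name)
  }
  structure(list(name = name, hyperparameters = hyperparameters,
                 fit = fit, predict_proba = predict_proba),
            class = "classifier_spec")
}

builtin_adapters <- list(
  gradient_boosting = list(
    fit = function(x, y, seed, hp) {
      params <- utils::modifyList(
        list(objective = "binary:logistic", eta = 0.3, gamma = 0,
             lambda = 1, alpha = 0, max_depth = 6, nthread = 1,
             seed = seed),
        hp[setdiff(names(hp), "nrounds")])
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds %||% 100L, verbose = 0)
    },
    predict_proba = function(model, x) {
      p1 <- stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
      cbind(1 - p1, p1)
    }
  ),
  kernel_svm = list(
    fit = function(x, y, seed, hp) {
      with_seed(seed, {
        args <- utils::modifyList(
          list(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = 1, probability = TRUE, scale = FALSE),
          hp)
        do.call(e1071::svm, args)
      })
    },
    predict_proba = function(model, x) {
      pred <- stats::predict(model, x, probability = TRUE)
      pr <- attr(pred, "probabilities")
      cbind(pr[, "0"], pr[, "1"])
    }
  ),
  mlp = list(
    fit = function(x, y, seed, hp) {
      with_seed(seed, {
        args <- utils::modifyList(
          list(x = x, y = y, size = 16L, decay = 1e-4, maxit = 200L,
               entropy = TRUE, MaxNWts = 1e6, trace = FALSE),
          hp)
        do.call(nnet::nnet, args)
      })
    },
    predict_proba = function(model, x) {
      p1 <- as.numeric(stats::predict(model, x))
      cbind(1 - p1, p1)
    }
  )
)

fold_prediction <- function(modality, fold_index, train_accuracy,
                            validation_ids, proba) {
  stopifnot(nrow(proba) == length(validation_ids))
  if (any(abs(rowSums(proba) - 1) > 1e-9) || any(proba < -1e-12)) {
    stop("adapter returned invalid probability pairs")
  }
  colnames(proba) <- c("p0", "p1")
  rownames(proba) <- validation_ids
  structure(list(modality = modality, fold_index = fold_index,
                 train_accuracy = train_accuracy,
                 validation_ids = validation_ids, proba = proba),
            class = "fold_prediction")
}

fit_fold <- function(m, labels, spec, fold, fold_index, seed) {
  xt <- m$values[fold$train_ids, , drop = FALSE]
  yt <- labels[fold$train_ids]
  xv <- m$values[fold$validation_ids, , drop = FALSE]
  model <- tryCatch(
    spec$fit(xt, yt, seed, spec$hyperparameters),
    error = function(e) stop(sprintf("adapter '%s' failed on %s fold %d: %s",
                                     spec$name, m$modality, fold_index,
                                     conditionMessage(e)))
  )
  proba_t <- spec$predict_proba(model, xt)
  train_acc <- mean((proba_t[, 2] > proba_t[, 1]) == (yt == 1L))
  fold_prediction(m$modality, fold_index, train_acc,
                  fold$validation_ids, spec$predict_proba(model, xv))
}

#' Run one cross-validated benchmark over both modalities
#'
#' For every fold of the plan and each modality, fits the classifier on
#' the fold's training split, records the train-split accuracy (the
#' quantity the fusion weights are derived from) and the validation-split
#' class probabilities. The *same* fold plan is used for both modalities,
#' so per-sample probability pairs are aligned for fusion.
#'
#' @param cohort A [build_cohort()] result.
#' @param spec A [classifier_spec()].
#' @param plan A [make_fold_plan()] built over the cohort's labels.
#' @return A list of class `benchmark_result` with elements `rna` and
#'   `cnv`, each a list of per-fold `fold_prediction` objects, plus
#'   `seed` and `spec_name`.
#' @export
run_benchmark <- function(cohort, spec, plan) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            inherits(spec, "classifier_spec"),
            inherits(plan, "fold_plan"))
  plan_ids <- sort(unlist(lapply(plan$folds, `[[`, "validation_ids")))
  if (!identical(plan_ids, sort(cohort$common_sample_ids))) {
    stop("fold plan does not cover exactly the cohort's samples")
  }
  res <- lapply(list(cohort$rna, cohort$cnv), function(m) {
    lapply(seq_along(plan$folds), function(i) {
      fit_fold(m, cohort$labels, spec, plan$folds[[i]], i, plan$seed)
    })
  })
  structure(list(rna = res[[1]], cnv = res[[2]], seed = plan$seed,
                 spec_name = spec$name),
            class = "benchmark_result")
}

#' Concatenate both modalities into one joint feature matrix
#'
#' Column-wise concatenation with modality-prefixed gene IDs
#' (`RNA:<gene>`, `CNV:<gene>`), preserving sample order — the
#' feature-level ("early") integration baseline against which
#' decision-level fusion is compared.
#'
#' @param cohort A [build_cohort()] result.
#' @return An [omics_matrix()] with modality tag `"joint"`.
#' @export
concat_joint_features <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  vals <- cbind(cohort$rna$values, cohort$cnv$values)
  omics_matrix(vals, "joint",
               sample_ids = cohort$common_sample_ids,
               gene_ids = c(paste0("RNA:", cohort$rna$gene_ids),
                            paste0("CNV:", cohort$cnv$gene_ids)))
}

#' Repeat a benchmark over several random seeds
#'
#' One fold plan and one [run_benchmark()] call per seed, so the
#' cross-validation partition (and any model-internal randomness) varies
#' across repetitions while remaining reproducible.
#'
#' @param cohort A [build_cohort()] result.
#' @param spec A [classifier_spec()].
#' @param k Folds per repetition.
#' @param seeds Integer vector of distinct seeds.
#' @return Named list (one element per seed) of lists with `plan` and
#'   `bench`.
#' @export
repeat_over_seeds <- function(cohort, spec, k = 5L, seeds = 1:5) {
  if (!length(seeds)) stop("seed list must be non-empty")
  if (anyDuplicated(seeds)) stop("duplicate seeds")
  out <- lapply(seeds, function(s) {
    plan <- make_fold_plan(cohort$labels, k = k, seed = s)
    list(plan = plan, bench = run_benchmark(cohort, spec, plan))
  })
  names(out) <- as.character(seeds)
  out
}
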