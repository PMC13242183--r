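# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 7L, ...) {
  defaults <- list(
    n_class0 = 20L, n_class1 = 20L, n_genes_rna = 50L, n_genes_cnv = 40L,
    n_shared_informative = 5L, n_rna_only_informative = 3L,
    n_cnv_only_informative = 3L, effect_size_rna = 1.5,
    effect_size_cnv = 1.0, block_size = 5L, block_rho = 0.3,
    dropout_fraction_rna = 0, dropout_fraction_cnv = 0, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_cohort <- function(seed = 7L, normalize = TRUE, ...) {
  g <- generate_cohort(tiny_config(seed = seed, ...))
  list(cohort = build_cohort(g$rna, g$cnv, g$labels, normalize = normalize),
       truth = g$truth, raw = g)
}

# A trivially fast deterministic adapter: class-conditional mean
# (nearest-centroid) classifier with a logistic score. Used where a test
# needs a real fit/predict cycle without the cost of the heavy adapters.
centroid_spec <- function() {
  classifier_spec(
    name = "centroid",
    fit = function(x, y, seed, hp) {
      list(mu0 = colMeans(x[y == 0, , drop = FALSE]),
           mu1 = colMeans(x[y == 1, , drop = FALSE]))
    },
    predict_proba = function(model, x) {
      d0 <- sqrt(rowSums(sweep(x, 2, model$mu0)^2))
      d1 <- sqrt(rowSums(sweep(x, 2, model$mu1)^2))
      p1 <- 1 / (1 + exp(d1 - d0))
      cbind(1 - p1, p1)
    }
  )
}

# A 1-NN adapter that memorizes its training points (train accuracy 1 on
# distinct points).
one_nn_spec <- function() {
  classifier_spec(
    name = "one_nn",
    fit = function(x, y, seed, hp) list(x = x, y = y),
    predict_proba = function(model, x) {
      p1 <- apply(x, 1, function(row) {
        d <- colSums((t(model$x) - row)^2)
        model$y[which.min(d)]
      })
      eps <- 1e-9
      p1 <- pmin(pmax(p1, eps), 1 - eps)
      cbind(1 - p1, p1)
    }
  )
}
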