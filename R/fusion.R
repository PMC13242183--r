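#' Exponential accuracy-gap scaling for fusion weights
#'
#' The fusion sharpness parameter is derived from the two modalities'
#' train-split accuracies as
#' \deqn{\alpha = |e^{acc_{CNV}} - e^{acc_{RNA}}| \cdot k}
#' where `k_scale` controls how sharply the weights favor the more
#' accurate modality. `alpha` is zero exactly when the two accuracies are
#' equal, in which case fusion reduces to equal-weight soft voting.
#'
#' @param acc_rna,acc_cnv Train-split accuracies in `[0, 1]`.
#' @param k_scale Positive scaling factor; default 10, above which the
#'   accuracy-vs-k curve plateaus.
#' @return Nonnegative scalar `alpha`.
#' @export
compute_alpha <- function(acc_rna, acc_cnv, k_scale = 10) {
  if (any(acc_rna < 0 | acc_rna > 1) || any(acc_cnv < 0 | acc_cnv > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  if (any(k_scale <= 0)) stop("k_scale must be positive")
  abs(exp(acc_cnv) - exp(acc_rna)) * k_scale
}

#' Accuracy-weighted softmax fusion weights
#'
#' \deqn{w_R = e^{\alpha \cdot acc_R} / (e^{\alpha \cdot acc_R} +
#'   e^{\alpha \cdot acc_C})} and symmetrically for \eqn{w_C} — a softmax
#' over the alpha-scaled accuracies, computed in the numerically stable
#' form (max exponent subtracted) so no overflow occurs even for very
#' large `alpha`. The weights sum to 1; the modality with the higher
#' accuracy gets the larger weight.
#'
#' @param acc_rna,acc_cnv Accuracies in `[0, 1]`.
#' @param alpha Nonnegative sharpness, typically from [compute_alpha()].
#' @return Named numeric vector `c(w_rna = ..., w_cnv = ...)`.
#' @export
compute_weights <- function(acc_rna, acc_cnv, alpha) {
  if (any(alpha < 0)) stop("alpha must be nonnegative")
  a_r <- alpha * acc_rna
  a_c <- alpha * acc_cnv
  m <- pmax(a_r, a_c)
  e_r <- exp(a_r - m)
  e_c <- exp(a_c - m)
  c(w_rna = e_r / (e_r + e_c), w_cnv = e_c / (e_r + e_c))
}

#' Bundle per-fold fusion weights
#'
#' @param acc_rna,acc_cnv Train accuracies the weights derive from.
#' @param k_scale Scaling factor.
#' @return List of class `fusion_weights` with `alpha`, `w_rna`, `w_cnv`,
#'   `k_scale`.
#' @export
fusion_weights <- function(acc_rna, acc_cnv, k_scale = 10) {
  alpha <- compute_alpha(acc_rna, acc_cnv, k_scale)
  w <- compute_weights(acc_rna, acc_cnv, alpha)
  structure(list(alpha = alpha, w_rna = unname(w["w_rna"]),
                 w_cnv = unname(w["w_cnv"]), k_scale = k_scale),
            class = "fusion_weights")
}

check_proba_pairs <- function(p, what, tol = 1e-6) {
  p <- rbind(p)
  if (ncol(p) != 2) stop(what, " must be an n x 2 probability matrix")
  if (any(abs(rowSums(p) - 1) > tol) || any(p < -tol)) {
    stop(what, " rows must be probability pairs summing to 1")
  }
  p
}

#' Fuse two modality probability pairs
#'
#' Per-class convex combination of the two modality probabilities:
#' \deqn{p^F_{y=c} = w_C \cdot p^C_{y=c} + w_R \cdot p^R_{y=c}} and the
#' fused label is the argmax class (ties broken to class 0). Each fused
#' probability therefore lies between the two modality probabilities, and
#' fused pairs sum to 1 whenever the inputs do.
#'
#' @param p_rna,p_cnv Probability pairs (vectors of length 2, or `n x 2`
#'   matrices), columns class 0 then class 1, rows summing to 1.
#' @param w A `fusion_weights` object, or any list with `w_rna`, `w_cnv`.
#' @return A list with `p0`, `p1` (fused probabilities) and `label`
#'   (predicted class), each of length `n`.
#' @export
fuse_probabilities <- function(p_rna, p_cnv, w) {
  p_rna <- check_proba_pairs(p_rna, "p_rna")
  p_cnv <- check_proba_pairs(p_cnv, "p_cnv")
  stopifnot(nrow(p_rna) == nrow(p_cnv))
  p0 <- w$w_cnv * p_cnv[, 1] + w$w_rna * p_rna[, 1]
  p1 <- w$w_cnv * p_cnv[, 2] + w$w_rna * p_rna[, 2]
  list(p0 = unname(p0), p1 = unname(p1),
       label = as.integer(p1 > p0))
}

#' Fuse an aligned pair of fold predictions
#'
#' Fusion weights are computed once per fold from the two modalities'
#' train-split accuracies (accuracies vary by fold, so weights are
#' per-fold rather than global) and applied to every validation sample of
#' that fold. Requires the two predictions to cover identical validation
#' IDs in identical order — guaranteed when both come from the same
#' [make_fold_plan()].
#'
#' @param pred_rna,pred_cnv `fold_prediction` objects for the same fold.
#' @param k_scale Scaling factor.
#' @return Data frame with `sample_id`, `p0`, `p1`, `label`; the
#'   `fusion_weights` used are attached as attribute `weights`.
#' @export
fuse_fold <- function(pred_rna, pred_cnv, k_scale = 10) {
  stopifnot(inherits(pred_rna, "fold_prediction"),
            inherits(pred_cnv, "fold_prediction"))
  if (!identical(pred_rna$validation_ids, pred_cnv$validation_ids)) {
    stop("validation IDs of the two modalities are not aligned")
  }
  w <- fusion_weights(pred_rna$train_accuracy, pred_cnv$train_accuracy,
                      k_scale)
  fused <- fuse_probabilities(pred_rna$proba, pred_cnv$proba, w)
  out <- data.frame(sample_id = pred_rna$validation_ids,
                    p0 = fused$p0, p1 = fused$p1, label = fused$label,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  out
}

#' Equal-weight soft-voting baseline
#'
#' Conventional soft voting assigns equal weight to the two modalities;
#' it is exactly [fuse_probabilities()] with `w = (0.5, 0.5)`, and
#' decision-level fusion reduces to it whenever the two train accuracies
#' are equal.
#'
#' @inheritParams fuse_probabilities
#' @return As [fuse_probabilities()].
#' @export
soft_vote <- function(p_rna, p_cnv) {
  fuse_probabilities(p_rna, p_cnv, list(w_rna = 0.5, w_cnv = 0.5))
}

#' Hard-voting (majority) baseline
#'
#' Majority vote over the two modality labels. With two voters every
#' disagreement is a 1–1 tie, which falls back to the soft-vote label
#' computed from the probability pairs.
#'
#' @param label_rna,label_cnv Predicted 0/1 labels per sample.
#' @param p_rna,p_cnv Probability pairs used to resolve ties.
#' @return Integer vector of fused labels.
#' @export
hard_vote <- function(label_rna, label_cnv, p_rna, p_cnv) {
  stopifnot(length(label_rna) == length(label_cnv))
  soft <- soft_vote(p_rna, p_cnv)$label
  ifelse(label_rna == label_cnv, as.integer(label_rna), soft)
}

#' Sweep the scaling factor and record fused accuracy
#'
#' Evaluates the fused-label accuracy over a grid of scaling-factor
#' values for one aligned pair of per-fold prediction lists. The curve is
#' how the scaling factor is chosen empirically: it typically rises and
#' then plateaus once the weights saturate toward the stronger modality.
#'
#' @param preds_rna,preds_cnv Lists of `fold_prediction` objects (one per
#'   fold), aligned across modalities.
#' @param labels Named true 0/1 labels covering all validation samples.
#' @param k_grid Vector of scaling-factor values.
#' @return Data frame with columns `k_scale` and `accuracy`.
#' @export
sweep_k <- function(preds_rna, preds_cnv, labels, k_grid = 2:30) {
  if (!length(k_grid)) stop("k_grid must be non-empty")
  acc <- vapply(k_grid, function(k) {
    fused <- lapply(seq_along(preds_rna), function(i) {
      fuse_fold(preds_rna[[i]], preds_cnv[[i]], k_scale = k)
    })
    fused <- do.call(rbind, fused)
    mean(fused$label == labels[fused$sample_id])
  }, numeric(1))
  data.frame(k_scale = k_grid, accuracy = acc)
}
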