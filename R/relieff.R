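#' ReliefF configuration
#'
#' @param k_neighbors Number of nearest hits and misses per evaluated
#'   instance (default 100, the customary ReliefF default; clipped with a
#'   warning to one less than the smaller class when the data are too
#'   small for it).
#' @param n_sampled Number of instances to evaluate, or `"all"` for a
#'   deterministic full pass over every instance (the default; random
#'   instance selection then degenerates to a full sweep).
#' @param seed Seed used only when `n_sampled` is a count smaller than
#'   the number of instances.
#' @return List of class `relieff_config`.
#' @export
relieff_config <- function(k_neighbors = 100L, n_sampled = "all",
                           seed = 1L) {
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (!identical(n_sampled, "all")) {
    n_sampled <- as.integer(n_sampled)
    if (n_sampled < 1) stop("n_sampled must be >= 1 or \"all\"")
  }
  structure(list(k_neighbors = k_neighbors, n_sampled = n_sampled,
                 seed = as.integer(seed)),
            class = "relieff_config")
}

#' Range-normalized attribute difference
#'
#' The standard Relief contrast for continuous attributes:
#' `|x - y| / range`, which lies in `[0, 1]` when both values fall in
#' the observed attribute range; zero-range (constant) attributes return
#' 0.
#'
#' @param x,y Attribute values.
#' @param range Attribute range (max - min over the training split).
#' @return Difference value(s) in `[0, 1]`.
#' @export
relief_diff <- function(x, y, range) {
  ifelse(range > 0, abs(x - y) / range, 0)
}

#' ReliefF feature weights for a binary-labeled matrix
#'
#' Scores every feature by the contrast between its values at each
#' instance's `k` nearest same-class neighbors (hits, never the instance
#' itself) and `k` nearest other-class neighbors (misses), under the
#' Manhattan distance on range-normalized attributes. Each evaluated
#' instance contributes `(mean miss diff - mean hit diff) / n` to a
#' feature's weight, so weights are bounded in `[-1, 1]`: positive for
#' features whose values separate the classes locally, near zero for
#' noise. With `n_sampled = "all"` (the default) the pass is
#' deterministic; distance ties are broken by row order.
#'
#' @param x Numeric samples-by-features matrix (or an [omics_matrix()]).
#' @param y Binary 0/1 labels, one per row of `x`.
#' @param config A [relieff_config()].
#' @param clip_k If the requested `k_neighbors` exceeds what the class
#'   sizes allow, clip it to (min class size - 1) with a warning
#'   (default); with `clip_k = FALSE` raise an error instead.
#' @return Named numeric vector of feature weights.
#' @export
relieff_weights <- function(x, y, config = relieff_config(),
                            clip_k = TRUE) {
  if (inherits(x, "omics_matrix")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x))
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("one label per row required")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  class_sizes <- tabulate(y + 1L, nbins = 2L)
  if (any(class_sizes < 2L)) {
    stop("each class needs at least 2 samples for hit/miss search")
  }
  k <- config$k_neighbors
  k_max <- min(class_sizes) - 1L
  if (k > k_max) {
    if (clip_k) {
      warning(sprintf(
        "k_neighbors = %d exceeds min class size - 1; clipped to %d",
        k, k_max))
      k <- k_max
    } else {
      stop(sprintf(
        "a class has fewer than k_neighbors + 1 = %d samples; lower k_neighbors",
        k + 1L))
    }
  }
  n <- nrow(x)
  if (identical(config$n_sampled, "all") || config$n_sampled >= n) {
    eval_idx <- seq_len(n)
  } else {
    eval_idx <- with_seed(config$seed,
                          sort(sample.int(n, config$n_sampled)))
  }
  w <- relieff_weights_cpp(x, y, k, as.integer(eval_idx))
  names(w) <- colnames(x)
  w
}
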