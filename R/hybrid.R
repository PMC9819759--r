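#' Hybrid-weighting configuration
#'
#' @param alpha_grid candidate weighting factors in `[0, 1]` (default a 0.05
#'   grid); `alpha = 1` is pure classifier, `alpha = 0` pure collaborative
#'   filtering.
#' @param selection_metric cross-validation criterion used by
#'   [select_alpha()].
#' @param seed integer seed (reserved for stochastic selection metrics).
#' @return an object of class `hybrid_config`.
#' @export
hybrid_config <- function(alpha_grid = seq(0, 1, by = 0.05),
                          selection_metric = c("micro_auc", "recall_at_5"),
                          seed = 1L) {
  if (length(alpha_grid) == 0L || any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha_grid must be a nonempty set of values in [0, 1]", call. = FALSE)
  }
  structure(list(alpha_grid = sort(unique(alpha_grid)),
                 selection_metric = match.arg(selection_metric),
                 seed = as.integer(seed)),
            class = "hybrid_config")
}

#' Per-visit min-max normalization of a score matrix
#'
#' Classifier probabilities and factorization scores live on different
#' scales; rescaling each visit's scores to `[0, 1]` makes the hybrid weight
#' interpretable while preserving within-visit ranking. Constant rows map
#' to 0.5.
#'
#' @param s numeric visits x labels score matrix.
#' @return the rescaled matrix (dimnames and `model_tag` preserved).
#' @export
normalize_scores <- function(s) {
  s <- as.matrix(s)
  stopifnot(all(is.finite(s)))
  rng <- cbind(apply(s, 1L, min), apply(s, 1L, max))
  span <- rng[, 2L] - rng[, 1L]
  out <- (s - rng[, 1L]) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0.5
  attr(out, "model_tag") <- attr(s, "model_tag")
  out
}

#' Weighted combination of classification and collaborative-filtering scores
#'
#' `p = alpha * p_class + (1 - alpha) * p_collab`, elementwise. Inputs must
#' share shape and label order (normalize first; see [normalize_scores()]).
#'
#' @param p_class,p_collab numeric score matrices of identical shape and
#'   dimnames.
#' @param alpha weighting factor in `[0, 1]`.
#' @return the combined score matrix with `model_tag = "hybrid"`.
#' @export
combine_scores <- function(p_class, p_collab, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(dim(p_class), dim(p_collab)) ||
      !identical(colnames(p_class), colnames(p_collab))) {
    stop("score matrices must share shape and label order", call. = FALSE)
  }
  out <- alpha * unclass(p_class) + (1 - alpha) * unclass(p_collab)
  attr(out, "model_tag") <- "hybrid"
  out
}

#' Cross-validated selection of the hybrid weighting factor
#'
#' Evaluates every grid value of alpha on held-out fold scores and returns
#' the one maximizing the mean selection metric across folds. Ties are broken
#' toward the larger alpha, favouring the classifier component.
#'
#' @param fold_scores a list with one element per fold, each a list with
#'   normalized score matrices `class` and `collab` and the binary truth
#'   matrix `truth` for that fold's held-out visits.
#' @param config a [hybrid_config()].
#' @return a list with the selected `alpha` and the per-alpha CV `curve`.
#' @export
select_alpha <- function(fold_scores, config = hybrid_config()) {
  stopifnot(inherits(config, "hybrid_config"), length(fold_scores) > 0L)
  grid <- config$alpha_grid
  curve <- vapply(grid, function(a) {
    mean(vapply(fold_scores, function(f) {
      p <- combine_scores(f$class, f$collab, a)
      if (config$selection_metric == "micro_auc") {
        auroc_label(as.numeric(p), as.numeric(f$truth))
      } else {
        mean(topk_metrics(p, f$truth, 5L)$recall)
      }
    }, numeric(1L)))
  }, numeric(1L))
  best <- max(curve)
  alpha <- max(grid[curve >= best - 1e-12])   # tie-break toward larger alpha
  list(alpha = alpha, curve = data.frame(alpha = grid, metric = curve))
}
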