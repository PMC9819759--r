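## Ranked label order for one visit: descending score, lexicographic label
## tie-break (vote-fraction classifiers produce many ties).
rank_labels <- function(scores, labels = names(scores)) {
  if (is.null(labels)) labels <- sprintf("L%03d", seq_along(scores))
  order(-scores, labels)
}

#' Top-K ranking metrics for a single visit
#'
#' `recall_at_k` is the proportion of the actually prescribed drug groups
#' found in the top-K list; `precision_at_k` the proportion of the top-K list
#' that was actually prescribed; `hit_at_k` whether any top-K item was
#' prescribed; `ndcg_at_k` the rank-discounted gain normalized by the ideal
#' ranking (`DCG@K / IDCG@K` with gain `1/log2(i + 1)` at rank i).
#'
#' @param scores numeric score vector over drug groups (names used for
#'   deterministic tie-breaking).
#' @param truth binary vector, 1 for groups actually prescribed; must contain
#'   at least one positive.
#' @param k list length K (>= 1).
#' @return a proportion in `[0, 1]` (`hit_at_k`: 0 or 1).
#' @export
recall_at_k <- function(scores, truth, k) {
  hits <- topk_hits(scores, truth, k)
  hits / sum(truth)
}

#' @rdname recall_at_k
#' @export
precision_at_k <- function(scores, truth, k) {
  topk_hits(scores, truth, k) / k
}

#' @rdname recall_at_k
#' @export
hit_at_k <- function(scores, truth, k) {
  as.integer(topk_hits(scores, truth, k) >= 1L)
}

#' @rdname recall_at_k
#' @export
ndcg_at_k <- function(scores, truth, k) {
  check_instance(scores, truth, k)
  ord <- rank_labels(scores)[seq_len(min(k, length(scores)))]
  gains <- 1 / log2(seq_along(ord) + 1)
  dcg <- sum(gains[truth[ord] == 1])
  ideal <- min(k, sum(truth))
  idcg <- sum(1 / log2(seq_len(ideal) + 1))
  dcg / idcg
}

check_instance <- function(scores, truth, k) {
  stopifnot(length(scores) == length(truth), k >= 1, sum(truth) >= 1,
            all(is.finite(scores)))
}

topk_hits <- function(scores, truth, k) {
  check_instance(scores, truth, k)
  ord <- rank_labels(scores)[seq_len(min(k, length(scores)))]
  sum(truth[ord] == 1)
}

## Vectorized top-K metrics over the rows of a score matrix. Rows of `truth`
## without any positive are excluded (returned as NA).
topk_metrics <- function(scores, truth, k) {
  labels <- colnames(scores) %||% sprintf("L%03d", seq_len(ncol(scores)))
  n <- nrow(scores)
  rec <- prec <- hit <- ndcg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    if (sum(tr) < 1) next
    s <- stats::setNames(scores[i, ], labels)
    rec[i] <- recall_at_k(s, tr, k)
    prec[i] <- precision_at_k(s, tr, k)
    hit[i] <- hit_at_k(s, tr, k)
    ndcg[i] <- ndcg_at_k(s, tr, k)
  }
  list(recall = rec[!is.na(rec)], precision = prec[!is.na(prec)],
       hit = hit[!is.na(hit)], ndcg = ndcg[!is.na(ndcg)],
       n_excluded = sum(is.na(rec)))
}

#' Average precision for one label
#'
#' Step-function (non-interpolated) average precision over descending-score
#' thresholds: `AP = sum_n (R_n - R_{n-1}) P_n`, with tied scores treated as
#' a single threshold.
#'
#' @param scores numeric scores of all visits for this label.
#' @param truth binary vector; needs at least one positive and one negative.
#' @return AP in `[0, 1]`.
#' @export
average_precision_label <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  np <- as.numeric(sum(truth == 1))
  nn <- as.numeric(sum(truth == 0))
  if (np == 0 || nn == 0) {
    stop("degenerate label: needs at least one positive and one negative",
         call. = FALSE)
  }
  ord <- order(-scores)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y)
  pred_pos <- seq_along(y)
  last_of_threshold <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_threshold]
  pred_pos <- pred_pos[last_of_threshold]
  recall <- tp / np
  precision <- tp / pred_pos
  sum(diff(c(0, recall)) * precision)
}

#' Tie-corrected AUROC for one label
#'
#' Mann-Whitney formulation with midrank tie correction:
#' `P(score_pos > score_neg) + 0.5 * P(equal)`. Constant scores give exactly
#' 0.5, which is why the non-personalized bias-only recommender anchors at a
#' macro AUC of 50%.
#'
#' @inheritParams average_precision_label
#' @return AUROC in `[0, 1]`.
#' @export
auroc_label <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  np <- as.numeric(sum(truth == 1))
  nn <- as.numeric(sum(truth == 0))
  if (np == 0 || nn == 0) {
    stop("degenerate label: needs at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Aggregate a full metric report
#'
#' Computes the per-visit top-K metrics (averaged over visits with at least
#' one prescribed group), macro (unweighted over labels) and micro (pooled
#' over all visit-label pairs) AP and AUROC, and the per-label AUC table.
#' Labels without both a positive and a negative in `truth` are dropped from
#' the macro means, with the count reported via a message. All summary values
#' are percentages.
#'
#' @param scores numeric visits x drug-groups score matrix.
#' @param truth binary matrix of actual prescriptions, same shape.
#' @param k top-K list length.
#' @param model_tag provenance string for printing.
#' @return an object of class `metric_report`: a list with `recall_at_k`,
#'   `precision_at_k`, `hit_at_k`, `ndcg_at_k`, `macro_ap`, `micro_ap`,
#'   `macro_auc`, `micro_auc` (percent), `per_label`
#'   (group / n_positives / auc), `k`, `model_tag`.
#' @export
evaluate_scores <- function(scores, truth, k = 5L, model_tag = NULL) {
  scores <- as.matrix(scores)
  truth <- as.matrix(truth)
  stopifnot(identical(dim(scores), dim(truth)))
  labels <- colnames(scores) %||% sprintf("L%03d", seq_len(ncol(scores)))
  model_tag <- model_tag %||% attr(scores, "model_tag") %||% "model"

  tk <- topk_metrics(scores, truth, k)
  if (tk$n_excluded > 0L) {
    message(sprintf("excluding %d visit(s) with no prescribed group", tk$n_excluded))
  }
  if (length(tk$recall) == 0L) stop("no evaluable visits", call. = FALSE)

  n_pos <- colSums(truth)
  valid <- n_pos >= 1 & n_pos < nrow(truth)
  if (!any(valid)) stop("no evaluable labels", call. = FALSE)
  if (any(!valid)) {
    message(sprintf("excluding %d degenerate label(s) from macro averages",
                    sum(!valid)))
  }
  ap <- auc <- rep(NA_real_, length(labels))
  for (j in which(valid)) {
    ap[j] <- average_precision_label(scores[, j], truth[, j])
    auc[j] <- auroc_label(scores[, j], truth[, j])
  }
  structure(list(
    recall_at_k = 100 * mean(tk$recall),
    precision_at_k = 100 * mean(tk$precision),
    hit_at_k = 100 * mean(tk$hit),
    ndcg_at_k = 100 * mean(tk$ndcg),
    macro_ap = 100 * mean(ap[valid]),
    micro_ap = 100 * average_precision_label(as.numeric(scores), as.numeric(truth)),
    macro_auc = 100 * mean(auc[valid]),
    micro_auc = 100 * auroc_label(as.numeric(scores), as.numeric(truth)),
    per_label = data.frame(group = labels, n_positives = as.integer(n_pos),
                           auc = 100 * auc, stringsAsFactors = FALSE),
    k = k, model_tag = model_tag
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report [%s], K = %d\n", x$model_tag, x$k))
  v <- unlist(x[c("recall_at_k", "precision_at_k", "hit_at_k", "ndcg_at_k",
                  "macro_ap", "micro_ap", "macro_auc", "micro_auc")])
  names(v) <- c(sprintf(c("Recall@%d", "Precision@%d", "Hit@%d", "NDCG@%d"), x$k),
                "Macro AP", "Micro AP", "Macro AUC", "Micro AUC")
  print(round(v, 2))
  invisible(x)
}

#' Score threshold achieving a target pooled recall
#'
#' The largest threshold `t` such that at least `target` of all actual
#' prescriptions (pooled over visits and labels) have score `>= t`. Used to
#' turn scores into recommendation lists at, e.g., validation recall 0.80.
#'
#' @param scores numeric score matrix (or vector).
#' @param truth binary matrix (or vector) of the same shape.
#' @param target required pooled recall, in (0, 1).
#' @return the threshold, a scalar.
#' @export
threshold_for_recall <- function(scores, truth, target = 0.8) {
  stopifnot(target > 0, target < 1)
  pos <- as.numeric(scores)[as.numeric(truth) == 1]
  if (length(pos) == 0L) stop("no positives: recall target unreachable", call. = FALSE)
  sort(pos, decreasing = TRUE)[ceiling(target * length(pos))]
}

#' Recommendation lists above a threshold
#'
#' @param scores numeric visits x drug-groups score matrix.
#' @param t score threshold.
#' @return a list, per visit, of the drug groups with score `>= t`, sorted by
#'   descending score (lexicographic tie-break); may be empty.
#' @export
recommend_above_threshold <- function(scores, t) {
  labels <- colnames(scores) %||% sprintf("L%03d", seq_len(ncol(scores)))
  lapply(seq_len(nrow(scores)), function(i) {
    ord <- rank_labels(stats::setNames(scores[i, ], labels))
    keep <- ord[scores[i, ord] >= t]
    labels[keep]
  })
}

#' Stratified sample of test visits for expert review
#'
#' Greedy coverage sampling: iterate diagnosis codes by ascending test-set
#' frequency; for each, sample visits containing the code until it is covered
#' by at least `min_per_code` sampled visits; finally fill uniformly to
#' `n_items`. Guarantees every retained code appears in at least
#' `min_per_code` sampled visits.
#'
#' @param test an `encoded_visits` test set.
#' @param n_items sample size.
#' @param min_per_code minimum sampled visits per diagnosis code.
#' @param seed integer seed.
#' @return a character vector of `n_items` visit ids.
#' @export
stratified_eval_sample <- function(test, n_items = 200L, min_per_code = 10L,
                                   seed = 1L) {
  stopifnot(inherits(test, "encoded_visits"))
  counts <- colSums(test$X_dx)
  short <- counts < min_per_code
  if (any(short)) {
    stop("code(s) with fewer than min_per_code test visits: ",
         paste(test$dx_codes[short], collapse = ", "), call. = FALSE)
  }
  if (n_items > length(test$visit_ids)) {
    stop("n_items exceeds the number of test visits", call. = FALSE)
  }
  with_seed(derive_seed(seed, "eval_sample"), {
    sampled <- logical(length(test$visit_ids))
    for (j in order(counts)) {
      have <- sum(test$X_dx[sampled, j])
      if (have >= min_per_code) next
      cand <- which(!sampled & test$X_dx[, j] == 1)
      need <- min(min_per_code - have, length(cand))
      pick <- if (length(cand) == 1L) cand else sample(cand, need)
      sampled[pick[seq_len(need)]] <- TRUE
    }
    if (sum(sampled) > n_items) {
      stop(sprintf("covering every code needs %d visits > n_items = %d",
                   sum(sampled), n_items), call. = FALSE)
    }
    rest <- which(!sampled)
    fill <- if (length(rest) > 0L) sample(rest, n_items - sum(sampled)) else integer(0)
    sampled[fill] <- TRUE
    test$visit_ids[sampled]
  })
}

#' Per-rater acceptance percentages
#'
#' @param ratings an items x raters matrix (or data.frame) with entries
#'   `"agree"`/`"disagree"` (or logical, `TRUE` = agree).
#' @return a list with `per_rater` (percent agreement per rater) and `mean`
#'   (their arithmetic mean).
#' @export
acceptance_summary <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (length(ratings) == 0L) stop("empty rater table", call. = FALSE)
  agree <- if (is.logical(ratings)) ratings else ratings == "agree"
  if (any(is.na(agree))) stop("rater table must be complete", call. = FALSE)
  per <- 100 * colMeans(agree)
  list(per_rater = per, mean = mean(per))
}

#' Fleiss' kappa for a two-category rater table
#'
#' Chance-corrected agreement for a fixed set of raters judging every item:
#' `kappa = (Pbar - Pe) / (1 - Pe)` with the standard fixed-rater
#' formulation.
#'
#' @inheritParams acceptance_summary
#' @return kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  agree <- if (is.logical(ratings)) ratings else ratings == "agree"
  N <- nrow(agree); n <- ncol(agree)
  if (N < 2L || n < 2L) stop("need at least 2 items and 2 raters", call. = FALSE)
  if (any(is.na(agree))) stop("rater table must be complete", call. = FALSE)
  r <- rowSums(agree)
  P_i <- (r * (r - 1) + (n - r) * (n - r - 1)) / (n * (n - 1))
  P_bar <- mean(P_i)
  p <- sum(r) / (N * n)
  P_e <- p^2 + (1 - p)^2
  if (1 - P_e < .Machine$double.eps) {
    stop("all ratings fall in one category: kappa undefined", call. = FALSE)
  }
  (P_bar - P_e) / (1 - P_e)
}
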