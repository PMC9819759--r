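test_that("top-K metrics match their worked examples", {
  labels <- sprintf("g%02d", 1:8)
  # truth items ranked at positions 1 and 6
  s <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), labels)
  truth <- setNames(c(1, 0, 0, 0, 0, 1, 0, 0), labels)
  expect_equal(recall_at_k(s, truth, 5), 0.5)
  expect_equal(precision_at_k(s, truth, 5), 1 / 5)
  expect_equal(hit_at_k(s, truth, 5), 1L)

  # all of tau inside the top-3
  t3 <- setNames(c(1, 1, 1, 0, 0, 0, 0, 0), labels)
  expect_equal(recall_at_k(s, t3, 5), 1.0)
  expect_equal(ndcg_at_k(s, t3, 5), 1.0)

  # K covering all labels is exhaustive
  expect_equal(recall_at_k(s, truth, 8), 1.0)

  # single positive ranked second
  t1 <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0), labels)
  expect_equal(ndcg_at_k(s, t1, 5), 1 / log2(3), tolerance = 1e-12)
  expect_equal(round(ndcg_at_k(s, t1, 5), 4), 0.6309)

  # no overlap
  tn <- setNames(c(0, 0, 0, 0, 0, 0, 1, 1), labels)
  expect_equal(precision_at_k(s, tn, 5), 0)
  expect_equal(hit_at_k(s, tn, 5), 0L)
})

test_that("precision/recall/hit identities hold on random instances", {
  set.seed(31)
  labels <- sprintf("g%02d", 1:12)
  for (rep in 1:50) {
    s <- setNames(round(runif(12), 2), labels)  # rounded to force ties
    truth <- setNames(rbinom(12, 1, 0.4), labels)
    if (sum(truth) == 0) next
    k <- sample(1:12, 1)
    expect_equal(precision_at_k(s, truth, k) * k,
                 recall_at_k(s, truth, k) * sum(truth))
    expect_equal(hit_at_k(s, truth, k),
                 as.integer(recall_at_k(s, truth, k) > 0))
  }
})

test_that("average precision matches its threshold-enumeration example", {
  expect_equal(average_precision_label(c(0.9, 0.8, 0.7), c(0, 1, 0)), 0.5)
  expect_equal(average_precision_label(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1.0)
  # null baseline: AP tends to prevalence under random scores
  set.seed(7)
  truth <- rbinom(4000, 1, 0.3)
  ap <- average_precision_label(runif(4000), truth)
  expect_lt(abs(ap - 0.3), 0.05)
  expect_error(average_precision_label(c(1, 2), c(1, 1)), "degenerate")
})

test_that("AUROC uses midrank tie correction", {
  # scores (3, 2, 1), truth (1, 0, 1): pairs (3 > 2) and (1 < 2) -> 1/2
  expect_equal(auroc_label(c(3, 2, 1), c(1, 0, 1)), 0.5)
  expect_equal(oracle_auc(c(3, 2, 1), c(1, 0, 1)), 0.5)
  expect_equal(auroc_label(rep(1, 10), rbinom(10, 1, 0.5) * 0 + c(1, rep(0, 9))), 0.5)
  expect_equal(auroc_label(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1.0)
  set.seed(9)
  s <- round(runif(50), 1)
  y <- rbinom(50, 1, 0.5)
  if (sum(y) > 0 && sum(y) < 50) {
    expect_equal(auroc_label(s, y), oracle_auc(s, y))
  }
})

test_that("auroc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:5) {
    s <- round(runif(60), 1)
    y <- rbinom(60, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 60) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc_label(s, y), ref, tolerance = 1e-10)
  }
})

test_that("aggregate reports are internally consistent", {
  set.seed(13)
  S <- matrix(runif(40 * 6), 40, 6, dimnames = list(NULL, sprintf("g%d", 1:6)))
  Y <- matrix(rbinom(240, 1, 0.4), 40, 6, dimnames = dimnames(S))
  Y[1, ] <- c(1, rep(0, 5))  # ensure at least one positive in row 1
  rep_ <- suppressMessages(evaluate_scores(S, Y, k = 3))
  vals <- unlist(rep_[c("recall_at_k", "precision_at_k", "hit_at_k",
                        "ndcg_at_k", "macro_ap", "micro_ap", "macro_auc",
                        "micro_auc")])
  expect_true(all(vals >= 0 & vals <= 100))
  expect_equal(nrow(rep_$per_label), 6L)

  # single-label degenerate: macro equals micro equals the per-label value
  S1 <- S[, 1, drop = FALSE]
  Y1 <- Y[, 1, drop = FALSE]
  r1 <- suppressMessages(evaluate_scores(S1, Y1, k = 1))
  expect_equal(r1$macro_auc, r1$micro_auc)
  expect_equal(r1$macro_auc, r1$per_label$auc[1])

  # macro is prevalence-invariant, micro is not (2-label toy)
  Sa <- cbind(a = c(0.9, 0.8, 0.3, 0.2), b = c(0.6, 0.5, 0.4, 0.1))
  Ya <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  ra <- evaluate_scores(Sa, Ya, k = 2)
  expect_equal(ra$macro_auc, 100 * mean(c(
    auroc_label(Sa[, 1], Ya[, 1]), auroc_label(Sa[, 2], Ya[, 2]))))
  expect_false(isTRUE(all.equal(ra$micro_auc, ra$macro_auc)))
})

test_that("threshold selection achieves the pooled recall target", {
  # positives scored 0.9 / 0.7 / 0.5; 2/3 < 0.8 so the third must pass
  s <- c(0.9, 0.7, 0.5, 0.4, 0.3)
  y <- c(1, 1, 1, 0, 0)
  expect_equal(threshold_for_recall(s, y, 0.8), 0.5)
  expect_equal(threshold_for_recall(s, y, 0.01), 0.9)  # tiny target: max score
  expect_equal(threshold_for_recall(rep(1, 4), c(1, 1, 0, 0), 0.99), 1.0)
  expect_error(threshold_for_recall(s, rep(0, 5), 0.8), "no positives")

  set.seed(17)
  S <- matrix(runif(300), 50, 6)
  Y <- matrix(rbinom(300, 1, 0.3), 50, 6)
  t80 <- threshold_for_recall(S, Y, 0.8)
  got <- sum(S[Y == 1] >= t80) / sum(Y)
  expect_gte(got, 0.8)
  # largest such threshold: nudging it up breaks the target
  expect_lt(sum(S[Y == 1] > t80) / sum(Y), 0.8 + 1e-9)
})

test_that("threshold recommendations are ranked and respect the cutoff", {
  S <- rbind(c(a = 0.9, b = 0.2, c = 0.5), c(a = 0.1, b = 0.1, c = 0.05))
  recs <- recommend_above_threshold(S, 0.5)
  expect_equal(recs[[1]], c("a", "c"))
  expect_equal(recs[[2]], character(0))
  expect_equal(recommend_above_threshold(S, 2)[[1]], character(0))
  expect_equal(sort(recommend_above_threshold(S, -Inf)[[2]]), c("a", "b", "c"))
})

test_that("stratified sampling covers every code at least min_per_code times", {
  ds <- small_encoded(n_patients = 400, seed = 41)
  spl <- split_by_patient(ds, 0.35, seed = 1)
  te <- spl$test
  ok <- colSums(te$X_dx) >= 5
  te_ok <- rxrec:::subset_encoded(te, seq_along(te$visit_ids))
  te_ok$X_dx <- te$X_dx[, ok, drop = FALSE]
  te_ok$dx_codes <- te$dx_codes[ok]
  n_items <- min(200L, length(te_ok$visit_ids))
  ids <- stratified_eval_sample(te_ok, n_items = n_items, min_per_code = 5,
                                seed = 3)
  expect_length(ids, n_items)
  sel <- te_ok$X_dx[match(ids, te_ok$visit_ids), , drop = FALSE]
  expect_true(all(colSums(sel) >= 5))
  # determinism
  expect_identical(ids, stratified_eval_sample(te_ok, n_items = n_items,
                                               min_per_code = 5, seed = 3))
  # infeasible demands error and name the codes
  expect_error(stratified_eval_sample(te_ok, n_items = n_items,
                                      min_per_code = 10000),
               "fewer than")
})

test_that("acceptance summaries average per-rater percentages", {
  r <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE, FALSE), 4, 2)
  out <- acceptance_summary(r)
  expect_equal(unname(out$per_rater), c(50, 50))
  expect_equal(out$mean, 50)

  allagree <- matrix("agree", 3, 3)
  expect_equal(acceptance_summary(allagree)$mean, 100)
  two <- cbind(rep("agree", 4), rep("disagree", 4))
  expect_equal(acceptance_summary(two)$mean, 50)
})

test_that("fleiss kappa matches its fixed-rater formulation", {
  # unanimity with both categories present
  r <- rbind(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE))
  expect_equal(fleiss_kappa(r), 1)

  # chance-level table: P_bar equals P_e
  r0 <- rbind(c(TRUE, TRUE), c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(fleiss_kappa(r0), 0)

  # bounded in [-1, 1] on random complete tables
  set.seed(23)
  for (rep in 1:20) {
    rr <- matrix(rbinom(5 * 3, 1, runif(1, 0.2, 0.8)) == 1, 5, 3)
    if (all(rr) || all(!rr)) next
    k <- fleiss_kappa(rr)
    expect_gte(k, -1)
    expect_lte(k, 1)
  }

  expect_error(fleiss_kappa(matrix(TRUE, 3, 3)), "one category")
  expect_error(fleiss_kappa(matrix(TRUE, 1, 3)), "at least 2")
})
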