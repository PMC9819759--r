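make_count_table <- function(code_sets, drug_sets) {
  n <- length(code_sets)
  tab <- data.frame(
    visit_id = sprintf("V%d", seq_len(n)),
    patient_id = sprintf("P%d", seq_len(n)),
    age = rep(70, n), sex = rep("F", n),
    stringsAsFactors = FALSE
  )
  tab$dx_codes <- code_sets
  tab$drugs <- drug_sets
  class(tab) <- c("visit_table", "data.frame")
  tab
}

test_that("select_top ranks by count with lexicographic tie-break", {
  tab <- make_count_table(
    code_sets = c(rep(list("A"), 5), rep(list("B"), 3), list("C")),
    drug_sets = rep(list("d1"), 9)
  )
  v <- select_top(tab, n_dx = 2, n_drugs = 1)
  expect_equal(v$dx_codes, c("A", "B"))
  expect_true(min(v$dx_counts) >= 1)

  tie <- make_count_table(
    code_sets = c(rep(list("B"), 3), rep(list("A"), 3)),
    drug_sets = rep(list("d1"), 6)
  )
  expect_equal(select_top(tie, n_dx = 1, n_drugs = 1)$dx_codes, "A")

  expect_warning(select_top(tab, n_dx = 10, n_drugs = 1), "exceeds")
})

test_that("retention is monotone in n_dx", {
  sc <- small_cohort(n_patients = 80, seed = 13)
  for (n in c(5, 10, 20)) {
    v_small <- suppressWarnings(select_top(sc$tab, n, 60))
    v_big <- suppressWarnings(select_top(sc$tab, n + 5, 60))
    expect_true(all(v_small$dx_codes %in% v_big$dx_codes))
  }
})

test_that("apply_grouping deduplicates within groups and errors on unmapped drugs", {
  tab <- make_count_table(
    code_sets = list("A", "A"),
    drug_sets = list(c("simva", "atorva"), c("simva", "metf"))
  )
  m <- c(simva = "statins", atorva = "statins", metf = "antidiabetics")
  g <- apply_grouping(tab, m)
  expect_equal(g$drugs[[1]], "statins")              # merged, size 1
  expect_equal(g$drugs[[2]], c("antidiabetics", "statins"))  # distinct preserved

  expect_error(apply_grouping(tab, m[-3]), "metf")
})

test_that("encoding produces correct indicators and drops emptied visits", {
  tab <- make_count_table(
    code_sets = list(c("c1", "c_unknown"), c("c1", "c2"), "c_unknown"),
    drug_sets = list("g1", c("g1", "g2"), "g1")
  )
  expect_message(
    ds <- encode_visits(tab, dx_codes = c("c1", "c2"), drug_groups = c("g1", "g2")),
    "dropping 1")
  expect_equal(nrow(ds$X_dx), 2L)
  expect_equal(unname(ds$X_dx[1, ]), c(1L, 0L))
  expect_equal(unname(ds$X_dx[2, ]), c(1L, 1L))
  expect_equal(unname(ds$Y_drug[2, ]), c(1L, 1L))
  expect_equal(ds$sex_indicator, c(1L, 1L))
})

test_that("encode/decode is lossless over the retained vocabulary", {
  sc <- small_cohort(n_patients = 60, seed = 21)
  grouped <- apply_grouping(sc$tab, sc$vocab$truth$group_map)
  groups <- sort(unique(unlist(grouped$drugs)))
  ds <- suppressMessages(
    encode_visits(grouped, sc$vocab$dx_codes, groups))
  dec <- decode_visits(ds)
  keep <- match(dec$visit_id, grouped$visit_id)
  for (i in seq_len(nrow(dec))) {
    expect_equal(dec$dx_codes[[i]],
                 sort(intersect(grouped$dx_codes[[keep[i]]], sc$vocab$dx_codes)))
    expect_equal(dec$drugs[[i]], sort(grouped$drugs[[keep[i]]]))
  }
})

test_that("patient split is disjoint, deterministic and near the target fraction", {
  ds <- small_encoded(n_patients = 200, seed = 31)
  s1 <- split_by_patient(ds, 0.1, seed = 4)
  s2 <- split_by_patient(ds, 0.1, seed = 4)
  expect_identical(s1$test$visit_ids, s2$test$visit_ids)
  expect_length(intersect(unique(s1$train$patient_ids),
                          unique(s1$test$patient_ids)), 0L)
  frac <- length(s1$test$visit_ids) / length(ds$visit_ids)
  expect_lt(abs(frac - 0.1), 0.02)

  # property over seeds
  for (sd in 1:5) {
    sp <- split_by_patient(ds, 0.25, seed = sd)
    expect_length(intersect(unique(sp$train$patient_ids),
                            unique(sp$test$patient_ids)), 0L)
    expect_equal(sort(c(sp$train$visit_ids, sp$test$visit_ids)),
                 sort(ds$visit_ids))
  }

  one <- subset_rows <- which(ds$patient_ids == ds$patient_ids[1])
  single <- rxrec:::subset_encoded(ds, one)
  expect_error(split_by_patient(single, 0.1, 1), "2 patients")
})

test_that("CV folds partition patients and balance visit counts", {
  ds <- small_encoded(n_patients = 200, seed = 31)
  folds <- make_cv_folds(ds, k = 10, seed = 2)
  expect_length(folds, 10L)
  expect_equal(sort(unlist(folds)), seq_along(ds$visit_ids))
  # patient-disjoint
  pat_by_fold <- lapply(folds, function(ix) unique(ds$patient_ids[ix]))
  expect_equal(sum(lengths(pat_by_fold)),
               length(unique(ds$patient_ids)))
  # balanced within +-20% of each other
  sizes <- lengths(folds)
  expect_lt(max(sizes), 1.2 * min(sizes))
  # determinism
  expect_identical(folds, make_cv_folds(ds, k = 10, seed = 2))
  expect_error(make_cv_folds(ds, k = 1), "at least 2")
})
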