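## Tiny FNV-1a hash over a deparsed object; enough for provenance manifests.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

metric_row <- function(r) {
  data.frame(model = r$model_tag,
             recall_at_k = r$recall_at_k, precision_at_k = r$precision_at_k,
             hit_at_k = r$hit_at_k, ndcg_at_k = r$ndcg_at_k,
             macro_ap = r$macro_ap, micro_ap = r$micro_ap,
             macro_auc = r$macro_auc, micro_auc = r$micro_auc,
             stringsAsFactors = FALSE)
}

#' Compare metric reports across models
#'
#' One row per model in the canonical column order (Recall@K, Precision@K,
#' Hit@K, NDCG@K, Macro AP, Micro AP, Macro AUC, Micro AUC), with the best
#' model(s) per column flagged; ties flag all achievers.
#'
#' @param reports a list of `metric_report` objects.
#' @return a list with `table` (data.frame of percentages), `best` (logical
#'   matrix flagging per-column maxima) and `markdown` (a rendered table with
#'   the maxima in bold).
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2L)
  ks <- vapply(reports, function(r) r$k, numeric(1L))
  if (length(unique(ks)) != 1L) stop("reports use different K", call. = FALSE)
  tab <- do.call(rbind, lapply(reports, metric_row))
  vals <- as.matrix(tab[, -1L])
  best <- sweep(vals, 2L, apply(vals, 2L, max), ">=")
  hdr <- c("Model", sprintf(c("Recall@%d", "Precision@%d", "Hit@%d", "NDCG@%d"),
                            ks[1L]),
           "Macro AP", "Micro AP", "Macro AUC", "Micro AUC")
  fmt <- matrix(sprintf("%.2f", vals), nrow(vals))
  fmt[best] <- paste0("**", fmt[best], "**")
  md <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          vapply(seq_len(nrow(tab)), function(i) {
            paste0("| ", paste(c(tab$model[i], fmt[i, ]), collapse = " | "), " |")
          }, character(1L)))
  list(table = tab, best = best, markdown = paste(md, collapse = "\n"))
}

default_experiment_config <- function() {
  list(
    generator = list(),
    prep = list(n_dx = 40L, n_drugs = 60L, test_fraction = 0.1, cv_folds = 10L),
    models = list(
      classifiers = c("knn", "logreg", "rf", "mlp"),
      cf = c("most_popular", "cmf", "offsets"),
      fit = list(k = 10L, lambda_reg = 10, max_sweeps = 50L)
    ),
    hybrid = list(class_model = "mlp", collab_model = "offsets",
                  alpha = "auto", cv_folds = 3L),
    eval = list(K = 5L, recall_target = 0.80, eval_sample_n = 200L,
                min_per_code = 10L),
    seed = 1L
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

fit_one_model <- function(tag, train, fitcfg, seed) {
  if (tag %in% c("knn", "logreg", "rf", "mlp")) {
    fit_ovr(train, classifier_spec(tag), seed = derive_seed(seed, tag))
  } else {
    data <- build_interaction(train)
    cfg <- fit_config(k = fitcfg$k, lambda_reg = fitcfg$lambda_reg,
                      max_sweeps = fitcfg$max_sweeps,
                      seed = derive_seed(seed, tag))
    switch(tag,
           most_popular = fit_most_popular(data, cfg),
           cmf = fit_cmf(data, cfg),
           offsets = fit_offsets(data, cfg),
           stop("unknown model tag: ", tag, call. = FALSE))
  }
}

#' Run the full recommendation experiment
#'
#' Orchestrates generate, prepare, split, fit (classifiers and factorization
#' recommenders), hybrid weighting, and evaluation from a single nested
#' config (see `read_experiment_config()` for the YAML form). Every
#' stochastic stage derives its seed from `config$seed`, so reruns are
#' reproducible. When `output_dir` is given, metric reports, the model
#' comparison, per-label AUC tables, the recommended-drug frequency profile
#' at the target-recall threshold, and a provenance manifest are written as
#' JSON/Markdown files.
#'
#' @param config a nested list of overrides to the package defaults (sample
#'   sizes, model lists, hybrid settings, evaluation settings, seed).
#' @param output_dir optional directory for report artifacts.
#' @return a list: `reports` (per-model `metric_report`s, including
#'   `hybrid`), `comparison`, `alpha`, `threshold`, `recommended_freq`,
#'   `per_label`, `manifest`.
#' @export
run_experiment <- function(config = list(), output_dir = NULL) {
  cfg <- merge_config(default_experiment_config(), config)
  seed <- cfg$seed

  gen <- do.call(generator_config, c(cfg$generator, list(seed = derive_seed(seed, "gen"))))
  vocab <- generate_vocabulary(gen)
  cohort <- generate_cohort(gen, vocab)

  prep <- prepare_dataset(cohort, vocab$truth$group_map,
                          n_dx = cfg$prep$n_dx, n_drugs = cfg$prep$n_drugs)
  spl <- split_by_patient(prep$encoded, cfg$prep$test_fraction,
                          seed = derive_seed(seed, "split"))
  train <- spl$train; test <- spl$test

  tags <- c(cfg$models$classifiers, cfg$models$cf)
  models <- stats::setNames(
    lapply(tags, fit_one_model, train = train, fitcfg = cfg$models$fit,
           seed = seed),
    tags)
  scores <- lapply(models, function(mdl) predict(mdl, test))
  reports <- lapply(tags, function(tg) {
    evaluate_scores(scores[[tg]], test$Y_drug, k = cfg$eval$K, model_tag = tg)
  })
  names(reports) <- tags

  ## hybrid: cross-validated alpha over patient-disjoint folds of train
  ct <- cfg$hybrid$class_model
  cb <- cfg$hybrid$collab_model
  folds <- make_cv_folds(train, k = cfg$hybrid$cv_folds,
                         seed = derive_seed(seed, "hybrid_folds"))
  fold_scores <- lapply(seq_along(folds), function(f) {
    tr <- subset_encoded(train, setdiff(seq_along(train$visit_ids), folds[[f]]))
    ho <- subset_encoded(train, folds[[f]])
    mc <- fit_one_model(ct, tr, cfg$models$fit, derive_seed(seed, paste0("f", f)))
    mb <- fit_one_model(cb, tr, cfg$models$fit, derive_seed(seed, paste0("f", f)))
    list(class = normalize_scores(predict(mc, ho)),
         collab = normalize_scores(predict(mb, ho)),
         truth = ho$Y_drug)
  })
  if (identical(cfg$hybrid$alpha, "auto")) {
    sel <- select_alpha(fold_scores, hybrid_config())
    alpha <- sel$alpha
    curve <- sel$curve
  } else {
    alpha <- as.numeric(cfg$hybrid$alpha)
    curve <- NULL
  }
  hybrid_scores <- combine_scores(normalize_scores(scores[[ct]]),
                                  normalize_scores(scores[[cb]]), alpha)
  reports$hybrid <- evaluate_scores(hybrid_scores, test$Y_drug,
                                    k = cfg$eval$K, model_tag = "hybrid")

  comparison <- compare_models(reports)

  ## threshold at target recall from the pooled out-of-fold hybrid scores
  val_scores <- do.call(rbind, lapply(fold_scores, function(f) {
    combine_scores(f$class, f$collab, alpha)
  }))
  val_truth <- do.call(rbind, lapply(fold_scores, function(f) f$truth))
  thr <- threshold_for_recall(val_scores, val_truth, cfg$eval$recall_target)
  recs <- recommend_above_threshold(hybrid_scores, thr)
  rec_freq <- table(factor(unlist(recs), levels = test$drug_groups))
  rec_freq <- stats::setNames(as.integer(rec_freq), names(rec_freq))

  per_label <- lapply(reports[c(ct, cb, "hybrid")], function(r) r$per_label)

  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   package_version = as.character(utils::packageVersion("rxrec")),
                   n_train_visits = length(train$visit_ids),
                   n_test_visits = length(test$visit_ids),
                   alpha = alpha, threshold = thr)

  bundle <- list(reports = reports, comparison = comparison, alpha = alpha,
                 alpha_curve = curve, threshold = thr,
                 recommended_freq = rec_freq, per_label = per_label,
                 manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (tg in names(reports)) {
      r <- reports[[tg]]
      jsonlite::write_json(r[setdiff(names(r), "per_label")],
                           file.path(output_dir, paste0("metrics_", tg, ".json")),
                           auto_unbox = TRUE, digits = 10)
    }
    jsonlite::write_json(comparison$table,
                         file.path(output_dir, "comparison.json"), digits = 10)
    writeLines(comparison$markdown, file.path(output_dir, "comparison.md"))
    for (tg in names(per_label)) {
      utils::write.csv(per_label[[tg]],
                       file.path(output_dir, paste0("per_label_auc_", tg, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(as.list(rec_freq),
                         file.path(output_dir, "recommended_freq.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  bundle
}
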