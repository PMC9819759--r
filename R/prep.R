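## Presence counts: one occurrence per visit, descending count with
## lexicographic tie-break.
presence_counts <- function(sets) {
  cnt <- table(unlist(lapply(sets, unique)))
  cnt <- cnt[order(-as.integer(cnt), names(cnt))]
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Select the most frequent diagnosis codes and generic drugs
#'
#' Frequency filtering before encoding: keeps the `n_dx` most frequent
#' diagnosis codes and the `n_drugs` most frequent generic drugs, counting one
#' occurrence per visit (presence semantics). Ties are broken
#' lexicographically so the selection is deterministic.
#'
#' @param table a `visit_table` (drugs still at generic level).
#' @param n_dx number of diagnosis codes to retain.
#' @param n_drugs number of generic drugs to retain.
#' @return a list of class `rx_vocabulary` with `dx_codes`, `drugs` and the
#'   corresponding named count vectors `dx_counts`, `drug_counts`.
#' @export
select_top <- function(table, n_dx, n_drugs) {
  stopifnot(inherits(table, "visit_table"), nrow(table) > 0)
  dxc <- presence_counts(table$dx_codes)
  drc <- presence_counts(table$drugs)
  if (n_dx > length(dxc)) {
    warning(sprintf("n_dx = %d exceeds %d distinct codes; retaining all",
                    n_dx, length(dxc)))
    n_dx <- length(dxc)
  }
  if (n_drugs > length(drc)) {
    warning(sprintf("n_drugs = %d exceeds %d distinct drugs; retaining all",
                    n_drugs, length(drc)))
    n_drugs <- length(drc)
  }
  structure(list(
    dx_codes = names(dxc)[seq_len(n_dx)],
    drugs = names(drc)[seq_len(n_drugs)],
    dx_counts = dxc[seq_len(n_dx)],
    drug_counts = drc[seq_len(n_drugs)]
  ), class = "rx_vocabulary")
}

#' Restrict a visit table to a retained drug vocabulary
#'
#' Drops drugs outside `drugs` from each visit; visits whose drug set becomes
#' empty are dropped (mirroring the exclusion of visits without
#' prescriptions), with the number reported via a message.
#'
#' @param table a `visit_table`.
#' @param drugs character vector of retained generic drugs.
#' @return the filtered `visit_table`.
#' @export
restrict_drugs <- function(table, drugs) {
  stopifnot(inherits(table, "visit_table"))
  table$drugs <- lapply(table$drugs, function(d) d[d %in% drugs])
  empty <- lengths(table$drugs) == 0L
  if (any(empty)) {
    message(sprintf("dropping %d visit(s) with no retained drugs", sum(empty)))
    table <- table[!empty, , drop = FALSE]
    class(table) <- c("visit_table", "data.frame")
  }
  table
}

#' Replace generic drugs by their therapeutic groups
#'
#' Each visit's drug set becomes the deduplicated set of therapeutic groups of
#' its drugs. Every drug present in the table must be mapped.
#'
#' @param table a `visit_table` with generic-level drugs.
#' @param group_map named character vector, generic -> group.
#' @return a `visit_table` whose `drugs` column holds group labels.
#' @export
apply_grouping <- function(table, group_map) {
  stopifnot(inherits(table, "visit_table"))
  seen <- unique(unlist(table$drugs))
  unmapped <- setdiff(seen, names(group_map))
  if (length(unmapped) > 0L) {
    stop("drugs missing from group map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  table$drugs <- lapply(table$drugs,
                        function(d) sort(unique(unname(group_map[d]))))
  table
}

#' Encode a visit table as binary indicator matrices
#'
#' Builds the visits x codes and visits x drug-groups 0/1 matrices along with
#' demographic columns. Codes or groups outside the supplied vocabularies are
#' dropped; visits whose retained diagnosis or drug set becomes empty are
#' dropped, with the count reported via a message.
#'
#' @param table a `visit_table` whose `drugs` column holds group labels (see
#'   [apply_grouping()]).
#' @param dx_codes ordered character vector of retained diagnosis codes.
#' @param drug_groups ordered character vector of retained drug groups.
#' @return a list of class `encoded_visits`: `X_dx`, `Y_drug` (binary
#'   matrices), `age`, `sex_indicator` (1 = female), `visit_ids`,
#'   `patient_ids`, and the vocabularies as `dx_codes`, `drug_groups`.
#' @export
encode_visits <- function(table, dx_codes, drug_groups) {
  stopifnot(inherits(table, "visit_table"))
  keep_dx <- lapply(table$dx_codes, function(s) s[s %in% dx_codes])
  keep_dr <- lapply(table$drugs, function(s) s[s %in% drug_groups])
  drop <- lengths(keep_dx) == 0L | lengths(keep_dr) == 0L
  if (any(drop)) {
    message(sprintf("dropping %d visit(s) emptied by vocabulary filtering",
                    sum(drop)))
  }
  keep <- !drop
  keep_dx <- keep_dx[keep]
  keep_dr <- keep_dr[keep]
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)

  X <- matrix(0L, n, length(dx_codes), dimnames = list(NULL, dx_codes))
  if (n > 0) {
    X[cbind(rep(seq_len(n), lengths(keep_dx)),
            match(unlist(keep_dx), dx_codes))] <- 1L
  }
  Y <- matrix(0L, n, length(drug_groups), dimnames = list(NULL, drug_groups))
  if (n > 0) {
    Y[cbind(rep(seq_len(n), lengths(keep_dr)),
            match(unlist(keep_dr), drug_groups))] <- 1L
  }
  structure(list(
    X_dx = X, Y_drug = Y,
    age = tab$age, sex_indicator = as.integer(tab$sex == "F"),
    visit_ids = tab$visit_id, patient_ids = tab$patient_id,
    dx_codes = dx_codes, drug_groups = drug_groups
  ), class = "encoded_visits")
}

#' Recover per-visit code and group sets from an encoded dataset
#'
#' Inverse of [encode_visits()] over the retained vocabulary; used to verify
#' that encoding is lossless.
#'
#' @param ds an `encoded_visits` object.
#' @return a data.frame with `visit_id` and list-columns `dx_codes`, `drugs`.
#' @export
decode_visits <- function(ds) {
  stopifnot(inherits(ds, "encoded_visits"))
  out <- data.frame(visit_id = ds$visit_ids, stringsAsFactors = FALSE)
  out$dx_codes <- apply(ds$X_dx, 1L, function(r) sort(ds$dx_codes[r == 1]),
                        simplify = FALSE)
  out$drugs <- apply(ds$Y_drug, 1L, function(r) sort(ds$drug_groups[r == 1]),
                     simplify = FALSE)
  out
}

## Row subset of an encoded dataset.
subset_encoded <- function(ds, idx) {
  structure(list(
    X_dx = ds$X_dx[idx, , drop = FALSE],
    Y_drug = ds$Y_drug[idx, , drop = FALSE],
    age = ds$age[idx], sex_indicator = ds$sex_indicator[idx],
    visit_ids = ds$visit_ids[idx], patient_ids = ds$patient_ids[idx],
    dx_codes = ds$dx_codes, drug_groups = ds$drug_groups
  ), class = "encoded_visits")
}

#' Patient-disjoint train/test split
#'
#' Partitions patients (never visits) between train and test. Patients are
#' shuffled with the given seed and a cut is chosen so the realized test
#' visit fraction is as close as possible to `test_fraction`.
#'
#' @param ds an `encoded_visits` object.
#' @param test_fraction target fraction of visits in the test set, in (0, 1).
#' @param seed integer seed.
#' @return a list with `encoded_visits` elements `train` and `test`.
#' @export
split_by_patient <- function(ds, test_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(ds, "encoded_visits"),
            test_fraction > 0, test_fraction < 1)
  patients <- unique(ds$patient_ids)
  if (length(patients) < 2L) {
    stop("cannot split fewer than 2 patients", call. = FALSE)
  }
  with_seed(derive_seed(seed, "split"), {
    patients <- sample(patients)
    visits_per <- as.integer(table(ds$patient_ids)[patients])
    cum <- cumsum(visits_per)
    target <- test_fraction * length(ds$visit_ids)
    cut <- which.min(abs(cum - target))
    test_pat <- patients[seq_len(cut)]
    test_idx <- which(ds$patient_ids %in% test_pat)
    list(train = subset_encoded(ds, setdiff(seq_along(ds$visit_ids), test_idx)),
         test = subset_encoded(ds, test_idx))
  })
}

#' Patient-disjoint cross-validation folds
#'
#' Assigns every patient to exactly one of `k` folds, balancing fold visit
#' counts greedily (largest patients first, each to the currently lightest
#' fold, with seeded random tie-breaking).
#'
#' @param ds an `encoded_visits` object.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return a list of `k` integer vectors of row indices into `ds`.
#' @export
make_cv_folds <- function(ds, k = 10L, seed = 1L) {
  stopifnot(inherits(ds, "encoded_visits"))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  patients <- unique(ds$patient_ids)
  if (length(patients) < k) {
    stop("fewer patients than folds", call. = FALSE)
  }
  with_seed(derive_seed(seed, "folds"), {
    counts <- table(ds$patient_ids)[patients]
    ord <- sample(seq_along(patients))               # random tie-breaking
    ord <- ord[order(-as.integer(counts)[ord])]
    load <- numeric(k)
    assign <- integer(length(patients))
    for (i in ord) {
      f <- which.min(load)
      assign[i] <- f
      load[f] <- load[f] + as.integer(counts)[i]
    }
    fold_of_visit <- assign[match(ds$patient_ids, patients)]
    lapply(seq_len(k), function(f) which(fold_of_visit == f))
  })
}

#' End-to-end data preparation
#'
#' The full preparation flow: frequency-filter generics and codes, drop
#' visits left without retained drugs, map generics to therapeutic groups,
#' order group labels by frequency, and encode to indicator matrices.
#'
#' @param table a `visit_table` at generic-drug level.
#' @param group_map named character vector, generic -> group.
#' @param n_dx,n_drugs vocabulary sizes passed to [select_top()].
#' @return a list with `encoded` (an `encoded_visits`) and `vocab` (the
#'   generic-level `rx_vocabulary`).
#' @export
prepare_dataset <- function(table, group_map, n_dx = 40L, n_drugs = 60L) {
  vocab <- select_top(table, n_dx, n_drugs)
  tab <- restrict_drugs(table, vocab$drugs)
  grouped <- apply_grouping(tab, group_map)
  gcounts <- presence_counts(grouped$drugs)
  encoded <- encode_visits(grouped, vocab$dx_codes, names(gcounts))
  list(encoded = encoded, vocab = vocab)
}
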