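# Fixtures are built in code at test time; nothing is read from disk.

# A 3-visit table with known contents, used by io/prep tests.
tiny_visit_table <- function() {
  tab <- data.frame(
    visit_id = c("V1", "V2", "V3"),
    patient_id = c("P1", "P1", "P2"),
    age = c(70.5, 71.0, 80.0),
    sex = c("F", "F", "M"),
    stringsAsFactors = FALSE
  )
  tab$dx_codes <- list(c("B", "A"), "A", c("C", "A"))
  tab$drugs <- list("simva", c("atorva", "metf"), "metf")
  class(tab) <- c("visit_table", "data.frame")
  tab
}

# Small generated cohort shared by several test files.
small_cohort <- function(n_patients = 150, seed = 42) {
  cfg <- generator_config(n_patients = n_patients, seed = seed)
  vocab <- generate_vocabulary(cfg)
  tab <- generate_cohort(cfg, vocab)
  list(cfg = cfg, vocab = vocab, tab = tab)
}

small_encoded <- function(n_patients = 150, seed = 42) {
  sc <- small_cohort(n_patients, seed)
  prep <- suppressWarnings(
    suppressMessages(prepare_dataset(sc$tab, sc$vocab$truth$group_map)))
  prep$encoded
}

# ---- independent brute-force metric oracles -------------------------------
# Same tie rule as the package contract (descending score, lexicographic
# label) but computed by naive enumeration, never by the package's code path.

oracle_topk <- function(scores, labels, k) {
  remaining <- seq_along(scores)
  picked <- integer(0)
  while (length(picked) < min(k, length(scores))) {
    best <- remaining[1]
    for (j in remaining) {
      if (scores[j] > scores[best] ||
          (scores[j] == scores[best] && labels[j] < labels[best])) {
        best <- j
      }
    }
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  picked
}

oracle_recall <- function(scores, truth, labels, k) {
  top <- oracle_topk(scores, labels, k)
  sum(truth[top] == 1) / sum(truth == 1)
}

oracle_precision <- function(scores, truth, labels, k) {
  top <- oracle_topk(scores, labels, k)
  sum(truth[top] == 1) / k
}

oracle_hit <- function(scores, truth, labels, k) {
  as.integer(oracle_recall(scores, truth, labels, k) > 0)
}

oracle_ndcg <- function(scores, truth, labels, k) {
  top <- oracle_topk(scores, labels, k)
  dcg <- 0
  for (i in seq_along(top)) {
    if (truth[top[i]] == 1) dcg <- dcg + 1 / log2(i + 1)
  }
  idcg <- 0
  for (i in seq_len(min(k, sum(truth == 1)))) idcg <- idcg + 1 / log2(i + 1)
  dcg / idcg
}

oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

oracle_ap <- function(scores, truth) {
  np <- sum(truth == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(truth[sel] == 1)
    r <- tp / np
    p <- tp / sum(sel)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# ---- cached default-scale cohort for the acceptance suite -----------------

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.acceptance_cache$data)) {
    cfg <- generator_config()                 # package defaults
    vocab <- generate_vocabulary(cfg)
    tab <- generate_cohort(cfg, vocab)
    prep <- suppressWarnings(
      suppressMessages(prepare_dataset(tab, vocab$truth$group_map)))
    spl <- split_by_patient(prep$encoded, 0.1, seed = cfg$seed)
    .acceptance_cache$data <- list(cfg = cfg, vocab = vocab,
                                   encoded = prep$encoded,
                                   train = spl$train, test = spl$test)
  }
  .acceptance_cache$data
}
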