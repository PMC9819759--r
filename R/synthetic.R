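#' Configuration for the synthetic outpatient cohort generator
#'
#' Bundles and validates the marginal statistics the generator targets. The
#' defaults emulate an elderly primary-care population with diabetes,
#' hypertension and dyslipidemia: roughly 7.25 visits per patient, 3.82
#' diagnosis codes and 6.36 drugs per visit, 57.7% female, ages 65-105, with
#' long-tailed (Zipf-like) code frequencies, 40 retained diagnosis codes and
#' 60 generic drugs grouped into 30 therapeutic groups.
#'
#' @param n_patients number of patients to simulate.
#' @param n_dx_codes number of distinct diagnosis codes in the vocabulary.
#' @param n_generic_drugs number of distinct generic drug names.
#' @param n_drug_groups number of therapeutic groups; must not exceed
#'   `n_generic_drugs`.
#' @param mean_visits_per_patient target mean visits per patient.
#' @param mean_dx_per_visit target mean diagnosis codes per visit.
#' @param mean_drugs_per_visit target mean prescribed drugs per visit.
#' @param female_fraction proportion of female patients, in `[0, 1]`.
#' @param age_range two-element numeric vector of admissible ages in years.
#' @param zipf_exponent exponent of the rank-frequency law for non-anchor
#'   diagnosis codes; larger values concentrate mass on the most common codes.
#' @param seed integer seed; every stochastic step of the generator derives
#'   its stream from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 4000,
                             n_dx_codes = 40,
                             n_generic_drugs = 60,
                             n_drug_groups = 30,
                             mean_visits_per_patient = 7.25,
                             mean_dx_per_visit = 3.82,
                             mean_drugs_per_visit = 6.36,
                             female_fraction = 0.577,
                             age_range = c(65, 105),
                             zipf_exponent = 1.1,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_dx_codes = as.integer(n_dx_codes),
    n_generic_drugs = as.integer(n_generic_drugs),
    n_drug_groups = as.integer(n_drug_groups),
    mean_visits_per_patient = mean_visits_per_patient,
    mean_dx_per_visit = mean_dx_per_visit,
    mean_drugs_per_visit = mean_drugs_per_visit,
    female_fraction = female_fraction,
    age_range = as.numeric(age_range),
    zipf_exponent = zipf_exponent,
    seed = as.integer(seed)
  )
  if (cfg$n_drug_groups > cfg$n_generic_drugs) {
    stop("n_drug_groups must not exceed n_generic_drugs", call. = FALSE)
  }
  if (cfg$n_patients < 1L || cfg$n_dx_codes < 3L) {
    stop("need at least 1 patient and 3 diagnosis codes (anchors)", call. = FALSE)
  }
  means <- c(cfg$mean_visits_per_patient, cfg$mean_dx_per_visit,
             cfg$mean_drugs_per_visit)
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("all target means must be positive", call. = FALSE)
  }
  if (cfg$mean_dx_per_visit > cfg$n_dx_codes) {
    stop("mean_dx_per_visit cannot exceed n_dx_codes", call. = FALSE)
  }
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1) {
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    stop("age_range must be an increasing pair", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

## Zipf probabilities over code ranks 1..n (anchors occupy the top ranks).
zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

## Draw per-visit diagnosis-code index sets: one anchor forced, the remaining
## codes Zipf-distributed without replacement. Returns a list of integer sets.
draw_dx_sets <- function(n_visits, config) {
  n_codes <- config$n_dx_codes
  probs <- zipf_probs(n_codes, config$zipf_exponent)
  extra <- stats::rpois(n_visits, max(config$mean_dx_per_visit - 1, 0))
  extra <- pmin(extra, n_codes - 1L)
  anchors <- sample.int(3L, n_visits, replace = TRUE)
  lapply(seq_len(n_visits), function(i) {
    set <- anchors[i]
    if (extra[i] > 0L) {
      p <- probs
      p[set] <- 0
      more <- sample.int(n_codes, extra[i], replace = FALSE, prob = p)
      set <- c(set, more)
    }
    sort.int(set)
  })
}

## Ages: shifted gamma (mode near 72), resampled into the configured range.
draw_ages <- function(n, config) {
  lo <- config$age_range[1]
  hi <- config$age_range[2]
  age <- lo + stats::rgamma(n, shape = 3, scale = 10 / 3)
  bad <- which(age > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    age[bad] <- lo + stats::rgamma(length(bad), shape = 3, scale = 10 / 3)
    bad <- which(age > hi)
    tries <- tries + 1L
  }
  pmin(age, hi)
}

#' Generate the synthetic vocabulary and planted prescription model
#'
#' Creates the diagnosis-code vocabulary (with three anchor codes standing in
#' for the cohort-defining diabetes/hypertension/dyslipidemia diagnoses), the
#' generic-drug vocabulary, a many-to-one map from generics to therapeutic
#' groups, and the planted logistic weights that drive prescribing. Group
#' intercepts are calibrated by bisection so that the implied mean number of
#' drugs per visit matches `config$mean_drugs_per_visit`, and they are spread
#' on the logit scale so per-group prescription prevalences span well over an
#' order of magnitude (a long-tailed group-frequency profile).
#'
#' @param config a [generator_config()].
#' @return a list with elements `dx_codes` (character; attribute `anchors`
#'   marks the three anchor codes), `drugs` (character), and `truth`, the
#'   planted model: `W` (groups x codes sparse weight matrix, each row with
#'   1-4 nonzero entries), `w0` (calibrated intercepts), `w_age`, `w_sex`,
#'   and `group_map` (named character vector, generic -> group).
#' @export
generate_vocabulary <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(derive_seed(config$seed, "vocabulary"), {
    anchors <- c("E11x", "I10x", "E78x")
    n_other <- config$n_dx_codes - 3L
    dx_codes <- c(anchors, sprintf("C%03d", seq_len(n_other)))
    attr(dx_codes, "anchors") <- anchors

    drugs <- sprintf("drug_%02d", seq_len(config$n_generic_drugs))
    groups <- sprintf("G%02d", seq_len(config$n_drug_groups))
    ## surjective assignment: first |groups| generics pin one group each,
    ## the remainder spread uniformly
    assign <- c(seq_len(config$n_drug_groups),
                sample.int(config$n_drug_groups,
                           config$n_generic_drugs - config$n_drug_groups,
                           replace = TRUE))
    group_map <- stats::setNames(groups[assign], drugs)

    G <- config$n_drug_groups
    ## Indications attach preferentially to the common chronic-disease codes
    ## (anchor diagnoses and the head of the Zipf tail): a drug group is
    ## driven by 1-4 codes sampled with probability proportional to code
    ## frequency, with mostly-positive weights (occasional negative entries
    ## play the role of contraindications).
    code_freq <- zipf_probs(config$n_dx_codes, config$zipf_exponent)
    W <- matrix(0, nrow = G, ncol = config$n_dx_codes,
                dimnames = list(groups, dx_codes))
    for (g in seq_len(G)) {
      nz <- sample.int(4L, 1L)
      cols <- sample.int(config$n_dx_codes, nz, prob = code_freq)
      W[g, cols] <- stats::runif(nz, 1.5, 3.5) *
        sample(c(-1, 1), nz, replace = TRUE, prob = c(0.2, 0.8))
    }
    w_age <- stats::rnorm(G, 0, 0.3)
    w_sex <- stats::rnorm(G, 0, 0.3)

    ## intercept spread: prevalence targets log-spaced 0.75 down to 0.02,
    ## then a common shift calibrated so E[drugs/visit] hits the target
    base_prev <- exp(seq(log(0.75), log(0.02), length.out = G))
    w0 <- stats::qlogis(base_prev)

    sim_n <- 3000L
    dx_sets <- draw_dx_sets(sim_n, config)
    ages <- draw_ages(sim_n, config)
    female <- stats::rbinom(sim_n, 1L, config$female_fraction)
    Xdx <- matrix(0, sim_n, config$n_dx_codes)
    Xdx[cbind(rep(seq_len(sim_n), lengths(dx_sets)), unlist(dx_sets))] <- 1
    base_lp <- Xdx %*% t(W) +
      outer((ages - 75) / 10, w_age) + outer(female, w_sex)

    mean_drugs <- function(delta) {
      mean(rowSums(sigmoid(sweep(base_lp, 2L, w0 + delta, "+"))))
    }
    lo <- -8; hi <- 8
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      if (mean_drugs(mid) < config$mean_drugs_per_visit) lo <- mid else hi <- mid
    }
    w0 <- w0 + (lo + hi) / 2

    list(dx_codes = dx_codes, drugs = drugs,
         truth = list(W = W, w0 = w0, w_age = w_age, w_sex = w_sex,
                      group_map = group_map))
  })
}

#' Generate a synthetic visit table from the planted model
#'
#' Simulates patients (sex, age, overdispersed visit counts) and visits
#' (anchor-plus-Zipf diagnosis sets, logistic group prescribing), then
#' materializes each prescribed therapeutic group as one uniformly chosen
#' generic drug from that group. Visit counts are `1 + NB(size = 1)` targeting
#' the configured mean, mimicking the heavy overdispersion seen in real
#' outpatient data. Visits in which no group is prescribed are redrawn, so
#' every emitted visit carries at least one diagnosis code and one drug.
#'
#' @param config a [generator_config()].
#' @param vocab the result of [generate_vocabulary()] for the same config.
#' @return a `data.frame` of class `visit_table` with columns `visit_id`,
#'   `patient_id`, `age`, `sex` and list-columns `dx_codes`, `drugs` (sorted
#'   character sets).
#' @export
generate_cohort <- function(config, vocab) {
  stopifnot(inherits(config, "generator_config"),
            is.list(vocab), !is.null(vocab$truth))
  truth <- vocab$truth
  with_seed(derive_seed(config$seed, "cohort"), {
    n_pat <- config$n_patients
    female <- stats::rbinom(n_pat, 1L, config$female_fraction)
    age <- draw_ages(n_pat, config)
    n_visits_pat <- 1L + stats::rnbinom(
      n_pat, size = 1, mu = max(config$mean_visits_per_patient - 1, 0.01))
    n_vis <- sum(n_visits_pat)

    pat_idx <- rep.int(seq_len(n_pat), n_visits_pat)
    dx_sets <- draw_dx_sets(n_vis, config)

    Xdx <- matrix(0, n_vis, config$n_dx_codes)
    Xdx[cbind(rep(seq_len(n_vis), lengths(dx_sets)), unlist(dx_sets))] <- 1
    lp <- sweep(Xdx %*% t(truth$W), 2L, truth$w0, "+") +
      outer((age[pat_idx] - 75) / 10, truth$w_age) +
      outer(female[pat_idx], truth$w_sex)
    P <- sigmoid(lp)

    Rx <- matrix(stats::runif(length(P)), nrow(P)) < P
    for (it in seq_len(100L)) {
      empty <- which(rowSums(Rx) == 0L)
      if (length(empty) == 0L) break
      Rx[empty, ] <- matrix(stats::runif(length(empty) * ncol(P)),
                            length(empty)) < P[empty, , drop = FALSE]
    }
    empty <- which(rowSums(Rx) == 0L)
    if (length(empty) > 0L) {
      Rx[cbind(empty, max.col(P[empty, , drop = FALSE]))] <- TRUE
    }

    groups <- rownames(truth$W)
    generics_by_group <- split(names(truth$group_map), truth$group_map)
    drugs <- lapply(seq_len(n_vis), function(i) {
      gs <- groups[Rx[i, ]]
      sort(vapply(generics_by_group[gs], function(cand) {
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, character(1L), USE.NAMES = FALSE))
    })

    dx_codes <- lapply(dx_sets, function(ix) sort(as.character(vocab$dx_codes[ix])))
    tab <- data.frame(
      visit_id = sprintf("V%06d", seq_len(n_vis)),
      patient_id = sprintf("P%05d", pat_idx),
      age = round(age[pat_idx], 1),
      sex = ifelse(female[pat_idx] == 1L, "F", "M"),
      stringsAsFactors = FALSE
    )
    tab$dx_codes <- dx_codes
    tab$drugs <- drugs
    class(tab) <- c("visit_table", "data.frame")
    tab
  })
}

#' Descriptive summary of a visit table
#'
#' Per-cohort counts and per-visit means in the layout of a descriptive
#' statistics table: visits, patients, visits per patient, mean codes and
#' drugs per visit (computed with [per_visit_mean()]), female fraction and
#' the age distribution.
#'
#' @param table a `visit_table`.
#' @return a list of summary statistics.
#' @export
cohort_summary <- function(table) {
  stopifnot(inherits(table, "visit_table"))
  n_vis <- nrow(table)
  pat <- unique(table$patient_id)
  list(
    n_visits = n_vis,
    n_patients = length(pat),
    mean_visits_per_patient = n_vis / length(pat),
    total_dx = sum(lengths(table$dx_codes)),
    total_drugs = sum(lengths(table$drugs)),
    mean_dx_per_visit = per_visit_mean(sum(lengths(table$dx_codes)), n_vis),
    mean_drugs_per_visit = per_visit_mean(sum(lengths(table$drugs)), n_vis),
    female_fraction = mean(table$sex[!duplicated(table$patient_id)] == "F"),
    age_mean = mean(table$age),
    age_sd = stats::sd(table$age)
  )
}

#' @export
print.visit_table <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf(
    "Synthetic visit table: %d visits, %d patients (%.1f visits/patient)\n",
    s$n_visits, s$n_patients, s$mean_visits_per_patient))
  cat(sprintf("  mean dx codes/visit %.2f, mean drugs/visit %.2f, %.1f%% female\n",
              s$mean_dx_per_visit, s$mean_drugs_per_visit,
              100 * s$female_fraction))
  invisible(x)
}
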