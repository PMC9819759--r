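#' Fitting configuration for the factorization recommenders
#'
#' @param k latent dimension (>= 1).
#' @param lambda_reg L2 regularization strength applied to every factor block
#'   and both bias vectors; must be positive (unregularized alternating least
#'   squares is ill-posed).
#' @param max_sweeps maximum number of ALS sweeps.
#' @param rel_tol relative objective-decrease tolerance for convergence.
#' @param seed integer seed for the factor initialization.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(k = 10L, lambda_reg = 1, max_sweeps = 100L,
                       rel_tol = 1e-5, seed = 1L) {
  stopifnot(k >= 1L, lambda_reg > 0, max_sweeps >= 1L, rel_tol > 0)
  structure(list(k = as.integer(k), lambda_reg = lambda_reg,
                 max_sweeps = as.integer(max_sweeps), rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Build interaction and side-information matrices
#'
#' Assembles the inputs of the factorization models from an encoded training
#' set: the binary visits x drug-groups interaction matrix `X` (every visit
#' is one row entity; absent prescriptions are observed zeros), the row-side
#' attribute matrix `S1` = [standardized age, sex, diagnosis indicators], and
#' the column-side attribute matrix `S2` whose row for group g is the
#' normalized distribution of diagnosis codes co-occurring with g in
#' training (all-zero for a group never prescribed).
#'
#' @param train an `encoded_visits` training set.
#' @return a list of class `interaction_data` with `X`, `S1`, `S2` and the
#'   feature-standardization statistics.
#' @export
build_interaction <- function(train) {
  stopifnot(inherits(train, "encoded_visits"))
  if (nrow(train$Y_drug) == 0L) stop("empty training set", call. = FALSE)
  S1 <- build_features(train)
  counts <- crossprod(train$Y_drug, train$X_dx)   # groups x codes
  rs <- rowSums(counts)
  S2 <- counts / ifelse(rs > 0, rs, 1)
  structure(list(
    X = matrix(as.numeric(train$Y_drug), nrow(train$Y_drug),
               dimnames = list(train$visit_ids, train$drug_groups)),
    S1 = S1, S2 = S2,
    center = attr(S1, "center"), scale = attr(S1, "scale"),
    dx_codes = train$dx_codes, drug_groups = train$drug_groups
  ), class = "interaction_data")
}

## outer-sum of biases
bias_grid <- function(b1, b2) outer(b1, b2, "+")

ridge_solve <- function(G, lambda) {
  solve(G + diag(lambda, nrow(G)))
}

## Solve  A V C + lambda V = D  for V (A, C symmetric PSD) by joint
## eigendecomposition; the normal equation of the attribute-projection blocks
## in the Offsets model.
sylvester_ridge <- function(A, C, D, lambda) {
  ea <- eigen(A, symmetric = TRUE)
  ec <- eigen(C, symmetric = TRUE)
  M <- crossprod(ea$vectors, D %*% ec$vectors)
  M <- M / (outer(ea$values, ec$values) + lambda)
  ea$vectors %*% M %*% t(ec$vectors)
}

new_factor_model <- function(kind, data, config, pieces, trace) {
  structure(c(list(kind = kind, k = config$k %||% 0L,
                   lambda_reg = config$lambda_reg,
                   objective_trace = trace,
                   center = data$center, scale = data$scale,
                   dx_codes = data$dx_codes,
                   drug_groups = data$drug_groups),
              pieces),
            class = "rx_factor_model")
}

#' Most Popular: the bias-only recommender
#'
#' Minimizes `||X - b1 - b2||^2 + lambda * (||b1||^2 + ||b2||^2)` by
#' alternating bias updates. Non-personalized: every cold-start row receives
#' the same score vector `b2`, so its per-label held-out AUROC is exactly 0.5
#' under midrank tie handling.
#'
#' @param data an `interaction_data` (only `X` is used).
#' @param config a [fit_config()] (`k` is ignored).
#' @return an `rx_factor_model` of kind `"most_popular"`.
#' @export
fit_most_popular <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "interaction_data"))
  X <- data$X
  lambda <- config$lambda_reg
  b1 <- numeric(nrow(X))
  b2 <- colMeans(X)
  obj <- function() {
    sum((X - bias_grid(b1, b2))^2) + lambda * (sum(b1^2) + sum(b2^2))
  }
  trace <- obj()
  for (it in seq_len(config$max_sweeps)) {
    b1 <- (rowSums(X) - sum(b2)) / (ncol(X) + lambda)
    b2 <- (colSums(X) - sum(b1)) / (nrow(X) + lambda)
    trace <- c(trace, obj())
    nt <- length(trace)
    if ((trace[nt - 1L] - trace[nt]) <= config$rel_tol * max(trace[nt - 1L], 1e-12)) break
  }
  new_factor_model("most_popular", data, config, list(b1 = b1, b2 = b2), trace)
}

cmf_objective <- function(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda) {
  sum((X - bias_grid(b1, b2) - tcrossprod(U1, U2))^2) +
    sum((S1 - tcrossprod(U1, V1))^2) +
    sum((S2 - tcrossprod(U2, V2))^2) +
    lambda * (sum(U1^2) + sum(U2^2) + sum(V1^2) + sum(V2^2) +
                sum(b1^2) + sum(b2^2))
}

#' Collective matrix factorization with side information
#'
#' Jointly factorizes the interaction matrix and both attribute matrices with
#' shared latent factors, minimizing
#' `||X - b1 - b2 - U1 U2'||^2 + ||S1 - U1 V1'||^2 + ||S2 - U2 V2'||^2`
#' plus L2 penalties, by alternating least squares over the blocks
#' (U1, U2, V1, V2, b1, b2). Each block update is an exact ridge solve, so the
#' objective is non-increasing every sweep (asserted). Initialization is
#' seeded Gaussian with scale `1/sqrt(k)`; biases start at row/column means.
#'
#' @param data an `interaction_data`.
#' @param config a [fit_config()].
#' @return an `rx_factor_model` of kind `"cmf"` carrying the factor blocks
#'   and the per-sweep objective trace.
#' @export
fit_cmf <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "interaction_data"), inherits(config, "fit_config"))
  X <- data$X; S1 <- unclass(data$S1); S2 <- data$S2
  attr(S1, "center") <- NULL; attr(S1, "scale") <- NULL
  n <- nrow(X); m <- ncol(X); k <- config$k; lambda <- config$lambda_reg
  with_seed(derive_seed(config$seed, "cmf"), {
    U1 <- matrix(stats::rnorm(n * k, sd = 1 / sqrt(k)), n, k)
    U2 <- matrix(stats::rnorm(m * k, sd = 1 / sqrt(k)), m, k)
    V1 <- matrix(stats::rnorm(ncol(S1) * k, sd = 1 / sqrt(k)), ncol(S1), k)
    V2 <- matrix(stats::rnorm(ncol(S2) * k, sd = 1 / sqrt(k)), ncol(S2), k)
    b2 <- colMeans(X)
    b1 <- rowMeans(X - matrix(b2, n, m, byrow = TRUE))

    trace <- cmf_objective(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda)
    for (sweep in seq_len(config$max_sweeps)) {
      R <- X - bias_grid(b1, b2)
      U1 <- (R %*% U2 + S1 %*% V1) %*%
        ridge_solve(crossprod(U2) + crossprod(V1), lambda)
      U2 <- (crossprod(R, U1) + S2 %*% V2) %*%
        ridge_solve(crossprod(U1) + crossprod(V2), lambda)
      V1 <- crossprod(S1, U1) %*% ridge_solve(crossprod(U1), lambda)
      V2 <- crossprod(S2, U2) %*% ridge_solve(crossprod(U2), lambda)
      P <- tcrossprod(U1, U2)
      b1 <- (rowSums(X - P) - sum(b2)) / (m + lambda)
      b2 <- (colSums(X - P) - sum(b1)) / (n + lambda)

      o <- cmf_objective(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda)
      if (!is.finite(o)) {
        stop("non-finite ALS objective; lambda_reg may be too small", call. = FALSE)
      }
      prev <- trace[length(trace)]
      stopifnot(o <= prev + 1e-8 * max(abs(prev), 1))
      trace <- c(trace, o)
      if ((prev - o) <= config$rel_tol * max(prev, 1e-12)) break
    }
    new_factor_model("cmf", data, config,
                     list(U1 = U1, U2 = U2, V1 = V1, V2 = V2, b1 = b1, b2 = b2),
                     trace)
  })
}

offsets_objective <- function(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda) {
  A <- U1 + S1 %*% V1
  B <- U2 + S2 %*% V2
  sum((X - bias_grid(b1, b2) - tcrossprod(A, B))^2) +
    lambda * (sum(U1^2) + sum(U2^2) + sum(V1^2) + sum(V2^2) +
                sum(b1^2) + sum(b2^2))
}

#' Offsets model: attribute-shifted factorization for cold-start scoring
#'
#' Factorizes `X - b1 - b2` as `(U1 + S1 V1)(U2 + S2 V2)'` with L2 penalties
#' on all blocks, by alternating least squares: the free-factor updates are
#' ridge solves, the attribute-projection updates are Sylvester-type solves
#' handled by joint eigendecomposition. Cold-start rows are scored by the
#' closed form `b2 + (s1 V1)(U2 + S2 V2)'` — a pure vector-matrix product
#' that never touches the training interactions.
#'
#' @inheritParams fit_cmf
#' @return an `rx_factor_model` of kind `"offsets"`.
#' @export
fit_offsets <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "interaction_data"), inherits(config, "fit_config"))
  X <- data$X; S1 <- unclass(data$S1); S2 <- data$S2
  attr(S1, "center") <- NULL; attr(S1, "scale") <- NULL
  n <- nrow(X); m <- ncol(X); k <- config$k; lambda <- config$lambda_reg
  with_seed(derive_seed(config$seed, "offsets"), {
    U1 <- matrix(stats::rnorm(n * k, sd = 1 / sqrt(k)), n, k)
    U2 <- matrix(stats::rnorm(m * k, sd = 1 / sqrt(k)), m, k)
    V1 <- matrix(stats::rnorm(ncol(S1) * k, sd = 1 / sqrt(k)), ncol(S1), k)
    V2 <- matrix(stats::rnorm(ncol(S2) * k, sd = 1 / sqrt(k)), ncol(S2), k)
    b2 <- colMeans(X)
    b1 <- rowMeans(X - matrix(b2, n, m, byrow = TRUE))
    S1tS1 <- crossprod(S1)
    S2tS2 <- crossprod(S2)

    trace <- offsets_objective(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda)
    for (sweep in seq_len(config$max_sweeps)) {
      R <- X - bias_grid(b1, b2)
      B <- U2 + S2 %*% V2
      BtB <- crossprod(B)
      U1 <- (R %*% B - S1 %*% V1 %*% BtB) %*% ridge_solve(BtB, lambda)
      Rp <- R - tcrossprod(U1, B)
      V1 <- sylvester_ridge(S1tS1, BtB, crossprod(S1, Rp %*% B), lambda)

      A <- U1 + S1 %*% V1
      AtA <- crossprod(A)
      U2 <- (crossprod(R, A) - S2 %*% V2 %*% AtA) %*% ridge_solve(AtA, lambda)
      Rp2 <- t(R) - tcrossprod(U2, A)
      V2 <- sylvester_ridge(S2tS2, AtA, crossprod(S2, Rp2 %*% A), lambda)

      A <- U1 + S1 %*% V1
      B <- U2 + S2 %*% V2
      P <- tcrossprod(A, B)
      b1 <- (rowSums(X - P) - sum(b2)) / (m + lambda)
      b2 <- (colSums(X - P) - sum(b1)) / (n + lambda)

      o <- offsets_objective(X, S1, S2, U1, U2, V1, V2, b1, b2, lambda)
      if (!is.finite(o)) {
        stop("non-finite ALS objective; lambda_reg may be too small", call. = FALSE)
      }
      prev <- trace[length(trace)]
      stopifnot(o <= prev + 1e-8 * max(abs(prev), 1))
      trace <- c(trace, o)
      if ((prev - o) <= config$rel_tol * max(prev, 1e-12)) break
    }
    new_factor_model("offsets", data, config,
                     list(U1 = U1, U2 = U2, V1 = V1, V2 = V2, b1 = b1, b2 = b2,
                          B = U2 + S2 %*% V2),
                     trace)
  })
}

#' Cross-validated hyperparameter selection for the factorization models
#'
#' Patient-disjoint K-fold cross-validation over a grid of latent dimensions
#' and regularization strengths, scoring each held-out fold cold-start (the
#' test-time regime) and selecting the combination with the best mean
#' macro-averaged AUROC.
#'
#' @param train an `encoded_visits` training set.
#' @param kind `"cmf"` or `"offsets"`.
#' @param k_grid candidate latent dimensions.
#' @param lambda_grid candidate L2 strengths.
#' @param n_folds number of CV folds.
#' @param max_sweeps ALS sweep budget per fit.
#' @param seed integer seed.
#' @return a list with the selected `k`, `lambda_reg`, and the full CV
#'   `grid` (data.frame of mean macro AUC per combination).
#' @export
select_cf_hyper <- function(train, kind = c("offsets", "cmf"),
                            k_grid = c(5L, 10L, 20L, 40L),
                            lambda_grid = c(0.1, 1, 10),
                            n_folds = 3L, max_sweeps = 50L, seed = 1L) {
  kind <- match.arg(kind)
  fitter <- if (kind == "offsets") fit_offsets else fit_cmf
  folds <- make_cv_folds(train, k = n_folds, seed = derive_seed(seed, "cf_cv"))
  grid <- expand.grid(k = k_grid, lambda_reg = lambda_grid)
  grid$macro_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_along(folds), function(f) {
      tr <- subset_encoded(train, setdiff(seq_along(train$visit_ids), folds[[f]]))
      ho <- subset_encoded(train, folds[[f]])
      mdl <- fitter(build_interaction(tr),
                    fit_config(k = grid$k[g], lambda_reg = grid$lambda_reg[g],
                               max_sweeps = max_sweeps,
                               seed = derive_seed(seed, paste0("cf", f))))
      rep <- suppressMessages(
        evaluate_scores(predict(mdl, ho), ho$Y_drug, k = 5L, model_tag = kind))
      rep$macro_auc
    }, numeric(1L))
    grid$macro_auc[g] <- mean(aucs)
  }
  best <- which.max(grid$macro_auc)
  list(k = grid$k[best], lambda_reg = grid$lambda_reg[best], grid = grid)
}

## Attribute rows for new visits, standardized with the training statistics.
factor_attributes <- function(object, newdata) {
  if (inherits(newdata, "encoded_visits")) {
    if (!identical(newdata$drug_groups, object$drug_groups)) {
      stop("drug-group vocabulary mismatch between model and data", call. = FALSE)
    }
    S <- build_features(newdata, object$center, object$scale)
    ids <- newdata$visit_ids
  } else {
    S <- as.matrix(newdata)
    ids <- rownames(S)
  }
  expected <- 2L + length(object$dx_codes)
  if (object$kind != "most_popular" && ncol(S) != expected) {
    stop(sprintf("attribute matrix has %d columns; expected %d",
                 ncol(S), expected), call. = FALSE)
  }
  list(S = S, ids = ids)
}

#' Cold-start scores from a fitted factorization model
#'
#' Scores unseen visits from their attributes alone. `most_popular` returns
#' the identical popularity-bias vector for every row; `cmf` infers latent
#' factors from the attributes by a ridge solve against `V1`; `offsets` uses
#' its closed-form vector-matrix product. Scores are raw real values intended
#' for ranking, not probabilities.
#'
#' @param object an `rx_factor_model`.
#' @param newdata an `encoded_visits` or a numeric attribute matrix laid out
#'   as `[standardized age, sex, dx indicators]`.
#' @param ... unused.
#' @return a numeric rows x drug-groups score matrix with attribute
#'   `model_tag`.
#' @export
predict.rx_factor_model <- function(object, newdata, ...) {
  at <- factor_attributes(object, newdata)
  n <- nrow(at$S)
  scores <- switch(object$kind,
    most_popular = matrix(object$b2, n, length(object$drug_groups), byrow = TRUE),
    cmf = {
      u1 <- at$S %*% object$V1 %*%
        ridge_solve(crossprod(object$V1), object$lambda_reg)
      matrix(object$b2, n, length(object$drug_groups), byrow = TRUE) +
        tcrossprod(u1, object$U2)
    },
    offsets = {
      matrix(object$b2, n, length(object$drug_groups), byrow = TRUE) +
        tcrossprod(at$S %*% object$V1, object$B)
    }
  )
  dimnames(scores) <- list(at$ids, object$drug_groups)
  attr(scores, "model_tag") <- object$kind
  scores
}

#' @export
print.rx_factor_model <- function(x, ...) {
  cat(sprintf("Factorization recommender '%s': %d drug groups%s\n",
              x$kind, length(x$drug_groups),
              if (x$kind == "most_popular") ""
              else sprintf(", k = %d, lambda = %g", x$k, x$lambda_reg)))
  cat(sprintf("  final objective %.6g after %d sweep(s)\n",
              x$objective_trace[length(x$objective_trace)],
              length(x$objective_trace) - 1L))
  invisible(x)
}
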