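#' Classifier specification
#'
#' Family and hyperparameters for the one-vs-rest multi-label classifiers.
#' Defaults follow the study protocol: 24 nearest neighbours with the
#' Minkowski (p = 2, Euclidean) metric; L2-penalized logistic regression with
#' C = 1; random forests with 200 trees of depth 8 split on Gini impurity;
#' and a perceptron with two 128-unit ReLU hidden layers trained with Adam at
#' step size 0.001 until the loss fails to improve by 1e-4 for 10 consecutive
#' epochs. Class weights inversely proportional to label frequencies are on
#' by default (the nearest-neighbour family, a pure vote, ignores them).
#'
#' @param family one of `"knn"`, `"logreg"`, `"rf"`, `"mlp"`.
#' @param use_class_weights apply inverse-frequency class weights.
#' @param ... family-specific overrides: `k`, `minkowski_p` (knn); `C`
#'   (logreg); `num_trees`, `max_depth` (rf); `hidden`, `learning_rate`,
#'   `tol`, `patience`, `max_epochs` (mlp).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "logreg", "rf", "mlp"),
                            use_class_weights = TRUE, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn = list(k = 24L, minkowski_p = 2),
    logreg = list(C = 1),
    rf = list(num_trees = 200L, max_depth = 8L),
    mlp = list(hidden = c(128L, 128L), learning_rate = 1e-3,
               tol = 1e-4, patience = 10L, max_epochs = 300L,
               batch_size = 200L)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(family = family, hyper = defaults,
                 use_class_weights = use_class_weights),
            class = "classifier_spec")
}

#' Inverse-frequency class weights
#'
#' For a label with `n_pos` positives among `n` rows, the positive and
#' negative weights are `n / (2 * n_pos)` and `n / (2 * (n - n_pos))`, so the
#' total weighted mass of positives equals that of negatives.
#'
#' @param Y_drug binary visits x labels matrix.
#' @return a data.frame with one row per label: `label`, `n_pos`, `w_pos`,
#'   `w_neg`.
#' @export
class_weights <- function(Y_drug) {
  Y_drug <- as.matrix(Y_drug)
  n <- nrow(Y_drug)
  n_pos <- colSums(Y_drug)
  deg <- which(n_pos == 0 | n_pos == n)
  if (length(deg) > 0L) {
    labs <- colnames(Y_drug) %||% as.character(deg)
    stop("degenerate label(s) (all 0 or all 1): ",
         paste(labs[deg], collapse = ", "), call. = FALSE)
  }
  data.frame(
    label = colnames(Y_drug) %||% paste0("L", seq_len(ncol(Y_drug))),
    n_pos = as.integer(n_pos),
    w_pos = n / (2 * n_pos),
    w_neg = n / (2 * (n - n_pos)),
    stringsAsFactors = FALSE
  )
}

#' Binary logistic response
#'
#' Overflow-safe evaluation of `1 / (1 + exp(-(b0 + sum(b * x))))`, the
#' probability model underlying the logistic-regression family.
#'
#' @param beta coefficient vector, intercept first.
#' @param x feature vector (length `length(beta) - 1`).
#' @return a probability in (0, 1).
#' @export
logistic_probability <- function(beta, x) {
  stopifnot(length(beta) == length(x) + 1L)
  sigmoid(beta[1L] + sum(beta[-1L] * x))
}

## Design matrix: standardized age, sex indicator, diagnosis indicators.
## Standardization statistics come from the training set.
build_features <- function(ds, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(ds$age)
  if (is.null(scale)) {
    scale <- stats::sd(ds$age)
    if (!is.finite(scale) || scale == 0) scale <- 1
  }
  X <- cbind(age = (ds$age - center) / scale,
             sex = ds$sex_indicator,
             ds$X_dx)
  attr(X, "center") <- center
  attr(X, "scale") <- scale
  X
}

#' Fit one-vs-rest multi-label classifiers
#'
#' Trains one probabilistic binary model per drug group on features
#' [standardized age, sex indicator, diagnosis indicators]. Labels with no
#' positive (or no negative) training visit are skipped with a warning and
#' scored at their training prevalence. Random-forest and perceptron fits are
#' deterministic given `seed`.
#'
#' @param train an `encoded_visits` training set.
#' @param spec a [classifier_spec()].
#' @param seed integer seed for the stochastic families.
#' @return an object of class `rx_classifier` with a [predict.rx_classifier()]
#'   method.
#' @export
fit_ovr <- function(train, spec, seed = 1L) {
  stopifnot(inherits(train, "encoded_visits"), inherits(spec, "classifier_spec"))
  if (nrow(train$Y_drug) == 0L) stop("empty training set", call. = FALSE)
  X <- build_features(train)
  Y <- train$Y_drug
  n <- nrow(Y)
  labels <- train$drug_groups
  n_pos <- colSums(Y)
  ## labels need at least 2 positives and 2 negatives to support a fit;
  ## anything below is scored at training prevalence
  degenerate <- n_pos < 2 | n_pos > n - 2
  if (any(degenerate)) {
    warning("skipping degenerate label(s): ",
            paste(labels[degenerate], collapse = ", "))
  }
  live <- which(!degenerate)

  weights <- NULL
  if (spec$use_class_weights && spec$family != "knn" && length(live) > 0L) {
    weights <- class_weights(Y[, live, drop = FALSE])
  }
  case_weight <- function(j_live, y) {
    if (is.null(weights)) return(rep(1, length(y)))
    ifelse(y == 1, weights$w_pos[j_live], weights$w_neg[j_live])
  }

  fits <- NULL
  if (spec$family == "logreg") {
    fits <- lapply(seq_along(live), function(jl) {
      y <- Y[, live[jl]]
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = 1 / (spec$hyper$C * n),
                     weights = case_weight(jl, y),
                     standardize = FALSE)
    })
  } else if (spec$family == "rf") {
    fits <- lapply(seq_along(live), function(jl) {
      y <- Y[, live[jl]]
      df <- data.frame(y = factor(y, levels = c(0, 1)), X)
      ranger::ranger(y ~ ., data = df, probability = TRUE,
                     num.trees = spec$hyper$num_trees,
                     max.depth = spec$hyper$max_depth,
                     splitrule = "gini",
                     case.weights = case_weight(jl, y),
                     seed = derive_seed(seed, paste0("rf", jl)),
                     num.threads = 1L)
    })
  } else if (spec$family == "mlp") {
    Wgt <- matrix(1, n, length(live))
    if (!is.null(weights)) {
      for (jl in seq_along(live)) {
        Wgt[, jl] <- case_weight(jl, Y[, live[jl]])
      }
    }
    fits <- mlp_fit(X, Y[, live, drop = FALSE], Wgt,
                    hidden = spec$hyper$hidden,
                    learning_rate = spec$hyper$learning_rate,
                    tol = spec$hyper$tol, patience = spec$hyper$patience,
                    max_epochs = spec$hyper$max_epochs,
                    batch_size = spec$hyper$batch_size,
                    seed = derive_seed(seed, "mlp"))
  } else if (spec$family == "knn") {
    if (spec$hyper$minkowski_p != 2) {
      stop("only the Euclidean member (p = 2) of the Minkowski family is supported",
           call. = FALSE)
    }
    fits <- list(X = X, Y = Y[, live, drop = FALSE], k = spec$hyper$k)
  }

  structure(list(
    spec = spec, fits = fits, live = live, labels = labels,
    prevalence = n_pos / n,
    center = attr(X, "center"), scale = attr(X, "scale"),
    seed = seed
  ), class = "rx_classifier")
}

## k nearest neighbours by blocked Euclidean distance; vote fraction per label.
knn_scores <- function(fit, Xnew) {
  k <- min(fit$k, nrow(fit$X))
  tr_sq <- rowSums(fit$X^2)
  out <- matrix(0, nrow(Xnew), ncol(fit$Y))
  block <- 512L
  for (start in seq(1L, nrow(Xnew), by = block)) {
    idx <- start:min(start + block - 1L, nrow(Xnew))
    Xa <- Xnew[idx, , drop = FALSE]
    D2 <- outer(rowSums(Xa^2), tr_sq, "+") - 2 * Xa %*% t(fit$X)
    for (r in seq_along(idx)) {
      nb <- order(D2[r, ])[seq_len(k)]   # stable: index breaks distance ties
      out[idx[r], ] <- colMeans(fit$Y[nb, , drop = FALSE])
    }
  }
  out
}

#' Predict per-visit drug-group probability scores
#'
#' @param object an `rx_classifier`.
#' @param newdata an `encoded_visits` with the same vocabularies as training.
#' @param ... unused.
#' @return a numeric visits x drug-groups matrix of scores in `[0, 1]`, with
#'   visit ids as row names and an attribute `model_tag`.
#' @export
predict.rx_classifier <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "encoded_visits"))
  if (!identical(newdata$drug_groups, object$labels)) {
    stop("drug-group vocabulary mismatch between model and data", call. = FALSE)
  }
  X <- build_features(newdata, object$center, object$scale)
  n <- nrow(X)
  S <- matrix(rep(object$prevalence, each = n), n, length(object$labels),
              dimnames = list(newdata$visit_ids, object$labels))
  live <- object$live
  if (length(live) > 0L) {
    fam <- object$spec$family
    if (fam == "logreg") {
      for (jl in seq_along(live)) {
        S[, live[jl]] <- as.numeric(
          stats::predict(object$fits[[jl]], newx = X, type = "response"))
      }
    } else if (fam == "rf") {
      for (jl in seq_along(live)) {
        pr <- stats::predict(object$fits[[jl]], data = data.frame(X),
                             num.threads = 1L)$predictions
        S[, live[jl]] <- pr[, "1"]
      }
    } else if (fam == "mlp") {
      S[, live] <- mlp_predict(object$fits, X)
    } else if (fam == "knn") {
      S[, live] <- knn_scores(object$fits, X)
    }
  }
  attr(S, "model_tag") <- object$spec$family
  S
}

#' @export
print.rx_classifier <- function(x, ...) {
  cat(sprintf("One-vs-rest %s classifier: %d drug-group labels (%d fitted)\n",
              x$spec$family, length(x$labels), length(x$live)))
  invisible(x)
}
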