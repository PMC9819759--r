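# Hand-built interaction data for controlled factorization experiments.
make_interaction <- function(X, S1 = NULL, S2 = NULL) {
  n <- nrow(X); m <- ncol(X)
  if (is.null(S1)) S1 <- matrix(0, n, 2)
  if (is.null(S2)) S2 <- matrix(0, m, 2)
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%02d", seq_len(m))
  structure(list(
    X = X, S1 = S1, S2 = S2, center = 0, scale = 1,
    dx_codes = character(0), drug_groups = colnames(X)
  ), class = "interaction_data")
}

test_that("build_interaction assembles X, S1 and normalized S2", {
  ds <- small_encoded(n_patients = 60, seed = 19)
  dat <- build_interaction(ds)
  expect_equal(unname(dat$X), unname(matrix(as.numeric(ds$Y_drug), nrow(ds$Y_drug))))
  expect_equal(ncol(dat$S1), 2L + ncol(ds$X_dx))
  rs <- rowSums(dat$S2)
  prescribed <- colSums(ds$Y_drug) > 0
  expect_equal(unname(rs[prescribed]), rep(1, sum(prescribed)))

  # drug seen with exactly one code gives a one-hot S2 row
  X <- cbind(g1 = c(1, 1, 0), g2 = c(0, 1, 1))
  toy <- structure(list(
    X_dx = cbind(c1 = c(1L, 1L, 0L), c2 = c(0L, 0L, 1L)),
    Y_drug = X, age = c(70, 75, 80), sex_indicator = c(0L, 1L, 0L),
    visit_ids = c("a", "b", "c"), patient_ids = c("a", "b", "c"),
    dx_codes = c("c1", "c2"), drug_groups = colnames(X)
  ), class = "encoded_visits")
  d2 <- build_interaction(toy)
  expect_equal(unname(d2$S2["g1", ]), c(1, 0))
})

test_that("most popular ranks by prevalence and is identical across cold rows", {
  set.seed(4)
  X <- cbind(a = rbinom(100, 1, 0.9), b = rbinom(100, 1, 0.1))
  mp <- fit_most_popular(make_interaction(X), fit_config(lambda_reg = 1e-6))
  expect_gt(mp$b2[1], mp$b2[2])

  s <- predict(mp, matrix(rnorm(10), 5, 2))
  expect_equal(s[1, ], s[2, ], ignore_attr = TRUE)
  for (i in 2:5) expect_equal(unname(s[i, ]), unname(s[1, ]))
})

test_that("ALS recovers a noiseless rank-1 interaction matrix", {
  set.seed(7)
  u <- rnorm(20); v <- rnorm(6)
  X <- tcrossprod(u, v)
  dat <- make_interaction(X)
  fit <- fit_cmf(dat, fit_config(k = 1, lambda_reg = 1e-6, max_sweeps = 200,
                                 rel_tol = 1e-12, seed = 3))
  pred <- outer(fit$b1, fit$b2, "+") + tcrossprod(fit$U1, fit$U2)
  rmse <- sqrt(mean((X - pred)^2))
  expect_lt(rmse, 1e-3)
})

test_that("the ALS objective is non-increasing on random data", {
  set.seed(9)
  for (rep in 1:3) {
    X <- matrix(rbinom(30 * 8, 1, 0.3), 30, 8)
    S1 <- matrix(rnorm(30 * 5), 30, 5)
    S2 <- matrix(runif(8 * 4), 8, 4)
    dat <- make_interaction(X, S1, S2)
    for (fitter in list(fit_cmf, fit_offsets)) {
      fit <- fitter(dat, fit_config(k = 3, lambda_reg = 0.5, max_sweeps = 25,
                                    seed = rep))
      expect_true(all(diff(fit$objective_trace) <= 1e-8))
    }
  }
})

test_that("larger latent dimension never worsens the converged objective", {
  set.seed(11)
  X <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10)
  dat <- make_interaction(X)
  objs <- vapply(c(1, 2, 4), function(k) {
    fit <- fit_cmf(dat, fit_config(k = k, lambda_reg = 0.1, max_sweeps = 100,
                                   rel_tol = 1e-10, seed = 5))
    fit$objective_trace[length(fit$objective_trace)]
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-6 * objs[1]))
})

test_that("ALS matches direct numerical minimization on a small problem", {
  set.seed(13)
  X <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1), 4, 3)
  S1 <- matrix(rnorm(8), 4, 2)
  S2 <- matrix(runif(6), 3, 2)
  dat <- make_interaction(X, S1, S2)
  lambda <- 0.01
  fit <- fit_cmf(dat, fit_config(k = 1, lambda_reg = lambda, max_sweeps = 5000,
                                 rel_tol = 1e-15, seed = 1))
  als_obj <- fit$objective_trace[length(fit$objective_trace)]

  # independent objective and optimizer over the full parameter vector
  unpack <- function(p) {
    list(U1 = matrix(p[1:4], 4, 1), U2 = matrix(p[5:7], 3, 1),
         V1 = matrix(p[8:9], 2, 1), V2 = matrix(p[10:11], 2, 1),
         b1 = p[12:15], b2 = p[16:18])
  }
  obj <- function(p) {
    q <- unpack(p)
    sum((X - outer(q$b1, q$b2, "+") - tcrossprod(q$U1, q$U2))^2) +
      sum((S1 - tcrossprod(q$U1, q$V1))^2) +
      sum((S2 - tcrossprod(q$U2, q$V2))^2) +
      lambda * (sum(q$U1^2) + sum(q$U2^2) + sum(q$V1^2) + sum(q$V2^2) +
                  sum(q$b1^2) + sum(q$b2^2))
  }
  start <- c(fit$U1, fit$U2, fit$V1, fit$V2, fit$b1, fit$b2)
  polish <- optim(start, obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(als_obj - polish$value) / max(abs(polish$value), 1e-12), 1e-4)
})

test_that("offsets cold-start scoring uses only attributes and biases", {
  set.seed(17)
  X <- matrix(rbinom(50 * 6, 1, 0.4), 50, 6)
  S1 <- cbind(rnorm(50), rbinom(50, 1, 0.5))
  S2 <- matrix(runif(12), 6, 2)
  dat <- make_interaction(X, S1, S2)
  fit <- fit_offsets(dat, fit_config(k = 2, lambda_reg = 1, max_sweeps = 50,
                                     seed = 2))
  # zero attributes reduce the closed form to the popularity biases
  s0 <- predict(fit, matrix(0, 1, 2))
  expect_equal(unname(s0[1, ]), unname(fit$b2))

  # manual closed form b2 + (s1 V1)(U2 + S2 V2)^T
  s1 <- matrix(rnorm(2), 1, 2)
  manual <- fit$b2 + as.numeric(s1 %*% fit$V1 %*% t(fit$U2 + S2 %*% fit$V2))
  expect_equal(unname(predict(fit, s1)[1, ]), unname(manual))
})

test_that("warm and cold-start offsets predictions agree under strong shrinkage", {
  set.seed(19)
  n <- 120
  S1 <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  B_true <- matrix(rnorm(6 * 2), 6, 2)
  X <- (S1 %*% t(B_true) + matrix(rnorm(n * 6, sd = 0.1), n, 6)) > 0
  X <- matrix(as.numeric(X), n, 6)
  dat <- make_interaction(X, S1, matrix(0, 6, 2))
  fit <- fit_offsets(dat, fit_config(k = 2, lambda_reg = 25, max_sweeps = 80,
                                     seed = 3))
  warm <- outer(fit$b1, fit$b2, "+") +
    tcrossprod(fit$U1 + S1 %*% fit$V1, fit$B)
  cold <- predict(fit, S1)
  # free per-row terms are shrunk hard, so the two predictions nearly agree
  expect_lt(sqrt(mean((warm - cold)^2)) / stats::sd(warm), 0.15)
  expect_gt(cor(as.numeric(warm), as.numeric(cold)), 0.98)
})

test_that("offsets beats the popularity baseline on linearly structured data", {
  set.seed(23)
  n_tr <- 600; n_te <- 300; p <- 12; m <- 10
  S1_tr <- cbind(matrix(rbinom(n_tr * p, 1, 0.3), n_tr, p))
  S1_te <- cbind(matrix(rbinom(n_te * p, 1, 0.3), n_te, p))
  Btrue <- matrix(rnorm(m * p, sd = 1.2), m, p)
  mk_y <- function(S) {
    P <- 1 / (1 + exp(-(S %*% t(Btrue) - 1)))
    matrix(rbinom(length(P), 1, as.numeric(P)), nrow(P), ncol(P))
  }
  Y_tr <- mk_y(S1_tr); Y_te <- mk_y(S1_te)
  colnames(Y_tr) <- colnames(Y_te) <- sprintf("g%02d", 1:m)
  S2 <- matrix(0, m, 2)
  dat <- make_interaction(Y_tr, S1_tr, S2)
  fit <- fit_offsets(dat, fit_config(k = 10, lambda_reg = 10, max_sweeps = 60,
                                     seed = 4))
  mp <- fit_most_popular(dat, fit_config())

  auc_macro <- function(S, Y) {
    mean(vapply(seq_len(ncol(Y)), function(j) auroc_label(S[, j], Y[, j]),
                numeric(1)))
  }
  a_off <- auc_macro(tcrossprod(S1_te %*% fit$V1, fit$B) +
                       matrix(fit$b2, n_te, m, byrow = TRUE), Y_te)
  a_mp <- auc_macro(matrix(mp$b2, n_te, m, byrow = TRUE), Y_te)
  expect_equal(a_mp, 0.5)
  expect_gt(a_off, 0.75)
})

test_that("hyperparameter selection returns grid members with CV scores", {
  ds <- small_encoded(n_patients = 80, seed = 29)
  sel <- select_cf_hyper(ds, "offsets", k_grid = c(2L, 4L),
                         lambda_grid = c(1, 10), n_folds = 2,
                         max_sweeps = 10, seed = 1)
  expect_true(sel$k %in% c(2L, 4L))
  expect_true(sel$lambda_reg %in% c(1, 10))
  expect_equal(nrow(sel$grid), 4L)
  expect_true(all(is.finite(sel$grid$macro_auc)))
})
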