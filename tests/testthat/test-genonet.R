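# Semi-supervised elastic-net scorer: objective, optimizer, AUROC, tuning.

make_training_fixture <- function(seed = 11) {
  simulate_training_data(sim_config(seed = seed))
}

test_that("objective reduces to supervised loss at gamma 0 and is bounded below", {
  td <- make_training_fixture()
  p <- ncol(td$labeled$features)
  cfg0 <- fit_config(gamma = 0, lambda = 0, l1_ratio = 0.5)
  m <- nrow(td$labeled$features)
  # zero coefficients, lambda 0, gamma 0: m * log(2) (logistic loss at 0.5)
  expect_equal(genonet_objective(rep(0, p + 1), td$labeled, td$unlabeled, cfg0),
               m * log(2), tolerance = 1e-12)
  # gamma = 0 drops the anchor term entirely
  set.seed(1)
  coefs <- rnorm(p + 1, sd = 0.3)
  cfgl <- fit_config(gamma = 0, lambda = 2, l1_ratio = 0.3)
  expect_equal(genonet_objective(coefs, td$labeled, td$unlabeled, cfgl),
               genonet_objective(coefs, td$labeled, NULL, cfgl),
               tolerance = 1e-12)
  # value dominates the anchor term alone
  cfgg <- fit_config(gamma = 3, lambda = 2, l1_ratio = 0.3)
  b <- coefs[1]; beta <- coefs[-1]
  anchor <- 3 * sum((td$unlabeled$anchors -
                       1 / (1 + exp(-(td$unlabeled$features %*% beta + b))))^2)
  expect_gte(genonet_objective(coefs, td$labeled, td$unlabeled, cfgg), anchor)
  expect_error(genonet_objective(coefs[-1], td$labeled, NULL, cfgl), "length")
})

test_that("gamma 0 fit matches an independent elastic-net logistic fit", {
  skip_if_not_installed("glmnet")
  td <- make_training_fixture()
  m <- nrow(td$labeled$features)
  cfg <- fit_config(gamma = 0, l1_ratio = 0.5, lambda = 1, tol = 1e-13,
                    max_iter = 50000)
  fit <- fit_semisupervised(td$labeled, td$unlabeled, cfg)
  g <- glmnet::glmnet(td$labeled$features, td$labeled$labels,
                      family = "binomial", alpha = 0.5, lambda = 1 / m,
                      standardize = TRUE, thresh = 1e-14, maxit = 1e6)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               as.numeric(stats::coef(g)), tolerance = 1e-6)
})

test_that("optimizer is monotone, convergent and reports a faithful objective", {
  td <- make_training_fixture()
  cfg <- fit_config(gamma = 2, l1_ratio = 0.5, lambda = 1, tol = 1e-11)
  fit <- fit_semisupervised(td$labeled, td$unlabeled, cfg)
  expect_true(fit$converged)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  expect_equal(fit$objective_value,
               genonet_objective(c(fit$intercept, fit$coefficients),
                                 td$labeled, td$unlabeled, cfg),
               tolerance = 1e-8)
  # deterministic: repeat fit identical
  fit2 <- fit_semisupervised(td$labeled, td$unlabeled, cfg)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_error(fit_semisupervised(
    training_set(td$labeled$features, rep(1, nrow(td$labeled$features))),
    td$unlabeled, cfg), "both classes")
})

test_that("internal standardization reproduces unstandardized predictions", {
  td <- make_training_fixture()
  cfg <- fit_config(gamma = 1, l1_ratio = 0, lambda = 0.5, tol = 1e-12,
                    standardize = TRUE)
  fit_std <- fit_semisupervised(td$labeled, td$unlabeled, cfg)
  # manually standardized features + standardize = FALSE: same predictions
  ctr <- colMeans(td$labeled$features)
  m <- nrow(td$labeled$features)
  sc <- sqrt(colMeans(sweep(td$labeled$features, 2, ctr)^2))
  std <- function(X) sweep(sweep(X, 2, ctr), 2, sc, "/")
  cfg2 <- cfg; cfg2$standardize <- FALSE
  fit_raw <- fit_semisupervised(
    training_set(std(td$labeled$features), td$labeled$labels),
    unlabeled_set(std(td$unlabeled$features), td$unlabeled$anchors), cfg2)
  expect_equal(predict(fit_std, td$holdout$features),
               predict(fit_raw, std(td$holdout$features)), tolerance = 1e-8)
})

test_that("predictions are probabilities, monotone and deterministic", {
  td <- make_training_fixture()
  fit <- fit_semisupervised(td$labeled, td$unlabeled,
                            fit_config(gamma = 1, lambda = 1))
  s <- predict(fit, td$holdout$features)
  expect_true(all(s > 0 & s < 1))
  expect_identical(s, predict(fit, td$holdout$features))
  fit0 <- fit
  fit0$coefficients[] <- 0; fit0$intercept <- 0
  expect_equal(predict(fit0, td$holdout$features),
               rep(0.5, nrow(td$holdout$features)))
  j <- which(fit$coefficients > 0)[1]
  if (!is.na(j)) {
    bumped <- td$holdout$features
    bumped[, j] <- bumped[, j] + 1
    expect_true(all(predict(fit, bumped) >= s))
  }
  expect_error(predict(fit, td$holdout$features[, -1]), "width")
})

test_that("AUROC equals the exhaustive pair-counting statistic", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "single class")
  set.seed(99)
  for (r in 1:25) {
    n <- sample(10:150, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- if (r %% 2 == 0) rnorm(n) else round(rnorm(n), 1)  # with ties
    expect_equal(auroc(y, s), auroc_pair_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("gamma tuning is deterministic, tie-broken small, and noise-robust", {
  td <- make_training_fixture()
  cfg <- fit_config(l1_ratio = 0.5, lambda = 1, tol = 1e-8, seed = 4)
  one <- tune_gamma(td$labeled, td$unlabeled, gamma_grid = 0.7, folds = 3, cfg)
  expect_equal(one$best_gamma, 0.7)
  t1 <- tune_gamma(td$labeled, td$unlabeled, c(0, 1), folds = 3, cfg)
  t2 <- tune_gamma(td$labeled, td$unlabeled, c(0, 1), folds = 3, cfg)
  expect_identical(t1$table, t2$table)
  expect_error(tune_gamma(td$labeled, td$unlabeled, numeric(0), 3, cfg),
               "empty")

  # uniform-noise anchors: the grid minimum should win more often than the max
  n_min <- 0; n_max <- 0
  for (r in 1:50) {
    tdr <- simulate_training_data(sim_config(seed = 400 + r, n_labeled = 50,
                                             n_unlabeled = 150))
    set.seed(4000 + r)
    noisy <- runif(length(tdr$unlabeled$anchors))
    unl <- unlabeled_set(tdr$unlabeled$features, noisy)
    cfgr <- fit_config(l1_ratio = 0.5, lambda = 1, tol = 1e-7, seed = r)
    best <- tune_gamma(tdr$labeled, unl, c(0, 10), folds = 3, cfgr)$best_gamma
    if (best == 0) n_min <- n_min + 1
    if (best == 10) n_max <- n_max + 1
  }
  expect_gt(n_min, n_max)
})
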