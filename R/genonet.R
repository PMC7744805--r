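# Semi-supervised tissue-specific functional scoring.
#
# The model minimizes, over an intercept b and coefficients beta,
#
#   sum_i nll(Y_i, sigma(b + X_i beta))                    (labeled variants)
#   + lambda * (l1_ratio * |beta|_1 + (1 - l1_ratio)/2 * |beta|_2^2)
#   + gamma * sum_i (Yhat_i - sigma(b + X_i beta))^2       (unlabeled anchors)
#
# The linear predictor is passed through the logistic link before the anchor
# comparison so both loss terms live on [0,1] probabilities (anchors are
# probabilities from a prior unsupervised method). Both sums are raw
# (unnormalized); `normalize_terms = TRUE` divides them by m and l.
# Optimization is monotone FISTA (proximal gradient with momentum, restart on
# increase, backtracking line search): the accepted objective sequence never
# increases.

#' Labeled training set for the semi-supervised scorer
#'
#' @param features numeric matrix, m variants x p annotation features.
#' @param labels binary 0/1 vector of length m (both classes required for
#'   fitting).
#' @param ids optional variant ids.
#' @param tissue tissue/cell-type label carried through to outputs.
#' @return a `training_set`.
#' @export
training_set <- function(features, labels, ids = NULL, tissue = "") {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite feature values", call. = FALSE)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(features)))
  structure(list(features = features, labels = labels, ids = ids,
                 tissue = tissue), class = "training_set")
}

#' Unlabeled set with anchor scores from a prior unsupervised method
#'
#' @param features numeric matrix, l variants x p (same feature columns as
#'   the labeled set).
#' @param anchors anchor scores in \[0, 1\] of length l.
#' @param ids optional variant ids.
#' @return an `unlabeled_set`.
#' @export
unlabeled_set <- function(features, anchors, ids = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite feature values", call. = FALSE)
  if (nrow(features) != length(anchors)) {
    stop("features and anchors disagree in length", call. = FALSE)
  }
  if (any(anchors < 0 | anchors > 1)) stop("anchors must lie in [0,1]", call. = FALSE)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (is.null(ids)) ids <- paste0("u", seq_len(nrow(features)))
  structure(list(features = features, anchors = as.numeric(anchors), ids = ids),
            class = "unlabeled_set")
}

#' Fit configuration for the semi-supervised scorer
#'
#' @param gamma anchor weight (>= 0); 0 recovers a purely supervised
#'   elastic-net logistic fit.
#' @param l1_ratio elastic-net mixing in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength (> 0), on the raw-sum objective scale.
#' @param max_iter optimizer iteration cap.
#' @param tol convergence tolerance on the relative objective change.
#' @param standardize standardize features internally (labeled-set mean/sd,
#'   population sd) before penalization; coefficients are reported on the
#'   original scale either way.
#' @param normalize_terms divide the labeled and anchor sums by m and l; off
#'   by default (raw sums).
#' @param seed RNG seed for cross-validation fold assignment.
#' @return a `fit_config`.
#' @export
fit_config <- function(gamma = 0, l1_ratio = 0.5, lambda = 1, max_iter = 10000L,
                       tol = 1e-10, standardize = TRUE, normalize_terms = FALSE,
                       seed = 1L) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0,1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, l1_ratio = l1_ratio, lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol,
                 standardize = isTRUE(standardize),
                 normalize_terms = isTRUE(normalize_terms),
                 seed = as.integer(seed)), class = "fit_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable sum of logistic negative log-likelihoods.
logistic_nll <- function(eta, y) {
  sum(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
}

# Standardization statistics from the labeled features (population sd, the
# glmnet convention); constant columns get scale 1.
standardize_stats <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))
  s[s == 0] <- 1
  list(center = m, scale = s)
}

#' Semi-supervised objective value
#'
#' Evaluates the penalized objective at a coefficient vector on the original
#' feature scale. When `config$standardize` is TRUE the elastic-net penalty
#' is applied to the standardized-scale coefficients (beta * sd), matching
#' what [fit_semisupervised()] optimizes; the likelihood and anchor terms are
#' scale-invariant.
#'
#' @param coefs numeric vector c(intercept, beta) on the original scale.
#' @param labeled a [training_set()].
#' @param unlabeled an [unlabeled_set()] or NULL (gamma term dropped).
#' @param config a [fit_config()].
#' @return the objective value (scalar).
#' @export
genonet_objective <- function(coefs, labeled, unlabeled = NULL,
                              config = fit_config()) {
  p <- ncol(labeled$features)
  if (length(coefs) != p + 1L) {
    stop("coefficient vector must have length p + 1 = ", p + 1L, call. = FALSE)
  }
  if (!is.null(unlabeled) && ncol(unlabeled$features) != p) {
    stop("labeled and unlabeled feature dimensions disagree", call. = FALSE)
  }
  b <- coefs[1]; beta <- coefs[-1]
  m <- nrow(labeled$features)
  eta <- drop(labeled$features %*% beta) + b
  nll <- logistic_nll(eta, labeled$labels)
  if (config$normalize_terms) nll <- nll / m
  pen_beta <- if (config$standardize) {
    beta * standardize_stats(labeled$features)$scale
  } else beta
  pen <- config$lambda * (config$l1_ratio * sum(abs(pen_beta)) +
                            (1 - config$l1_ratio) / 2 * sum(pen_beta^2))
  anchor <- 0
  if (!is.null(unlabeled) && config$gamma > 0) {
    eta_u <- drop(unlabeled$features %*% beta) + b
    anchor <- sum((unlabeled$anchors - sigmoid(eta_u))^2)
    if (config$normalize_terms) anchor <- anchor / nrow(unlabeled$features)
    anchor <- config$gamma * anchor
  }
  nll + pen + anchor
}

#' Fit the semi-supervised elastic-net logistic model
#'
#' Deterministic given the inputs (zero initialization, no randomness in the
#' optimizer). The accepted objective sequence is non-increasing by
#' construction; `converged` reports whether the relative objective change
#' fell below `config$tol` before `config$max_iter`.
#'
#' @param labeled a [training_set()] containing both classes.
#' @param unlabeled an [unlabeled_set()] or NULL.
#' @param config a [fit_config()].
#' @return a `genonet_fit`: intercept and coefficients on the original
#'   feature scale, objective value, convergence flag, objective trace.
#' @export
fit_semisupervised <- function(labeled, unlabeled = NULL, config = fit_config()) {
  y <- labeled$labels
  if (length(unique(y)) < 2) {
    stop("labeled set must contain both classes", call. = FALSE)
  }
  X <- labeled$features
  p <- ncol(X); m <- nrow(X)
  if (!is.null(unlabeled) && ncol(unlabeled$features) != p) {
    stop("labeled and unlabeled feature dimensions disagree", call. = FALSE)
  }
  st <- if (config$standardize) standardize_stats(X) else
    list(center = rep(0, p), scale = rep(1, p))
  Xs <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  use_anchor <- !is.null(unlabeled) && config$gamma > 0
  Us <- if (use_anchor) {
    sweep(sweep(unlabeled$features, 2, st$center), 2, st$scale, "/")
  } else NULL
  a <- if (use_anchor) unlabeled$anchors else NULL
  w_l <- if (config$normalize_terms) 1 / m else 1
  w_u <- if (use_anchor && config$normalize_terms) 1 / nrow(Us) else 1
  lam1 <- config$lambda * config$l1_ratio
  lam2 <- config$lambda * (1 - config$l1_ratio)
  gam <- config$gamma

  smooth_val <- function(th) {
    b <- th[1]; beta <- th[-1]
    eta <- drop(Xs %*% beta) + b
    v <- w_l * logistic_nll(eta, y) + lam2 / 2 * sum(beta^2)
    if (use_anchor) {
      q <- sigmoid(drop(Us %*% beta) + b)
      v <- v + gam * w_u * sum((a - q)^2)
    }
    v
  }
  smooth_grad <- function(th) {
    b <- th[1]; beta <- th[-1]
    pr <- sigmoid(drop(Xs %*% beta) + b)
    r <- w_l * (pr - y)
    g_b <- sum(r)
    g_beta <- drop(crossprod(Xs, r)) + lam2 * beta
    if (use_anchor) {
      q <- sigmoid(drop(Us %*% beta) + b)
      ru <- gam * w_u * 2 * (q - a) * q * (1 - q)
      g_b <- g_b + sum(ru)
      g_beta <- g_beta + drop(crossprod(Us, ru))
    }
    c(g_b, g_beta)
  }
  prox <- function(th, t) {
    # soft-threshold the coefficients (not the intercept)
    beta <- th[-1]
    th[-1] <- sign(beta) * pmax(abs(beta) - t * lam1, 0)
    th
  }
  obj <- function(th) smooth_val(th) + lam1 * sum(abs(th[-1]))

  th <- rep(0, p + 1L)          # current accepted point
  z <- th                       # momentum point
  t_mom <- 1
  L <- max(1, 0.25 * w_l * sum(Xs^2) / max(1, m))  # crude initial Lipschitz
  f_cur <- obj(th)
  trace <- f_cur
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    n_iter <- it
    g_z <- smooth_grad(z)
    f_z <- smooth_val(z)
    repeat {
      step <- 1 / L
      cand <- prox(z - step * g_z, step)
      dlt <- cand - z
      if (smooth_val(cand) <= f_z + sum(g_z * dlt) + L / 2 * sum(dlt^2) ||
          L > 1e18) break
      L <- L * 2
    }
    f_cand <- obj(cand)
    if (f_cand > f_cur) {
      # monotone safeguard: restart momentum from the best point
      z <- th
      t_mom <- 1
      g_z <- smooth_grad(z)
      f_z <- smooth_val(z)
      repeat {
        step <- 1 / L
        cand <- prox(z - step * g_z, step)
        dlt <- cand - z
        if (smooth_val(cand) <= f_z + sum(g_z * dlt) + L / 2 * sum(dlt^2) ||
            L > 1e18) break
        L <- L * 2
      }
      f_cand <- obj(cand)
      if (f_cand > f_cur) { converged <- TRUE; break }  # no further descent
    }
    t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    z <- cand + (t_mom - 1) / t_next * (cand - th)
    rel <- abs(f_cur - f_cand) / max(1, abs(f_cur))
    th <- cand
    f_prev <- f_cur
    f_cur <- f_cand
    trace <- c(trace, f_cur)
    t_mom <- t_next
    L <- max(L * 0.9, 1e-8)
    if (rel < config$tol && it > 1) { converged <- TRUE; break }
  }
  beta_std <- th[-1]
  beta_orig <- beta_std / st$scale
  intercept <- th[1] - sum(beta_std * st$center / st$scale)
  names(beta_orig) <- colnames(X)
  structure(list(
    intercept = intercept,
    coefficients = beta_orig,
    center = st$center, scale = st$scale,
    config = config,
    objective_value = f_cur,
    converged = converged,
    n_iter = n_iter,
    objective_trace = trace,
    tissue = labeled$tissue), class = "genonet_fit")
}

#' @export
print.genonet_fit <- function(x, ...) {
  cat("genonet_fit:", length(x$coefficients), "features;",
      sum(x$coefficients != 0), "nonzero; objective",
      format(x$objective_value, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Predict functional scores
#'
#' @param object a `genonet_fit`.
#' @param features numeric matrix with the fit's feature columns.
#' @param ... unused.
#' @return scores in (0, 1): sigma(intercept + X beta).
#' @export
predict.genonet_fit <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != length(object$coefficients)) {
    stop("feature width ", ncol(features), " does not match fit (",
         length(object$coefficients), ")", call. = FALSE)
  }
  sigmoid(drop(features %*% object$coefficients) + object$intercept)
}

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney rank statistic: the probability that a random
#' positive outscores a random negative, ties counted half.
#'
#' @param labels binary 0/1 vector (both classes required).
#' @param scores numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Tune the anchor weight gamma by cross-validated AUROC
#'
#' Stratified k-fold cross-validation on the labeled set; for each candidate
#' gamma the model is refit on each training split (with the full unlabeled
#' set) and scored on the held-out labeled variants. The gamma with the
#' highest mean AUROC wins; ties go to the smallest gamma (the less
#' assumption-laden model). Deterministic given `config$seed`.
#'
#' @param labeled a [training_set()].
#' @param unlabeled an [unlabeled_set()].
#' @param gamma_grid candidate gamma values (non-empty).
#' @param folds number of CV folds (>= 2).
#' @param config a [fit_config()] (its `gamma` is ignored).
#' @return list(best_gamma, table = data.frame(gamma, mean_auroc)).
#' @export
tune_gamma <- function(labeled, unlabeled, gamma_grid, folds = 5L,
                       config = fit_config()) {
  if (length(gamma_grid) == 0) stop("gamma grid is empty", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  gamma_grid <- sort(as.numeric(gamma_grid))
  fold_of <- stratified_folds(labeled$labels, folds, config$seed)
  for (k in seq_len(folds)) {
    test <- fold_of == k
    if (length(unique(labeled$labels[test])) < 2 ||
        length(unique(labeled$labels[!test])) < 2) {
      stop("fold ", k, " lacks both classes after stratification; ",
           "reduce folds", call. = FALSE)
    }
  }
  mean_auc <- vapply(gamma_grid, function(g) {
    cfg <- config; cfg$gamma <- g
    aucs <- vapply(seq_len(folds), function(k) {
      test <- fold_of == k
      tr <- training_set(labeled$features[!test, , drop = FALSE],
                         labeled$labels[!test], labeled$ids[!test],
                         labeled$tissue)
      fit <- fit_semisupervised(tr, unlabeled, cfg)
      auroc(labeled$labels[test],
            predict(fit, labeled$features[test, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- gamma_grid[which.max(mean_auc)]  # which.max takes the first (smallest) on ties
  list(best_gamma = best,
       table = data.frame(gamma = gamma_grid, mean_auroc = mean_auc))
}
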