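# Abiotic-vs-biotic classification on the binary feature matrix.
#
# Class encoding: abiotic = 1 (positive), biotic = 0, so positive decision
# scores and positive linear coefficients mean abiotic-enriched.
#
# Model families and hyperparameter grids:
#   logreg_l1 / logreg_l2  C in 10^-4..10^4   (glmnet, lambda = 1/(C*n))
#   svm                    C in 10^-3..10^3 x kernel in {linear, polynomial,
#                          radial basis function, sigmoid} (in-package SMO)
#   bernoulli_nb           alpha in {0.01, 0.1, 0.5, 1, 5, 10}
#   random_forest          trees in {20, 50, 100, 200, 500}
# Grids are ordered strongest-regularization-first so that validation ties
# break toward the more conservative model (important at n = 18).

MODEL_FAMILIES <- c("logreg_l1", "logreg_l2", "svm", "random_forest", "bernoulli_nb")

#' Model specification: family plus hyperparameter grid
#'
#' @param family One of `logreg_l1`, `logreg_l2`, `svm`, `random_forest`,
#'   `bernoulli_nb`.
#' @param grid Optional data.frame overriding the default grid (one row per
#'   grid point, columns named after the hyperparameters).
#' @return A `model_spec` list with `family` and `grid`.
#' @export
model_spec <- function(family = "logreg_l2", grid = NULL) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(grid)) {
    grid <- switch(family,
      logreg_l1 = ,
      logreg_l2 = data.frame(C = 10^(-4:4)),
      svm = expand.grid(C = 10^(-3:3),
                        kernel = c("linear", "polynomial", "radial basis function", "sigmoid"),
                        stringsAsFactors = FALSE)[, c("C", "kernel")],
      bernoulli_nb = data.frame(alpha = c(10, 5, 1, 0.5, 0.1, 0.01)),
      random_forest = data.frame(n_trees = c(20L, 50L, 100L, 200L, 500L)))
  }
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  structure(list(family = family, grid = grid), class = "model_spec")
}

# ---- individual fitters -------------------------------------------------

# All fitters take X (samples x features, 0/1), y (0/1), one grid row `hp`
# and a seed (used only where fitting is stochastic), and return a model
# whose decision scores from score_one() are > 0 for predicted class 1.

fit_one <- function(family, hp, X, y, seed = 0L) {
  if (length(unique(y)) < 2L) {
    return(structure(list(family = "constant", value = if (y[1L] == 1) 1e6 else -1e6),
                     class = "lt_model"))
  }
  m <- switch(family,
    logreg_l1 = fit_logreg(X, y, C = hp$C, alpha = 1),
    logreg_l2 = fit_logreg(X, y, C = hp$C, alpha = 0),
    svm = fit_svm(X, y, C = hp$C, kernel = hp$kernel),
    bernoulli_nb = fit_bernoulli_nb(X, y, alpha = hp$alpha),
    random_forest = fit_rf(X, y, n_trees = hp$n_trees, seed = seed),
    stopf("unknown model family: %s", family))
  m$family <- family
  m$hp <- hp
  class(m) <- "lt_model"
  m
}

score_one <- function(model, X) {
  if (model$family == "constant") return(rep(model$value, nrow(X)))
  switch(model$family,
    logreg_l1 = ,
    logreg_l2 = as.vector(X %*% model$coefficients) + model$intercept,
    svm = svm_decision(model, X),
    bernoulli_nb = nb_decision(model, X),
    random_forest = rf_decision(model, X))
}

# Ridge-penalized logistic regression by IRLS with an unpenalized
# intercept, minimizing sum(NLL) + (n*lam/2)||w||^2 -- the same objective as
# glmnet at lambda = lam. Used when glmnet refuses the input (a class with
# fewer than two observations, as happens in leave-one-out loops over very
# small training sets).
ridge_logreg_irls <- function(X, y, lam, maxit = 100L, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  w <- numeric(p + 1L)
  pen <- c(0, rep(n * lam, p))
  for (it in seq_len(maxit)) {
    eta <- as.vector(Z %*% w)
    mu <- 1 / (1 + exp(-eta))
    g <- as.vector(crossprod(Z, y - mu)) - pen * w
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * W, Z) + diag(pen + 1e-12, p + 1L)
    step <- solve(H, g)
    w <- w + step
    if (max(abs(step)) < tol) break
  }
  list(intercept = w[1L], coefficients = w[-1L])
}

# penalized logistic regression via glmnet; lambda = 1/(C * n) maps the
# sklearn-style inverse regularization strength C onto glmnet's objective
fit_logreg <- function(X, y, C, alpha) {
  n <- nrow(X)
  lam <- 1 / (C * n)
  if (min(table(y)) < 2L) return(ridge_logreg_irls(X, y, lam))
  Xp <- pad_two_cols(X)
  path <- sort(unique(c(lam, lam * c(1000, 100, 10))), decreasing = TRUE)
  # suppress glmnet's small-n advisory warnings; n = 15..18 is the use case
  fit <- suppressWarnings(
    glmnet::glmnet(Xp, y, family = "binomial", alpha = alpha,
                   lambda = path, standardize = FALSE, thresh = 1e-10))
  beta <- as.vector(stats::coef(fit, s = lam, exact = FALSE))
  list(intercept = beta[1L], coefficients = beta[-1L][seq_len(ncol(X))])
}

# glmnet refuses single-column predictor matrices
pad_two_cols <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, matrix(0, nrow = nrow(X), ncol = 2L - ncol(X)))
}

# Bernoulli naive Bayes with Laplace/Lidstone smoothing alpha
fit_bernoulli_nb <- function(X, y, alpha) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  th1 <- (colSums(X[y == 1, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  th0 <- (colSums(X[y == 0, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  list(log_prior = log(n1 / n0),
       w = log(th1) - log(th0) - (log(1 - th1) - log(1 - th0)),
       b = sum(log(1 - th1) - log(1 - th0)))
}

nb_decision <- function(model, X) {
  as.vector(X %*% model$w) + model$b + model$log_prior
}

# ---- kernel SVM via simplified SMO --------------------------------------

svm_kernel <- function(kernel, A, B, gamma, coef0 = 0, degree = 3) {
  G <- A %*% t(B)
  switch(kernel,
    "linear" = G,
    "polynomial" = (gamma * G + coef0)^degree,
    "radial basis function" = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    },
    "sigmoid" = tanh(gamma * G + coef0),
    stopf("unknown SVM kernel: %s", kernel))
}

fit_svm <- function(X, y, C, kernel, tol = 1e-3, max_passes = 20L) {
  ys <- ifelse(y == 1, 1, -1)
  v <- mean((X - mean(X))^2)                       # 'scale' gamma convention
  gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  K <- svm_kernel(kernel, X, X, gamma)
  n <- length(ys)
  alpha <- numeric(n); b <- 0
  passes <- 0L
  while (passes < max_passes) {
    changed <- 0L
    for (i in seq_len(n)) {
      f <- as.vector(K %*% (alpha * ys)) + b
      E <- f - ys
      if (!((ys[i] * E[i] < -tol && alpha[i] < C) ||
            (ys[i] * E[i] >  tol && alpha[i] > 0))) next
      j <- which.max(abs(E - E[i]))
      if (j == i) next
      ai0 <- alpha[i]; aj0 <- alpha[j]
      if (ys[i] != ys[j]) {
        L <- max(0, aj0 - ai0); H <- min(C, C + aj0 - ai0)
      } else {
        L <- max(0, ai0 + aj0 - C); H <- min(C, ai0 + aj0)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- min(H, max(L, aj0 - ys[j] * (E[i] - E[j]) / eta))
      if (abs(aj - aj0) < 1e-8) next
      ai <- ai0 + ys[i] * ys[j] * (aj0 - aj)
      alpha[i] <- ai; alpha[j] <- aj
      b1 <- b - E[i] - ys[i] * (ai - ai0) * K[i, i] - ys[j] * (aj - aj0) * K[i, j]
      b2 <- b - E[j] - ys[i] * (ai - ai0) * K[i, j] - ys[j] * (aj - aj0) * K[j, j]
      b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
      changed <- changed + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b, ys = ys, sv = X, gamma = gamma, kernel = kernel)
}

svm_decision <- function(model, X) {
  K <- svm_kernel(model$kernel, X, model$sv, model$gamma)
  as.vector(K %*% (model$alpha * model$ys)) + model$b
}

# ---- random forest (Gini, binary features) ------------------------------

fit_rf <- function(X, y, n_trees, seed = 0L, mtry = NULL) {
  p <- ncol(X)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  trees <- withr::with_seed(seed, lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(nrow(X), replace = TRUE)
    rf_grow(X[idx, , drop = FALSE], y[idx], mtry)
  }))
  list(trees = trees)
}

rf_gini <- function(y) {
  if (length(y) == 0L) return(0)
  p <- mean(y)
  2 * p * (1 - p)
}

rf_grow <- function(X, y, mtry, depth = 0L) {
  if (length(unique(y)) < 2L || depth >= 25L) return(list(leaf = TRUE, p = mean(y)))
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  base <- rf_gini(y)
  best <- NULL; best_gain <- 0
  for (f in feats) {
    on <- X[, f] == 1
    if (all(on) || !any(on)) next
    gain <- base - (mean(on) * rf_gini(y[on]) + mean(!on) * rf_gini(y[!on]))
    if (gain > best_gain + 1e-12) { best_gain <- gain; best <- f }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = mean(y)))
  on <- X[, best] == 1
  list(leaf = FALSE, feature = best,
       yes = rf_grow(X[on, , drop = FALSE], y[on], mtry, depth + 1L),
       no  = rf_grow(X[!on, , drop = FALSE], y[!on], mtry, depth + 1L))
}

rf_predict_tree <- function(node, x) {
  while (!node$leaf) node <- if (x[node$feature] == 1) node$yes else node$no
  node$p
}

rf_decision <- function(model, X) {
  probs <- vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(model$trees, rf_predict_tree, numeric(1), x = X[i, ]))
  }, numeric(1))
  probs - 0.5
}

# ---- shared CV machinery ------------------------------------------------

#' Area under the ROC curve from decision scores
#'
#' Mann-Whitney formulation with half-credit for tied scores.
#'
#' @param scores Numeric decision scores.
#' @param y 0/1 labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stopf("AUC requires both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# matrix (n_val x n_grid) of decision scores for every grid point; batched
# over the glmnet lambda path for the logistic families
validate_grid <- function(family, grid, X_tr, y_tr, X_val, seed = 0L) {
  if (length(unique(y_tr)) < 2L) {
    val <- if (y_tr[1L] == 1) 1e6 else -1e6
    return(matrix(val, nrow = nrow(X_val), ncol = nrow(grid)))
  }
  if (family %in% c("logreg_l1", "logreg_l2")) {
    n <- nrow(X_tr)
    lams <- 1 / (grid$C * n)
    if (min(table(y_tr)) < 2L) {
      # glmnet refuses near-degenerate classes; ridge IRLS per grid point
      sc <- vapply(lams, function(l) {
        m <- ridge_logreg_irls(X_tr, y_tr, l)
        as.vector(X_val %*% m$coefficients) + m$intercept
      }, numeric(nrow(X_val)))
      return(matrix(sc, nrow = nrow(X_val), ncol = nrow(grid)))
    }
    path <- sort(unique(c(lams, max(lams) * c(1000, 100, 10))), decreasing = TRUE)
    fit <- suppressWarnings(
      glmnet::glmnet(pad_two_cols(X_tr), y_tr, family = "binomial",
                     alpha = if (family == "logreg_l1") 1 else 0,
                     lambda = path, standardize = FALSE, thresh = 1e-10))
    pred <- stats::predict(fit, newx = pad_two_cols(X_val), s = lams,
                           type = "link", exact = FALSE)
    return(matrix(pred, nrow = nrow(X_val), ncol = nrow(grid)))
  }
  sc <- vapply(seq_len(nrow(grid)), function(g) {
    m <- fit_one(family, grid[g, , drop = FALSE], X_tr, y_tr, seed = seed)
    score_one(m, X_val)
  }, numeric(nrow(X_val)))
  matrix(sc, nrow = nrow(X_val), ncol = nrow(grid))
}

# leave-one-out hyperparameter selection on a training set: mean validation
# accuracy per grid point, first maximum (grids are ordered
# strongest-regularization-first)
select_hp_loo <- function(family, grid, X, y, seed = 0L) {
  n <- nrow(X)
  acc <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  for (v in seq_len(n)) {
    sc <- validate_grid(family, grid, X[-v, , drop = FALSE], y[-v],
                        X[v, , drop = FALSE], seed = seed)
    acc[v, ] <- as.integer(sc > 0) == y[v]
  }
  mean_acc <- colMeans(acc)
  list(index = which.max(mean_acc), mean_acc = mean_acc)
}

fm_xy <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- t(fm$matrix)
  storage.mode(X) <- "double"
  y <- as.integer(fm$labels == "abiotic")
  if (length(unique(y)) < 2L) stopf("classification requires both classes in the matrix")
  list(X = X, y = y)
}

#' Nested 9-fold / leave-one-out cross-validation
#'
#' Per seed the samples are shuffled and split into folds of two. For each
#' fold the held-out pair is scored by the model refit on the remaining
#' samples with the hyperparameters that maximize mean leave-one-out
#' validation accuracy inside the training set (ties toward stronger
#' regularization). Test accuracy is averaged over folds and seeds; AUC is
#' computed per seed by pooling decision scores across folds and then
#' averaged over seeds.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param n_seeds Number of random shuffles (default 10; seeds 0..n-1).
#' @param fold_size Samples per fold (default 2; 18 samples give 9 folds).
#' @return A `cv_report`: list with `scheme`, `mean_accuracy`, `mean_auc`,
#'   `per_seed` (data.frame seed/accuracy/auc) and `selected` (hyperparameter
#'   grid row chosen per seed x fold).
#' @export
ninefold_loo_cv <- function(fm, spec = model_spec("logreg_l2"), n_seeds = 10L,
                            fold_size = 2L) {
  d <- fm_xy(fm)
  n <- nrow(d$X)
  if (n %% fold_size != 0L) {
    stopf("%d samples cannot be split into folds of %d", n, fold_size)
  }
  n_folds <- n %/% fold_size
  per_seed <- data.frame(seed = seq_len(n_seeds) - 1L, accuracy = NA_real_, auc = NA_real_)
  selected <- list()
  for (s in seq_len(n_seeds)) {
    seed <- s - 1L
    perm <- withr::with_seed(seed, sample.int(n))
    folds <- split(perm, rep(seq_len(n_folds), each = fold_size))
    fold_acc <- numeric(n_folds)
    pooled_scores <- numeric(n); pooled_y <- integer(n); pos <- 1L
    for (k in seq_len(n_folds)) {
      test <- folds[[k]]
      train <- setdiff(perm, test)
      sel <- select_hp_loo(spec$family, spec$grid, d$X[train, , drop = FALSE],
                           d$y[train], seed = seed)
      hp <- spec$grid[sel$index, , drop = FALSE]
      m <- fit_one(spec$family, hp, d$X[train, , drop = FALSE], d$y[train], seed = seed)
      sc <- score_one(m, d$X[test, , drop = FALSE])
      fold_acc[k] <- mean(as.integer(sc > 0) == d$y[test])
      idx <- pos:(pos + length(test) - 1L)
      pooled_scores[idx] <- sc; pooled_y[idx] <- d$y[test]; pos <- pos + length(test)
      selected[[length(selected) + 1L]] <- cbind(seed = seed, fold = k, hp)
    }
    per_seed$accuracy[s] <- mean(fold_acc)
    per_seed$auc[s] <- auc_score(pooled_scores, pooled_y)
  }
  structure(list(scheme = "ninefold_loo", family = spec$family,
                 mean_accuracy = mean(per_seed$accuracy),
                 mean_auc = mean(per_seed$auc),
                 per_seed = per_seed,
                 selected = do.call(rbind, selected)),
            class = "cv_report")
}

# round-robin stratified fold assignment; guarantees every fold holds at
# least one sample of each class when each class has >= n_folds members
stratified_folds <- function(y, n_folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  assign
}

#' Nested stratified K-fold cross-validation
#'
#' Outer stratified split into `outer` folds (every fold holds at least one
#' sample of each class). For each outer fold, the remaining folds serve in
#' turn as inner validation folds; the grid point with the highest mean
#' validation AUC is refit on all remaining folds and scored on the held-out
#' fold by AUC. Fold AUCs are averaged over outer folds and seeds.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param outer,inner Outer fold count (default 6) and inner fold count
#'   (default 5, the remaining outer folds).
#' @param n_seeds Number of repetitions (default 10; seeds 0..n-1).
#' @return A `cv_report` with mean AUC/accuracy over folds and seeds.
#' @export
stratified_nested_cv <- function(fm, spec = model_spec("logreg_l2"), outer = 6L,
                                 inner = 5L, n_seeds = 10L) {
  d <- fm_xy(fm)
  if (min(table(d$y)) < outer) {
    stopf("each class needs >= %d samples for %d stratified folds", outer, outer)
  }
  per_seed <- data.frame(seed = seq_len(n_seeds) - 1L, accuracy = NA_real_, auc = NA_real_)
  for (s in seq_len(n_seeds)) {
    seed <- s - 1L
    assign <- stratified_folds(d$y, outer, seed)
    fold_auc <- numeric(outer); fold_acc <- numeric(outer)
    for (k in seq_len(outer)) {
      test <- which(assign == k)
      rest_folds <- setdiff(seq_len(outer), k)
      inner_folds <- rest_folds[seq_len(min(inner, length(rest_folds)))]
      # mean validation AUC per grid point over the inner folds
      val_auc <- matrix(NA_real_, nrow = length(inner_folds), ncol = nrow(spec$grid))
      for (vi in seq_along(inner_folds)) {
        val <- which(assign == inner_folds[vi])
        tr <- which(!assign %in% c(k, inner_folds[vi]))
        sc <- validate_grid(spec$family, spec$grid, d$X[tr, , drop = FALSE],
                            d$y[tr], d$X[val, , drop = FALSE], seed = seed)
        val_auc[vi, ] <- apply(sc, 2L, function(col) {
          if (length(unique(d$y[val])) < 2L) NA_real_ else auc_score(col, d$y[val])
        })
      }
      sel <- which.max(colMeans(val_auc, na.rm = TRUE))
      hp <- spec$grid[sel, , drop = FALSE]
      train <- which(assign != k)
      m <- fit_one(spec$family, hp, d$X[train, , drop = FALSE], d$y[train], seed = seed)
      sc <- score_one(m, d$X[test, , drop = FALSE])
      fold_auc[k] <- auc_score(sc, d$y[test])
      fold_acc[k] <- mean(as.integer(sc > 0) == d$y[test])
    }
    per_seed$auc[s] <- mean(fold_auc)
    per_seed$accuracy[s] <- mean(fold_acc)
  }
  structure(list(scheme = "stratified_6x5", family = spec$family,
                 mean_accuracy = mean(per_seed$accuracy),
                 mean_auc = mean(per_seed$auc),
                 per_seed = per_seed, selected = NULL),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s): mean accuracy %.3f, mean AUC %.3f over %d seeds\n",
              x$scheme, x$family, x$mean_accuracy, x$mean_auc, nrow(x$per_seed)))
  invisible(x)
}

#' Fit the final deployed classifier
#'
#' Leave-one-out over the full matrix selects the hyperparameters (ties
#' toward stronger regularization), then the model is refit on all samples.
#' The shipped configuration is L2 logistic regression; passing
#' `hyperparameters` (e.g. `data.frame(C = 0.1)`) skips the selection.
#'
#' @param fm A `feature_matrix` with both classes present.
#' @param spec A [model_spec()] (default L2 logistic regression).
#' @param hyperparameters Optional single-row data.frame fixing the grid
#'   point.
#' @param seed Seed for stochastic families.
#' @return A `fitted_classifier` with `coefficients` (named by feature_id;
#'   linear families only), `intercept`, `family`, `hyperparameters`.
#' @export
fit_final <- function(fm, spec = model_spec("logreg_l2"), hyperparameters = NULL,
                      seed = 0L) {
  d <- fm_xy(fm)
  if (is.null(hyperparameters)) {
    sel <- select_hp_loo(spec$family, spec$grid, d$X, d$y, seed = seed)
    hyperparameters <- spec$grid[sel$index, , drop = FALSE]
  }
  m <- fit_one(spec$family, hyperparameters, d$X, d$y, seed = seed)
  coefs <- if (spec$family %in% c("logreg_l1", "logreg_l2")) {
    stats::setNames(m$coefficients, colnames(d$X))
  } else NULL
  structure(list(family = spec$family, hyperparameters = hyperparameters,
                 coefficients = coefs,
                 intercept = if (!is.null(coefs)) m$intercept else NULL,
                 model = m, feature_ids = colnames(d$X)),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("<fitted_classifier> %s (%s), %d features\n",
              x$family, hp, length(x$feature_ids)))
  invisible(x)
}

#' Decision scores / class predictions from a fitted classifier
#'
#' @param object A `fitted_classifier`.
#' @param fm A `feature_matrix` (columns = samples to score).
#' @param type `"score"` (decision values) or `"class"` (0/1, 1 = abiotic).
#' @param ... Unused.
#' @return Named numeric (scores) or integer (classes) vector per sample.
#' @export
predict.fitted_classifier <- function(object, fm, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- t(fm$matrix)
  storage.mode(X) <- "double"
  # align columns on feature id
  X <- X[, object$feature_ids, drop = FALSE]
  sc <- if (!is.null(object$coefficients)) {
    as.vector(X %*% object$coefficients) + object$intercept
  } else {
    score_one(object$model, X)
  }
  names(sc) <- rownames(X)
  if (type == "score") sc else stats::setNames(as.integer(sc > 0), rownames(X))
}

#' Run one CV scheme for every model family and rank the results
#'
#' @param fm A `feature_matrix`.
#' @param scheme `"ninefold_loo"` or `"stratified_6x5"`.
#' @param families Model families to compare (default all five variants).
#' @param n_seeds Seeds per family.
#' @return data.frame ranked by mean accuracy then mean AUC.
#' @export
compare_models <- function(fm, scheme = c("ninefold_loo", "stratified_6x5"),
                           families = MODEL_FAMILIES, n_seeds = 10L) {
  scheme <- match.arg(scheme)
  rows <- lapply(families, function(f) {
    rep <- if (scheme == "ninefold_loo") {
      ninefold_loo_cv(fm, model_spec(f), n_seeds = n_seeds)
    } else {
      stratified_nested_cv(fm, model_spec(f), n_seeds = n_seeds)
    }
    data.frame(family = f, mean_accuracy = rep$mean_accuracy, mean_auc = rep$mean_auc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_accuracy, -out$mean_auc), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
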