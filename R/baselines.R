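## The 6 x 12 grid of baseline classifiers. Six algorithms (LR, PLS, KNN,
## SVM, ET, RF) are tuned by tenfold cross-validated MCC over fixed
## hyperparameter grids and emit predicted confidences ("probabilistic
## features", PFs) in [0, 1]. Training-set PFs use the out-of-fold protocol
## (same folds for all models) so the meta-learner never sees in-sample
## confidences; test-set PFs come from full-training refits.

BASELINE_ALGORITHMS <- c("LR", "PLS", "KNN", "SVM", "ET", "RF")

#' Hyperparameter search grid per algorithm
#'
#' ET and RF search `n_estimators` in {20, 50, 100, 200, 500}; LR searches
#' `C` in {0.001, 0.01, 0.1, 1, 10, 100}; SVM searches `C` in
#' {1, 2, 4, 8, 16, 32}. KNN and PLS use their defaults (empty grid).
#'
#' @param algorithm one of `"LR"`, `"PLS"`, `"KNN"`, `"SVM"`, `"ET"`, `"RF"`.
#' @return a named list with at most one numeric grid, sorted ascending.
#' @export
hyper_grid <- function(algorithm) {
  switch(match.arg(algorithm, BASELINE_ALGORITHMS),
         ET = list(n_estimators = c(20, 50, 100, 200, 500)),
         RF = list(n_estimators = c(20, 50, 100, 200, 500)),
         LR = list(C = c(0.001, 0.01, 0.1, 1, 10, 100)),
         SVM = list(C = c(1, 2, 4, 8, 16, 32)),
         KNN = list(),
         PLS = list())
}

#' Enumerate the baseline grid
#'
#' The full design crosses 6 algorithms with 12 fingerprint families, giving
#' 72 baseline model specs. The enumeration order (algorithms outer,
#' fingerprints inner) fixes the column order of the stacked feature matrix.
#'
#' @param algorithms subset of algorithms (default all six).
#' @param fingerprints subset of fingerprint family names (default all twelve).
#' @return a `data.frame` with columns `algorithm`, `fingerprint`, `id`
#'   (e.g. `"RF-Circle"`).
#' @export
baseline_grid <- function(algorithms = BASELINE_ALGORITHMS,
                          fingerprints = fingerprint_families()$name) {
  ## fingerprint names are free-form: the layer also runs on user-supplied
  ## precomputed feature blocks
  stopifnot(all(algorithms %in% BASELINE_ALGORITHMS), length(fingerprints) > 0)
  out <- expand.grid(fingerprint = fingerprints, algorithm = algorithms,
                     stringsAsFactors = FALSE)[, c("algorithm", "fingerprint")]
  out$id <- paste(out$algorithm, out$fingerprint, sep = "-")
  rownames(out) <- NULL
  out
}

#' Stratified cross-validation folds
#'
#' Assigns every compound to exactly one held-out fold, preserving the class
#' ratio per fold. The same fold vector is shared by all 72 baseline models
#' so their out-of-fold confidences are aligned.
#'
#' @param y binary labels.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return integer fold assignment, one entry per compound.
#' @export
make_folds <- function(y, n_folds = 10, seed = 1) {
  y <- as_binary01(y)
  if (min(table(y)) < n_folds) {
    stop_input("stratification error: smallest class (%d) has fewer members than folds (%d)",
               min(table(y)), n_folds)
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in c(0, 1)) {
      ix <- sample(which(y == cl))
      folds[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  folds
}

## ---- per-algorithm fit/predict -------------------------------------------

fit_algorithm <- function(algorithm, X, y, params = list(), seed = 1) {
  X <- as.matrix(X)
  y <- as_binary01(y)
  if (length(unique(y)) < 2) stop_input("training fold has a single class")
  fit <- switch(algorithm,
    LR = {
      C <- params$C %||% 1
      glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                     alpha = 0, lambda = 1 / (nrow(X) * C), standardize = FALSE)
    },
    PLS = {
      ncomp <- min(params$n_components %||% 2, ncol(X) - 1, nrow(X) - 1)
      keep <- which(apply(X, 2, stats::sd) > 0)
      if (length(keep) < 2) stop_input("PLS needs at least two non-constant features")
      f <- mixOmics::pls(X[, keep, drop = FALSE], matrix(as.numeric(y), ncol = 1),
                         ncomp = max(1, ncomp), mode = "regression", scale = FALSE)
      list(pls = f, keep = keep, ncomp = max(1, ncomp))
    },
    KNN = list(X = X, y = y, k = params$k %||% 5),
    SVM = {
      m <- e1071::svm(X, factor(y, levels = 0:1), kernel = "radial",
                      cost = params$C %||% 1, scale = FALSE)
      dv <- as.numeric(attr(stats::predict(m, X, decision.values = TRUE),
                            "decision.values"))
      ## Platt-style sigmoid on training decision values (deterministic,
      ## unlike libsvm's internal probability machinery)
      platt <- suppressWarnings(stats::glm(y ~ dv, family = stats::binomial(),
                                           data = data.frame(y = y, dv = dv)))
      list(svm = m, platt_coef = stats::coef(platt))
    },
    ET = ranger::ranger(x = X, y = factor(y, levels = 0:1),
                        num.trees = params$n_estimators %||% 100,
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        probability = TRUE, num.threads = 1, seed = seed,
                        verbose = FALSE),
    RF = ranger::ranger(x = X, y = factor(y, levels = 0:1),
                        num.trees = params$n_estimators %||% 100,
                        probability = TRUE, num.threads = 1, seed = seed,
                        verbose = FALSE),
    stop_config("unknown algorithm '%s'", algorithm))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 features = colnames(X), seed = seed),
            class = "baseline_fit")
}

predict_confidence <- function(model, X) {
  stopifnot(inherits(model, "baseline_fit"))
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (!is.null(model$features) && ncol(X) != length(model$features)) {
    stop_input("feature-width mismatch: model trained on %d features, input has %d",
               length(model$features), ncol(X))
  }
  p <- switch(model$algorithm,
    LR = as.numeric(stats::predict(model$fit, X, type = "response")),
    PLS = {
      pr <- stats::predict(model$fit$pls, X[, model$fit$keep, drop = FALSE])
      as.numeric(pr$predict[, 1, model$fit$ncomp])
    },
    KNN = {
      cl <- class::knn(model$fit$X, X, factor(model$fit$y, levels = 0:1),
                       k = model$fit$k, prob = TRUE)
      win <- attr(cl, "prob")
      ifelse(cl == "1", win, 1 - win)
    },
    SVM = {
      dv <- as.numeric(attr(stats::predict(model$fit$svm, X, decision.values = TRUE),
                            "decision.values"))
      stats::plogis(model$fit$platt_coef[1] + model$fit$platt_coef[2] * dv)
    },
    ET = stats::predict(model$fit, X, num.threads = 1)$predictions[, "1"],
    RF = stats::predict(model$fit, X, num.threads = 1)$predictions[, "1"])
  pmin(pmax(as.numeric(p), 0), 1)
}

## out-of-fold confidences for one (algorithm, params) under shared folds
oof_predict <- function(algorithm, X, y, folds, params, seed) {
  y <- as_binary01(y)
  pf <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
      stop_input("stratification error: fold %d degenerate", f)
    }
    m <- fit_algorithm(algorithm, X[tr, , drop = FALSE], y[tr], params,
                       seed = child_seed(seed, paste0(algorithm, f)))
    pf[!tr] <- predict_confidence(m, X[!tr, , drop = FALSE])
  }
  pf
}

## ---- tuning and PF generation --------------------------------------------

#' Tune one baseline model by cross-validated MCC
#'
#' Evaluates every grid point with the shared stratified folds, keeps the
#' value with the highest cross-validation MCC (ties go to the smaller
#' parameter value), then refits on all training rows.
#'
#' @param algorithm one of the six algorithm codes.
#' @param X normalized feature matrix (training rows).
#' @param y binary labels.
#' @param folds fold assignment from [make_folds()].
#' @param seed RNG seed for the fold models.
#' @return an object of class `trained_baseline` with elements `algorithm`,
#'   `params`, `model`, `cv_mcc`, `cv_scores` (one MCC per grid point) and
#'   `oof_pf` (out-of-fold confidences at the chosen parameters).
#' @export
tune_baseline <- function(algorithm, X, y, folds, seed = 1) {
  algorithm <- match.arg(algorithm, BASELINE_ALGORITHMS)
  y <- as_binary01(y)
  grid <- hyper_grid(algorithm)
  if (length(grid) == 0) {
    cand <- list(list())
    labels <- "default"
  } else {
    pname <- names(grid)[1]
    cand <- lapply(grid[[1]], function(v) stats::setNames(list(v), pname))
    labels <- as.character(grid[[1]])
  }
  oofs <- lapply(cand, function(p) oof_predict(algorithm, X, y, folds, p, seed))
  scores <- vapply(oofs, function(pf) mcc(cm_from_labels(as.integer(pf >= 0.5), y)),
                   numeric(1))
  best <- which.max(scores)  # grids ascend, so the first max is the smallest value
  model <- fit_algorithm(algorithm, X, y, cand[[best]], seed = child_seed(seed, algorithm))
  structure(list(algorithm = algorithm, params = cand[[best]],
                 model = model, cv_mcc = scores[best],
                 cv_scores = stats::setNames(scores, labels),
                 oof_pf = oofs[[best]]),
            class = "trained_baseline")
}

#' Out-of-fold probabilistic features
#'
#' Each training compound's PF is produced by the fold model that did not
#' train on it (standard stacked generalization). With
#' `pf_mode = "insample"` the confidences of the full refit are returned
#' instead.
#'
#' @param trained a [tune_baseline()] result.
#' @param X the training matrix the model was tuned on.
#' @param y binary labels.
#' @param pf_mode `"oof"` (default) or `"insample"`.
#' @return numeric PF vector in `[0, 1]`, one entry per training compound.
#' @export
oof_confidences <- function(trained, X, y, pf_mode = c("oof", "insample")) {
  pf_mode <- match.arg(pf_mode)
  stopifnot(inherits(trained, "trained_baseline"))
  if (pf_mode == "insample") return(predict_confidence(trained$model, X))
  trained$oof_pf
}

#' Test-set probabilistic features
#'
#' Confidences of the full-training refit on new compounds.
#'
#' @param trained a [tune_baseline()] result.
#' @param X_test feature matrix with the training feature width.
#' @return numeric PF vector in `[0, 1]`.
#' @export
test_confidences <- function(trained, X_test) {
  stopifnot(inherits(trained, "trained_baseline"))
  predict_confidence(trained$model, X_test)
}

#' Train the whole baseline layer
#'
#' Runs [tune_baseline()] for every cell of the algorithm x fingerprint grid
#' and assembles the stacked feature matrices: out-of-fold PFs for the
#' training compounds and refit PFs for test compounds.
#'
#' @param fps_train named list of normalized [fingerprint_matrix()] objects
#'   (training rows), one per family.
#' @param y binary training labels.
#' @param fps_test optional matching list for test rows.
#' @param algorithms algorithms to include (default all six).
#' @param n_folds folds for tuning and out-of-fold PFs (default 10).
#' @param seed RNG seed; also fixes the shared fold assignment.
#' @param pf_mode PF protocol for training rows, see [oof_confidences()].
#' @return a list with `models` (named `trained_baseline` list), `pf_train`
#'   and optionally `pf_test` ([pf_matrix()] objects), `folds`, `grid`.
#' @export
train_baseline_layer <- function(fps_train, y, fps_test = NULL,
                                 algorithms = BASELINE_ALGORITHMS,
                                 n_folds = 10, seed = 1,
                                 pf_mode = c("oof", "insample")) {
  pf_mode <- match.arg(pf_mode)
  y <- as_binary01(y)
  grid <- baseline_grid(algorithms, names(fps_train))
  folds <- make_folds(y, n_folds = n_folds, seed = seed)
  models <- vector("list", nrow(grid))
  pf_tr <- matrix(NA_real_, length(y), nrow(grid),
                  dimnames = list(fps_train[[1]]$ids, grid$id))
  pf_te <- NULL
  if (!is.null(fps_test)) {
    pf_te <- matrix(NA_real_, length(fps_test[[1]]$ids), nrow(grid),
                    dimnames = list(fps_test[[1]]$ids, grid$id))
  }
  for (k in seq_len(nrow(grid))) {
    alg <- grid$algorithm[k]; fam <- grid$fingerprint[k]
    msg("baseline %d/%d: %s", k, nrow(grid), grid$id[k])
    Xtr <- as.matrix(fps_train[[fam]])
    tb <- tune_baseline(alg, Xtr, y, folds, seed = child_seed(seed, grid$id[k]))
    models[[k]] <- tb
    pf_tr[, k] <- oof_confidences(tb, Xtr, y, pf_mode = pf_mode)
    if (!is.null(pf_te)) {
      pf_te[, k] <- test_confidences(tb, as.matrix(fps_test[[fam]]))
    }
  }
  names(models) <- grid$id
  list(models = models,
       pf_train = pf_matrix(pf_tr),
       pf_test = if (!is.null(pf_te)) pf_matrix(pf_te) else NULL,
       folds = folds, grid = grid, seed = seed, pf_mode = pf_mode)
}
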