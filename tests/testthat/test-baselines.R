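## the baseline layer is exercised on synthetic PF-style features so the
## tests isolate the learners from the chemistry

make_toy <- function(n = 80, p = 6, effect = 0.35, seed = 1) {
  syn <- make_synthetic_pf(n, n_columns = p, informative_columns = seq_len(p %/% 2),
                           effect = effect, noise_sd = 0.1, seed = seed)
  list(X = as.matrix(syn$pf), y = syn$y)
}

test_that("the full grid enumerates 72 specs in fixed order", {
  grid <- baseline_grid()
  expect_equal(nrow(grid), 72)
  expect_equal(length(unique(grid$algorithm)), 6)
  expect_equal(length(unique(grid$fingerprint)), 12)
  expect_equal(anyDuplicated(grid$id), 0)
  # order is fingerprint-inner within algorithm blocks and reproducible
  expect_identical(grid$id[1:3], c("LR-AP2D", "LR-Circle", "LR-CKD"))
  expect_identical(baseline_grid(), grid)
  # reduced grids enumerate the product
  expect_equal(nrow(baseline_grid(c("RF", "KNN"), c("MACCS", "Circle"))), 4)
})

test_that("hyperparameter grids expose the fixed search ranges", {
  expect_equal(hyper_grid("ET")$n_estimators, c(20, 50, 100, 200, 500))
  expect_equal(hyper_grid("RF")$n_estimators, c(20, 50, 100, 200, 500))
  expect_equal(hyper_grid("LR")$C, c(0.001, 0.01, 0.1, 1, 10, 100))
  expect_equal(hyper_grid("SVM")$C, c(1, 2, 4, 8, 16, 32))
  expect_length(hyper_grid("KNN"), 0)
  expect_length(hyper_grid("PLS"), 0)
})

test_that("stratified folds cover every compound once with both classes per fold", {
  y <- rep(c(1, 0), c(40, 24))
  folds <- make_folds(y, n_folds = 8, seed = 3)
  expect_equal(sort(unique(folds)), 1:8)
  expect_equal(length(folds), 64)
  for (f in 1:8) {
    expect_true(all(table(y[folds == f]) >= 1))
  }
  expect_identical(folds, make_folds(y, n_folds = 8, seed = 3))
  expect_error(make_folds(rep(c(1, 0), c(60, 4)), n_folds = 8), "stratification")
})

test_that("tuning evaluates each grid point once and breaks ties toward the smaller value", {
  toy <- make_toy(n = 60, p = 5, seed = 2)
  folds <- make_folds(toy$y, n_folds = 5, seed = 1)
  tb <- tune_baseline("ET", toy$X, toy$y, folds, seed = 1)
  expect_length(tb$cv_scores, 5)  # one CV evaluation per grid value
  expect_equal(tb$params$n_estimators,
               c(20, 50, 100, 200, 500)[which.max(tb$cv_scores)])
  # which.max returns the first maximum, i.e. the smallest tied value
  expect_equal(which.max(c(1, 1, 1, 1, 1)), 1)

  tbk <- tune_baseline("KNN", toy$X, toy$y, folds, seed = 1)
  expect_length(tbk$cv_scores, 1)  # defaults: no grid search
  expect_named(tbk$cv_scores, "default")
})

test_that("every algorithm emits confidences in [0,1] that separate an easy problem", {
  toy <- make_toy(n = 80, p = 6, effect = 0.4, seed = 4)
  folds <- make_folds(toy$y, n_folds = 5, seed = 2)
  for (alg in c("LR", "PLS", "KNN", "SVM", "ET", "RF")) {
    tb <- tune_baseline(alg, toy$X, toy$y, folds, seed = 3)
    pf <- oof_confidences(tb, toy$X, toy$y)
    expect_length(pf, length(toy$y))
    expect_true(all(pf >= 0 & pf <= 1), info = alg)
    expect_gt(tb$cv_mcc, 0.8)
    if (alg == "LR") {
      # ridge LR ties to the strongest regularization, so its confidences
      # stay near 0.5 on an easy problem; the ranking must still separate
      expect_gt(mean(pf[toy$y == 1]), mean(pf[toy$y == 0]))
    } else {
      # separable limit: confident PFs on the correct side
      expect_gt(mean(pf[toy$y == 1]), 0.7, label = paste(alg, "active PF"))
      expect_lt(mean(pf[toy$y == 0]), 0.3, label = paste(alg, "inactive PF"))
    }
  }
})

test_that("with shuffled labels the mean PF approaches the active fraction", {
  withr::with_seed(17, {
    n <- 200
    X <- matrix(runif(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(1, 0), c(120, 80))[sample(n)]  # active fraction 0.6
    folds <- make_folds(y, n_folds = 5, seed = 5)
    tb <- tune_baseline("RF", X, y, folds, seed = 6)
    pf <- oof_confidences(tb, X, y)
    expect_lt(abs(mean(pf[y == 1]) - 0.6), 0.1)
    expect_lt(abs(mean(pf[y == 0]) - 0.6), 0.1)
  })
})

test_that("test confidences are deterministic, shape-safe and near refit confidences", {
  toy <- make_toy(n = 60, p = 5, seed = 8)
  folds <- make_folds(toy$y, n_folds = 5, seed = 1)
  tb <- tune_baseline("RF", toy$X, toy$y, folds, seed = 9)

  expect_length(test_confidences(tb, toy$X[0, , drop = FALSE]), 0)

  dup <- toy$X[c(1, 1, 5), ]
  pf <- test_confidences(tb, dup)
  expect_equal(pf[1], pf[2])

  # test PF of a training compound equals its in-sample refit confidence
  expect_equal(test_confidences(tb, toy$X),
               oof_confidences(tb, toy$X, toy$y, pf_mode = "insample"))

  expect_error(test_confidences(tb, toy$X[, 1:3]), "mismatch")
})

test_that("the baseline layer assembles aligned PF matrices over the reduced grid", {
  toy <- make_toy(n = 50, p = 4, seed = 10)
  fams <- list(
    A = fingerprint_matrix(structure(list(name = "A", n_features = 4L, type = "binary",
                                          backend = "native", gated = FALSE),
                                     class = "fingerprint_spec"),
                           paste0("c", 1:50), (toy$X > 0.5) + 0),
    B = fingerprint_matrix(structure(list(name = "B", n_features = 4L, type = "binary",
                                          backend = "native", gated = FALSE),
                                     class = "fingerprint_spec"),
                           paste0("c", 1:50), (toy$X > 0.3) + 0))
  layer <- quietly(train_baseline_layer(fams, toy$y, algorithms = c("KNN", "RF"),
                                        n_folds = 5, seed = 2))
  m <- as.matrix(layer$pf_train)
  expect_equal(dim(m), c(50, 4))
  expect_identical(colnames(m), c("KNN-A", "KNN-B", "RF-A", "RF-B"))
  expect_true(all(m >= 0 & m <= 1))
  expect_length(layer$models, 4)
})
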