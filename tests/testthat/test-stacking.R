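test_that("PF assembly enforces alignment, width and range", {
  vecs <- setNames(lapply(1:72, function(i) runif(10)), baseline_grid()$id)
  pf <- assemble_pf_matrix(vecs)
  expect_equal(dim(as.matrix(pf)), c(10, 72))
  expect_identical(pf$columns, baseline_grid()$id)

  # one compound: the row is the concatenation of its PFs
  one <- setNames(lapply(seq_along(vecs), function(i) vecs[[i]][1]), names(vecs))
  pf1 <- assemble_pf_matrix(one)
  expect_equal(unname(as.matrix(pf1)[1, ]),
               unname(vapply(vecs, `[`, numeric(1), 1)))

  bad_len <- vecs; bad_len[[3]] <- runif(9)
  expect_error(assemble_pf_matrix(bad_len), "alignment")

  bad_val <- vecs; bad_val[[1]][2] <- 1.2
  expect_error(assemble_pf_matrix(bad_val), "\\[0, 1\\]")
})

test_that("PF matrices round-trip through CSV", {
  syn <- make_synthetic_pf(15, n_columns = 6, informative_columns = 1:2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_pf_csv(syn$pf, path)
  back <- read_pf_csv(path)
  expect_equal(as.matrix(back), as.matrix(syn$pf), tolerance = 1e-12)
})

test_that("the 3-bit parametric gene decodes every code to an admissible size", {
  expect_equal(decode_param(c(0, 0, 0)), 20)
  expect_equal(decode_param(c(0, 0, 1)), 50)
  expect_equal(decode_param(c(0, 1, 0)), 100)
  expect_equal(decode_param(c(0, 1, 1)), 200)
  expect_equal(decode_param(c(1, 0, 0)), 500)
  expect_equal(decode_param(c(1, 0, 1)), 20)   # 5 mod 5
  expect_equal(decode_param(c(1, 1, 0)), 50)   # 6 mod 5
  expect_equal(decode_param(c(1, 1, 1)), 100)  # 7 mod 5
  # total over all 8 codes, always one of the five admissible values
  codes <- expand.grid(0:1, 0:1, 0:1)
  vals <- apply(codes, 1, function(b) decode_param(as.numeric(b)))
  expect_true(all(vals %in% c(20, 50, 100, 200, 500)))
  expect_error(decode_param(c(1, 0)), "3 bits")
})

test_that("repair enforces the cardinality bounds with minimal edits", {
  mk <- function(bg) molstack:::new_chromosome(bg, c(0, 1, 0))
  withr::with_seed(8, {
    r0 <- repair(mk(rep(0, 72)))
    expect_equal(sum(r0$bg), 5)
    r1 <- repair(mk(rep(1, 72)))
    expect_equal(sum(r1$bg), 20)
    mid <- mk(rep(c(1, 0), c(12, 60)))
    expect_identical(repair(mid)$bg, mid$bg)

    # Hamming distance equals the deficit/excess exactly
    for (i in 1:50) {
      bg <- rbinom(72, 1, runif(1))
      r <- repair(mk(bg))
      s <- sum(bg)
      expected_edits <- max(0, 5 - s) + max(0, s - 20)
      expect_equal(sum(r$bg != bg), expected_edits)
      expect_true(sum(r$bg) >= 5 && sum(r$bg) <= 20)
    }
  })
})

test_that("fitness rewards informative columns, nulls out under permutation, and is deterministic", {
  syn <- make_synthetic_pf(120, n_columns = 20, informative_columns = 1:4,
                           effect = 0.3, noise_sd = 0.15, seed = 6)
  folds <- make_folds(syn$y, n_folds = 5, seed = 2)
  info_chrom <- molstack:::new_chromosome(rep(c(1, 0), c(5, 15)), c(0, 0, 0))
  noise_chrom <- molstack:::new_chromosome(rep(c(0, 1), c(15, 5)), c(0, 0, 0))

  # planted signal vs pure noise, over independent replicates
  wins <- 0
  for (rep in 1:5) {
    s <- make_synthetic_pf(120, n_columns = 20, informative_columns = 1:4,
                           effect = 0.3, noise_sd = 0.15, seed = 100 + rep)
    f <- make_folds(s$y, n_folds = 5, seed = rep)
    fi <- fitness(info_chrom, s$pf, s$y, f, seed = rep)
    fn <- fitness(noise_chrom, s$pf, s$y, f, seed = rep)
    wins <- wins + (fi > fn)
  }
  expect_gte(wins, 4)

  # permutation null: shuffled labels carry no signal
  withr::with_seed(9, {
    y_perm <- sample(syn$y)
    f0 <- fitness(info_chrom, syn$pf, y_perm, make_folds(y_perm, 5, 3), seed = 1)
    expect_lt(abs(f0), 0.3)
  })

  # determinism
  f1 <- fitness(info_chrom, syn$pf, syn$y, folds, seed = 5)
  f2 <- fitness(info_chrom, syn$pf, syn$y, folds, seed = 5)
  expect_identical(f1, f2)

  expect_error(fitness(molstack:::new_chromosome(rep(0, 20), c(0, 0, 0)),
                       syn$pf, syn$y, folds), "empty")
})

test_that("run_gasar respects the cardinality constraint, reports frequencies, and is reproducible", {
  syn <- make_synthetic_pf(120, n_columns = 20, informative_columns = 1:4,
                           effect = 0.35, noise_sd = 0.1, seed = 12)
  cfg <- gasar_config(population_size = 8, generations = 3, n_runs = 2,
                      n_folds = 4, seed = 21)
  res <- run_gasar(syn$pf, syn$y, cfg)
  expect_s3_class(res, "ga_result")
  expect_true(res$m >= 5 && res$m <= 20)
  expect_length(res$selected_columns, res$m)
  expect_true(all(res$sar_frequencies %in% c(0, 0.5, 1)))
  expect_true(res$n_estimators %in% c(20, 50, 100, 200, 500))
  # every evaluated chromosome was feasible
  expect_gte(res$evaluated_cardinalities[1], 5)
  expect_lte(res$evaluated_cardinalities[2], 20)

  # single run: frequencies are indicator values
  res1 <- run_gasar(syn$pf, syn$y,
                    gasar_config(population_size = 8, generations = 2,
                                 n_runs = 1, n_folds = 4, seed = 5))
  expect_true(all(res1$sar_frequencies %in% c(0, 1)))

  # byte-identical reproduction under the same config
  res2 <- run_gasar(syn$pf, syn$y, cfg)
  expect_identical(ga_result_json(res), ga_result_json(res2))

  expect_error(run_gasar(syn$pf, syn$y, gasar_config(population_size = 2)),
               class = "molstack_config_error")
})

test_that("the meta model trains, predicts with the positive-tie rule, and validates columns", {
  syn <- make_synthetic_pf(100, n_columns = 10, informative_columns = 1:3,
                           effect = 0.35, noise_sd = 0.1, seed = 14)
  meta <- train_meta(syn$pf, syn$y, columns = syn$pf$columns[1:5],
                     n_estimators = 50, seed = 2)
  pred <- predict_meta(meta, syn$pf)
  expect_equal(nrow(pred), 100)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred$class, ifelse(pred$probability >= 0.5, "active", "inactive"))

  # deterministic re-scoring
  pred2 <- predict_meta(meta, syn$pf)
  expect_identical(pred, pred2)

  # control mode: all columns, same output shape
  ctrl <- train_meta(syn$pf, syn$y, n_estimators = 50, seed = 2)
  expect_length(ctrl$columns, 10)
  expect_equal(nrow(predict_meta(ctrl, syn$pf)), 100)

  # schema error names the missing column
  sub <- pf_matrix(as.matrix(syn$pf)[, 2:10])
  expect_error(predict_meta(meta, sub), "PF1")
})

test_that("permutation importance ranks planted columns above noise and zeroes constants", {
  # a single planted column, so shuffling it must hurt the forest
  syn <- make_synthetic_pf(150, n_columns = 8, informative_columns = 1,
                           effect = 0.4, noise_sd = 0.1, seed = 16)
  vals <- as.matrix(syn$pf)
  vals[, 8] <- 0.5  # constant column
  pf <- pf_matrix(vals)
  meta <- train_meta(pf, syn$y, n_estimators = 100, seed = 3)
  imp <- feature_importance(meta, pf, syn$y, k = 5, seed = 7)
  expect_length(imp, 8)
  expect_gt(imp[1], max(imp[2:7]))
  expect_gt(imp[1], 0.5)
  expect_equal(unname(imp[8]), 0)

  expect_error(feature_importance(meta, pf, syn$y, backend = "shap"),
               class = "molstack_config_error")
})
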