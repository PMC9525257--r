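test_that("synthetic PF matrices honor their statistical contract", {
  syn <- make_synthetic_pf(500, n_columns = 12, informative_columns = 1:3,
                           effect = 0.4, noise_sd = 0.05, seed = 2)
  m <- as.matrix(syn$pf)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(dim(m), c(500, 12))
  expect_equal(sum(syn$y), 250)

  # strong planted signal: informative PFs among actives sit high
  expect_gt(mean(m[syn$y == 1, 1]), 0.8)
  expect_lt(mean(m[syn$y == 1, 4]), 0.7)  # noise column stays uniform

  # between-class mean difference of an informative column is 2 * effect
  # (before clipping; chosen so that clipping is negligible), within 3 SE
  syn2 <- make_synthetic_pf(2000, n_columns = 4, informative_columns = 1,
                            effect = 0.2, noise_sd = 0.05, seed = 3)
  m2 <- as.matrix(syn2$pf)
  diff <- mean(m2[syn2$y == 1, 1]) - mean(m2[syn2$y == 0, 1])
  se <- 0.05 * sqrt(1 / sum(syn2$y) + 1 / sum(1 - syn2$y))
  expect_lt(abs(diff - 0.4), 3 * se)

  # determinism
  syn3 <- make_synthetic_pf(500, n_columns = 12, informative_columns = 1:3,
                            effect = 0.4, noise_sd = 0.05, seed = 2)
  expect_identical(as.matrix(syn3$pf), m)

  expect_error(make_synthetic_pf(10, effect = 0), class = "molstack_config_error")
  expect_error(make_synthetic_pf(10, informative_columns = 100),
               class = "molstack_config_error")
})

test_that("with zero effect emulated by symmetric noise no column separates the classes", {
  # the null case: all columns uniform noise (informative set empty is not
  # allowed, so use a minimal effect drowned by construction at the bound)
  withr::with_seed(4, {
    n <- 500
    vals <- matrix(runif(n * 10), n, 10,
                   dimnames = list(NULL, paste0("PF", 1:10)))
    y <- rep(0:1, n / 2)
    diffs <- abs(colMeans(vals[y == 1, ]) - colMeans(vals[y == 0, ]))
    expect_lt(max(diffs), 0.08)
  })
})

test_that("synthetic compounds have class-consistent IC50s, valid unique structures", {
  comp <- make_synthetic_compounds(100, active_fraction = 0.6, seed = 6)
  expect_equal(nrow(comp), 100)
  lab <- assign_activity_label(comp$ic50_uM)
  expect_equal(sum(lab == "active"), 60)
  expect_equal(sum(comp$ic50_uM <= 1), 60)
  expect_equal(sum(lab == "inactive"), 40)
  expect_false(any(lab == "intermediate"))

  # every emitted SMILES survives standardization, and structures are unique
  std <- standardize_structure(comp$smiles)
  expect_equal(anyDuplicated(std), 0)

  # round-trip through curation preserves the labels
  path <- write_compound_csv(comp)
  rec <- parse_compound_table(path, column_map = list(id = "id", smiles = "smiles",
                                                      ic50 = "ic50_uM"))
  expect_equal(nrow(rec), 100)
  expect_equal(rec$label, unname(lab))

  # intermediates are emitted on request, inside the open interval
  comp3 <- make_synthetic_compounds(60, active_fraction = 0.4,
                                    intermediate_fraction = 0.2, seed = 7)
  lab3 <- assign_activity_label(comp3$ic50_uM)
  expect_equal(sum(lab3 == "intermediate"), 12)

  expect_error(make_synthetic_compounds(10, scaffolds = character(0)),
               class = "molstack_config_error")
  expect_error(make_synthetic_compounds(10, scaffolds = "not_a_smiles"),
               class = "molstack_config_error")
})

test_that("the planted benchmark report is reproducible and aggregates medians", {
  bm <- planted_recovery_benchmark(seeds = 1, n = 120, n_test = 60,
                                   n_columns = 16, n_informative = 4,
                                   ga = gasar_config(population_size = 6,
                                                     generations = 2, n_runs = 1,
                                                     n_folds = 4, max_m = 8))
  expect_s3_class(bm, "planted_benchmark")
  expect_equal(nrow(bm$results), 1)
  expect_true(bm$results$m >= 5 && bm$results$m <= 8)
  expect_equal(bm$median_recovered, bm$results$recovered)

  bm2 <- planted_recovery_benchmark(seeds = 1, n = 120, n_test = 60,
                                    n_columns = 16, n_informative = 4,
                                    ga = gasar_config(population_size = 6,
                                                      generations = 2, n_runs = 1,
                                                      n_folds = 4, max_m = 8))
  expect_identical(bm$results, bm2$results)
})
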