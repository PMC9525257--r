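test_that("IC50 thresholding is total, inclusive at both boundaries, and matches interval counting", {
  expect_equal(assign_activity_label(1.0), "active")
  expect_equal(assign_activity_label(10.0), "inactive")
  expect_equal(assign_activity_label(5.0), "intermediate")
  expect_equal(assign_activity_label(c(0.001, 0.999, 1.0001, 9.999, 10.0001)),
               c("active", "active", "intermediate", "intermediate", "inactive"))
  expect_error(assign_activity_label(0), "positive")
  expect_error(assign_activity_label(-3), "positive")
  expect_error(assign_activity_label(NA), "positive")

  # label counts over random potencies equal brute-force interval counting
  withr::with_seed(99, {
    ic50 <- 10^runif(1000, -4, 4)
    lab <- assign_activity_label(ic50)
    expect_equal(sum(lab == "active"), sum(ic50 <= 1))
    expect_equal(sum(lab == "inactive"), sum(ic50 >= 10))
    expect_equal(sum(lab == "intermediate"), sum(ic50 > 1 & ic50 < 10))
  })
})

test_that("structure standardization strips salts, keeps the organic fragment, and is idempotent", {
  expect_equal(standardize_structure("CCO"), "CCO")

  # counter-ion removed: the acetic-acid fragment (4 heavy atoms) survives
  acid <- standardize_structure("CC(=O)O.[Na+]")
  expect_false(grepl("Na", acid))
  expect_false(grepl(".", acid, fixed = TRUE))
  expect_equal(molstack:::count_heavy_atoms(acid), 4L)

  # organic fragment preferred even against a larger inorganic cluster
  organic <- standardize_structure("C[N+](C)(C)C.[Cl-]")
  expect_true(grepl("N", organic))
  expect_false(grepl("Cl", organic))

  std1 <- standardize_structure(smiles_panel())
  expect_identical(standardize_structure(std1), std1)

  expect_error(standardize_structure("not_a_smiles"), "unparseable")
})

test_that("compound tables parse with unit conversion, drops, and duplicate collapsing", {
  path <- write_compound_csv(data.frame(
    id = c("C1", "C2", "C3"), smiles = c("CCO", "CCC", "CCN"),
    ic50 = c(500, 2000, 50)))
  rec <- parse_compound_table(path, unit = "nM")
  expect_equal(rec$ic50_uM, c(0.5, 2, 0.05))
  expect_equal(rec$id, c("C1", "C2", "C3"))
  expect_equal(rec$label, c("active", "intermediate", "active"))

  # unparseable SMILES dropped with a count
  path2 <- write_compound_csv(data.frame(
    id = c("A", "B"), smiles = c("CCO", "not_a_smiles"), ic50 = c(1, 2)))
  rec2 <- quietly(parse_compound_table(path2))
  expect_equal(nrow(rec2), 1)
  expect_equal(attr(rec2, "n_dropped"), 1L)

  # same structure twice -> one record with geometric-mean IC50
  path3 <- write_compound_csv(data.frame(
    id = c("A", "B"), smiles = c("CCO", "OCC"), ic50 = c(0.1, 10)))
  rec3 <- quietly(parse_compound_table(path3))
  expect_equal(nrow(rec3), 1)
  expect_equal(rec3$ic50_uM, 1)  # sqrt(0.1 * 10)

  expect_error(parse_compound_table(tempfile()), "not found")
  expect_error(parse_compound_table(path, column_map = list(id = "nope", smiles = "smiles")),
               "missing")
})

test_that("stratified split reproduces class-wise test sizes and partitions the data", {
  # the reference design: 463 active + 260 inactive at fraction 0.2
  ds <- labeled_dataset(data.frame(
    id = paste0("C", 1:723), smiles = "CCO",
    label = rep(c("active", "inactive"), c(463, 260)),
    check.names = FALSE))
  sp <- stratified_split(ds, test_fraction = 0.2, seed = 7)
  expect_equal(sum(sp$test$label == "active"), 93)
  expect_equal(sum(sp$test$label == "inactive"), 52)
  expect_equal(sum(sp$train$label == "active"), 370)
  expect_equal(sum(sp$train$label == "inactive"), 208)

  # partition: disjoint and exhaustive by id
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), ds$id)

  # symmetric half split
  ds2 <- labeled_dataset(data.frame(id = paste0("x", 1:20), smiles = "CCO",
                                    label = rep(c("active", "inactive"), each = 10)))
  sp2 <- stratified_split(ds2, test_fraction = 0.5, seed = 1)
  expect_equal(as.vector(table(sp2$test$label)), c(5, 5))

  # determinism
  sp3 <- stratified_split(ds, test_fraction = 0.2, seed = 7)
  expect_identical(sp$test$id, sp3$test$id)
  sp4 <- stratified_split(ds, test_fraction = 0.2, seed = 8)
  expect_false(identical(sp$test$id, sp4$test$id))

  expect_error(stratified_split(ds2, test_fraction = 0.01), "too small")
})

test_that("labeled datasets exclude intermediates and validate invariants", {
  df <- data.frame(id = c("a", "b", "c"), smiles = "CCO",
                   label = c("active", "intermediate", "inactive"))
  ds <- quietly(labeled_dataset(df))
  expect_equal(nrow(ds), 2)
  expect_equal(unname(attr(ds, "class_counts")), c(1L, 1L))

  expect_error(labeled_dataset(data.frame(id = c("a", "a"), smiles = "C",
                                          label = "active")), "unique")
  expect_error(labeled_dataset(data.frame(id = "a", smiles = "C", label = "maybe")),
               "label")
})

test_that("dataset CSV round-trips through the exchange schema", {
  comp <- make_synthetic_compounds(20, active_fraction = 0.5, seed = 5)
  comp$label <- assign_activity_label(comp$ic50_uM)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(comp, path)
  back <- parse_compound_table(path, column_map = list(id = "id", smiles = "smiles",
                                                       ic50 = "ic50_uM"))
  expect_equal(back$label, comp$label)
  expect_equal(back$ic50_uM, comp$ic50_uM, tolerance = 1e-12)
})

test_that(".smi files read with and without ids", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1"), path)
  smi <- read_smi(path)
  expect_equal(smi$id, c("mol1", "M2"))
  expect_equal(smi$smiles, c("CCO", "c1ccccc1"))
})
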