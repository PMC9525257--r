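## End-to-end workflow commands binding curation, featurization, the
## baseline layer, GA-SAR and the meta-predictor. Each command writes a JSON
## manifest capturing the configuration and seeds, so a run is reproducible
## from config + inputs. A thin command-line launcher around these functions
## ships in inst/cli/molstack.

#' Workflow configuration
#'
#' @param fingerprints fingerprint families to compute (default MACCS +
#'   Circle + FP4 + AP2D; pass `fingerprint_families()$name` for the full
#'   twelve).
#' @param algorithms baseline algorithms (default all six).
#' @param allow_approx allow native hashed approximations of the CDK-family
#'   fingerprints (see [compute_fingerprint()]).
#' @param n_folds cross-validation folds (default 10).
#' @param pf_mode training PF protocol, `"oof"` or `"insample"`.
#' @param selection `"gasar"` (GA-SAR subset) or `"none"` (all-columns
#'   control meta model).
#' @param ga a [gasar_config()].
#' @param threshold meta decision threshold (default 0.5).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(fingerprints = c("MACCS", "Circle", "FP4", "AP2D"),
                       algorithms = BASELINE_ALGORITHMS,
                       allow_approx = FALSE, n_folds = 10,
                       pf_mode = c("oof", "insample"),
                       selection = c("gasar", "none"),
                       ga = gasar_config(), threshold = 0.5, seed = 1) {
  structure(list(fingerprints = fingerprints, algorithms = algorithms,
                 allow_approx = allow_approx, n_folds = n_folds,
                 pf_mode = match.arg(pf_mode), selection = match.arg(selection),
                 ga = ga, threshold = threshold, seed = seed),
            class = "run_config")
}

write_manifest <- function(outdir, command, config, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(utils::packageVersion("molstack")),
                     config = unclass(config)),
                extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Curate a compound table into train/test splits
#'
#' Parses and standardizes the table, assigns activity labels from IC50,
#' excludes intermediates, splits stratified, and writes `train.csv` /
#' `test.csv` plus a manifest with the drop counts.
#'
#' @param input path to the raw compound table.
#' @param outdir output directory (created if needed).
#' @param unit IC50 unit of the input, `"uM"` or `"nM"`.
#' @param column_map see [parse_compound_table()].
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed split seed.
#' @return invisibly, `list(train = , test = )` of datasets.
#' @export
cmd_curate <- function(input, outdir, unit = "uM",
                       column_map = list(id = "id", smiles = "smiles", ic50 = "ic50"),
                       test_fraction = 0.2, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- parse_compound_table(input, unit = unit, column_map = column_map)
  ds <- labeled_dataset(records)
  split <- stratified_split(ds, test_fraction = test_fraction, seed = seed)
  write_dataset_csv(split$train, file.path(outdir, "train.csv"))
  write_dataset_csv(split$test, file.path(outdir, "test.csv"))
  write_manifest(outdir, "curate", list(unit = unit, test_fraction = test_fraction,
                                        seed = seed),
                 extra = list(n_dropped = attr(records, "n_dropped"),
                              n_collapsed = attr(records, "n_collapsed"),
                              class_counts = as.list(attr(ds, "class_counts"))))
  msg("curate: %d train / %d test compounds written to %s",
      nrow(split$train), nrow(split$test), outdir)
  invisible(split)
}

featurize_normalized <- function(smiles, ids, config, scalers = NULL) {
  fps <- compute_fingerprints(smiles, config$fingerprints, ids = ids,
                              allow_approx = config$allow_approx)
  if (is.null(scalers)) scalers <- lapply(fps, fit_minmax)
  fps <- lapply(names(fps), function(f) apply_minmax(scalers[[f]], fps[[f]]))
  names(fps) <- config$fingerprints
  list(fps = fps, scalers = scalers)
}

#' Train the full stacked model
#'
#' Featurizes the training compounds, trains and tunes the baseline grid,
#' assembles out-of-fold PFs, runs GA-SAR (or skips selection for the
#' control), trains the meta forest, and writes the model bundle
#' (`bundle.rds`), the GA result JSON and a manifest into `outdir`.
#'
#' @param train_csv labeled training CSV (`id,smiles,ic50_uM,label`).
#' @param outdir output directory.
#' @param config a [run_config()].
#' @return invisibly, the bundle list.
#' @export
cmd_train <- function(train_csv, outdir, config = run_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- labeled_dataset(utils::read.csv(train_csv, stringsAsFactors = FALSE))
  y <- as.integer(ds$label == "active")

  t0 <- Sys.time()
  feat <- featurize_normalized(ds$smiles, ds$id, config)
  msg("train: featurization done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  layer <- train_baseline_layer(feat$fps, y, algorithms = config$algorithms,
                                n_folds = config$n_folds, seed = config$seed,
                                pf_mode = config$pf_mode)
  msg("train: %d baseline models tuned (%.1fs)", length(layer$models),
      as.numeric(Sys.time() - t1, units = "secs"))

  t2 <- Sys.time()
  ga <- NULL
  if (config$selection == "gasar") {
    cfg <- config$ga
    cfg$n_folds <- config$n_folds
    cfg$seed <- child_seed(config$seed, "gasar")
    ga <- run_gasar(layer$pf_train, y, cfg)
    ga_result_json(ga, file.path(outdir, "ga_result.json"))
    msg("train: GA-SAR selected %d PFs (%.1fs)", ga$m,
        as.numeric(Sys.time() - t2, units = "secs"))
  }
  meta <- train_meta(layer$pf_train, y, result = ga,
                     seed = child_seed(config$seed, "meta"))
  meta$threshold <- config$threshold

  bundle <- list(config = config, scalers = feat$scalers,
                 models = layer$models, grid = layer$grid,
                 folds = layer$folds, pf_train = layer$pf_train,
                 y_train = y, ga = ga, meta = meta)
  saveRDS(bundle, file.path(outdir, "bundle.rds"))
  write_manifest(outdir, "train", config,
                 extra = list(n_train = nrow(ds),
                              n_baselines = length(layer$models),
                              selected_columns = meta$columns))
  msg("train: bundle written to %s", outdir)
  invisible(bundle)
}

load_bundle <- function(bundle) {
  if (is.character(bundle)) {
    path <- if (dir.exists(bundle)) file.path(bundle, "bundle.rds") else bundle
    if (!file.exists(path)) stop_input("bundle not found: %s", bundle)
    bundle <- readRDS(path)
  }
  bundle
}

## PFs for new compounds from the trained baseline layer
bundle_pf <- function(bundle, smiles, ids) {
  config <- bundle$config
  feat <- featurize_normalized(smiles, ids, config, scalers = bundle$scalers)
  grid <- bundle$grid
  pf <- matrix(NA_real_, length(ids), nrow(grid),
               dimnames = list(ids, grid$id))
  for (k in seq_len(nrow(grid))) {
    pf[, k] <- test_confidences(bundle$models[[grid$id[k]]],
                                as.matrix(feat$fps[[grid$fingerprint[k]]]))
  }
  pf_matrix(pf)
}

#' Predict new compounds
#'
#' Reads SMILES (CSV with `id,smiles` columns or a `.smi` file), flags rows
#' whose SMILES cannot be parsed (they are reported, not fatal), and writes
#' `id,probability,class` predictions.
#'
#' @param bundle a [cmd_train()] output directory, `bundle.rds` path, or
#'   bundle list.
#' @param input CSV or `.smi` input path.
#' @param out optional output CSV path.
#' @return the predictions `data.frame` (invalid rows carry `NA` probability
#'   and class `"invalid_smiles"`).
#' @export
cmd_predict <- function(bundle, input, out = NULL) {
  bundle <- load_bundle(bundle)
  tab <- if (grepl("\\.smi$", input)) read_smi(input) else {
    utils::read.csv(input, stringsAsFactors = FALSE)
  }
  if (!all(c("id", "smiles") %in% names(tab))) {
    stop_input("input needs id and smiles columns")
  }
  if (nrow(tab) == 0) {
    res <- data.frame(id = character(0), probability = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  } else {
    std <- vapply(tab$smiles, standardize_one, character(1), USE.NAMES = FALSE)
    valid <- !is.na(std)
    if (any(!valid)) msg("predict: %d row(s) with unparseable SMILES flagged", sum(!valid))
    res <- data.frame(id = as.character(tab$id), probability = NA_real_,
                      class = "invalid_smiles", stringsAsFactors = FALSE)
    if (any(valid)) {
      pf <- bundle_pf(bundle, std[valid], tab$id[valid])
      pred <- predict_meta(bundle$meta, pf)
      res$probability[valid] <- pred$probability
      res$class[valid] <- pred$class
    }
  }
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Evaluate on a labeled dataset
#'
#' Scores the stacked model on a labeled CSV and compares it against the
#' top baseline models (ranked by training CV MCC), mirroring the usual
#' optimal-vs-baselines comparison table. With `from_confusion` the metric
#' suite is computed directly from the four counts and no bundle is needed.
#'
#' @param bundle see [cmd_predict()]; ignored when `from_confusion` given.
#' @param labeled_csv labeled CSV (`id,smiles,...,label`).
#' @param out optional JSON output path.
#' @param from_confusion optional counts `c(tp, fn, tn, fp)`.
#' @param top_n how many baselines to include in the comparison (default 5).
#' @return `list(report = metrics_report, comparison = data.frame or NULL)`.
#' @export
cmd_evaluate <- function(bundle = NULL, labeled_csv = NULL, out = NULL,
                         from_confusion = NULL, top_n = 5) {
  if (!is.null(from_confusion)) {
    cm <- confusion_matrix(from_confusion[1], from_confusion[2],
                           from_confusion[3], from_confusion[4])
    report <- metrics_report(cm)
    if (!is.null(out)) {
      jsonlite::write_json(as.data.frame(report), out, auto_unbox = TRUE, digits = NA)
    }
    return(list(report = report, comparison = NULL))
  }
  bundle <- load_bundle(bundle)
  ds <- labeled_dataset(utils::read.csv(labeled_csv, stringsAsFactors = FALSE))
  y <- as.integer(ds$label == "active")
  pf <- bundle_pf(bundle, ds$smiles, ds$id)
  pred <- predict_meta(bundle$meta, pf)
  report <- metrics_report(y, as.integer(pred$class == "active"),
                           scores = pred$probability)

  cv <- vapply(bundle$models, `[[`, numeric(1), "cv_mcc")
  top <- names(sort(cv, decreasing = TRUE))[seq_len(min(top_n, length(cv)))]
  reports <- stats::setNames(lapply(top, function(id) {
    p <- as.matrix(pf)[, id]
    metrics_report(y, as.integer(p >= 0.5), scores = p)
  }), top)
  reports$stacked <- report
  comparison <- compare_models(reports, reference = "stacked")
  if (!is.null(out)) {
    jsonlite::write_json(list(report = as.data.frame(report), comparison = comparison),
                         out, auto_unbox = TRUE, digits = NA)
  }
  list(report = report, comparison = comparison)
}
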