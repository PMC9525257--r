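## Synthetic inputs with known structure, so every stage of the pipeline is
## testable offline: PF matrices with planted informative columns, compound
## tables with IC50s drawn inside each class's range, and the
## planted-recovery benchmark that exercises GA-SAR end to end.

#' Synthetic PF matrix with planted signal
#'
#' Emulates the stacking layer's input: `n_columns` probabilistic features in
#' `[0, 1]`. Informative columns are centred at `0.5 + effect` for actives
#' and `0.5 - effect` for inactives with Gaussian noise (clipped to `[0, 1]`
#' so the PF invariant holds exactly); the remaining columns are
#' uninformative `Uniform(0, 1)` draws. The between-class mean difference of
#' an informative column is `2 * effect` before clipping.
#'
#' @param n_compounds number of compounds.
#' @param n_columns number of PF columns (default 72; the columns are then
#'   named after the real baseline grid).
#' @param informative_columns indices of columns carrying signal (default
#'   `1:8`).
#' @param effect mean PF shift toward the true label, in `(0, 0.5]`
#'   (default 0.35).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param class_balance fraction of active compounds (default 0.5).
#' @param seed RNG seed.
#' @return `list(pf = pf_matrix, y = integer labels, informative = indices)`.
#' @export
make_synthetic_pf <- function(n_compounds, n_columns = 72,
                              informative_columns = 1:8, effect = 0.35,
                              noise_sd = 0.1, class_balance = 0.5, seed = 1) {
  if (effect <= 0 || effect > 0.5) stop_config("effect must lie in (0, 0.5]")
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (any(informative_columns < 1 | informative_columns > n_columns)) {
    stop_config("informative_columns out of range")
  }
  withr::with_seed(seed, {
    n_act <- round(n_compounds * class_balance)
    y <- sample(c(rep(1L, n_act), rep(0L, n_compounds - n_act)))
    vals <- matrix(stats::runif(n_compounds * n_columns), n_compounds, n_columns)
    for (j in informative_columns) {
      centre <- ifelse(y == 1, 0.5 + effect, 0.5 - effect)
      vals[, j] <- pmin(pmax(centre + stats::rnorm(n_compounds, 0, noise_sd), 0), 1)
    }
    cols <- if (n_columns == 72) baseline_grid()$id else paste0("PF", seq_len(n_columns))
    colnames(vals) <- cols
    rownames(vals) <- sprintf("S%04d", seq_len(n_compounds))
    list(pf = pf_matrix(vals), y = y, informative = informative_columns)
  })
}

## small pool of common drug-like scaffolds (all valid SMILES)
SCAFFOLD_POOL <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "c1ccc2c(c1)cccn2",                  # quinoline
  "c1ccc(cc1)C(=O)Nc2ccccc2",         # benzanilide
  "CC1CCC(CC1)NC(=O)C",               # cyclohexyl amide
  "c1ccc(cc1)S(=O)(=O)N",             # benzenesulfonamide
  "COc1ccc(cc1)CCN",                   # methoxyphenethylamine
  "c1ccc(cc1)c2ccccn2",               # phenylpyridine
  "CC(C)NCC(O)COc1ccccc1",            # propranolol-like
  "O=C1CCCCC1"                          # cyclohexanone
)

DECORATIONS <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC",
                 "CCO", "CCCO", "CCCCO", "CCN", "CCCN", "CCCCN",
                 "CC(C)C", "CCC(C)C", "CC(C)CC", "CCOC", "CCCOC",
                 "CCNC", "CCCNC", "CC(C)O", "CC(C)N", "CCC(=O)O",
                 "CCOCC", "CCNCC", "CCSC", "CC(C)(C)C", "CCC(C)O",
                 "CCC(C)N", "CCOC(C)C")

#' Synthetic compound table
#'
#' Emits `n` compounds built from a pool of drug-like scaffolds joined to
#' simple aliphatic decorations (every emitted SMILES is valid), with IC50
#' values drawn log-uniformly inside the class's range: actives in
#' `[0.001, 1]` uM, inactives in `[10, 1000]` uM, intermediates in `(1, 10)`
#' uM — so labels are recoverable exactly by [assign_activity_label()].
#'
#' @param n number of compounds.
#' @param active_fraction fraction of actives (default 0.5).
#' @param intermediate_fraction fraction of intermediates (default 0).
#' @param scaffolds SMILES pool (validated at config time).
#' @param seed RNG seed.
#' @param path optional CSV output path (columns `id,smiles,ic50_uM`).
#' @return a `data.frame` with columns `id`, `smiles`, `ic50_uM` (and the CSV
#'   written when `path` is given).
#' @export
make_synthetic_compounds <- function(n, active_fraction = 0.5,
                                     intermediate_fraction = 0,
                                     scaffolds = SCAFFOLD_POOL, seed = 1,
                                     path = NULL) {
  if (length(scaffolds) == 0) stop_config("scaffold pool is empty")
  bad <- !vapply(scaffolds, function(s) nzchar(ob_canonical(s)), logical(1))
  if (any(bad)) stop_config("invalid scaffold SMILES: %s", paste(scaffolds[bad], collapse = ", "))
  if (active_fraction + intermediate_fraction > 1) {
    stop_config("class fractions exceed 1")
  }
  withr::with_seed(seed, {
    n_act <- round(n * active_fraction)
    n_int <- round(n * intermediate_fraction)
    cls <- sample(c(rep("active", n_act), rep("intermediate", n_int),
                    rep("inactive", n - n_act - n_int)))
    ## draw structurally unique compounds: scaffold x decoration candidates
    ## are deduplicated on their canonical form so curation keeps all n
    combos <- as.vector(outer(scaffolds, DECORATIONS, paste0))
    combos <- sample(combos)
    smiles <- character(0); seen <- character(0)
    for (cand in combos) {
      if (length(smiles) >= n) break
      can <- standardize_one(cand)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      smiles <- c(smiles, cand)
    }
    if (length(smiles) < n) {
      stop_config("scaffold/decoration pool exhausted at %d unique compounds (requested %d)",
                  length(smiles), n)
    }
    ic50 <- vapply(cls, function(cl) {
      switch(cl,
             active = 10^stats::runif(1, -3, 0),         # 0.001-1 uM
             inactive = 10^stats::runif(1, 1, 3),        # 10-1000 uM
             intermediate = 10^stats::runif(1, 0.05, 0.95))  # inside (1, 10)
    }, numeric(1), USE.NAMES = FALSE)
    out <- data.frame(id = sprintf("C%04d", seq_len(n)), smiles = smiles,
                      ic50_uM = ic50, stringsAsFactors = FALSE)
    if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    out
  })
}

#' Planted-recovery benchmark for GA-SAR
#'
#' For each seed: generate training and test PF matrices with
#' `n_informative` planted columns, run GA-SAR, train the selected-subset
#' meta model and the all-columns control, and record how many informative
#' columns were recovered plus both models' test MCC. The defaults are the
#' benchmark's study conditions (400 training compounds, 72 columns, 8
#' informative, effect 0.35, noise 0.1, GA population 30 x 40 generations).
#'
#' @param seeds integer vector; one benchmark replicate per seed.
#' @param n training compounds (default 400).
#' @param n_test test compounds (default 150).
#' @param n_columns PF columns (default 72).
#' @param n_informative planted informative columns (default 8).
#' @param effect,noise_sd generator parameters (defaults 0.35 and 0.1).
#' @param ga a [gasar_config()]; the seed field is replaced per replicate.
#' @return an object of class `planted_benchmark`: per-seed `data.frame`
#'   (`results`) and medians (`median_recovered`, `median_meta_mcc`,
#'   `median_control_mcc`), plus the per-seed GA results.
#' @export
planted_recovery_benchmark <- function(seeds, n = 400, n_test = 150,
                                       n_columns = 72, n_informative = 8,
                                       effect = 0.35, noise_sd = 0.1,
                                       ga = gasar_config(population_size = 30,
                                                         generations = 40,
                                                         n_runs = 1)) {
  rows <- vector("list", length(seeds))
  ga_results <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    train <- make_synthetic_pf(n, n_columns = n_columns,
                               informative_columns = seq_len(n_informative),
                               effect = effect, noise_sd = noise_sd, seed = s)
    test <- make_synthetic_pf(n_test, n_columns = n_columns,
                              informative_columns = seq_len(n_informative),
                              effect = effect, noise_sd = noise_sd,
                              seed = child_seed(s, "test"))
    cfg <- ga
    cfg$seed <- child_seed(s, "ga")
    res <- run_gasar(train$pf, train$y, cfg)
    ga_results[[i]] <- res
    informative_ids <- train$pf$columns[train$informative]

    meta <- train_meta(train$pf, train$y, result = res,
                       seed = child_seed(s, "meta"))
    ctrl <- train_meta(train$pf, train$y, n_estimators = res$n_estimators,
                       seed = child_seed(s, "ctrl"))
    mcc_of <- function(model) {
      pred <- predict_meta(model, test$pf)
      mcc(cm_from_labels(as.integer(pred$class == "active"), test$y))
    }
    rows[[i]] <- data.frame(seed = s,
                            m = res$m,
                            recovered = length(intersect(res$selected_columns,
                                                         informative_ids)),
                            meta_test_mcc = mcc_of(meta),
                            control_test_mcc = mcc_of(ctrl),
                            best_fitness = res$best_fitness)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 median_recovered = stats::median(results$recovered),
                 median_meta_mcc = stats::median(results$meta_test_mcc),
                 median_control_mcc = stats::median(results$control_test_mcc),
                 n_informative = n_informative,
                 ga_results = ga_results),
            class = "planted_benchmark")
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat(sprintf("planted-recovery benchmark over %d seed(s):\n", nrow(x$results)))
  cat(sprintf("  median recovered informative: %.1f of %d\n",
              x$median_recovered, x$n_informative))
  cat(sprintf("  median test MCC: meta %.3f vs control %.3f\n",
              x$median_meta_mcc, x$median_control_mcc))
  invisible(x)
}
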