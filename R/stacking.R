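## Stacked meta-learning layer. The 72 baseline confidences form a
## probabilistic-feature (PF) vector per compound; a genetic algorithm with a
## self-assessment report (GA-SAR) picks m in [5, 20] PF columns and the
## meta random forest's n_estimators; the meta-predictor is a random forest
## on the selected columns.

META_TREE_VALUES <- c(20L, 50L, 100L, 200L, 500L)

#' PF matrix container
#'
#' Probabilistic features: one row per compound, one column per baseline
#' model (algorithm x fingerprint), every value a predicted confidence in
#' `[0, 1]`. Column order is fixed by the baseline grid enumeration and
#' recorded in the column names.
#'
#' @param values numeric matrix with column names (baseline ids) and,
#'   optionally, row names (compound ids).
#' @param ids compound ids; defaults to row names.
#' @return an object of class `pf_matrix`.
#' @export
pf_matrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop_input("PF matrix needs baseline column names")
  if (anyNA(values)) stop_input("PF matrix contains missing values")
  if (any(values < 0 | values > 1)) {
    stop_input("PF values must lie in [0, 1]; found range [%g, %g]",
               min(values), max(values))
  }
  ids <- as.character(ids %||% rownames(values) %||% seq_len(nrow(values)))
  rownames(values) <- ids
  structure(list(ids = ids, columns = colnames(values), values = values),
            class = "pf_matrix")
}

#' @export
print.pf_matrix <- function(x, ...) {
  cat(sprintf("pf_matrix: %d compounds x %d probabilistic features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.pf_matrix <- function(x, ...) x$values

#' Assemble a PF matrix from aligned PF vectors
#'
#' Concatenates per-baseline confidence vectors into the stacked feature
#' matrix (a compound's row is its PF vector across all baseline models).
#'
#' @param pf_vectors named list of equal-length numeric vectors, one per
#'   baseline model, all in the same compound order.
#' @param ids optional compound ids.
#' @return a [pf_matrix()].
#' @export
assemble_pf_matrix <- function(pf_vectors, ids = NULL) {
  if (is.null(names(pf_vectors)) || any(names(pf_vectors) == "")) {
    stop_input("pf_vectors must be named by baseline id")
  }
  lens <- lengths(pf_vectors)
  if (length(unique(lens)) != 1) {
    stop_input("alignment error: PF vectors have differing lengths (%s)",
               paste(unique(lens), collapse = ", "))
  }
  pf_matrix(do.call(cbind, pf_vectors), ids = ids)
}

#' Read/write PF matrices as CSV
#'
#' @param x a [pf_matrix()]; `path` a file path.
#' @return `read_pf_csv` returns a [pf_matrix()].
#' @export
write_pf_csv <- function(x, path) {
  utils::write.csv(data.frame(id = x$ids, x$values, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pf_csv
#' @export
read_pf_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pf_matrix(as.matrix(tab[, -1, drop = FALSE]), ids = tab[[1]])
}

## ---- chromosome ----------------------------------------------------------

#' Decode the 3-bit parametric gene
#'
#' The three bits read as an MSB-first binary number, taken modulo 5, index
#' the admissible meta-forest sizes (20, 50, 100, 200, 500). The map is
#' total: all 8 codes decode to a valid size.
#'
#' @param param_bits integer vector of exactly three bits.
#' @return one of 20, 50, 100, 200, 500.
#' @examples
#' decode_param(c(0, 0, 0))  # 20
#' decode_param(c(1, 0, 0))  # 4 -> 500
#' decode_param(c(1, 1, 0))  # 6 mod 5 = 1 -> 50
#' @export
decode_param <- function(param_bits) {
  if (length(param_bits) != 3 || !all(param_bits %in% c(0, 1))) {
    stop_input("param_bits must be exactly 3 bits")
  }
  v <- param_bits[1] * 4 + param_bits[2] * 2 + param_bits[3]
  META_TREE_VALUES[(v %% 5) + 1]
}

new_chromosome <- function(bg, param_bits) {
  structure(list(bg = as.integer(bg), param_bits = as.integer(param_bits),
                 fitness = NA_real_),
            class = "chromosome")
}

random_chromosome <- function(n_col, p_on = min(0.5, 12 / n_col)) {
  new_chromosome(stats::rbinom(n_col, 1, p_on), stats::rbinom(3, 1, 0.5))
}

#' Repair a chromosome to the cardinality constraint
#'
#' The number of selected PF columns must lie in `[min_m, max_m]` (5-20).
#' Deficits are fixed by switching randomly chosen zeros on, excesses by
#' switching randomly chosen ones off; a feasible chromosome is returned
#' unchanged, so the Hamming distance to the input equals the deficit or
#' excess exactly.
#'
#' @param chrom a chromosome (list with `bg` and `param_bits`).
#' @param min_m,max_m cardinality bounds (defaults 5 and 20).
#' @return a feasible chromosome.
#' @export
repair <- function(chrom, min_m = 5, max_m = 20) {
  s <- sum(chrom$bg)
  if (s < min_m) {
    zeros <- which(chrom$bg == 0)
    chrom$bg[zeros[sample.int(length(zeros), min_m - s)]] <- 1L
  } else if (s > max_m) {
    ones <- which(chrom$bg == 1)
    chrom$bg[ones[sample.int(length(ones), s - max_m)]] <- 0L
  }
  chrom$fitness <- NA_real_
  chrom
}

chrom_key <- function(chrom) {
  paste(c(chrom$bg, chrom$param_bits), collapse = "")
}

## tenfold-CV MCC of an RF on a given column subset; the workhorse shared by
## chromosome fitness and the SAR truncation refits
cv_rf_mcc <- function(values, y, cols, n_trees, folds, seed) {
  pred <- integer(length(y))
  X <- values[, cols, drop = FALSE]
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- ranger::ranger(x = X[tr, , drop = FALSE],
                          y = factor(y[tr], levels = 0:1),
                          num.trees = n_trees, num.threads = 1,
                          seed = child_seed(seed, f), verbose = FALSE)
    pred[!tr] <- as.integer(as.character(
      stats::predict(fit, X[!tr, , drop = FALSE], num.threads = 1)$predictions))
  }
  mcc(cm_from_labels(pred, y))
}

#' Chromosome fitness
#'
#' Cross-validated MCC (pooled out-of-fold predictions) of a random forest
#' with the chromosome's decoded tree count, trained on the PF columns the
#' chromosome selects. Deterministic for a fixed seed and fold assignment.
#'
#' @param chrom a repaired chromosome.
#' @param pf_train a [pf_matrix()] of training PFs.
#' @param y binary labels.
#' @param folds fold assignment from [make_folds()].
#' @param seed RNG seed for the forests.
#' @return the CV MCC.
#' @export
fitness <- function(chrom, pf_train, y, folds, seed = 1) {
  y <- as_binary01(y)
  cols <- which(chrom$bg == 1)
  if (length(cols) == 0) stop_input("fitness of an empty chromosome (repair first)")
  cv_rf_mcc(as.matrix(pf_train), y, cols, decode_param(chrom$param_bits),
            folds, child_seed(seed, chrom_key(chrom)))
}

#' Cross-validated MCC of a meta forest on chosen PF columns
#'
#' Convenience wrapper around the same CV routine chromosome fitness uses:
#' stratified folds, pooled out-of-fold class predictions, MCC. Used to
#' compare the stacked model against single baselines and to audit leakage
#' (with permuted labels the value must hover near zero).
#'
#' @param pf a [pf_matrix()].
#' @param y binary labels.
#' @param columns PF columns to use (default all).
#' @param n_estimators forest size (default 100).
#' @param n_folds folds (default 10).
#' @param seed RNG seed.
#' @return the CV MCC.
#' @export
meta_cv_mcc <- function(pf, y, columns = NULL, n_estimators = 100,
                        n_folds = 10, seed = 1) {
  stopifnot(inherits(pf, "pf_matrix"))
  y <- as_binary01(y)
  columns <- columns %||% pf$columns
  folds <- make_folds(y, n_folds = n_folds, seed = seed)
  cv_rf_mcc(as.matrix(pf), y, match(columns, pf$columns), n_estimators,
            folds, seed)
}

#' GA-SAR configuration
#'
#' Conventional wrapper-GA settings: tournament selection (size 3), uniform
#' crossover, per-gene bit-flip mutation, elitism of one, several independent
#' runs aggregated by the self-assessment report.
#'
#' @param population_size even integer >= 4 (default 50).
#' @param generations number of generations per run (default 100).
#' @param crossover_rate probability a mating pair recombines (default 0.8).
#' @param mutation_rate per-gene flip probability (default 1/75).
#' @param tournament_size selection tournament size (default 3).
#' @param n_runs independent GA runs aggregated by the report (default 10).
#' @param n_folds CV folds for fitness (default 10).
#' @param seed master seed.
#' @param min_m,max_m cardinality constraint (defaults 5, 20).
#' @return a `gasar_config` list.
#' @export
gasar_config <- function(population_size = 50, generations = 100,
                         crossover_rate = 0.8, mutation_rate = 1 / 75,
                         tournament_size = 3, n_runs = 10, n_folds = 10,
                         seed = 1, min_m = 5, max_m = 20) {
  if (population_size < 4) stop_config("population_size must be at least 4")
  if (population_size %% 2 != 0) stop_config("population_size must be even")
  if (crossover_rate < 0 || crossover_rate > 1 || mutation_rate < 0 || mutation_rate > 1) {
    stop_config("rates must lie in [0, 1]")
  }
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = tournament_size, n_runs = n_runs,
                 n_folds = n_folds, seed = seed, min_m = min_m, max_m = max_m),
            class = "gasar_config")
}

#' Run GA-SAR feature selection
#'
#' Runs `n_runs` independent genetic algorithms (selection, uniform
#' crossover, bit-flip mutation, repair, elitism 1) over chromosomes of 72
#' binary selection genes plus a 3-bit meta-forest gene. The self-assessment
#' report is the per-column frequency of appearing in each run's best
#' chromosome; columns are ranked by that frequency (ties broken by the mean
#' fitness of evaluated chromosomes containing the column) and the ranking is
#' truncated at the cardinality in `[min_m, max_m]` whose refitted CV MCC is
#' highest (ties go to the larger cardinality). The meta-forest size comes from
#' the best chromosome over all runs.
#'
#' @param pf_train a [pf_matrix()] of out-of-fold training PFs.
#' @param y binary labels.
#' @param config a [gasar_config()].
#' @return an object of class `ga_result`: `selected_columns`,
#'   `n_estimators`, `sar_frequencies`, `best_fitness`, `best_chromosome`,
#'   `run_best` (per-run best fitness), `trace` (per-run, per-generation best
#'   fitness), `m`, `truncation_mcc`, `n_evaluations`, and
#'   `evaluated_cardinalities` (range of selected-gene counts over every
#'   chromosome whose fitness was computed).
#' @export
run_gasar <- function(pf_train, y, config = gasar_config()) {
  stopifnot(inherits(pf_train, "pf_matrix"))
  y <- as_binary01(y)
  values <- as.matrix(pf_train)
  n_col <- ncol(values)
  cfg <- config
  ## reduced grids can have fewer columns than the cardinality bounds
  cfg$min_m <- min(cfg$min_m, n_col)
  cfg$max_m <- min(cfg$max_m, n_col)

  cache <- new.env(parent = emptyenv())
  col_fit_sum <- numeric(n_col)
  col_fit_n <- integer(n_col)
  n_evals <- 0L
  card_range <- c(Inf, -Inf)

  withr::with_seed(cfg$seed, {
    folds <- make_folds(y, n_folds = cfg$n_folds,
                        seed = child_seed(cfg$seed, "gasar_folds"))

    eval_chrom <- function(ch) {
      key <- chrom_key(ch)
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) { ch$fitness <- hit; return(ch) }
      ch$fitness <- fitness(ch, pf_train, y, folds, seed = cfg$seed)
      assign(key, ch$fitness, envir = cache)
      on <- which(ch$bg == 1)
      col_fit_sum[on] <<- col_fit_sum[on] + ch$fitness
      col_fit_n[on] <<- col_fit_n[on] + 1L
      n_evals <<- n_evals + 1L
      card_range <<- c(min(card_range[1], sum(ch$bg)), max(card_range[2], sum(ch$bg)))
      ch
    }

    run_bests <- vector("list", cfg$n_runs)
    trace <- matrix(NA_real_, cfg$n_runs, cfg$generations)
    for (run in seq_len(cfg$n_runs)) {
      pop <- lapply(seq_len(cfg$population_size), function(i)
        repair(random_chromosome(n_col), cfg$min_m, cfg$max_m))
      pop <- lapply(pop, eval_chrom)
      fits <- vapply(pop, `[[`, numeric(1), "fitness")
      best <- pop[[which.max(fits)]]

      ## parsimony tie-break: at equal fitness prefer the chromosome with
      ## fewer selected features (the selection stage exists to find a small
      ## informative subset, and CV MCC often saturates on strong signal)
      better <- function(cand, cur) {
        cand$fitness > cur$fitness ||
          (cand$fitness == cur$fitness && sum(cand$bg) < sum(cur$bg))
      }

      for (gen in seq_len(cfg$generations)) {
        children <- vector("list", cfg$population_size)
        for (k in seq(1, cfg$population_size, by = 2)) {
          p1 <- pop[[tournament(fits, cfg$tournament_size)]]
          p2 <- pop[[tournament(fits, cfg$tournament_size)]]
          pair <- crossover(p1, p2, cfg$crossover_rate)
          children[[k]] <- mutate(pair[[1]], cfg$mutation_rate)
          children[[k + 1]] <- mutate(pair[[2]], cfg$mutation_rate)
        }
        children <- lapply(children, repair, min_m = cfg$min_m, max_m = cfg$max_m)
        children[[1]] <- best  # elitism
        pop <- lapply(children, eval_chrom)
        fits <- vapply(pop, `[[`, numeric(1), "fitness")
        for (cand in pop[fits >= best$fitness]) {
          if (better(cand, best)) best <- cand
        }
        trace[run, gen] <- best$fitness
      }
      run_bests[[run]] <- best
    }

    ## self-assessment report: how often each column enters a run's best
    freq <- rowMeans(vapply(run_bests, function(b) b$bg, integer(n_col)))
    mean_fit <- ifelse(col_fit_n > 0, col_fit_sum / col_fit_n, -Inf)
    ranking <- order(-freq, -mean_fit, seq_len(n_col))

    run_fit <- vapply(run_bests, `[[`, numeric(1), "fitness")
    best_overall <- run_bests[[which.max(run_fit)]]
    n_trees <- decode_param(best_overall$param_bits)

    ## truncate the ranking at the cardinality with the best refitted CV MCC
    ms <- seq(cfg$min_m, min(cfg$max_m, n_col))
    trunc_mcc <- vapply(ms, function(m) {
      cv_rf_mcc(values, y, ranking[seq_len(m)], n_trees, folds,
                child_seed(cfg$seed, paste0("trunc", m)))
    }, numeric(1))
    ## several cardinalities often tie on refit MCC (the PF signal can
    ## saturate); keep the largest tied cardinality — the ranking has already
    ## ordered columns by evidence and retaining them is the conservative
    ## choice for weaker-signal regimes
    m_best <- ms[max(which(trunc_mcc == max(trunc_mcc)))]
    selected <- sort(ranking[seq_len(m_best)])

    structure(list(selected_columns = colnames(values)[selected],
                   n_estimators = n_trees,
                   sar_frequencies = stats::setNames(freq, colnames(values)),
                   best_fitness = max(run_fit),
                   best_chromosome = best_overall,
                   run_best = run_fit,
                   trace = trace,
                   m = m_best,
                   truncation_mcc = stats::setNames(trunc_mcc, ms),
                   n_evaluations = n_evals,
                   evaluated_cardinalities = card_range,
                   folds = folds, config = cfg),
              class = "ga_result")
  })
}

tournament <- function(fits, size) {
  cand <- sample.int(length(fits), min(size, length(fits)))
  cand[which.max(fits[cand])]
}

crossover <- function(p1, p2, rate) {
  if (stats::runif(1) >= rate) return(list(p1, p2))
  g1 <- c(p1$bg, p1$param_bits); g2 <- c(p2$bg, p2$param_bits)
  swap <- stats::runif(length(g1)) < 0.5
  c1 <- ifelse(swap, g2, g1); c2 <- ifelse(swap, g1, g2)
  n <- length(p1$bg)
  list(new_chromosome(c1[seq_len(n)], c1[n + 1:3]),
       new_chromosome(c2[seq_len(n)], c2[n + 1:3]))
}

mutate <- function(ch, rate) {
  g <- c(ch$bg, ch$param_bits)
  flip <- stats::runif(length(g)) < rate
  g[flip] <- 1L - g[flip]
  n <- length(ch$bg)
  new_chromosome(g[seq_len(n)], g[n + 1:3])
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA-SAR result: m = %d selected PFs, meta-RF %d trees, best CV MCC %.3f\n",
              x$m, x$n_estimators, x$best_fitness))
  cat("selected:", paste(x$selected_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a GA result to JSON
#'
#' Stable serialization (column ids, frequencies, chosen size, traces) used
#' by the model bundle; identical results serialize byte-identically.
#'
#' @param result a `ga_result`.
#' @param path optional output file.
#' @return the JSON string, invisibly when `path` is given.
#' @export
ga_result_json <- function(result, path = NULL) {
  payload <- list(selected_columns = result$selected_columns,
                  n_estimators = result$n_estimators,
                  m = result$m,
                  best_fitness = result$best_fitness,
                  sar_frequencies = as.list(result$sar_frequencies),
                  run_best = result$run_best,
                  truncation_mcc = as.list(result$truncation_mcc),
                  trace = apply(result$trace, 1, identity, simplify = FALSE),
                  n_evaluations = result$n_evaluations)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

## ---- meta model ------------------------------------------------------------

#' Train the meta random forest
#'
#' Fits the meta-predictor on the selected PF columns (or on all columns for
#' the no-selection control) with the chosen number of trees.
#'
#' @param pf_train a [pf_matrix()].
#' @param y binary labels.
#' @param result optional `ga_result`; supplies columns and tree count.
#' @param columns PF column ids (default: all columns — the control model).
#' @param n_estimators forest size (default 100).
#' @param seed RNG seed.
#' @return an object of class `meta_model`.
#' @export
train_meta <- function(pf_train, y, result = NULL, columns = NULL,
                       n_estimators = NULL, seed = 1) {
  stopifnot(inherits(pf_train, "pf_matrix"))
  y <- as_binary01(y)
  if (!is.null(result)) {
    columns <- columns %||% result$selected_columns
    n_estimators <- n_estimators %||% result$n_estimators
  }
  columns <- columns %||% pf_train$columns
  n_estimators <- n_estimators %||% 100
  missing <- setdiff(columns, pf_train$columns)
  if (length(missing)) {
    stop_input("PF matrix lacks selected column(s): %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(pf_train)[, columns, drop = FALSE]
  fit <- ranger::ranger(x = X, y = factor(y, levels = 0:1),
                        num.trees = n_estimators, probability = TRUE,
                        num.threads = 1, seed = seed, verbose = FALSE)
  structure(list(fit = fit, columns = columns, n_estimators = n_estimators,
                 threshold = 0.5, seed = seed),
            class = "meta_model")
}

#' Predict with the meta model
#'
#' @param model a [train_meta()] result.
#' @param pf_new a [pf_matrix()] (or matrix with named columns) containing at
#'   least the selected columns.
#' @return a `data.frame` with `id`, `probability` and `class`
#'   (`probability >= 0.5` is called active; the tie goes to the positive
#'   class).
#' @export
predict_meta <- function(model, pf_new) {
  stopifnot(inherits(model, "meta_model"))
  if (inherits(pf_new, "pf_matrix")) {
    ids <- pf_new$ids; X <- as.matrix(pf_new)
  } else {
    X <- as.matrix(pf_new); ids <- rownames(X) %||% seq_len(nrow(X))
  }
  missing <- setdiff(model$columns, colnames(X))
  if (length(missing)) {
    stop_input("PF matrix lacks selected column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(X) == 0) {
    return(data.frame(id = character(0), probability = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  p <- stats::predict(model$fit, X[, model$columns, drop = FALSE],
                      num.threads = 1)$predictions[, "1"]
  data.frame(id = as.character(ids), probability = as.numeric(p),
             class = ifelse(p >= model$threshold, "active", "inactive"),
             stringsAsFactors = FALSE)
}

#' Per-column importance of the meta model
#'
#' The native backend is permutation importance: the drop in MCC, averaged
#' over `k` seeded shuffles of one column at a time. A SHAP backend can be
#' plugged in through an external engine; none ships with this package.
#'
#' @param model a [train_meta()] result.
#' @param pf a [pf_matrix()] with labels to score against.
#' @param y binary labels.
#' @param backend `"permutation"` (native) or `"shap"` (external hook).
#' @param k shuffles per column (default 10).
#' @param seed RNG seed.
#' @return named numeric vector of mean MCC drops, one per selected column.
#' @export
feature_importance <- function(model, pf, y, backend = c("permutation", "shap"),
                               k = 10, seed = 1) {
  backend <- tryCatch(match.arg(backend),
                      error = function(e) stop_config("unknown importance backend"))
  if (backend == "shap") {
    stop_config("the 'shap' backend needs an external SHAP engine; use backend = 'permutation'")
  }
  y <- as_binary01(y)
  X <- as.matrix(pf)[, model$columns, drop = FALSE]
  base_pred <- as.integer(stats::predict(model$fit, X, num.threads = 1)$predictions[, "1"] >= model$threshold)
  base_mcc <- mcc(cm_from_labels(base_pred, y))
  withr::with_seed(seed, {
    drops <- vapply(model$columns, function(col) {
      mean(vapply(seq_len(k), function(i) {
        Xp <- X
        Xp[, col] <- sample(Xp[, col])
        pred <- as.integer(stats::predict(model$fit, Xp, num.threads = 1)$predictions[, "1"] >= model$threshold)
        base_mcc - mcc(cm_from_labels(pred, y))
      }, numeric(1)))
    }, numeric(1))
  })
  drops
}
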