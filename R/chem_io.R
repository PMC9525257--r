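## Compound curation: reading tables, structure standardization, IC50
## thresholding and stratified splitting. The internal potency unit is uM
## throughout; nM inputs are converted at parse time.

#' Assign activity labels from IC50
#'
#' Potency thresholds: IC50 <= 1 uM is active, IC50 >= 10 uM is inactive,
#' values strictly between are intermediate (excluded from modelling sets).
#' Both boundaries are inclusive of their class.
#'
#' @param ic50_um positive IC50 values in micromolar.
#' @return character vector in `{"active","inactive","intermediate"}`.
#' @examples
#' assign_activity_label(c(0.5, 1, 5, 10, 50))
#' @export
assign_activity_label <- function(ic50_um) {
  ic50_um <- as.numeric(ic50_um)
  if (any(is.na(ic50_um)) || any(ic50_um <= 0)) {
    stop_input("IC50 values must be positive and non-missing")
  }
  ifelse(ic50_um <= 1, "active", ifelse(ic50_um >= 10, "inactive", "intermediate"))
}

## rough heavy-atom count from a SMILES string; used only to pick the
## largest fragment when stripping salts
count_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    n_br <- 0L
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (length(brackets)) {
      n_br <- sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", brackets))
      s <- gsub("\\[[^]]*\\]", "", s)
    }
    n2 <- length(gregexpr("Cl|Br|Si|Se", s)[[1]])
    if (n2 == 1 && gregexpr("Cl|Br|Si|Se", s)[[1]][1] == -1) n2 <- 0L
    s <- gsub("Cl|Br|Si|Se", "", s)
    n1 <- length(gregexpr("[BCNOPSFIbcnops]", s)[[1]])
    if (n1 == 1 && gregexpr("[BCNOPSFIbcnops]", s)[[1]][1] == -1) n1 <- 0L
    n_br + n2 + n1
  }, integer(1), USE.NAMES = FALSE)
}

ob_canonical <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- sub("\t.*$", "", sub("\n$", "", out))
  trimws(out)
}

standardize_one <- function(smiles, strip_salt = TRUE) {
  can <- ob_canonical(smiles)
  if (!nzchar(can)) return(NA_character_)
  if (strip_salt && grepl(".", can, fixed = TRUE)) {
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    has_c <- grepl("[Cc]", gsub("Cl|Ca|Cu|Co|Cr|Cd|Cs|Sc", "", frags))
    if (any(has_c)) frags <- frags[has_c]
    n <- count_heavy_atoms(frags)
    frags <- frags[order(-n, -nchar(frags), frags)]
    can <- ob_canonical(frags[1])
    if (!nzchar(can)) return(NA_character_)
  }
  can
}

#' Standardize a SMILES structure
#'
#' Strips salts/counter-ions (the largest organic fragment is kept) and
#' emits the Open Babel canonical SMILES, which normalizes aromaticity and
#' atom ordering. The operation is idempotent. Note that no enumeration-based
#' canonical-tautomer selection is applied: normalization is limited to what
#' canonical SMILES generation performs.
#'
#' @param smiles character vector of SMILES.
#' @param strip_salt keep only the largest organic fragment (default TRUE).
#' @return canonical SMILES, same length as the input.
#' @examples
#' standardize_structure("CC(=O)O.[Na+]")  # acetic acid fragment only
#' @export
standardize_structure <- function(smiles, strip_salt = TRUE) {
  out <- vapply(smiles, standardize_one, character(1),
                strip_salt = strip_salt, USE.NAMES = FALSE)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop_input("unparseable SMILES: %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Parse a compound table
#'
#' Reads a delimited table of compounds (id, SMILES and IC50 and/or label
#' columns), converts IC50 to micromolar, standardizes structures, drops
#' rows whose SMILES cannot be parsed (with a logged count), and collapses
#' duplicate standardized structures to a single record with the
#' geometric-mean IC50 (standard curation practice for replicated assay
#' values).
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param unit unit of the IC50 column: `"uM"` (default) or `"nM"`.
#' @param column_map named list mapping roles to column names, e.g.
#'   `list(id = "compound_id", smiles = "canonical_smiles", ic50 = "ic50")`.
#'   Roles `id` and `smiles` are required; `ic50` and `label` optional.
#' @param delim field delimiter; inferred from the extension when `NULL`.
#' @param standardize apply [standardize_structure()] (default TRUE).
#' @return a `data.frame` with columns `id`, `smiles`, `ic50_uM`, `label`
#'   plus attributes `n_dropped` (unparseable SMILES) and `n_collapsed`
#'   (duplicate structures merged).
#' @export
parse_compound_table <- function(path, unit = c("uM", "nM"),
                                 column_map = list(id = "id", smiles = "smiles",
                                                   ic50 = "ic50"),
                                 delim = NULL, standardize = TRUE) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  delim <- delim %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(tab) == 0) stop_input("empty compound table: %s", path)
  for (role in c("id", "smiles")) {
    if (is.null(column_map[[role]])) stop_config("column_map must name an '%s' column", role)
  }
  for (col in unlist(column_map)) {
    if (!col %in% names(tab)) stop_config("declared column '%s' missing from %s", col, path)
  }
  out <- data.frame(id = as.character(tab[[column_map$id]]),
                    smiles = as.character(tab[[column_map$smiles]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$smiles))) stop_input("empty SMILES entries in %s", path)
  out$ic50_uM <- if (!is.null(column_map$ic50)) {
    v <- as.numeric(tab[[column_map$ic50]])
    if (unit == "nM") v / 1000 else v
  } else NA_real_
  out$label <- if (!is.null(column_map$label)) {
    as.character(tab[[column_map$label]])
  } else NA_character_

  if (standardize) {
    std <- vapply(out$smiles, standardize_one, character(1), USE.NAMES = FALSE)
  } else {
    std <- out$smiles
    bad <- !vapply(out$smiles, function(s) nzchar(ob_canonical(s)), logical(1))
    std[bad] <- NA_character_
  }
  n_dropped <- sum(is.na(std))
  if (n_dropped > 0) {
    msg("parse_compound_table: dropped %d row(s) with unparseable SMILES", n_dropped)
    out <- out[!is.na(std), , drop = FALSE]
    std <- std[!is.na(std)]
  }
  if (nrow(out) == 0) stop_input("no parseable compounds in %s", path)
  if (standardize) out$smiles <- std

  ## collapse duplicated standardized structures: geometric-mean IC50
  n_collapsed <- 0L
  if (standardize && anyDuplicated(out$smiles)) {
    groups <- split(seq_len(nrow(out)), out$smiles)
    keep <- vapply(groups, `[`, integer(1), 1)
    gm <- vapply(groups, function(ix) {
      v <- out$ic50_uM[ix]
      if (all(is.na(v))) NA_real_ else exp(mean(log(v[!is.na(v)])))
    }, numeric(1))
    n_collapsed <- nrow(out) - length(groups)
    ord <- order(keep)
    out <- out[keep[ord], , drop = FALSE]
    out$ic50_uM <- gm[ord]
    if (n_collapsed > 0) {
      msg("parse_compound_table: collapsed %d duplicate structure(s)", n_collapsed)
    }
  }
  if (anyDuplicated(out$id)) stop_input("compound ids are not unique")

  ## derive/verify labels against the thresholding rule
  has_ic50 <- !is.na(out$ic50_uM)
  derived <- rep(NA_character_, nrow(out))
  derived[has_ic50] <- assign_activity_label(out$ic50_uM[has_ic50])
  given <- !is.na(out$label)
  clash <- given & has_ic50 & out$label != derived
  if (any(clash)) {
    stop_input("label/IC50 disagreement for: %s",
               paste(utils::head(out$id[clash], 5), collapse = ", "))
  }
  out$label <- ifelse(has_ic50, derived, out$label)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' Read a .smi file
#'
#' One molecule per line: SMILES followed by an optional whitespace-separated
#' identifier. Missing ids are generated as `M1, M2, ...`.
#'
#' @param path path to the file.
#' @return a `data.frame` with columns `id` and `smiles`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_input("empty .smi file: %s", path)
  parts <- strsplit(lines, "[ \t]+")
  data.frame(id = vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("M", i)
  }, character(1)),
  smiles = vapply(parts, `[`, character(1), 1),
  stringsAsFactors = FALSE)
}

#' Labeled modelling dataset
#'
#' Restricts a compound table to active/inactive records (intermediates are
#' excluded from modelling) and validates the container invariants: unique
#' ids, no missing labels, class counts consistent.
#'
#' @param records a `data.frame` with at least `id`, `smiles`, `label`.
#' @return an object of class `labeled_dataset` (a `data.frame` with a
#'   `class_counts` attribute).
#' @export
labeled_dataset <- function(records) {
  req <- c("id", "smiles", "label")
  if (!all(req %in% names(records))) {
    stop_input("records must have columns %s", paste(req, collapse = ", "))
  }
  if (anyNA(records$label)) stop_input("records with missing labels")
  n_int <- sum(records$label == "intermediate")
  if (n_int > 0) {
    msg("labeled_dataset: excluding %d intermediate compound(s)", n_int)
    records <- records[records$label != "intermediate", , drop = FALSE]
  }
  if (!all(records$label %in% c("active", "inactive"))) {
    stop_input("labels must be active/inactive/intermediate")
  }
  if (anyDuplicated(records$id)) stop_input("compound ids are not unique")
  rownames(records) <- NULL
  structure(records,
            class = c("labeled_dataset", "data.frame"),
            class_counts = c(n_active = sum(records$label == "active"),
                             n_inactive = sum(records$label == "inactive")))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("labeled dataset: %d compounds (%d active, %d inactive)\n",
              nrow(x), cc["n_active"], cc["n_inactive"]))
  invisible(x)
}

#' Stratified train/test split
#'
#' Draws a seeded random split preserving the class ratio: per class,
#' `round(test_fraction * n)` compounds go to the test set. With the default
#' `test_fraction = 0.2`, a 463 active / 260 inactive dataset yields the
#' usual 93 + 52 compound test set.
#'
#' @param data a [labeled_dataset()].
#' @param test_fraction fraction held out, in (0, 1); default 0.2.
#' @param seed integer RNG seed; the split is deterministic given the seed.
#' @return `list(train = , test = )` of [labeled_dataset()] objects.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1) {
  if (!inherits(data, "labeled_dataset")) data <- labeled_dataset(data)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must be in (0, 1)")
  }
  idx_test <- withr::with_seed(seed, {
    unlist(lapply(c("active", "inactive"), function(cl) {
      ix <- which(data$label == cl)
      n_test <- round(test_fraction * length(ix))
      if (length(ix) == 0 || n_test < 1 || n_test >= length(ix)) {
        stop_input("class '%s' too small for a %.2f test fraction", cl, test_fraction)
      }
      sample(ix, n_test)
    }), use.names = FALSE)
  })
  list(train = labeled_dataset(data[-idx_test, , drop = FALSE]),
       test = labeled_dataset(data[sort(idx_test), , drop = FALSE]))
}

#' Write a dataset to CSV
#'
#' Emits the canonical exchange schema `id,smiles,ic50_uM,label`, the same
#' schema [parse_compound_table()] accepts back.
#'
#' @param data a `data.frame` with at least `id`, `smiles`, `label`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  out <- data.frame(id = data$id, smiles = data$smiles,
                    ic50_uM = if ("ic50_uM" %in% names(data)) data$ic50_uM else NA,
                    label = data$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
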