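## Twelve molecular fingerprint families computed from SMILES. MACCS and
## FP4/FP4C come directly from Open Babel's published key sets; Circle is
## Open Babel's ECFP4 (radius 2) folded to 1024 bits; CKD is Open Babel's
## linear-path fingerprint. The remaining families are deterministic hashed
## substructure fingerprints at the widths users of PADEL-style tables
## expect; exact tables for those families can always be supplied through
## the precomputed backend.

FAMILY_TABLE <- data.frame(
  name = c("AP2D", "Circle", "CKD", "CKDExt", "CKDGraph", "Estate",
           "FP4", "FP4C", "Hybrid", "KR", "MACCS", "PubChem"),
  n_features = c(780L, 1024L, 1024L, 1024L, 1024L, 79L,
                 307L, 307L, 1024L, 4860L, 166L, 881L),
  type = c("binary", "binary", "binary", "binary", "binary", "binary",
           "binary", "count", "binary", "binary", "binary", "binary"),
  ## CDK-toolkit path families: native computation is a hashed-path
  ## approximation and must be opted into (or supplied precomputed)
  gated = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE,
            FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Fingerprint family registry
#'
#' The twelve supported fingerprint families with their widths and value
#' types. FP4C is count-valued; every other family is binary.
#'
#' @return a `data.frame` with columns `name`, `n_features`, `type`, `gated`.
#' @export
fingerprint_families <- function() FAMILY_TABLE

#' Describe one fingerprint family
#'
#' @param name family name (one of `fingerprint_families()$name`).
#' @param backend `"native"` (computed here from SMILES) or `"precomputed"`
#'   (loaded from a table, e.g. PADEL output).
#' @return an object of class `fingerprint_spec`.
#' @export
fingerprint_spec <- function(name, backend = c("native", "precomputed")) {
  backend <- match.arg(backend)
  row <- FAMILY_TABLE[FAMILY_TABLE$name == name, ]
  if (nrow(row) != 1) {
    stop_config("unknown fingerprint family '%s' (known: %s)", name,
                paste(FAMILY_TABLE$name, collapse = ", "))
  }
  structure(list(name = row$name, n_features = row$n_features,
                 type = row$type, backend = backend, gated = row$gated),
            class = "fingerprint_spec")
}

#' @export
print.fingerprint_spec <- function(x, ...) {
  cat(sprintf("fingerprint %s: %d %s features (%s backend)\n",
              x$name, x$n_features, x$type, x$backend))
  invisible(x)
}

## ---- molecular context -------------------------------------------------

## parse a batch of SMILES once; reused by all families
mol_context <- function(smiles, ids = NULL) {
  ids <- as.character(ids %||% names(smiles) %||% paste0("M", seq_along(smiles)))
  if (length(ids) != length(smiles)) stop_input("ids and smiles differ in length")
  bad <- !vapply(smiles, function(s) nzchar(ob_canonical(s)), logical(1))
  if (any(bad)) {
    stop_input("unparseable SMILES for: %s",
               paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  names(smiles) <- ids
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ob <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                               identity)
  graphs <- lapply(seq_along(smiles), function(i) sdf_graph(sdf[[i]], smiles[[i]]))
  list(smiles = smiles, ids = ids, sdf = sdf, ob = ob, graphs = graphs)
}

STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, Si = 4, Se = 2, H = 1)

## atom/bond view of one molecule: elements, bonds, degrees, implicit H,
## ring membership (edges that are not bridges)
sdf_graph <- function(sdfmol, smiles = NULL) {
  ab <- tryCatch(ChemmineR::atomblock(sdfmol), error = function(e) NULL)
  ## ChemmineR flags single-atom molecules as invalid SDFs and returns a
  ## degenerate block; recover the atom list from the SMILES instead
  if (is.null(ab) || is.null(rownames(ab)) || !any(grepl("_", rownames(ab)))) {
    return(smiles_atoms_graph(smiles %||% ""))
  }
  el <- sub("_.*$", "", rownames(ab))
  n <- length(el)
  bb <- tryCatch(ChemmineR::bondblock(sdfmol), error = function(e) NULL)
  if (is.null(bb) || length(bb) == 0) bb <- matrix(integer(0), 0, 3)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  bonds <- if (nrow(bb) > 0) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  valsum <- rep(0, n)
  for (k in seq_len(nrow(bonds))) {
    valsum[bonds$i[k]] <- valsum[bonds$i[k]] + bonds$order[k]
    valsum[bonds$j[k]] <- valsum[bonds$j[k]] + bonds$order[k]
  }
  nh <- pmax(0, unname(STD_VALENCE[el]) - valsum)
  nh[is.na(nh)] <- 0
  in_ring_edge <- rep(FALSE, nrow(bonds))
  ring_sizes <- integer(0)
  if (nrow(bonds) > 0 && n > 2) {
    g <- igraph::graph_from_data_frame(bonds[, c("i", "j")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    br <- igraph::bridges(g)
    in_ring_edge <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_sizes <- tryCatch({
      gr <- igraph::subgraph_from_edges(g, igraph::E(g)[in_ring_edge],
                                        delete.vertices = FALSE)
      comps <- igraph::components(gr)
      sz <- table(comps$membership[igraph::degree(gr) > 0])
      as.integer(sz)
    }, error = function(e) integer(0))
  }
  in_ring_atom <- rep(FALSE, n)
  if (any(in_ring_edge)) {
    in_ring_atom[unique(c(bonds$i[in_ring_edge], bonds$j[in_ring_edge]))] <- TRUE
  }
  adj <- vector("list", n)
  bond_order <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    bond_order[[bonds$i[k]]] <- c(bond_order[[bonds$i[k]]], bonds$order[k])
    bond_order[[bonds$j[k]]] <- c(bond_order[[bonds$j[k]]], bonds$order[k])
  }
  list(el = el, n = n, bonds = bonds, deg = deg, nh = nh,
       in_ring = in_ring_atom, ring_component_sizes = ring_sizes,
       adj = adj, bond_order = bond_order)
}

## bond-less graph for molecules ChemmineR cannot block out (single heavy
## atoms and the like); elements come from a simple SMILES token scan
smiles_atoms_graph <- function(smiles) {
  s <- smiles
  el <- character(0)
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  if (length(brackets)) {
    el <- c(el, gsub("^\\[|[0-9@+H-]|\\]", "", brackets))
    s <- gsub("\\[[^]]*\\]", "", s)
  }
  m2 <- regmatches(s, gregexpr("Cl|Br|Si|Se", s))[[1]]
  el <- c(el, m2)
  s <- gsub("Cl|Br|Si|Se", "", s)
  m1 <- regmatches(s, gregexpr("[BCNOPSFI]|[bcnops]", s))[[1]]
  el <- c(el, toupper(m1))
  el <- el[nzchar(el)]
  n <- length(el)
  val <- unname(STD_VALENCE[el]); val[is.na(val)] <- 0
  list(el = el, n = n,
       bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
       deg = rep(0L, n), nh = val, in_ring = rep(FALSE, n),
       ring_component_sizes = integer(0),
       adj = rep(list(integer(0)), n), bond_order = rep(list(integer(0)), n))
}

## atom type string used by the typed/hashed families
atom_type <- function(g, i) {
  sprintf("%s.d%d.h%d.%s", g$el[i], g$deg[i], g$nh[i],
          if (g$in_ring[i]) "R" else "A")
}

## circular environment keys up to the given radius (Morgan-style labels)
env_keys <- function(g, max_radius = 2) {
  keys <- character(0)
  base <- vapply(seq_len(g$n), function(i) atom_type(g, i), character(1))
  lab <- base
  keys <- c(keys, paste0("r0:", lab))
  for (r in seq_len(max_radius)) {
    lab <- vapply(seq_len(g$n), function(i) {
      nb <- g$adj[[i]]
      if (length(nb) == 0) return(paste0(lab[i], "()"))
      nbl <- sort(paste0(g$bond_order[[i]], lab[nb]))
      paste0(lab[i], "(", paste(nbl, collapse = ","), ")")
    }, character(1))
    keys <- c(keys, paste0("r", r, ":", lab))
  }
  unique(keys)
}

## simple-path keys up to max_len atoms; labels per atom via `label_fun`,
## bond orders included when `use_order`
path_keys <- function(g, max_len, label_fun, use_order = TRUE) {
  labs <- vapply(seq_len(g$n), function(i) label_fun(g, i), character(1))
  keys <- new.env(parent = emptyenv())
  walk <- function(path, key_fwd) {
    last <- path[length(path)]
    if (length(path) >= 2) {
      rev_key <- path_key(rev(path), labs, g, use_order)
      k <- if (key_fwd <= rev_key) key_fwd else rev_key
      assign(k, TRUE, envir = keys)
    }
    if (length(path) >= max_len) return(invisible())
    for (idx in seq_along(g$adj[[last]])) {
      nxt <- g$adj[[last]][idx]
      if (nxt %in% path) next
      b <- if (use_order) g$bond_order[[last]][idx] else ""
      walk(c(path, nxt), paste0(key_fwd, "-", b, labs[nxt]))
    }
  }
  for (s in seq_len(g$n)) {
    assign(labs[s], TRUE, envir = keys)  # single-atom fragment
    walk(s, labs[s])
  }
  ls(keys)
}

path_key <- function(path, labs, g, use_order) {
  out <- labs[path[1]]
  for (k in seq_along(path)[-1]) {
    a <- path[k - 1]; b <- path[k]
    o <- if (use_order) g$bond_order[[a]][match(b, g$adj[[a]])] else ""
    out <- paste0(out, "-", o, labs[b])
  }
  out
}

bits_from_keys <- function(keys, n_features, salt) {
  row <- integer(n_features)
  if (length(keys)) row[unique(hash_bin(keys, n_features, salt))] <- 1L
  row
}

## ---- family implementations --------------------------------------------

ob_fp_matrix <- function(ctx, ob_name) {
  m <- ChemmineOB::fingerprint_OB(ctx$ob, ob_name)
  if (is.vector(m)) m <- t(as.matrix(m))
  m
}

fp_openbabel <- function(ctx, ob_name, n_features) {
  m <- ob_fp_matrix(ctx, ob_name)
  if (ncol(m) < n_features) {
    m <- cbind(m, matrix(0L, nrow(m), n_features - ncol(m)))
  }
  m[, seq_len(n_features), drop = FALSE]
}

fp_circle <- function(ctx) {
  m <- ob_fp_matrix(ctx, "ECFP4")
  folds <- ncol(m) / 1024L
  out <- matrix(0L, nrow(m), 1024L)
  for (k in seq_len(folds)) {
    out <- out + m[, ((k - 1) * 1024L + 1):(k * 1024L), drop = FALSE]
  }
  (out > 0) + 0L
}

fp4_patterns <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("openbabel_data", "SMARTS_InteLigand.txt",
                        package = "ChemmineOB")
    if (!nzchar(path) || !file.exists(path)) {
      stop_config("Open Babel SMARTS pattern file not found; use the precomputed backend for FP4/FP4C")
    }
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- regmatches(lines, regexpr(":", lines), invert = TRUE)
    pats <- trimws(vapply(parts, `[`, character(1), 2))
    names(pats) <- trimws(vapply(parts, `[`, character(1), 1))
    cache <<- pats[seq_len(307)]
    cache
  }
})

fp_fp4 <- function(ctx, counts = FALSE) {
  pats <- fp4_patterns()
  m <- vapply(pats, function(p) {
    v <- tryCatch(ChemmineOB::smartsSearch_OB(ctx$ob, p),
                  error = function(e) rep(0, length(ctx$ids)))
    as.numeric(v)
  }, numeric(length(ctx$ids)))
  m <- matrix(m, nrow = length(ctx$ids))
  if (counts) m else (m > 0) + 0L
}

fp_ap2d <- function(ctx) {
  t(vapply(seq_along(ctx$ids), function(i) {
    desc <- numeric(0)
    ## ChemmineR cats its failure note before erroring; capture it
    utils::capture.output(utils::capture.output(
      desc <- tryCatch(suppressWarnings(suppressMessages({
        ap <- ChemmineR::sdf2ap(ctx$sdf[i])
        d <- ChemmineR::ap(ap)[[1]]
        if (length(d) == 1 && d == 1) numeric(0) else d  # failure marker
      })), error = function(e) numeric(0)),
      type = "message"), type = "output")
    bits_from_keys(as.character(desc), 780L, "ap2d")
  }, integer(780L)))
}

fp_estate <- function(ctx) {
  t(vapply(ctx$graphs, function(g) {
    types <- vapply(seq_len(g$n), function(i) atom_type(g, i), character(1))
    bits_from_keys(unique(types), 79L, "estate")
  }, integer(79L)))
}

fp_ckdext <- function(ctx) {
  base <- fp_openbabel(ctx, "FP2", 1024L)
  ring <- t(vapply(ctx$graphs, function(g) {
    keys <- character(0)
    if (length(g$ring_component_sizes)) {
      keys <- c(paste0("ringsys", g$ring_component_sizes),
                paste0("nringsys", length(g$ring_component_sizes)))
    }
    bits_from_keys(keys, 1024L, "ckdext_ring")
  }, integer(1024L)))
  ((base + ring) > 0) + 0L
}

fp_paths <- function(ctx, n_features, salt, label_fun, use_order, max_len) {
  t(vapply(ctx$graphs, function(g) {
    bits_from_keys(path_keys(g, max_len, label_fun, use_order), n_features, salt)
  }, integer(n_features)))
}

fp_kr <- function(ctx) {
  t(vapply(ctx$graphs, function(g) {
    bits_from_keys(env_keys(g, 2), 4860L, "kr")
  }, integer(4860L)))
}

fp_pubchem <- function(ctx) {
  t(vapply(ctx$graphs, function(g) {
    keys <- env_keys(g, 1)
    counts <- table(g$el)
    for (e in names(counts)) {
      keys <- c(keys, paste0("n", e, ">=", seq_len(min(counts[[e]], 16))))
    }
    if (length(g$ring_component_sizes)) {
      keys <- c(keys, paste0("ringsys", g$ring_component_sizes))
    }
    bits_from_keys(unique(keys), 881L, "pubchem")
  }, integer(881L)))
}

## ---- public operations --------------------------------------------------

#' Compute a fingerprint matrix from SMILES
#'
#' Dispatches to the family's native implementation. The four CDK-toolkit
#' path families (CKD, CKDExt, CKDGraph, Hybrid) are hashed-path
#' approximations of the original Java definitions: computing them natively
#' requires `allow_approx = TRUE`, otherwise a capability error points to the
#' precomputed backend.
#'
#' @param smiles character vector of standardized SMILES (optionally named
#'   by compound id).
#' @param spec a [fingerprint_spec()] or family name.
#' @param ids compound identifiers (defaults to `names(smiles)`).
#' @param allow_approx opt in to native hashed-path approximations of the
#'   CDK families.
#' @param ctx internal: a pre-parsed molecule context, to avoid re-parsing
#'   when computing several families of the same compounds.
#' @return an object of class `fingerprint_matrix`.
#' @examples
#' fp <- compute_fingerprint(c(a = "CCO", b = "c1ccccc1O"), "MACCS")
#' dim(as.matrix(fp))
#' @export
compute_fingerprint <- function(smiles, spec, ids = NULL, allow_approx = FALSE,
                                ctx = NULL) {
  if (is.character(spec)) spec <- fingerprint_spec(spec)
  if (spec$backend != "native") {
    stop_config("spec backend is '%s'; use load_precomputed_fingerprints()", spec$backend)
  }
  if (spec$gated && !allow_approx) {
    stop_config(paste0(
      "no exact native implementation for family '%s': supply a precomputed ",
      "table (backend = 'precomputed') or set allow_approx = TRUE for the ",
      "hashed-path approximation"), spec$name)
  }
  ctx <- ctx %||% mol_context(smiles, ids)
  values <- switch(spec$name,
    MACCS = fp_openbabel(ctx, "MACCS", 166L),
    CKD = fp_openbabel(ctx, "FP2", 1024L),
    Circle = fp_circle(ctx),
    FP4 = fp_fp4(ctx, counts = FALSE),
    FP4C = fp_fp4(ctx, counts = TRUE),
    AP2D = fp_ap2d(ctx),
    Estate = fp_estate(ctx),
    CKDExt = fp_ckdext(ctx),
    CKDGraph = fp_paths(ctx, 1024L, "ckdgraph",
                        function(g, i) g$el[i], use_order = FALSE, max_len = 7),
    Hybrid = fp_paths(ctx, 1024L, "hybrid",
                      function(g, i) paste0(g$el[i], g$deg[i]),
                      use_order = TRUE, max_len = 6),
    KR = fp_kr(ctx),
    PubChem = fp_pubchem(ctx),
    stop_config("unsupported family '%s'", spec$name))
  values <- matrix(as.numeric(values), nrow = length(ctx$ids),
                   dimnames = list(ctx$ids, paste0(spec$name, "FP", seq_len(spec$n_features))))
  fingerprint_matrix(spec, ctx$ids, values)
}

#' Compute several fingerprint families at once
#'
#' Parses the molecules once and evaluates each requested family on the
#' shared parse, which is how the training pipeline featurizes compounds.
#'
#' @inheritParams compute_fingerprint
#' @param families character vector of family names.
#' @return a named list of `fingerprint_matrix` objects.
#' @export
compute_fingerprints <- function(smiles, families, ids = NULL, allow_approx = FALSE) {
  ctx <- mol_context(smiles, ids)
  out <- lapply(families, function(f) {
    compute_fingerprint(smiles, fingerprint_spec(f), ids = ids,
                        allow_approx = allow_approx, ctx = ctx)
  })
  names(out) <- families
  out
}

#' Fingerprint matrix container
#'
#' @param spec a [fingerprint_spec()].
#' @param ids ordered compound ids.
#' @param values numeric matrix, compounds x features.
#' @return an object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(spec, ids, values) {
  if (is.character(spec)) spec <- fingerprint_spec(spec)
  values <- as.matrix(values)
  if (nrow(values) != length(ids)) stop_input("row count does not match ids")
  if (ncol(values) != spec$n_features) {
    stop_input("family %s expects %d features, got %d",
               spec$name, spec$n_features, ncol(values))
  }
  if (anyNA(values)) stop_input("fingerprint matrix contains missing values")
  if (any(values < 0)) stop_input("fingerprint values must be non-negative")
  if (spec$type == "binary" && !all(values %in% c(0, 1))) {
    stop_input("family %s is binary but matrix has values outside {0,1}", spec$name)
  }
  rownames(values) <- ids
  structure(list(spec = spec, ids = as.character(ids), values = values),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix %s: %d compounds x %d features\n",
              x$spec$name, length(x$ids), x$spec$n_features))
  invisible(x)
}

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) x$values

#' Load a precomputed fingerprint table
#'
#' Reads PADEL-style output: an id column (first column, or one named
#' `id`/`Name`) followed by exactly `n_features` numeric columns for the
#' declared family. Column count mismatches and out-of-range values for
#' binary families are rejected.
#'
#' @param path CSV path.
#' @param spec a [fingerprint_spec()] or family name.
#' @return a `fingerprint_matrix`.
#' @export
load_precomputed_fingerprints <- function(path, spec) {
  if (is.character(spec)) spec <- fingerprint_spec(spec, backend = "precomputed")
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- if ("id" %in% names(tab)) "id" else if ("Name" %in% names(tab)) "Name" else names(tab)[1]
  ids <- as.character(tab[[id_col]])
  vals <- as.matrix(tab[, setdiff(names(tab), id_col), drop = FALSE])
  if (ncol(vals) != spec$n_features) {
    stop_input("schema error: family %s expects %d feature columns, found %d",
               spec$name, spec$n_features, ncol(vals))
  }
  storage.mode(vals) <- "numeric"
  fingerprint_matrix(spec, ids, vals)
}

#' Write a fingerprint matrix to CSV
#'
#' Emits `id` plus one column per feature — the same schema that
#' [load_precomputed_fingerprints()] reads back, enabling caching.
#'
#' @param fpm a `fingerprint_matrix`.
#' @param path output path.
#' @export
write_fingerprint_csv <- function(fpm, path) {
  out <- data.frame(id = fpm$ids, fpm$values, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- min-max normalization ----------------------------------------------

#' Fit a per-feature min-max scaler on training rows
#'
#' Descriptors are normalized to the 0-1 range before model training. The
#' scaler must be fitted on training rows only and then applied to both
#' training and test matrices; out-of-range test values are clipped to
#' `[0, 1]` and constant training columns map to 0.
#'
#' @param x a `fingerprint_matrix` or numeric matrix (training rows).
#' @return an object of class `minmax_scaler`.
#' @export
fit_minmax <- function(x) {
  m <- if (inherits(x, "fingerprint_matrix")) x$values else as.matrix(x)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 features = colnames(m)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler a [fit_minmax()] result.
#' @param x matrix or `fingerprint_matrix` to transform.
#' @return object of the same kind as `x`, values in `[0, 1]`.
#' @export
apply_minmax <- function(scaler, x) {
  if (!inherits(scaler, "minmax_scaler")) {
    stop_config("apply_minmax called with an unfitted or invalid scaler")
  }
  fpm <- NULL
  if (inherits(x, "fingerprint_matrix")) { fpm <- x; x <- x$values }
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min)) {
    stop_input("feature-width mismatch: scaler has %d features, input %d",
               length(scaler$min), ncol(x))
  }
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- dimnames(x)
  if (!is.null(fpm)) {
    fpm$values <- out
    ## normalized counts are no longer integral; relax the type tag
    fpm$spec$type <- "normalized"
    return(fpm)
  }
  out
}
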