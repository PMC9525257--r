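## shared fixtures built in code

# a small panel of valid drug-like SMILES covering rings, heteroatoms,
# charges and salts
smiles_panel <- function() {
  c("CCO", "CC(=O)O", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "c1ccc2c(c1)cccn2", "CC(=O)Oc1ccccc1C(=O)O", "C1CCCCC1",
    "c1ccc(cc1)S(=O)(=O)N", "CCN(CC)CC", "COc1ccc(cc1)CCN",
    "CC(C)NCC(O)COc1ccccc1", "O=C1CCCCC1", "CC(=O)O.[Na+]",
    "C[N+](C)(C)C.[Cl-]", "OC(=O)c1ccccc1O", "CNC", "CCS", "c1ccncc1")
}

# write a compound CSV and return its path
write_compound_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# small labeled dataset with perfectly informative MACCS-visible structure?
# no: labels here are random wrt structure; used to test plumbing only
tiny_labeled_csv <- function(n = 60, seed = 42) {
  comp <- make_synthetic_compounds(n, active_fraction = 0.5, seed = seed)
  comp$label <- assign_activity_label(comp$ic50_uM)
  write_compound_csv(comp)
}

quietly <- function(expr) suppressMessages(expr)
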