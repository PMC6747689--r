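# shared fixtures, built in code

random_block <- function(id = "B", kind = "binary", n = 6, p = 4, seed = 1) {
  set.seed(seed)
  v <- switch(kind,
    binary = matrix(rbinom(n * p, 1, 0.4), n),
    count = matrix(rpois(n * p, 1.5), n),
    continuous = matrix(round(rnorm(n * p), 6), n))
  feature_block(id, kind, v, compound_ids = sprintf("c%02d", seq_len(n)),
                feature_names = sprintf("f%d", seq_len(p)))
}

# five small blocks mirroring the full layout: two signal fingerprints,
# two noise fingerprints (one a count block), and the descriptors
tiny_block_specs <- function() {
  data.frame(
    block_id = c("ExtendedFP", "KRFP", "MaccsFP", "nKRFP", "DESCRIPTORS"),
    kind = c("binary", "binary", "binary", "count", "continuous"),
    width = c(24L, 32L, 12L, 16L, 7L))
}

tiny_config <- function(n = 120, seed = 1, signal = default_signal()) {
  generator_config(n_compounds = n, block_specs = tiny_block_specs(),
                   signal = signal, seed = seed)
}

tiny_dataset <- function(n = 120, seed = 1, signal = default_signal()) {
  generate_dili_data(tiny_config(n, seed, signal))
}

# linearly separable two-feature toy problem
separable_toy <- function(n = 20, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5),
             b = rnorm(n))
  list(X = X, y = y)
}

table1_grid <- function() {
  read_accuracy_grid(system.file("extdata", "table1.csv",
                                 package = "dilivote"))
}

table1_counts_printed <- c(LR = 2L, SVM = 0L, GDBT = 9L, AdaBT = 2L,
                           XGBT = 10L, RF = 11L, ExtraTrees = 6L,
                           LGBT = 9L, CatBT = 11L)

write_test_sdf <- function(path) {
  writeLines(c(
    "MoleculeA", "  dilivote", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END",
    "$$$$",
    "aspirin", "  dilivote", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END",
    "> <PUBCHEM_COMPOUND_CID>",
    "2244", "",
    "$$$$"), path)
  path
}
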