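# Small in-code fixtures shared across test files.

# A TissueExpressionSet built from an explicit matrix.
makeTable <- function(m, species = "test_sp") {
  LEDtools::TissueExpressionSet(m, species)
}

# Random TPM table: n genes x T tissues, lognormal-ish positive values.
randomTable <- function(n, T = 9, species = "rand_sp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(2^rnorm(n * T, 5, 2), n, T,
              dimnames = list(sprintf("g%04d", seq_len(n)),
                              paste0("t", seq_len(T))))
  makeTable(m, species)
}

# Write a data.frame as a TSV in a temp file and return the path.
tmpTsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# Random normalized profiles (rows sum to 1) for distance/LED property tests.
randomProfiles <- function(n, T = 9) {
  v <- matrix(abs(rnorm(n * T)) + 1e-3, n, T)
  v / rowSums(v)
}

# A tiny GoDag: chain leaf -> mid -> root plus a sibling leaf, all one
# namespace.
chainDag <- function() {
  new("GoDag",
    terms = data.frame(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
      name = c("root", "mid", "leaf", "leaf2"),
      namespace = "biological_process"
    ),
    parents = list(
      "GO:0000001" = character(0),
      "GO:0000002" = "GO:0000001",
      "GO:0000003" = "GO:0000002",
      "GO:0000004" = "GO:0000002"
    )
  )
}
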