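#' Construct a TissueExpressionSet from a TPM matrix
#'
#' @param tpm numeric matrix of TPM values, genes in rows (rownames = gene
#'   identifiers), tissues in columns (colnames = tissue names).
#' @param species single character, species identifier.
#' @return a validated [TissueExpressionSet-class].
#' @examples
#' m <- matrix(c(1, 4, 0, 8), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("leaf", "anther")))
#' TissueExpressionSet(m, "demo_species")
#' @export
TissueExpressionSet <- function(tpm, species) {
  tpm <- as.matrix(tpm)
  storage.mode(tpm) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  new("TissueExpressionSet", se, species = as.character(species))
}

#' Read a per-species gene x tissue TPM table
#'
#' Parses a TSV whose header row names the tissues, whose first column holds
#' gene identifiers and whose remaining cells are non-negative TPM values.
#'
#' @param path path to the TSV file.
#' @param species species identifier attached to the resulting object.
#' @param tissues optional character vector of expected tissue names; when
#'   supplied (e.g. taken from the first table loaded in a run) the file must
#'   contain exactly these tissues in this order.
#' @return a [TissueExpressionSet-class].
#' @details Duplicate gene identifiers, non-numeric or negative cells (the
#'   offending row and column are named) and tissue mismatches against
#'   `tissues` are rejected.
#' @export
readTpmTable <- function(path, species, tissues = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("TPM table needs a gene column and >=1 tissue column")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene identifier '%s' in %s",
                 genes[duplicated(genes)][1L], path))
  }
  tiss <- colnames(df)[-1L]
  if (!is.null(tissues) && !identical(tiss, as.character(tissues))) {
    stop(sprintf(
      "tissue columns of %s (%s) do not match the run's tissues (%s)",
      path, paste(tiss, collapse = ","), paste(tissues, collapse = ",")
    ))
  }
  m <- matrix(NA_real_, nrow(df), length(tiss),
              dimnames = list(genes, tiss))
  for (j in seq_along(tiss)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', tissue '%s'",
                   df[[j + 1L]][bad[1L]], genes[bad[1L]], tiss[j]))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("negative TPM %g at gene '%s', tissue '%s'",
                   v[neg[1L]], genes[neg[1L]], tiss[j]))
    }
    m[, j] <- v
  }
  TissueExpressionSet(m, species)
}

#' Read a 1:1:1 ortholog triple table
#'
#' Expects the header `gene_x<TAB>gene_y<TAB>gene_z` (an optional leading
#' `triple_id` column is honoured). Each gene identifier may occur in at most
#' one triple.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `triple_id`, `gene_x`, `gene_y`, `gene_z`.
#' @export
readOrthologTriples <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  need <- c("gene_x", "gene_y", "gene_z")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns gene_x, gene_y, gene_z")
  }
  if (!"triple_id" %in% names(df)) {
    df$triple_id <- sprintf("tr%05d", seq_len(nrow(df)))
  }
  for (col in need) {
    if (anyDuplicated(df[[col]])) {
      stop(sprintf("gene '%s' occurs in more than one triple (column %s)",
                   df[[col]][duplicated(df[[col]])][1L], col))
    }
  }
  df[, c("triple_id", need)]
}

#' Genes passing the expression filter
#'
#' A gene is retained when its log2 TPM strictly exceeds `threshold`
#' (equivalently TPM > 2^threshold) in at least one tissue. The filter acts on
#' raw TPM, so zeros are excluded automatically and no pseudocount is
#' involved.
#'
#' @param x a [TissueExpressionSet-class].
#' @param threshold log2-TPM cutoff; default 2, i.e. TPM > 4.
#' @return character vector of retained gene identifiers, in table order.
#' @examples
#' m <- matrix(c(4, 0, 5, 0), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("t1", "t2")))
#' filterExpressed(TissueExpressionSet(m, "s"))  # g1: max TPM 5 > 4
#' @export
filterExpressed <- function(x, threshold = 2) {
  stopifnot(is(x, "TissueExpressionSet"), is.numeric(threshold),
            length(threshold) == 1L)
  m <- tpm(x)
  keep <- apply(m, 1L, max) > 2^threshold
  rownames(m)[keep]
}

#' Relative-abundance expression profiles
#'
#' For each requested gene, TPM values are transformed to
#' v_t = log2(TPM_t + pseudocount) and normalized to sum to one
#' (`scale = "log"`, the default). With `scale = "raw"` the profile is the
#' raw-TPM share per tissue instead.
#'
#' @param x a [TissueExpressionSet-class].
#' @param genes gene identifiers to profile; all must be present in `x`.
#' @param pseudocount added before the log transform; default 1.
#' @param scale `"log"` (normalize log-transformed values) or `"raw"`
#'   (normalize raw TPM).
#' @return numeric matrix genes x tissues; every row sums to 1.
#' @export
makeProfiles <- function(x, genes = rownames(x), pseudocount = 1,
                         scale = c("log", "raw")) {
  scale <- match.arg(scale)
  stopifnot(is(x, "TissueExpressionSet"))
  m <- tpm(x)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop(sprintf("gene '%s' absent from table for species '%s'",
                 missing[1L], species(x)))
  }
  m <- m[genes, , drop = FALSE]
  v <- if (scale == "log") log2(m + pseudocount) else m
  tot <- rowSums(v)
  if (any(tot <= 0)) {
    stop(sprintf("profile undefined for gene '%s' (all-zero expression)",
                 genes[which(tot <= 0)[1L]]))
  }
  v / tot
}

#' Restrict ortholog triples to genes passing the expression filter everywhere
#'
#' A triple enters LED computation only when all three members passed
#' [filterExpressed()] in their own species.
#'
#' @param triples data.frame from [readOrthologTriples()].
#' @param retained list of three character vectors (genes retained in species
#'   x, y, z, in that order).
#' @param universe optional list of three character vectors of all gene
#'   identifiers per species; a triple referencing a gene absent from its
#'   species' table is an error.
#' @return list with `triples` (the retained subset, original order) and
#'   `dropped` (named integer vector: triples failing the filter per species).
#' @export
alignTriples <- function(triples, retained, universe = NULL) {
  stopifnot(is.list(retained), length(retained) == 3L)
  cols <- c("gene_x", "gene_y", "gene_z")
  if (!is.null(universe)) {
    stopifnot(is.list(universe), length(universe) == 3L)
    for (i in 1:3) {
      bad <- !(triples[[cols[i]]] %in% universe[[i]])
      if (any(bad)) {
        stop(sprintf("triple '%s': gene '%s' absent from species table %d",
                     triples$triple_id[bad][1L],
                     triples[[cols[i]]][bad][1L], i))
      }
    }
  }
  pass <- vapply(1:3, function(i) triples[[cols[i]]] %in% retained[[i]],
                 logical(nrow(triples)))
  if (nrow(triples) == 1L) pass <- matrix(pass, nrow = 1L)
  keep <- rowSums(pass) == 3L
  dropped <- as.integer(colSums(!pass))
  names(dropped) <- c("species_x", "species_y", "species_z")
  list(triples = triples[keep, , drop = FALSE], dropped = dropped)
}
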