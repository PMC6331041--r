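#' Tissue specificity index tau
#'
#' tau = sum_i(1 - x_i / max(x)) / (T - 1), ranging from 0 for a uniformly
#' expressed gene to 1 for a gene expressed in exactly one tissue.
#'
#' @param x non-negative expression vector over T >= 2 tissues; at least one
#'   entry must be positive. The pipeline applies this to log2(TPM + 1)
#'   values (see [tissueSpecificity()]).
#' @return tau in [0, 1].
#' @examples
#' computeTau(c(1, 0.5, 0))  # 0.75
#' @export
computeTau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least two tissues")
  if (any(x < 0) || anyNA(x)) stop("expression values must be non-negative")
  xmax <- max(x)
  if (xmax == 0) stop("tau undefined for an all-zero expression vector")
  sum(1 - x / xmax) / (length(x) - 1L)
}

#' Per-gene tissue specificity for a species table
#'
#' Applies [computeTau()] to log2(TPM + pseudocount) per gene, the same
#' transform used for profile construction.
#'
#' @param x a [TissueExpressionSet-class].
#' @param genes gene identifiers (default: all genes in `x`).
#' @param pseudocount added before the log transform; default 1.
#' @return named numeric vector of tau values.
#' @export
tissueSpecificity <- function(x, genes = rownames(x), pseudocount = 1) {
  m <- log2(tpm(x)[genes, , drop = FALSE] + pseudocount)
  apply(m, 1L, computeTau)
}

#' Primary tissue of an expression vector
#'
#' The tissue with maximal expression; ties are broken by the first
#' occurrence in the canonical tissue order.
#'
#' @param x non-negative expression vector with at least one positive entry.
#' @param tissues tissue names, same length and order as `x`.
#' @return a single tissue name.
#' @export
primaryTissue <- function(x, tissues) {
  stopifnot(length(x) == length(tissues))
  if (max(x) <= 0) stop("primary tissue undefined for an all-zero vector")
  tissues[which.max(x)]
}

#' Primary tissue for every gene of a species table
#'
#' @param x a [TissueExpressionSet-class].
#' @param genes gene identifiers (default: all genes in `x`).
#' @return named character vector of tissue names (raw-TPM argmax,
#'   first-occurrence tie-break).
#' @export
primaryTissues <- function(x, genes = rownames(x)) {
  m <- tpm(x)[genes, , drop = FALSE]
  if (any(apply(m, 1L, max) <= 0)) {
    stop("primary tissue undefined for an all-zero gene")
  }
  setNames(tissues(x)[max.col(m, ties.method = "first")], genes)
}

#' Genes in the top fraction of a score
#'
#' Returns the k = ceiling(fraction * N) genes with the largest scores. Ties
#' at the cut are resolved deterministically: descending score, then
#' lexicographic gene identifier.
#'
#' @param scores named numeric vector (gene -> score, e.g. LED).
#' @param fraction in (0, 1]; default 0.01 (the top 1 percent).
#' @return character vector of gene identifiers, ordered as selected.
#' @export
selectTopFraction <- function(scores, fraction = 0.01) {
  if (!length(scores)) stop("empty score table")
  stopifnot(fraction > 0, fraction <= 1, !is.null(names(scores)))
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}

#' Read a per-gene sequence-divergence table
#'
#' Expects the header `gene<TAB>branch_length<TAB>ka<TAB>ka_ks`. Empty cells
#' become missing values (e.g. Ka/Ks undefined when Ks = 0 upstream);
#' negative values are rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `branch_length`, `ka`, `ka_ks`.
#' @export
readDivergenceTable <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  need <- c("gene", "branch_length", "ka", "ka_ks")
  if (!all(need %in% names(df))) {
    stop("divergence table must have columns gene, branch_length, ka, ka_ks")
  }
  for (col in need[-1L]) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(trimws(raw)) & !is.na(raw))
    if (length(bad)) {
      stop(sprintf("non-numeric %s '%s' for gene '%s'",
                   col, raw[bad[1L]], df$gene[bad[1L]]))
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop(sprintf("negative %s for gene '%s'",
                   col, df$gene[which(v < 0)[1L]]))
    }
    df[[col]] <- v
  }
  df[, need]
}

#' Read a per-gene interaction-count table
#'
#' Expects the header `gene<TAB>n_partners` with non-negative integer counts.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `n_partners` (integer).
#' @export
readInteractions <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (!all(c("gene", "n_partners") %in% names(df))) {
    stop("interaction table must have columns gene, n_partners")
  }
  v <- suppressWarnings(as.numeric(df$n_partners))
  bad <- which(is.na(v) | v < 0 | v != round(v))
  if (length(bad)) {
    stop(sprintf("interaction count '%s' for gene '%s' is not a non-negative integer",
                 df$n_partners[bad[1L]], df$gene[bad[1L]]))
  }
  data.frame(gene = df$gene, n_partners = as.integer(v))
}

#' Join per-gene correlates, preserving missingness
#'
#' Left-joins tissue specificity, primary tissue, sequence divergence and
#' interaction counts onto a gene list. Genes absent from a table carry NA;
#' table rows for unknown genes are reported via a message and kept out of
#' the join. Downstream statistics use complete cases per property and
#' report the complete-case n.
#'
#' @param genes character vector of gene identifiers.
#' @param tau named numeric vector from [tissueSpecificity()].
#' @param primary named character vector from [primaryTissues()].
#' @param divergence optional data.frame from [readDivergenceTable()].
#' @param interactions optional data.frame from [readInteractions()].
#' @return data.frame, one row per gene.
#' @export
genicCorrelates <- function(genes, tau, primary, divergence = NULL,
                            interactions = NULL) {
  out <- data.frame(
    gene = genes,
    tau = unname(tau[genes]),
    primary_tissue = unname(primary[genes])
  )
  if (!is.null(divergence)) {
    unknown <- setdiff(divergence$gene, genes)
    if (length(unknown)) {
      message(sprintf("%d divergence-table genes not in the gene list",
                      length(unknown)))
    }
    i <- match(genes, divergence$gene)
    out$tree_branch_length <- divergence$branch_length[i]
    out$ka <- divergence$ka[i]
    out$ka_ks <- divergence$ka_ks[i]
  }
  if (!is.null(interactions)) {
    unknown <- setdiff(interactions$gene, genes)
    if (length(unknown)) {
      message(sprintf("%d interaction-table genes not in the gene list",
                      length(unknown)))
    }
    out$interaction_count <- interactions$n_partners[match(genes, interactions$gene)]
  }
  out
}
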