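#' Rank-based GO enrichment of divergence scores
#'
#' Genes are ranked by descending score (e.g. LED). For each term with at
#' least `node_size` annotated genes, a one-sided two-sample
#' Kolmogorov-Smirnov test asks whether the annotated genes' ranks are
#' shifted toward the top relative to the remaining scored genes.
#'
#' With `algorithm = "classic"` every term is tested independently. With
#' `algorithm = "elim"` (default) terms are processed children before
#' parents; whenever a term achieves p < `alpha_elim`, its (remaining)
#' annotated genes are removed from all of its ancestors before those are
#' tested, decorrelating nested terms. When no term passes `alpha_elim`,
#' `elim` output equals `classic`.
#'
#' @param dag a [GoDag-class].
#' @param annotations propagated annotation data.frame (see
#'   [propagateAnnotations()]); an unpropagated set is an error.
#' @param scores named numeric vector gene -> score, covering every annotated
#'   gene; the names define the scored universe.
#' @param node_size minimum number of annotated genes for a term to be
#'   tested; default 10.
#' @param algorithm `"elim"` or `"classic"`.
#' @param alpha_elim elimination threshold for `"elim"`; default 0.01.
#' @return data.frame, ordered by ascending p, with columns `term`, `name`,
#'   `namespace`, `n_annotated`, `ks_stat`, `p_value`, `algorithm`. Empty
#'   (with a warning) when no term is eligible.
#' @export
ksEnrichment <- function(dag, annotations, scores, node_size = 10,
                         algorithm = c("elim", "classic"),
                         alpha_elim = 0.01) {
  algorithm <- match.arg(algorithm)
  if (!isTRUE(attr(annotations, "propagated"))) {
    stop("annotations must be propagated first (see propagateAnnotations)")
  }
  if (is.null(names(scores))) stop("'scores' must be a named vector")
  univ <- names(scores)
  missing <- setdiff(unique(annotations$gene), univ)
  if (length(missing)) {
    stop(sprintf("score missing for annotated gene '%s'", missing[1L]))
  }
  term_genes <- split(annotations$gene, annotations$term)
  n_ann <- lengths(term_genes)
  eligible <- names(term_genes)[n_ann >= node_size]
  if (!length(eligible)) {
    warning("no term has enough annotated genes")
    return(data.frame(
      term = character(0), name = character(0), namespace = character(0),
      n_annotated = integer(0), ks_stat = numeric(0), p_value = numeric(0),
      algorithm = character(0)
    ))
  }
  ranks <- setNames(rank(-scores, ties.method = "average"), univ)

  ks_top <- function(genes_in) {
    genes_out <- setdiff(univ, genes_in)
    if (!length(genes_in) || !length(genes_out)) {
      return(list(stat = 0, p = 1))
    }
    # ranks shifted toward the top = CDF of in-group ranks above out-group
    kt <- suppressWarnings(
      ks.test(ranks[genes_in], ranks[genes_out],
              alternative = "greater", exact = FALSE)
    )
    list(stat = unname(kt$statistic), p = unname(kt$p.value))
  }

  if (algorithm == "classic") {
    res <- lapply(eligible, function(t) ks_top(term_genes[[t]]))
  } else {
    depth <- goDepths(dag)
    anc <- goAncestors(dag)
    # children before parents: deepest terms first
    eligible <- eligible[order(-depth[eligible])]
    removed <- new.env(parent = emptyenv())
    res <- lapply(eligible, function(t) {
      rem <- if (exists(t, envir = removed)) get(t, envir = removed) else character(0)
      genes_t <- setdiff(term_genes[[t]], rem)
      r <- ks_top(genes_t)
      if (r$p < alpha_elim && length(genes_t)) {
        for (a in intersect(anc[[t]], names(term_genes))) {
          prev <- if (exists(a, envir = removed)) get(a, envir = removed) else character(0)
          assign(a, union(prev, genes_t), envir = removed)
        }
      }
      r
    })
  }
  out <- data.frame(
    term = eligible,
    name = dag@terms$name[match(eligible, dag@terms$id)],
    namespace = dag@terms$namespace[match(eligible, dag@terms$id)],
    n_annotated = unname(n_ann[eligible]),
    ks_stat = vapply(res, `[[`, numeric(1L), "stat"),
    p_value = vapply(res, `[[`, numeric(1L), "p"),
    algorithm = algorithm
  )
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep significantly enriched terms
#'
#' @param rows data.frame from [ksEnrichment()].
#' @param alpha strict significance cutoff; default 0.01 (p < alpha).
#' @return the retained rows, ordered by ascending p.
#' @export
filterSignificant <- function(rows, alpha = 0.01) {
  out <- rows[rows$p_value < alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
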