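#' Parse a Gene Ontology OBO subset
#'
#' Reads `[Term]` stanzas (fields `id`, `name`, `namespace`, `is_a`,
#' `is_obsolete`) from an OBO file. Obsolete terms are skipped; relationship
#' lines other than `is_a` are ignored and their count reported via a
#' message. Cycles and is_a targets that are not declared terms are errors.
#'
#' @param path path to the OBO file.
#' @return a [GoDag-class].
#' @export
parseOboSubset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found")
  stanza_starts <- grep("^\\[", lines)
  ids <- character(0)
  nms <- character(0)
  nss <- character(0)
  parents <- list()
  n_other_rel <- 0L
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    block <- lines[(s + 1L):end]
    block <- sub("!.*$", "", block)
    block <- trimws(block)
    block <- block[nzchar(block)]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    if (any(tolower(field("is_obsolete")) == "true")) next
    id <- field("id")
    if (length(id) != 1L) stop("term stanza without a unique id")
    nm <- field("name")
    ns <- field("namespace")
    if (length(ns) != 1L) stop(sprintf("term %s lacks a namespace", id))
    isa <- vapply(field("is_a"), function(v) strsplit(v, "\\s+")[[1L]][1L],
                  character(1L), USE.NAMES = FALSE)
    n_other_rel <- n_other_rel +
      sum(startsWith(block, "relationship:"))
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    nss <- c(nss, ns)
    parents[[id]] <- isa
  }
  if (n_other_rel > 0L) {
    message(sprintf("ignored %d non-is_a relationship lines", n_other_rel))
  }
  new("GoDag",
      terms = data.frame(id = ids, name = nms, namespace = nss),
      parents = parents)
}

#' All ancestors of each term of a GO DAG
#'
#' @param dag a [GoDag-class].
#' @return named list: for each term id, the character vector of all its
#'   ancestors (transitive is_a closure, the term itself excluded).
#' @export
goAncestors <- function(dag) {
  order <- .topoOrder(dag@parents)
  anc <- list()
  for (id in order) {
    pp <- dag@parents[[id]]
    anc[[id]] <- unique(c(pp, unlist(anc[pp], use.names = FALSE)))
  }
  anc[names(dag@parents)]
}

## Topological order of the child->parent edge list with parents first.
.topoOrder <- function(parents) {
  n_unmet <- vapply(parents, length, integer(1L)) # unprocessed parents per term
  ready <- names(parents)[n_unmet == 0L]
  children <- list()
  for (child in names(parents)) {
    for (p in parents[[child]]) children[[p]] <- c(children[[p]], child)
  }
  out <- character(0)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      n_unmet[[ch]] <- n_unmet[[ch]] - 1L
      if (n_unmet[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) != length(parents)) stop("cycle detected in term graph")
  out
}

#' Depth of each term (longest path from a root)
#'
#' @param dag a [GoDag-class].
#' @return named integer vector; roots have depth 0.
#' @export
goDepths <- function(dag) {
  order <- .topoOrder(dag@parents)
  depth <- setNames(integer(length(order)), order)
  for (id in order) {
    pp <- dag@parents[[id]]
    depth[[id]] <- if (length(pp)) max(depth[pp]) + 1L else 0L
  }
  depth[names(dag@parents)]
}

#' Read gene-to-term annotations
#'
#' @param path two-column TSV with header `gene<TAB>term`.
#' @return data.frame with columns `gene`, `term`; attribute `propagated` is
#'   FALSE.
#' @export
readAnnotations <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (!all(c("gene", "term") %in% names(df))) {
    stop("annotation table must have columns gene, term")
  }
  ann <- unique(df[, c("gene", "term")])
  attr(ann, "propagated") <- FALSE
  ann
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. The operation is idempotent.
#'
#' @param dag a [GoDag-class].
#' @param direct data.frame with columns `gene`, `term`; every term must
#'   exist in `dag`.
#' @return data.frame with columns `gene`, `term`, attribute
#'   `propagated = TRUE`, unique rows.
#' @export
propagateAnnotations <- function(dag, direct) {
  unknown <- setdiff(unique(direct$term), dag@terms$id)
  if (length(unknown)) {
    stop(sprintf("annotation references unknown term '%s'", unknown[1L]))
  }
  anc <- goAncestors(dag)
  extra_terms <- anc[direct$term]
  n_extra <- lengths(extra_terms)
  out <- data.frame(
    gene = c(direct$gene, rep(direct$gene, n_extra)),
    term = c(direct$term, unlist(extra_terms, use.names = FALSE))
  )
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "propagated") <- TRUE
  out
}
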