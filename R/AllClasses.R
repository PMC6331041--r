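#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats median pchisq pnorm pt rnorm rpois runif rbinom binom.test
#'   complete.cases cor glm ks.test poisson quantile sd setNames
#' @importFrom utils read.delim write.table packageVersion head combn modifyList
NULL

#' Container for a per-species gene x tissue TPM table
#'
#' `TissueExpressionSet` holds one species' expression matrix (genes in rows,
#' tissues in columns, values in transcripts per million) together with the
#' species identifier. It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so the usual assay,
#' rowname and colname accessors apply; the single assay is named `"tpm"`.
#'
#' Validity requires all values to be finite and non-negative, gene
#' identifiers (rownames) to be unique and non-empty, and tissue names
#' (colnames) to be non-empty.
#'
#' @slot species single character, the species identifier.
#'
#' @seealso [TissueExpressionSet()] for construction from a matrix,
#'   [readTpmTable()] for construction from a TSV file.
#' @export
setClass("TissueExpressionSet",
  contains = "SummarizedExperiment",
  representation(species = "character")
)

.validTissueExpressionSet <- function(object) {
  msg <- NULL
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species)) {
    msg <- c(msg, "'species' must be a single non-empty string")
  }
  if (!"tpm" %in% SummarizedExperiment::assayNames(object)) {
    return(c(msg, "assay 'tpm' is required"))
  }
  m <- SummarizedExperiment::assay(object, "tpm")
  if (is.null(rownames(m)) || anyNA(rownames(m)) || !all(nzchar(rownames(m)))) {
    msg <- c(msg, "gene identifiers (rownames) must be non-empty")
  } else if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1L]
    msg <- c(msg, sprintf("duplicate gene identifier '%s'", dup))
  }
  if (is.null(colnames(m)) || !all(nzchar(colnames(m)))) {
    msg <- c(msg, "tissue names (colnames) must be non-empty")
  }
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    msg <- c(msg, "TPM values must be numeric and finite")
  } else if (any(m < 0)) {
    msg <- c(msg, "TPM values must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("TissueExpressionSet", .validTissueExpressionSet)

#' Gene Ontology DAG restricted to is_a edges
#'
#' A directed acyclic graph of GO terms. Terms carry a name and a namespace
#' (one of `biological_process`, `molecular_function`,
#' `cellular_component`); edges point from child to parent and never cross
#' namespaces. Validity enforces declared endpoints, acyclicity and
#' namespace purity along edges.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list; for each term id, the character vector of its
#'   direct is_a parents (possibly empty).
#'
#' @seealso [parseOboSubset()], [propagateAnnotations()], [ksEnrichment()]
#' @export
setClass("GoDag",
  representation(terms = "data.frame", parents = "list")
)

.validGoDag <- function(object) {
  tt <- object@terms
  msg <- NULL
  need <- c("id", "name", "namespace")
  if (!all(need %in% names(tt))) {
    return("'terms' must have columns id, name, namespace")
  }
  if (anyDuplicated(tt$id)) {
    msg <- c(msg, "duplicate term identifiers")
  }
  ok_ns <- c("biological_process", "molecular_function", "cellular_component")
  if (!all(tt$namespace %in% ok_ns)) {
    msg <- c(msg, "unknown namespace in 'terms'")
  }
  ids <- tt$id
  if (!setequal(names(object@parents), ids)) {
    msg <- c(msg, "'parents' must be named by exactly the declared term ids")
  }
  targets <- unlist(object@parents, use.names = FALSE)
  bad <- setdiff(targets, ids)
  if (length(bad)) {
    msg <- c(msg, sprintf("is_a target '%s' is not a declared term", bad[1L]))
  } else {
    ns <- setNames(tt$namespace, tt$id)
    for (child in names(object@parents)) {
      pp <- object@parents[[child]]
      if (length(pp) && any(ns[pp] != ns[[child]])) {
        msg <- c(msg, sprintf("edge from '%s' crosses namespaces", child))
        break
      }
    }
    cyc <- .findCycle(object@parents)
    if (!is.null(cyc)) {
      msg <- c(msg, paste0("cycle detected: ", paste(cyc, collapse = " -> ")))
    }
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("GoDag", .validGoDag)

## Returns one cycle (as a vector of term ids) or NULL if the edge list is
## acyclic. Iterative DFS with colour marks.
.findCycle <- function(parents) {
  colour <- setNames(rep(0L, length(parents)), names(parents)) # 0 new, 1 open, 2 done
  stack_path <- character(0)
  visit <- function(v) {
    colour[[v]] <<- 1L
    stack_path <<- c(stack_path, v)
    for (p in parents[[v]]) {
      if (colour[[p]] == 1L) {
        i <- match(p, stack_path)
        return(c(stack_path[i:length(stack_path)], p))
      }
      if (colour[[p]] == 0L) {
        res <- visit(p)
        if (!is.null(res)) return(res)
      }
    }
    colour[[v]] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
    NULL
  }
  for (v in names(parents)) {
    if (colour[[v]] == 0L) {
      res <- visit(v)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}
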