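#' @describeIn TissueExpressionSet-accessors species identifier
#' @export
setGeneric("species", function(object) standardGeneric("species"))

#' @describeIn TissueExpressionSet-accessors TPM matrix (genes x tissues)
#' @export
setGeneric("tpm", function(object) standardGeneric("tpm"))

#' @describeIn TissueExpressionSet-accessors tissue names, in canonical order
#' @export
setGeneric("tissues", function(object) standardGeneric("tissues"))

#' Accessors for TissueExpressionSet
#'
#' @param object a [TissueExpressionSet-class].
#' @return `species()` a single character; `tpm()` the numeric genes x
#'   tissues matrix; `tissues()` the character vector of tissue names.
#' @name TissueExpressionSet-accessors
NULL

#' @rdname TissueExpressionSet-accessors
#' @export
setMethod("species", "TissueExpressionSet", function(object) object@species)

#' @rdname TissueExpressionSet-accessors
#' @export
setMethod("tpm", "TissueExpressionSet", function(object) {
  SummarizedExperiment::assay(object, "tpm")
})

#' @rdname TissueExpressionSet-accessors
#' @export
setMethod("tissues", "TissueExpressionSet", function(object) colnames(object))

setMethod("show", "TissueExpressionSet", function(object) {
  cat(sprintf(
    "TissueExpressionSet: %s\n  %d genes x %d tissues\n  tissues: %s\n",
    species(object), nrow(object), ncol(object),
    paste(tissues(object), collapse = ", ")
  ))
})

setMethod("show", "GoDag", function(object) {
  ns <- table(object@terms$namespace)
  cat(sprintf(
    "GoDag: %d terms, %d is_a edges\n  %s\n",
    nrow(object@terms),
    length(unlist(object@parents, use.names = FALSE)),
    paste(sprintf("%s: %d", names(ns), as.integer(ns)), collapse = ", ")
  ))
})
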