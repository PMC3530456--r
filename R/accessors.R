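#' Accessors for BetaSet and ExprSet
#'
#' Small convenience accessors used throughout the pipeline instead of raw
#' slot/assay access.
#'
#' @param x a [BetaSet-class] or [ExprSet-class].
#' @return \code{betaValues}/\code{detectionP}/\code{exprValues} return the
#'   corresponding assay matrix; \code{sampleGroups} a named character
#'   vector of group labels; \code{probeAnnotation} the probe annotation as
#'   a data.frame with a \code{probe_id} column.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' @rdname accessors
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname accessors
#' @export
setMethod("detectionP", "BetaSet", function(x) assay(x, "detectionP"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExprSet", function(x) assay(x, "log2"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

.groupsOf <- function(x) structure(as.character(x$group),
                                   names = colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "BetaSet", .groupsOf)

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExprSet", .groupsOf)

#' @rdname accessors
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))

#' @rdname accessors
#' @export
setMethod("probeAnnotation", "BetaSet", function(x) {
    rd <- as.data.frame(rowData(x))
    data.frame(probe_id = rownames(x),
               gene_symbol = rd$gene_symbol,
               chromosome = rd$chromosome,
               is_autosomal = rd$is_autosomal,
               stringsAsFactors = FALSE)
})
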