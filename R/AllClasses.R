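#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.GROUP_LEVELS <- c("control", "case")

.validGroups <- function(group) {
    if (is.null(group))
        return("colData must carry a 'group' column")
    if (!all(group %in% .GROUP_LEVELS))
        return(sprintf("group labels must be in {%s}; found: %s",
                       paste(.GROUP_LEVELS, collapse = ", "),
                       paste(unique(setdiff(group, .GROUP_LEVELS)),
                             collapse = ", ")))
    NULL
}

#' BetaSet: CpG beta values with paired detection p-values
#'
#' A \linkS4class{SummarizedExperiment} holding a probe-by-sample matrix of
#' Infinium-style methylation fractions (\code{beta} assay, values in
#' \eqn{[0,1]} or \code{NA} once masked) together with the matching
#' per-entry detection p-values (\code{detectionP} assay). Row metadata
#' carries the probe annotation (\code{gene_symbol}, \code{chromosome},
#' \code{is_autosomal}); column metadata carries the two-group design
#' (\code{group}, one of \code{"case"}/\code{"control"}).
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [BetaSet()] for the constructor, [maskLowDetection()],
#'   [testProbeDM()].
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("beta", "detectionP") %in% an))
        return("assays 'beta' and 'detectionP' are both required")
    b <- assay(object, "beta")
    d <- assay(object, "detectionP")
    if (!identical(dim(b), dim(d)))
        msg <- c(msg, "beta and detectionP must have identical dimensions")
    bf <- b[is.finite(b)]
    if (length(bf) && (min(bf) < 0 || max(bf) > 1))
        msg <- c(msg, "finite beta values must lie in [0, 1]")
    df <- d[is.finite(d)]
    if (length(df) && (min(df) < 0 || max(df) > 1))
        msg <- c(msg, "finite detection p-values must lie in [0, 1]")
    need <- c("gene_symbol", "chromosome", "is_autosomal")
    if (!all(need %in% colnames(rowData(object))))
        msg <- c(msg, sprintf("rowData must contain columns: %s",
                              paste(need, collapse = ", ")))
    gm <- .validGroups(object$group)
    if (!is.null(gm)) msg <- c(msg, gm)
    if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric probe-by-sample matrix of beta values in \eqn{[0,1]}
#'   (or \code{NA} for masked entries); rownames are probe ids, colnames
#'   sample ids.
#' @param detectionP numeric matrix of per-entry detection p-values, same
#'   dimensions and dimnames as \code{beta}.
#' @param annotation data.frame with columns \code{probe_id},
#'   \code{gene_symbol}, \code{chromosome} (and optionally
#'   \code{is_autosomal}; derived from \code{chromosome} when absent),
#'   covering every row of \code{beta}.
#' @param group character vector (one entry per sample) of
#'   \code{"case"}/\code{"control"} labels, or a named vector matched
#'   against the sample ids.
#' @return A \linkS4class{BetaSet}.
#' @examples
#' cfg <- simConfig(n_probes = 60, n_genes = 30, n_case = 4, n_ctrl = 4)
#' ann <- simulateAnnotation(cfg)
#' sim <- simulateMethylation(cfg, ann)
#' sim$betaset
#' @export
BetaSet <- function(beta, detectionP, annotation, group) {
    beta <- as.matrix(beta)
    detectionP <- as.matrix(detectionP)
    if (!identical(dim(beta), dim(detectionP)))
        stop("'beta' and 'detectionP' must have identical dimensions")
    if (is.null(rownames(beta)))
        stop("'beta' must have probe ids as rownames")
    if (is.null(colnames(beta)))
        stop("'beta' must have sample ids as colnames")
    annotation <- as.data.frame(annotation)
    if (!all(c("probe_id", "gene_symbol", "chromosome") %in%
             colnames(annotation)))
        stop("annotation needs columns probe_id, gene_symbol, chromosome")
    if (anyDuplicated(annotation$probe_id))
        stop("duplicated probe_id in annotation")
    missing_pb <- setdiff(rownames(beta), annotation$probe_id)
    if (length(missing_pb))
        stop("probes absent from annotation: ",
             paste(utils::head(missing_pb, 5), collapse = ", "))
    annotation <- annotation[match(rownames(beta), annotation$probe_id), ]
    if (is.null(annotation$is_autosomal))
        annotation$is_autosomal <- isAutosome(annotation$chromosome)
    if (!is.null(names(group)))
        group <- group[colnames(beta)]
    if (length(group) != ncol(beta))
        stop("'group' must supply one label per sample")
    se <- SummarizedExperiment(
        assays = list(beta = beta, detectionP = detectionP),
        rowData = DataFrame(annotation[, c("gene_symbol", "chromosome",
                                           "is_autosomal")],
                            row.names = annotation$probe_id),
        colData = DataFrame(group = as.character(group),
                            row.names = colnames(beta)))
    new("BetaSet", se)
}

#' ExprSet: log2 expression intensities for a two-group design
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{log2} assay of
#' gene-by-sample expression intensities (already summarised per gene and
#' log2-scaled upstream) and a \code{group} column
#' (\code{"case"}/\code{"control"}) in its column metadata.
#'
#' @seealso [ExprSet()], [fitIntensityPrior()], [moderatedT()].
#' @export
setClass("ExprSet", contains = "SummarizedExperiment")

setValidity("ExprSet", function(object) {
    msg <- character()
    if (!"log2" %in% assayNames(object))
        return("assay 'log2' is required")
    x <- assay(object, "log2")
    if (any(!is.finite(x)))
        msg <- c(msg, "log2 intensities must be finite (no missing values)")
    gm <- .validGroups(object$group)
    if (!is.null(gm)) msg <- c(msg, gm)
    if (length(msg)) msg else TRUE
})

#' Construct an ExprSet
#'
#' @param log2_intensity numeric gene-by-sample matrix of log2 intensities;
#'   rownames are gene symbols, colnames sample ids.
#' @param group character vector of \code{"case"}/\code{"control"} labels,
#'   one per sample (named vectors are matched by sample id).
#' @return An \linkS4class{ExprSet}.
#' @export
ExprSet <- function(log2_intensity, group) {
    log2_intensity <- as.matrix(log2_intensity)
    if (is.null(rownames(log2_intensity)))
        stop("'log2_intensity' must have gene symbols as rownames")
    if (is.null(colnames(log2_intensity)))
        stop("'log2_intensity' must have sample ids as colnames")
    if (!is.null(names(group)))
        group <- group[colnames(log2_intensity)]
    if (length(group) != ncol(log2_intensity))
        stop("'group' must supply one label per sample")
    se <- SummarizedExperiment(
        assays = list(log2 = log2_intensity),
        colData = DataFrame(group = as.character(group),
                            row.names = colnames(log2_intensity)))
    new("ExprSet", se)
}

#' Planted truth emitted by the simulator
#'
#' Records, per probe and per gene, the effects planted by
#' [simulateMethylation()] so downstream calls can be scored against a
#' known answer: the realised (possibly clipped) signed delta-beta per
#' probe, the gene-level methylation direction, the gene-level expression
#' direction, and the subset of genes planted as direction-concordant.
#'
#' @slot probeEffects data.frame \code{(probe_id, delta_beta, truncated)};
#'   \code{delta_beta} is 0 for null probes.
#' @slot geneDM data.frame \code{(gene_symbol, direction)} with direction
#'   in \code{hyper}/\code{hypo}/\code{none}.
#' @slot geneDE data.frame \code{(gene_symbol, direction)} with direction
#'   in \code{up}/\code{down}/\code{none}.
#' @slot concordant data.frame \code{(gene_symbol, class)} with class in
#'   \code{hypo_up}/\code{hyper_down}.
#' @export
setClass("MethTruth",
         representation(probeEffects = "data.frame",
                        geneDM = "data.frame",
                        geneDE = "data.frame",
                        concordant = "data.frame"))

setValidity("MethTruth", function(object) {
    msg <- character()
    cc <- object@concordant
    if (nrow(cc)) {
        dm <- structure(object@geneDM$direction,
                        names = object@geneDM$gene_symbol)
        de <- structure(object@geneDE$direction,
                        names = object@geneDE$gene_symbol)
        want_dm <- ifelse(cc$class == "hypo_up", "hypo", "hyper")
        want_de <- ifelse(cc$class == "hypo_up", "up", "down")
        if (!all(dm[cc$gene_symbol] == want_dm, na.rm = FALSE) ||
            !all(de[cc$gene_symbol] == want_de, na.rm = FALSE))
            msg <- c(msg,
                "concordant genes must have matching dm/de directions ",
                "(hypo with up, hyper with down)")
        if (!all(cc$class %in% c("hypo_up", "hyper_down")))
            msg <- c(msg, "concordant class must be hypo_up or hyper_down")
    }
    if (length(msg)) paste(msg, collapse = "") else TRUE
})

#' @describeIn MethTruth compact display.
#' @param object a \code{MethTruth}.
#' @export
setMethod("show", "MethTruth", function(object) {
    cat("MethTruth with", nrow(object@probeEffects), "probes /",
        nrow(object@geneDM), "genes\n")
    cat("  planted DM probes:",
        sum(object@probeEffects$delta_beta != 0), "\n")
    cat("  DM genes:", sum(object@geneDM$direction != "none"),
        " DE genes:", sum(object@geneDE$direction != "none"), "\n")
    cat("  concordant genes:", nrow(object@concordant),
        sprintf("(%d hypo_up, %d hyper_down)\n",
                sum(object@concordant$class == "hypo_up"),
                sum(object@concordant$class == "hyper_down")))
})

#' @describeIn BetaSet display with masking summary.
#' @param object a \code{BetaSet}.
#' @export
setMethod("show", "BetaSet", function(object) {
    callNextMethod()
    b <- assay(object, "beta")
    cat(sprintf("masked entries: %d (%.1f%%); autosomal probes: %d/%d\n",
                sum(is.na(b)), 100 * mean(is.na(b)),
                sum(rowData(object)$is_autosomal), nrow(object)))
})
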