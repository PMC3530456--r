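#' Genes called in both the methylation and expression layers
#'
#' Exact, case-sensitive symbol intersection of DMG and DEG calls. Genes
#' with ambiguous methylation direction should be excluded upstream (they
#' are dropped by [buildEpigeneRecords()] in any case).
#'
#' @param dmgs gene-call data.frame from [callDMGs()].
#' @param degs DE data.frame from [callDEGs()].
#' @return character vector of common gene symbols.
#' @export
overlapGenes <- function(dmgs, degs) {
    intersect(dmgs$gene_symbol, degs$gene_symbol)
}

#' Classify methylation/expression direction pairs
#'
#' The 2x2 mapping: hypo+up -> \code{hypo_up}, hyper+down ->
#' \code{hyper_down} (the two concordant classes: methylation loss with
#' over-expression, methylation gain with silencing), hyper+up ->
#' \code{hyper_up}, hypo+down -> \code{hypo_down} (same-direction,
#' non-concordant).
#'
#' @param dm_direction \code{"hyper"} or \code{"hypo"} (vectorised);
#'   \code{"ambiguous"} is an error here - filter such genes out first.
#' @param de_direction \code{"up"} or \code{"down"} (vectorised).
#' @return character vector of classes.
#' @examples
#' classifyConcordance("hypo", "up")     # "hypo_up"
#' classifyConcordance("hyper", "down")  # "hyper_down"
#' @export
classifyConcordance <- function(dm_direction, de_direction) {
    if (!all(dm_direction %in% c("hyper", "hypo")))
        stop("dm_direction must be 'hyper' or 'hypo' (no ambiguous calls)")
    if (!all(de_direction %in% c("up", "down")))
        stop("de_direction must be 'up' or 'down'")
    paste(dm_direction, de_direction, sep = "_")
}

#' Is a concordance class concordant?
#'
#' @param concord_class classes from [classifyConcordance()].
#' @return logical; TRUE for \code{hypo_up} and \code{hyper_down}.
#' @export
isConcordant <- function(concord_class) {
    concord_class %in% c("hypo_up", "hyper_down")
}

#' Join DMG and DEG calls into per-gene epigene records
#'
#' For every gene called in both layers, carries the methylation direction
#' and best-probe statistics (DiffScore, percent methylation change) next
#' to the expression direction and signed fold change, plus the
#' concordance class. Ambiguous-direction DMGs are rejected with a
#' message; symbols present in only one layer are reported via a warning
#' when \code{warn_unmatched}.
#'
#' @param dmgs gene-call data.frame from [callDMGs()].
#' @param degs DE data.frame from [moderatedT()]/[callDEGs()].
#' @param warn_unmatched warn about one-layer-only symbols (default
#'   FALSE).
#' @return data.frame, one row per common gene: \code{gene_symbol},
#'   \code{dm_direction}, \code{diff_score}, \code{delta_5mc_pct},
#'   \code{signed_fc}, \code{de_direction}, \code{concord_class},
#'   \code{concordant}.
#' @export
buildEpigeneRecords <- function(dmgs, degs, warn_unmatched = FALSE) {
    if (warn_unmatched) {
        only <- c(setdiff(dmgs$gene_symbol, degs$gene_symbol),
                  setdiff(degs$gene_symbol, dmgs$gene_symbol))
        if (length(only))
            warning(length(only),
                    " symbol(s) present in one omics layer only")
    }
    amb <- dmgs$direction == "ambiguous"
    if (any(amb))
        message(sum(amb),
                " gene(s) with ambiguous methylation direction excluded")
    dmgs <- dmgs[!amb, , drop = FALSE]
    common <- overlapGenes(dmgs, degs)
    dm <- dmgs[match(common, dmgs$gene_symbol), , drop = FALSE]
    de <- degs[match(common, degs$gene_symbol), , drop = FALSE]
    if (!length(common))
        return(data.frame(gene_symbol = character(),
                          dm_direction = character(),
                          diff_score = numeric(),
                          delta_5mc_pct = numeric(),
                          signed_fc = numeric(),
                          de_direction = character(),
                          concord_class = character(),
                          concordant = logical(),
                          stringsAsFactors = FALSE))
    cls <- classifyConcordance(dm$direction, de$direction)
    data.frame(gene_symbol = common,
               dm_direction = dm$direction,
               diff_score = dm$best_diff_score,
               delta_5mc_pct = dm$delta_5mc_pct,
               signed_fc = de$signed_fc,
               de_direction = de$direction,
               concord_class = cls,
               concordant = isConcordant(cls),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary counts of a methylome-transcriptome integration
#'
#' @param dmgs gene-call data.frame (ambiguous calls are not counted as
#'   usable DMGs for the overlap).
#' @param degs DE data.frame.
#' @param records epigene records from [buildEpigeneRecords()].
#' @return one-row data.frame: \code{n_dmg}, \code{n_deg},
#'   \code{n_common}, \code{n_concordant}, \code{n_hypo_up},
#'   \code{n_hyper_down}, \code{pct_hyper_of_common}.
#' @export
summarizeIntegration <- function(dmgs, degs, records) {
    n_hu <- sum(records$concord_class == "hypo_up")
    n_hd <- sum(records$concord_class == "hyper_down")
    data.frame(
        n_dmg = nrow(dmgs),
        n_deg = nrow(degs),
        n_common = nrow(records),
        n_concordant = n_hu + n_hd,
        n_hypo_up = n_hu,
        n_hyper_down = n_hd,
        pct_hyper_of_common = if (nrow(records))
            100 * mean(records$dm_direction == "hyper") else 0)
}

#' Write the concordant epigene tables
#'
#' Splits concordant records into the hypo-methylated/up-regulated and
#' hyper-methylated/down-regulated sets and writes each as TSV sorted by
#' descending |signed fold change| (stable: equal folds keep input
#' order), the usual published-table ordering. Fold and percent columns
#' are rounded to one decimal, half away from zero.
#'
#' @param records epigene records from [buildEpigeneRecords()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the two written data.frames
#'   (\code{hypo_up}, \code{hyper_down}).
#' @export
writeEpigeneTable <- function(records, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- lapply(c(hypo_up = "hypo_up", hyper_down = "hyper_down"),
                  function(cl) {
        tb <- records[records$concord_class == cl, , drop = FALSE]
        tb <- tb[order(-abs(tb$signed_fc)), , drop = FALSE]
        tb <- data.frame(gene_symbol = tb$gene_symbol,
                         delta_5mc_pct = roundHalfAway(tb$delta_5mc_pct),
                         diff_score = tb$diff_score,
                         fc = roundHalfAway(tb$signed_fc),
                         stringsAsFactors = FALSE)
        writeTsv(tb, file.path(dir, paste0("epigenes_", cl, ".tsv")))
        tb
    })
    invisible(out)
}

#' Reference table of published concordant epigenes
#'
#' A transcription of the 112 concordant epigenes (51 hypo-methylated/
#' up-regulated, 61 hyper-methylated/down-regulated) reported in a
#' published integrative methylome-transcriptome study of sporadic ALS
#' spinal cord, with the printed percent methylation change, DiffScore
#' and expression fold change per gene. Used as a fixture for the
#' concordance classifier.
#'
#' @return data.frame: \code{gene_id}, \code{gene_symbol},
#'   \code{delta_5mc_pct}, \code{diff_score}, \code{fc}, \code{set}
#'   (\code{hypo_up}/\code{hyper_down} per the source table).
#' @export
epigeneReference <- function() {
    path <- system.file("extdata", "epigenes_sals_spinal_cord.tsv",
                        package = "epiConcord", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference table of published RT-PCR validation summaries
#'
#' Control and case group means (+/- SEM) of 2^-ddCt relative expression
#' for 14 targets from the same study, with the printed fold change and
#' the microarray fold change. Fixture for the signed fold-change
#' convention.
#'
#' @return data.frame: \code{gene_symbol}, \code{mean_ctrl},
#'   \code{sem_ctrl}, \code{mean_case}, \code{sem_case}, \code{p_printed},
#'   \code{fold_printed}, \code{array_fc}, \code{confirmed}.
#' @export
qpcrReference <- function() {
    path <- system.file("extdata", "qpcr_validation_sals.tsv",
                        package = "epiConcord", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
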