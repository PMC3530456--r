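#' TSV reading/writing helpers
#'
#' All tabular artifacts use one dialect: UTF-8, tab-delimited, '.'
#' decimal, 'NA' for missing, header row, no quoting or row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{writeTsv} invisibly returns \code{path}; \code{readTsv}
#'   returns a data.frame.
#' @export
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA",
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, row.names = 1)
    as.matrix(df)
}

.writeMatrixTsv <- function(m, path, id_col) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
    writeTsv(df, path)
}

#' Read a sample sheet
#'
#' A TSV with header columns \code{sample_id} and \code{group}; groups
#' must be \code{case} or \code{control}, sample ids unique.
#'
#' @param path path to the sheet.
#' @return named character vector (sample id -> group).
#' @export
readSampleSheet <- function(path) {
    df <- readTsv(path)
    if (!nrow(df)) stop("empty sample sheet: ", path)
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("sample sheet needs columns sample_id, group")
    bad <- !(df$group %in% c("case", "control"))
    if (any(bad))
        stop("unknown group label in sample sheet row(s) ",
             paste(which(bad), collapse = ", "), ": ",
             paste(unique(df$group[bad]), collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    structure(df$group, names = df$sample_id)
}

#' Read a BetaSet from TSV files
#'
#' @param beta_path probe x sample beta-value TSV (first column probe
#'   ids).
#' @param detection_path matching detection-p TSV.
#' @param annotation_path probe annotation TSV (\code{probe_id},
#'   \code{gene_symbol}, \code{chromosome}).
#' @param samples_path sample sheet TSV (see [readSampleSheet()]).
#' @return a [BetaSet-class].
#' @export
readBetaSet <- function(beta_path, detection_path, annotation_path,
                        samples_path) {
    BetaSet(.readMatrixTsv(beta_path), .readMatrixTsv(detection_path),
            readTsv(annotation_path), readSampleSheet(samples_path))
}

#' Read an ExprSet from TSV files
#'
#' @param expr_path gene x sample log2 expression TSV (first column gene
#'   symbols).
#' @param samples_path sample sheet TSV.
#' @return an [ExprSet-class].
#' @export
readExprSet <- function(expr_path, samples_path) {
    ExprSet(.readMatrixTsv(expr_path), readSampleSheet(samples_path))
}

#' Write a simulated dataset to a directory
#'
#' Writes the beta matrix, detection-p matrix, probe annotation, log2
#' expression matrix, sample sheet and planted truth as TSVs readable by
#' the paired readers.
#'
#' @param betaset a [BetaSet-class].
#' @param exprset an [ExprSet-class].
#' @param truth a [MethTruth-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(betaset, exprset, truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(beta = file.path(dir, "beta.tsv"),
               detection = file.path(dir, "detection_p.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               expression = file.path(dir, "expression.tsv"),
               samples = file.path(dir, "samples.tsv"),
               truth_probes = file.path(dir, "truth_probes.tsv"),
               truth_genes = file.path(dir, "truth_genes.tsv"))
    .writeMatrixTsv(betaValues(betaset), paths["beta"], "probe_id")
    .writeMatrixTsv(detectionP(betaset), paths["detection"], "probe_id")
    writeTsv(probeAnnotation(betaset), paths["annotation"])
    .writeMatrixTsv(exprValues(exprset), paths["expression"],
                    "gene_symbol")
    grp <- sampleGroups(betaset)
    writeTsv(data.frame(sample_id = names(grp), group = unname(grp)),
             paths["samples"])
    writeTsv(truth@probeEffects, paths["truth_probes"])
    gene_truth <- merge(truth@geneDM, truth@geneDE, by = "gene_symbol",
                        suffixes = c("_dm", "_de"))
    gene_truth$concordant_class <-
        truth@concordant$class[match(gene_truth$gene_symbol,
                                     truth@concordant$gene_symbol)]
    writeTsv(gene_truth, paths["truth_genes"])
    invisible(paths)
}
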