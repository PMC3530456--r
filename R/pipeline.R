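#' Pipeline configuration
#'
#' Validates the thresholds, flags and paths steering [runPipeline()].
#' Unknown keys are rejected so config typos fail loudly.
#'
#' @param beta,detection,annotation,samples,expression input TSV paths
#'   (see the readers in this package).
#' @param gmt optional GMT path; enrichment of the concordant epigenes is
#'   run when supplied.
#' @param outdir output directory.
#' @param detection_p detection p-value masking threshold (default 0.05).
#' @param diffscore DiffScore gate (default 13).
#' @param de_fdr DE FDR cutoff (default 0.10).
#' @param enrich_alpha enrichment q-value cutoff (default 0.05).
#' @param min_per_group minimum usable samples per group per probe
#'   (default 3).
#' @param mvalue_test,welch,ease_variant,tukey_fences analysis flags
#'   (defaults all FALSE).
#' @param seed integer seed recorded in the manifest.
#' @param ... rejected; catches unknown keys.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(beta, detection, annotation, samples,
                           expression, gmt = NULL, outdir,
                           detection_p = 0.05, diffscore = 13,
                           de_fdr = 0.10, enrich_alpha = 0.05,
                           min_per_group = 3, mvalue_test = FALSE,
                           welch = FALSE, ease_variant = FALSE,
                           tukey_fences = FALSE, seed = 1, ...) {
    extra <- list(...)
    if (length(extra))
        stop("unknown configuration key(s): ",
             paste(names(extra), collapse = ", "))
    if (detection_p <= 0 || detection_p >= 1)
        stop("'detection_p' must lie in (0, 1)")
    if (diffscore <= 0) stop("'diffscore' must be > 0")
    if (de_fdr <= 0 || de_fdr >= 1) stop("'de_fdr' must lie in (0, 1)")
    if (enrich_alpha <= 0 || enrich_alpha >= 1)
        stop("'enrich_alpha' must lie in (0, 1)")
    structure(list(beta = beta, detection = detection,
                   annotation = annotation, samples = samples,
                   expression = expression, gmt = gmt, outdir = outdir,
                   detection_p = detection_p, diffscore = diffscore,
                   de_fdr = de_fdr, enrich_alpha = enrich_alpha,
                   min_per_group = min_per_group,
                   mvalue_test = mvalue_test, welch = welch,
                   ease_variant = ease_variant,
                   tukey_fences = tukey_fences,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return a validated \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full methylome-transcriptome integration pipeline
#'
#' Executes, in order: detection-p masking and per-probe differential
#' methylation, gene-level DM calling; intensity-moderated differential
#' expression at the configured FDR; concordance integration; optional
#' gene-set enrichment of the concordant genes against the
#' assay-annotation universe. Every intermediate is written as TSV under
#' \code{outdir}, together with a \code{manifest.txt} recording the
#' configuration, seed, package version and per-stage row counts, so
#' filtering attrition is auditable and reruns are comparable.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return invisibly, a list with \code{summary} (the integration
#'   summary), \code{records}, \code{dmg}, \code{deg}, \code{enrichment}
#'   (NULL without a GMT) and \code{manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    for (f in c("beta", "detection", "annotation", "samples",
                "expression"))
        if (!file.exists(config[[f]]))
            stop("input file for '", f, "' not found: ", config[[f]])
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- c(sprintf("package_version: %s",
                          as.character(utils::packageVersion("epiConcord"))),
                  sprintf("seed: %d", config$seed),
                  vapply(c("detection_p", "diffscore", "de_fdr",
                           "enrich_alpha", "min_per_group",
                           "mvalue_test", "welch", "ease_variant"),
                         function(k) sprintf("%s: %s", k,
                                             format(config[[k]])),
                         character(1)))
    note <- function(fmt, ...) {
        manifest <<- c(manifest, sprintf(fmt, ...))
        message(sprintf(fmt, ...))
    }

    # -- methylome ---------------------------------------------------
    bs <- readBetaSet(config$beta, config$detection, config$annotation,
                      config$samples)
    note("stage dm: input probes: %d", nrow(bs))
    bs <- maskLowDetection(bs, config$detection_p, config$min_per_group)
    note("stage dm: probes after masking: %d", nrow(bs))
    probe_res <- testProbeDM(bs, m_value = config$mvalue_test)
    dmg <- callDMGs(probe_res, probeAnnotation(bs), config$diffscore)
    note("stage dm: probes tested: %d; DMGs called: %d (%d ambiguous)",
         nrow(probe_res), nrow(dmg), sum(dmg$direction == "ambiguous"))
    writeTsv(probe_res, file.path(config$outdir, "probe_dm.tsv"))
    writeTsv(dmg, file.path(config$outdir, "gene_dm.tsv"))

    # -- transcriptome -----------------------------------------------
    es <- readExprSet(config$expression, config$samples)
    prior <- fitIntensityPrior(es)
    de_all <- moderatedT(es, prior)
    deg <- callDEGs(de_all, config$de_fdr)
    note("stage de: genes tested: %d; DEGs at FDR %.2f: %d (prior df %s)",
         nrow(de_all), config$de_fdr, nrow(deg),
         format(prior$prior_df, digits = 3))
    writeTsv(de_all, file.path(config$outdir, "de_all.tsv"))
    writeTsv(deg, file.path(config$outdir, "deg.tsv"))

    # -- integration -------------------------------------------------
    records <- buildEpigeneRecords(dmg, deg)
    summ <- summarizeIntegration(dmg[dmg$direction != "ambiguous", ,
                                     drop = FALSE], deg, records)
    note(paste0("stage integrate: common: %d; concordant: %d ",
                "(%d hypo_up, %d hyper_down)"),
         summ$n_common, summ$n_concordant, summ$n_hypo_up,
         summ$n_hyper_down)
    writeTsv(records, file.path(config$outdir, "epigene_records.tsv"))
    writeTsv(summ, file.path(config$outdir, "integration_summary.tsv"))
    writeEpigeneTable(records, config$outdir)

    # -- enrichment (optional) ---------------------------------------
    enrichment <- NULL
    if (!is.null(config$gmt)) {
        collection <- readGMT(config$gmt)
        universe <- unique(probeAnnotation(bs)$gene_symbol)
        query <- intersect(records$gene_symbol[records$concordant],
                           universe)
        enrichment <- enrichCollection(query, collection, universe,
                                       alpha = config$enrich_alpha,
                                       ease = config$ease_variant)
        note("stage enrich: terms tested: %d; significant: %d",
             nrow(enrichment), sum(enrichment$significant))
        writeTsv(enrichment, file.path(config$outdir, "enrichment.tsv"))
    }

    writeLines(manifest, file.path(config$outdir, "manifest.txt"))
    invisible(list(summary = summ, records = records, dmg = dmg,
                   deg = deg, enrichment = enrichment,
                   manifest = manifest))
}
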