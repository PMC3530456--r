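#' Configuration for the synthetic two-group data generator
#'
#' Holds every knob of the simulator. Defaults emulate the design of a
#' two-group spinal-cord array study on the 27K methylation platform:
#' 12 cases vs 11 controls, about 1.9 CpG probes per gene (27,578 sites /
#' 14,495 genes on that platform), roughly 15\% of autosomal probes
#' differentially methylated, 10\% of genes differentially expressed and
#' 10\% planted as direction-concordant epigenes.
#'
#' @slot n_probes,n_genes,n_case,n_ctrl counts (probes >= genes).
#' @slot probes_per_gene_mean mean probes per gene (> 0).
#' @slot frac_dm_probes fraction of autosomal probes carrying a planted
#'   delta-beta.
#' @slot delta_beta planted effect size on the beta scale (additive; the
#'   percent-methylation-change statistic downstream is defined on raw
#'   beta, so effects are planted there, not on logits).
#' @slot beta_precision Beta-distribution concentration of per-sample beta
#'   draws around the probe mean.
#' @slot detection_fail_rate fraction of entries whose detection p-value
#'   exceeds 0.05 (independent across entries).
#' @slot frac_de_genes fraction of genes with a planted log2 fold change.
#' @slot log2fc_effect magnitude of planted log2 fold changes.
#' @slot expr_base_mean centre of baseline log2 intensities.
#' @slot expr_sd_slope slope of log residual-SD on mean intensity
#'   (negative = variance shrinking with intensity, the structure the
#'   intensity-based variance prior is designed to learn).
#' @slot frac_concordant fraction of genes planted as concordant
#'   (hypo-methylated+up-regulated or hyper-methylated+down-regulated);
#'   must not exceed \code{min(frac_dm_probes, frac_de_genes)}.
#' @slot frac_nonautosomal fraction of genes placed on sex chromosomes
#'   (their probes are excluded from DM calling downstream).
#' @slot mix_weights weights of the low (~0.1) / high (~0.85) /
#'   intermediate (~0.5) baseline beta modes.
#' @slot seed master seed; each modality derives its own stream from it so
#'   modalities can be regenerated independently.
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimulationConfig",
    representation(n_probes = "numeric", n_genes = "numeric",
        probes_per_gene_mean = "numeric", n_case = "numeric",
        n_ctrl = "numeric", frac_dm_probes = "numeric",
        delta_beta = "numeric", beta_precision = "numeric",
        detection_fail_rate = "numeric", frac_de_genes = "numeric",
        log2fc_effect = "numeric", expr_base_mean = "numeric",
        expr_sd_slope = "numeric", frac_concordant = "numeric",
        frac_nonautosomal = "numeric", mix_weights = "numeric",
        seed = "numeric"),
    prototype(n_probes = 2000, n_genes = 1000,
        probes_per_gene_mean = 1.9, n_case = 12, n_ctrl = 11,
        frac_dm_probes = 0.15, delta_beta = 0.15, beta_precision = 50,
        detection_fail_rate = 0.01, frac_de_genes = 0.10,
        log2fc_effect = 1, expr_base_mean = 8, expr_sd_slope = -0.1,
        frac_concordant = 0.10, frac_nonautosomal = 0.05,
        mix_weights = c(0.55, 0.35, 0.10), seed = 1))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chk <- function(expr, m) if (!isTRUE(expr)) msg <<- c(msg, m)
    chk(object@n_probes >= 1 && object@n_genes >= 1 &&
        object@n_case >= 1 && object@n_ctrl >= 1,
        "counts must be >= 1")
    chk(object@n_probes >= object@n_genes,
        "n_probes must be >= n_genes (every gene needs a probe)")
    chk(object@probes_per_gene_mean > 0, "probes_per_gene_mean must be > 0")
    chk(object@beta_precision > 0, "beta_precision must be > 0")
    for (f in c("frac_dm_probes", "detection_fail_rate", "frac_de_genes",
                "frac_concordant", "frac_nonautosomal"))
        chk(slot(object, f) >= 0 && slot(object, f) <= 1,
            paste0(f, " must lie in [0, 1]"))
    chk(object@delta_beta > 0 && object@delta_beta < 1,
        "delta_beta must lie in (0, 1)")
    chk(object@frac_concordant <=
            min(object@frac_dm_probes, object@frac_de_genes) + 1e-12,
        "frac_concordant must not exceed min(frac_dm_probes, frac_de_genes)")
    chk(length(object@mix_weights) == 3 && all(object@mix_weights >= 0) &&
        sum(object@mix_weights) > 0,
        "mix_weights must be 3 non-negative weights")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param ... named values overriding the defaults documented in
#'   \linkS4class{SimulationConfig}; unknown names are rejected.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' simConfig(n_probes = 500, n_genes = 250, seed = 7)
#' @export
simConfig <- function(...) {
    args <- list(...)
    known <- slotNames("SimulationConfig")
    bad <- setdiff(names(args), known)
    if (length(bad))
        stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    do.call(new, c(list("SimulationConfig"), args))
}

#' @describeIn simConfig compact display of a configuration.
#' @param object a \code{SimulationConfig}.
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d probes / %d genes, %d case vs %d control\n",
        object@n_probes, object@n_genes, object@n_case, object@n_ctrl))
    cat(sprintf(
        "  DM: %.0f%% probes at delta-beta %.2f | DE: %.0f%% genes at |log2FC| %.2f | concordant: %.0f%%\n",
        100 * object@frac_dm_probes, object@delta_beta,
        100 * object@frac_de_genes, object@log2fc_effect,
        100 * object@frac_concordant))
    cat("  seed:", object@seed, "\n")
})

.seedFor <- function(config, offset) {
    as.integer((config@seed + offset) %% (.Machine$integer.max - 7L))
}

.sampleIds <- function(config) {
    c(sprintf("case_%02d", seq_len(config@n_case)),
      sprintf("ctrl_%02d", seq_len(config@n_ctrl)))
}

.sampleGroupVec <- function(config) {
    structure(rep(c("case", "control"), c(config@n_case, config@n_ctrl)),
              names = .sampleIds(config))
}

#' Simulate a probe-to-gene annotation table
#'
#' Every probe maps to exactly one gene; probes-per-gene counts are drawn
#' as 1 + Poisson around the configured mean and then adjusted so they sum
#' exactly to \code{n_probes}. A configurable fraction of genes is placed
#' on chromosome X (their probes are non-autosomal and will be excluded
#' from differential-methylation calling downstream).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame \code{(probe_id, gene_symbol, chromosome,
#'   is_autosomal)} with \code{n_probes} rows.
#' @export
simulateAnnotation <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(.seedFor(config, 0L))
    ng <- config@n_genes
    np <- config@n_probes
    genes <- sprintf("GENE%05d", seq_len(ng))
    counts <- 1L + stats::rpois(ng, max(config@probes_per_gene_mean - 1, 0))
    # rebalance to hit n_probes exactly while keeping every gene covered
    excess <- sum(counts) - np
    while (excess > 0) {
        idx <- which(counts > 1L)
        i <- idx[sample.int(length(idx), 1L)]
        counts[i] <- counts[i] - 1L
        excess <- excess - 1L
    }
    if (excess < 0)
        counts <- counts + stats::rmultinom(1, -excess, rep(1, ng))[, 1]
    n_sex <- round(config@frac_nonautosomal * ng)
    chrom <- sample(as.character(1:22), ng, replace = TRUE)
    if (n_sex > 0)
        chrom[sample.int(ng, n_sex)] <- "X"
    data.frame(probe_id = sprintf("cg%06d", seq_len(np)),
               gene_symbol = rep(genes, counts),
               chromosome = rep(chrom, counts),
               is_autosomal = rep(isAutosome(chrom), counts),
               stringsAsFactors = FALSE)
}

# Decide which genes get methylation / expression effects and in which
# direction. Concordant genes get both, with matched signs; extra DM-only
# and DE-only genes are disjoint so the planted concordant set is exactly
# the set of genes carrying both effects.
.planTruth <- function(config, annotation) {
    genes <- unique(annotation$gene_symbol)
    ng <- length(genes)
    probes_per_gene <- table(annotation$gene_symbol)[genes]
    auto_genes <- unique(annotation$gene_symbol[annotation$is_autosomal])

    n_conc <- round(config@frac_concordant * ng)
    if (n_conc > length(auto_genes))
        stop("not enough autosomal genes to plant the concordant fraction")
    conc <- auto_genes[sample.int(length(auto_genes), n_conc)]
    n_up <- ceiling(n_conc / 2)
    conc_class <- rep(c("hypo_up", "hyper_down"),
                      c(n_up, n_conc - n_up))

    # grow the DM gene set (concordant first) until the planted-probe
    # budget over autosomal probes is met
    n_auto_probes <- sum(annotation$is_autosomal)
    target_probes <- round(config@frac_dm_probes * n_auto_probes)
    dm_genes <- conc
    dm_dir <- ifelse(conc_class == "hypo_up", "hypo", "hyper")
    pool <- setdiff(auto_genes, conc)
    pool <- pool[sample.int(length(pool))]
    i <- 1L
    while (sum(probes_per_gene[dm_genes]) < target_probes &&
           i <= length(pool)) {
        dm_genes <- c(dm_genes, pool[i])
        dm_dir <- c(dm_dir, sample(c("hyper", "hypo"), 1L))
        i <- i + 1L
    }

    n_de <- round(config@frac_de_genes * ng)
    de_pool <- setdiff(genes, dm_genes)
    n_extra_de <- max(n_de - n_conc, 0L)
    extra_de <- de_pool[sample.int(length(de_pool),
                                   min(n_extra_de, length(de_pool)))]
    de_genes <- c(conc, extra_de)
    de_dir <- c(ifelse(conc_class == "hypo_up", "up", "down"),
                sample(c("up", "down"), length(extra_de), replace = TRUE))

    gene_dm <- data.frame(gene_symbol = genes, direction = "none",
                          stringsAsFactors = FALSE)
    gene_dm$direction[match(dm_genes, genes)] <- dm_dir
    gene_de <- data.frame(gene_symbol = genes, direction = "none",
                          stringsAsFactors = FALSE)
    gene_de$direction[match(de_genes, genes)] <- de_dir
    list(gene_dm = gene_dm, gene_de = gene_de,
         concordant = data.frame(gene_symbol = conc, class = conc_class,
                                 stringsAsFactors = FALSE))
}

#' Simulate a two-group beta-value matrix with planted effects
#'
#' Per-probe baseline betas come from a three-mode Beta mixture (low ~0.1,
#' high ~0.85, minor intermediate ~0.5), reproducing the characteristic
#' bimodality of Infinium beta values. Probes of planted genes get an
#' additive delta-beta in the case group (clipped so means stay inside
#' (0,1); clipping is recorded in the truth). Per-sample values are Beta
#' draws around the probe mean with concentration \code{beta_precision}.
#' Detection p-values fail (exceed 0.05) independently at
#' \code{detection_fail_rate}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param annotation output of [simulateAnnotation()] (or a compatible
#'   table).
#' @return list with elements \code{betaset} (a [BetaSet-class]) and
#'   \code{truth} (a [MethTruth-class] covering methylation, expression
#'   and concordance plans).
#' @export
simulateMethylation <- function(config, annotation) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(.seedFor(config, 1L))
    np <- nrow(annotation)
    stopifnot(np == config@n_probes)

    plan <- .planTruth(config, annotation)
    dm_dir <- structure(plan$gene_dm$direction,
                        names = plan$gene_dm$gene_symbol)
    probe_dir <- dm_dir[annotation$gene_symbol]
    probe_sign <- ifelse(probe_dir == "hyper", 1,
                         ifelse(probe_dir == "hypo", -1, 0))

    w <- config@mix_weights / sum(config@mix_weights)
    mode_means <- c(0.10, 0.85, 0.50)
    comp <- sample.int(3L, np, replace = TRUE, prob = w)
    m <- mode_means[comp]
    baseline <- stats::rbeta(np, m * 10, (1 - m) * 10)
    baseline <- pmin(pmax(baseline, 0.02), 0.98)

    intended <- probe_sign * config@delta_beta
    case_mean <- pmin(pmax(baseline + intended, 0.02), 0.98)
    realised <- case_mean - baseline

    prec <- config@beta_precision
    draw <- function(means, n_samp) {
        matrix(stats::rbeta(np * n_samp,
                            rep(means * prec, n_samp),
                            rep((1 - means) * prec, n_samp)),
               nrow = np)
    }
    beta <- cbind(draw(case_mean, config@n_case),
                  draw(baseline, config@n_ctrl))
    fails <- matrix(stats::runif(length(beta)) < config@detection_fail_rate,
                    nrow = np)
    detp <- matrix(stats::runif(length(beta), 0, 0.049), nrow = np)
    detp[fails] <- stats::runif(sum(fails), 0.051, 1)
    dimnames(beta) <- dimnames(detp) <-
        list(annotation$probe_id, .sampleIds(config))

    truth <- new("MethTruth",
        probeEffects = data.frame(probe_id = annotation$probe_id,
                                  delta_beta = realised,
                                  truncated = realised != intended,
                                  stringsAsFactors = FALSE),
        geneDM = plan$gene_dm, geneDE = plan$gene_de,
        concordant = plan$concordant)
    validObject(truth)
    list(betaset = BetaSet(beta, detp, annotation, .sampleGroupVec(config)),
         truth = truth)
}

#' Simulate a two-group log2 expression matrix with planted fold changes
#'
#' Baseline log2 intensities are uniform over \code{expr_base_mean} +/- 4;
#' each gene's residual SD follows
#' \code{0.5 * exp(expr_sd_slope * (baseline - expr_base_mean))}, so a
#' negative slope yields the decreasing variance-intensity trend an
#' intensity-based variance prior must learn. Genes planted as
#' differentially expressed (per the truth) have their case-group mean
#' shifted by \code{+/- log2fc_effect}; concordant genes shift in the
#' direction matching their methylation plan.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth the [MethTruth-class] returned by [simulateMethylation()].
#' @return an [ExprSet-class] over the truth's genes and the configured
#'   samples.
#' @export
simulateExpression <- function(config, truth) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "MethTruth"))
    set.seed(.seedFor(config, 2L))
    genes <- truth@geneDE$gene_symbol
    ng <- length(genes)
    base <- stats::runif(ng, config@expr_base_mean - 4,
                         config@expr_base_mean + 4)
    sdg <- 0.5 * exp(config@expr_sd_slope * (base - config@expr_base_mean))
    shift <- ifelse(truth@geneDE$direction == "up", config@log2fc_effect,
                    ifelse(truth@geneDE$direction == "down",
                           -config@log2fc_effect, 0))
    n1 <- config@n_case; n2 <- config@n_ctrl
    x <- cbind(
        matrix(stats::rnorm(ng * n1, rep(base + shift, n1), rep(sdg, n1)),
               nrow = ng),
        matrix(stats::rnorm(ng * n2, rep(base, n2), rep(sdg, n2)),
               nrow = ng))
    dimnames(x) <- list(genes, .sampleIds(config))
    ExprSet(x, .sampleGroupVec(config))
}

#' Simulate per-sample global methylation percentages (ELISA-style)
#'
#' Draws \code{n_per_group} values per group from
#' Normal(mean, sem * sqrt(n)), i.e. the per-sample SD implied by a
#' reported group SEM.
#'
#' @param mean_case,mean_ctrl target group means (percent).
#' @param sem target standard error of the mean (percent), shared by both
#'   groups.
#' @param n_per_group samples per group (>= 2).
#' @param seed integer seed.
#' @return data.frame \code{(sample_id, group, percent)}.
#' @examples
#' simulateElisa(3.58, 2.56, 0.18, 11, seed = 1)
#' @export
simulateElisa <- function(mean_case, mean_ctrl, sem, n_per_group, seed) {
    if (!is.numeric(sem) || sem <= 0) stop("'sem' must be > 0")
    .stopifnot_count(n_per_group, "n_per_group", min = 2)
    set.seed(as.integer(seed))
    sd <- sem * sqrt(n_per_group)
    data.frame(
        sample_id = c(sprintf("case_%02d", seq_len(n_per_group)),
                      sprintf("ctrl_%02d", seq_len(n_per_group))),
        group = rep(c("case", "control"), each = n_per_group),
        percent = c(stats::rnorm(n_per_group, mean_case, sd),
                    stats::rnorm(n_per_group, mean_ctrl, sd)),
        stringsAsFactors = FALSE)
}

#' Simulate qPCR Ct values with known fold changes
#'
#' Control-group delta-Ct (target minus housekeeping) per target is drawn
#' around a random offset; case-group delta-Ct is shifted by
#' \code{-log2(true_fold)} so the 2^-ddCt estimator recovers
#' \code{true_fold} exactly when \code{noise_sd = 0}.
#'
#' @param true_fold named positive numeric vector of per-target fold
#'   changes (case vs control).
#' @param ct_hk housekeeping-gene mean Ct (cycles).
#' @param noise_sd per-measurement Ct noise SD (cycles).
#' @param n_per_group samples per group.
#' @param seed integer seed.
#' @return data.frame \code{(sample_id, group, target, ct_target,
#'   ct_housekeeping)} suitable for [ddctFoldChange()].
#' @examples
#' qp <- simulateQpcr(c(SLC11A1 = 12.7), noise_sd = 0, n_per_group = 4,
#'                    seed = 1)
#' ddctFoldChange(qp)
#' @export
simulateQpcr <- function(true_fold, ct_hk = 18, noise_sd = 0.2,
                         n_per_group = 10, seed = 1) {
    if (any(true_fold <= 0)) stop("'true_fold' must be positive")
    .stopifnot_count(n_per_group, "n_per_group", min = 1)
    if (is.null(names(true_fold)))
        names(true_fold) <- sprintf("target_%02d", seq_along(true_fold))
    set.seed(as.integer(seed))
    out <- lapply(names(true_fold), function(tg) {
        dct0 <- stats::runif(1, 4, 8)
        grp <- rep(c("case", "control"), each = n_per_group)
        dct <- ifelse(grp == "case", dct0 - log2(true_fold[[tg]]), dct0) +
            stats::rnorm(2 * n_per_group, 0, noise_sd)
        hk <- ct_hk + stats::rnorm(2 * n_per_group, 0, noise_sd)
        data.frame(
            sample_id = paste0(rep(c("case_", "ctrl_"),
                                   each = n_per_group),
                               sprintf("%02d", rep(seq_len(n_per_group),
                                                   2))),
            group = grp, target = tg,
            ct_target = hk + dct, ct_housekeeping = hk,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
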