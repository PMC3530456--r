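#' Mask beta values with unreliable detection p-values
#'
#' Entries whose detection p-value is strictly greater than the threshold
#' become \code{NA} (the boundary value itself is retained). Probes left
#' with fewer than \code{min_per_group} usable values in either group are
#' dropped; the number dropped is recorded in
#' \code{metadata(.)$n_probes_dropped} and reported via a message.
#'
#' @param bs a [BetaSet-class].
#' @param threshold detection p-value cutoff in (0,1); default 0.05.
#' @param min_per_group minimum usable samples per group per probe after
#'   masking (default 3; a variance estimate from fewer values is
#'   unstable).
#' @return a masked, possibly row-subset [BetaSet-class].
#' @export
maskLowDetection <- function(bs, threshold = 0.05, min_per_group = 3) {
    stopifnot(is(bs, "BetaSet"))
    if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie in (0, 1)")
    beta <- betaValues(bs)
    detp <- detectionP(bs)
    if (!identical(dim(beta), dim(detp)))
        stop("beta and detectionP dimensions differ")
    beta[detp > threshold] <- NA_real_
    grp <- sampleGroups(bs)
    ok_case <- rowSums(!is.na(beta[, grp == "case", drop = FALSE]))
    ok_ctrl <- rowSums(!is.na(beta[, grp == "control", drop = FALSE]))
    keep <- ok_case >= min_per_group & ok_ctrl >= min_per_group
    n_drop <- sum(!keep)
    if (n_drop > 0)
        message(n_drop, " probe(s) dropped: fewer than ", min_per_group,
                " usable samples in a group after detection-p masking")
    out <- BetaSet(beta[keep, , drop = FALSE],
                   detp[keep, , drop = FALSE],
                   probeAnnotation(bs)[keep, , drop = FALSE],
                   grp)
    metadata(out)$n_probes_dropped <- n_drop
    metadata(out)$detection_threshold <- threshold
    out
}

# vectorised equal-variance two-sample t on the rows of x/y matrices with
# NAs allowed; returns list(delta, p, n1, n2, m1, m2)
.rowPooledT <- function(xc, xk) {
    n1 <- rowSums(!is.na(xc)); n2 <- rowSums(!is.na(xk))
    m1 <- rowMeans(xc, na.rm = TRUE); m2 <- rowMeans(xk, na.rm = TRUE)
    v1 <- rowSums((xc - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
    v2 <- rowSums((xk - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    delta <- m1 - m2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- delta / se
    p <- 2 * stats::pt(-abs(tt), df)
    # degenerate: zero pooled variance -> p = 1 when means agree, else
    # the smallest representable p (DiffScore capping handles it)
    zero_var <- sp2 <= 0
    p[zero_var & delta == 0] <- 1
    p[zero_var & delta != 0] <- .Machine$double.xmin
    tt[zero_var] <- ifelse(delta[zero_var] == 0, 0,
                           sign(delta[zero_var]) * Inf)
    list(delta = delta, t = tt, p = p, n1 = n1, n2 = n2, m1 = m1, m2 = m2)
}

#' Per-probe differential methylation test
#'
#' Equal-variance two-sample t-test on beta values (case vs control) per
#' probe, on unmasked entries only. Reports the beta-scale group means,
#' delta-beta (case minus control), the two-sided p-value, a
#' Benjamini-Hochberg q-value across tested probes, the signed DiffScore
#' \eqn{10 \cdot sgn(\Delta\beta) \cdot (-\log_{10} p)} and the
#' percent-methylation-change statistic
#' \eqn{100 |\Delta\beta| / \beta_{ctrl}}.
#'
#' An optional M-value variant tests logit2-transformed betas (often
#' better-behaved variances near the boundaries) while still reporting
#' effect sizes on the beta scale; it is not the default.
#'
#' @param bs a (typically masked) [BetaSet-class] with >= 2 usable samples
#'   per group per probe; probes failing that are excluded with a message.
#' @param m_value logical; test on M-values instead of betas.
#' @param diffscore_cap cap on |DiffScore| guarding p = 0 (default 350).
#' @return data.frame, one row per tested probe: \code{probe_id},
#'   \code{mean_beta_case}, \code{mean_beta_ctrl}, \code{delta_beta},
#'   \code{p_value}, \code{q_value}, \code{diff_score},
#'   \code{delta_5mc_pct}, \code{n_case_used}, \code{n_ctrl_used}.
#' @export
testProbeDM <- function(bs, m_value = FALSE, diffscore_cap = 350) {
    stopifnot(is(bs, "BetaSet"))
    beta <- betaValues(bs)
    grp <- sampleGroups(bs)
    xc <- beta[, grp == "case", drop = FALSE]
    xk <- beta[, grp == "control", drop = FALSE]
    usable <- rowSums(!is.na(xc)) >= 2 & rowSums(!is.na(xk)) >= 2
    if (any(!usable))
        message(sum(!usable),
                " probe(s) excluded: fewer than 2 usable samples in a group")
    xc <- xc[usable, , drop = FALSE]
    xk <- xk[usable, , drop = FALSE]
    st_beta <- .rowPooledT(xc, xk)
    st <- if (m_value) .rowPooledT(.beta2m(xc), .beta2m(xk)) else st_beta
    delta_beta <- st_beta$delta
    p <- st$p
    res <- data.frame(
        probe_id = rownames(beta)[usable],
        mean_beta_case = st_beta$m1,
        mean_beta_ctrl = st_beta$m2,
        delta_beta = delta_beta,
        p_value = p,
        q_value = bhFDR(p),
        diff_score = computeDiffScore(p, delta_beta, cap = diffscore_cap),
        delta_5mc_pct = suppressWarnings(
            delta5mcPercent(st_beta$m1, st_beta$m2)),
        n_case_used = st_beta$n1,
        n_ctrl_used = st_beta$n2,
        stringsAsFactors = FALSE, row.names = NULL)
    res
}

#' Signed DiffScore transformation of a p-value
#'
#' \eqn{DiffScore = 10 \cdot sgn(\Delta\beta) \cdot (-\log_{10} p)}: the
#' significance score convention of methylation-array software, under
#' which p = 0.05, 0.01, 0.001 correspond to |DiffScore| = 13, 20, 30
#' (13.0103... before integer rounding). A zero delta-beta gives score 0;
#' p = 0 (or underflow) is capped at \code{+/- cap}.
#'
#' @param p_value p-values in (0, 1].
#' @param delta_beta signed effect (its sign becomes the score's sign).
#' @param cap maximum |DiffScore| (default 350, mirroring the usual
#'   software output ceiling).
#' @return signed numeric scores.
#' @examples
#' computeDiffScore(c(0.05, 0.01, 0.001), c(-1, 1, 1))
#' @export
computeDiffScore <- function(p_value, delta_beta, cap = 350) {
    if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    mag <- -10 * log10(p_value)
    mag[!is.finite(mag) | mag > cap] <- cap
    sign(delta_beta) * mag
}

#' Invert a DiffScore back to its p-value
#'
#' @param diff_score signed scores as produced by [computeDiffScore()].
#' @return p-values; the inverse of the transformation (up to the cap).
#' @export
diffScoreToP <- function(diff_score) 10^(-abs(diff_score) / 10)

#' Percent methylation change
#'
#' \eqn{100 \cdot |\beta_{case} - \beta_{ctrl}| / \beta_{ctrl}}; the
#' relative change in mean methylation, in percent of the control level.
#'
#' @param mean_beta_case,mean_beta_ctrl group mean beta values.
#' @return percent change (>= 0); \code{NA} with a warning where the
#'   control mean is zero (the statistic is undefined there).
#' @examples
#' delta5mcPercent(0.55, 0.50)  # 10
#' @export
delta5mcPercent <- function(mean_beta_case, mean_beta_ctrl) {
    out <- 100 * abs(mean_beta_case - mean_beta_ctrl) / mean_beta_ctrl
    bad <- !is.na(mean_beta_ctrl) & mean_beta_ctrl == 0
    if (any(bad)) {
        warning("control mean beta of 0: percent change undefined, NA returned")
        out[bad] <- NA_real_
    }
    out
}

#' Aggregate probe statistics to gene-level methylation calls
#'
#' Non-autosomal probes are excluded first. A gene is called
#' differentially methylated iff at least one of its autosomal probes has
#' \code{|DiffScore| >= diffscore_threshold}; its direction
#' (\code{hyper}/\code{hypo}) is taken from the probe with maximal
#' |DiffScore|. Genes whose maximal-|DiffScore| probes tie with opposite
#' signs are marked \code{ambiguous} (they are excluded from concordance
#' analysis downstream).
#'
#' @param results per-probe data.frame from [testProbeDM()].
#' @param annotation probe annotation data.frame (\code{probe_id},
#'   \code{gene_symbol}, \code{chromosome}, optionally
#'   \code{is_autosomal}); probes missing from it are skipped with a
#'   message.
#' @param diffscore_threshold positive gate on |DiffScore| (default 13,
#'   the conventional 5\%-FDR-equivalent cut).
#' @return data.frame, one row per called gene: \code{gene_symbol},
#'   \code{direction}, \code{best_diff_score}, \code{best_probe},
#'   \code{delta_beta}, \code{delta_5mc_pct}, \code{n_probes_total},
#'   \code{n_probes_significant} (best_* columns describe the
#'   maximal-|DiffScore| probe).
#' @export
callDMGs <- function(results, annotation, diffscore_threshold = 13) {
    if (diffscore_threshold <= 0)
        stop("'diffscore_threshold' must be > 0")
    annotation <- as.data.frame(annotation)
    if (is.null(annotation$is_autosomal))
        annotation$is_autosomal <- isAutosome(annotation$chromosome)
    unknown <- !(results$probe_id %in% annotation$probe_id)
    if (any(unknown))
        message(sum(unknown), " probe(s) absent from annotation; skipped")
    res <- merge(results[!unknown, , drop = FALSE],
                 annotation[, c("probe_id", "gene_symbol", "is_autosomal")],
                 by = "probe_id")
    res <- res[res$is_autosomal, , drop = FALSE]
    if (!nrow(res))
        return(data.frame(gene_symbol = character(), direction = character(),
                          best_diff_score = numeric(),
                          best_probe = character(), delta_beta = numeric(),
                          delta_5mc_pct = numeric(),
                          n_probes_total = integer(),
                          n_probes_significant = integer(),
                          stringsAsFactors = FALSE))
    parts <- split(res, res$gene_symbol)
    rows <- lapply(parts, function(g) {
        sig <- abs(g$diff_score) >= diffscore_threshold
        if (!any(sig)) return(NULL)
        amax <- max(abs(g$diff_score))
        at_max <- which(abs(g$diff_score) == amax)
        dirs <- unique(sign(g$diff_score[at_max]))
        best <- at_max[1L]
        data.frame(
            gene_symbol = g$gene_symbol[1L],
            direction = if (length(dirs) > 1L) "ambiguous"
                        else if (dirs > 0) "hyper" else "hypo",
            best_diff_score = g$diff_score[best],
            best_probe = g$probe_id[best],
            delta_beta = g$delta_beta[best],
            delta_5mc_pct = g$delta_5mc_pct[best],
            n_probes_total = nrow(g),
            n_probes_significant = sum(sig),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
}
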