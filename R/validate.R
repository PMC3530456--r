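#' IQR-based outlier exclusion
#'
#' Default window is centred on the median: values with
#' \eqn{|v - median| \le 1.5 \times IQR} are kept. (Note this is the
#' window some assay-figure legends state, not the conventional Tukey
#' fences \eqn{[Q_1 - 1.5 IQR, Q_3 + 1.5 IQR]}; set
#' \code{tukey_fences = TRUE} for the latter.) Quartiles use linear
#' interpolation between order statistics (quantile type 7); the
#' exclusion set can depend on this convention, so it is fixed here.
#'
#' @param values numeric vector, length >= 3.
#' @param tukey_fences use Q1/Q3-anchored fences instead of the
#'   median-centred window.
#' @return the retained values (the median itself is never removed).
#' @examples
#' iqrOutlierFilter(c(1, 2, 3, 4, 100))  # drops 100
#' @export
iqrOutlierFilter <- function(values, tukey_fences = FALSE) {
    if (length(values) < 3) stop("need at least 3 values")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    iqr <- q[3] - q[1]
    win <- if (tukey_fences) c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
           else q[2] + c(-1.5, 1.5) * iqr
    values[values >= win[1] & values <= win[2]]
}

#' Two-sample t-test from raw values
#'
#' Equal-variance (pooled) two-sided t-test by default; Welch behind the
#' flag. Degenerate input with zero pooled variance returns t = 0, p = 1
#' when the means agree and is an error otherwise.
#'
#' @param values_case,values_ctrl numeric vectors, >= 2 values each.
#' @param equal_variance pooled-variance test (default TRUE).
#' @return list \code{(t, df, p)}.
#' @export
twoSampleT <- function(values_case, values_ctrl, equal_variance = TRUE) {
    if (length(values_case) < 2 || length(values_ctrl) < 2)
        stop("need at least 2 values per group")
    if (stats::var(values_case) == 0 && stats::var(values_ctrl) == 0) {
        if (mean(values_case) == mean(values_ctrl))
            return(list(t = 0,
                        df = length(values_case) + length(values_ctrl) - 2,
                        p = 1))
        stop("zero variance in both groups with unequal means: ",
             "t is unbounded")
    }
    ht <- stats::t.test(values_case, values_ctrl,
                        var.equal = equal_variance)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Two-sample t-test from group summaries (mean, SEM, n)
#'
#' Recovers the equal-variance test from published summaries:
#' \eqn{t = (\bar{x}_1 - \bar{x}_2) / \sqrt{SEM_1^2 + SEM_2^2}} with
#' \eqn{df = n_1 + n_2 - 2} (SEMs are converted back to SDs and pooled;
#' with equal n this reduces to the displayed formula exactly). Welch
#' degrees of freedom behind the flag.
#'
#' @param mean_case,sem_case,n_case case-group summary (n >= 2, sem > 0).
#' @param mean_ctrl,sem_ctrl,n_ctrl control-group summary.
#' @param welch use Welch-Satterthwaite df instead of pooled.
#' @return list \code{(t, df, p)}.
#' @examples
#' twoSampleTSummary(3.58, 0.18, 11, 2.56, 0.18, 11)  # p ~ 0.0007
#' @export
twoSampleTSummary <- function(mean_case, sem_case, n_case,
                              mean_ctrl, sem_ctrl, n_ctrl,
                              welch = FALSE) {
    if (n_case < 2 || n_ctrl < 2) stop("need n >= 2 per group")
    if (sem_case <= 0 || sem_ctrl <= 0) stop("SEMs must be > 0")
    v1 <- (sem_case * sqrt(n_case))^2
    v2 <- (sem_ctrl * sqrt(n_ctrl))^2
    if (welch) {
        se2 <- v1 / n_case + v2 / n_ctrl
        tt <- (mean_case - mean_ctrl) / sqrt(se2)
        df <- se2^2 / ((v1 / n_case)^2 / (n_case - 1) +
                       (v2 / n_ctrl)^2 / (n_ctrl - 1))
    } else {
        df <- n_case + n_ctrl - 2
        sp2 <- ((n_case - 1) * v1 + (n_ctrl - 1) * v2) / df
        tt <- (mean_case - mean_ctrl) /
            sqrt(sp2 * (1 / n_case + 1 / n_ctrl))
    }
    list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Fold change between positive group means
#'
#' Plain ratio case/control (for e.g. global percent-methylation
#' comparisons, where a 1.4-fold increase means mean_case/mean_ctrl =
#' 1.4). Use [signedFoldChange()] for the signed array-table convention.
#'
#' @param mean_case,mean_ctrl positive means.
#' @return the ratio.
#' @examples
#' foldChangeMeans(3.58, 2.56)  # 1.398 -> prints as 1.4
#' @export
foldChangeMeans <- function(mean_case, mean_ctrl) {
    if (any(mean_case <= 0) || any(mean_ctrl <= 0))
        stop("means must be positive")
    mean_case / mean_ctrl
}

#' Relative qPCR quantification by 2^-ddCt
#'
#' Per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}} (when a
#' sample has replicate rows for a target they are averaged first); per
#' target, \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{case} -
#' \overline{\Delta Ct}_{control}} and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}. Folds below 1 are also reported as the
#' negative reciprocal for table parity.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{group}
#'   (\code{case}/\code{control}), \code{target}, \code{ct_target},
#'   \code{ct_housekeeping}. Samples missing a housekeeping Ct are
#'   excluded with a warning; a group left empty is an error.
#' @return data.frame per target: \code{target}, \code{ddct},
#'   \code{fold}, \code{signed_fold}, \code{n_case}, \code{n_ctrl}.
#' @export
ddctFoldChange <- function(samples) {
    need <- c("sample_id", "group", "target", "ct_target",
              "ct_housekeeping")
    if (!all(need %in% colnames(samples)))
        stop("samples must have columns: ", paste(need, collapse = ", "))
    bad <- !is.finite(samples$ct_housekeeping) |
        !is.finite(samples$ct_target)
    if (any(bad)) {
        warning(sum(bad), " sample row(s) with missing Ct excluded")
        samples <- samples[!bad, , drop = FALSE]
    }
    out <- lapply(split(samples, samples$target), function(sdf) {
        dct <- sdf$ct_target - sdf$ct_housekeeping
        per_sample <- tapply(dct, list(sdf$sample_id), mean)
        grp <- tapply(sdf$group, list(sdf$sample_id),
                      function(g) g[1])[names(per_sample)]
        if (!any(grp == "case") || !any(grp == "control"))
            stop("target '", sdf$target[1],
                 "': a group is empty after exclusions")
        ddct <- mean(per_sample[grp == "case"]) -
            mean(per_sample[grp == "control"])
        fold <- 2^(-ddct)
        data.frame(target = sdf$target[1], ddct = ddct, fold = fold,
                   signed_fold = if (fold >= 1) fold else -1 / fold,
                   n_case = sum(grp == "case"),
                   n_ctrl = sum(grp == "control"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Region and per-site mean percent methylation (pyrosequencing-style)
#'
#' Each sample contributes percent-methylation values at a fixed set of
#' CpG sites within a region; the per-sample region value is the mean
#' across sites; group summaries are mean +/- SEM, overall and per site.
#'
#' @param region data.frame with columns \code{sample_id}, \code{group},
#'   \code{site_index}, \code{percent} (in \eqn{[0,100]}); every sample
#'   must cover the same sites (ragged input is an error).
#' @return list with \code{region} (per-group mean, sem, n over
#'   per-sample region means) and \code{per_site} (per group x site mean
#'   and sem).
#' @export
regionMeanMethylation <- function(region) {
    need <- c("sample_id", "group", "site_index", "percent")
    if (!all(need %in% colnames(region)))
        stop("region must have columns: ", paste(need, collapse = ", "))
    if (any(region$percent < 0 | region$percent > 100))
        stop("percent values must lie in [0, 100]")
    sites_by_sample <- tapply(region$site_index, region$sample_id,
                              function(s) paste(sort(s), collapse = ","))
    if (length(unique(sites_by_sample)) != 1)
        stop("ragged site lists: all samples must cover the same sites")
    sample_means <- tapply(region$percent, region$sample_id, mean)
    grp <- tapply(region$group, region$sample_id,
                  function(g) g[1])[names(sample_means)]
    sem <- function(x) if (length(x) > 1)
        stats::sd(x) / sqrt(length(x)) else 0
    region_sum <- do.call(rbind, lapply(split(
        as.numeric(sample_means), grp), function(v)
            data.frame(mean = mean(v), sem = sem(v), n = length(v))))
    region_sum <- data.frame(group = rownames(region_sum), region_sum,
                             row.names = NULL, stringsAsFactors = FALSE)
    per_site <- stats::aggregate(percent ~ group + site_index,
                                 data = region,
                                 FUN = function(v) c(mean = mean(v),
                                                     sem = sem(v)))
    per_site <- data.frame(group = per_site$group,
                           site_index = per_site$site_index,
                           mean = per_site$percent[, "mean"],
                           sem = per_site$percent[, "sem"],
                           stringsAsFactors = FALSE)
    list(region = region_sum, per_site = per_site)
}
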