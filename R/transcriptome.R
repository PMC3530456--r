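#' Quantile-normalize the columns of an expression matrix
#'
#' Replaces each column by the reference distribution of row-wise means of
#' the sorted columns, preserving within-column ranks, so every column
#' ends with exactly the same sorted value multiset. Ties are assigned by
#' first occurrence, which keeps the defining property exact. Exists to
#' condition synthetic data; real arrays are assumed normalized upstream.
#'
#' @param x numeric matrix (complete; missing values are an error) or an
#'   [ExprSet-class].
#' @return an object of the same type with normalized columns.
#' @export
quantileNormalize <- function(x) {
    if (is(x, "ExprSet")) {
        m <- quantileNormalize(exprValues(x))
        return(ExprSet(m, sampleGroups(x)))
    }
    x <- as.matrix(x)
    if (anyNA(x)) stop("matrix must be complete (no missing values)")
    if (ncol(x) < 2) return(x)
    ref <- rowMeans(apply(x, 2, sort))
    out <- apply(x, 2, function(col) ref[rank(col, ties.method = "first")])
    dimnames(out) <- dimnames(x)
    out
}

# Newton solve of trigamma(x) = y; vectorised over y
.trigammaInverse <- function(y) {
    vapply(y, function(yy) {
        if (yy <= 0) return(Inf)
        x <- 0.5 + 1 / yy
        for (i in seq_len(60)) {
            step <- (trigamma(x) - yy) / psigamma(x, 2)
            x <- max(x - step, 1e-8)
            if (abs(step) < 1e-10 * x) break
        }
        x
    }, numeric(1))
}

#' Fit an intensity-dependent variance prior (empirical Bayes)
#'
#' Per-gene pooled residual variances \eqn{s^2} (equal-variance two-group
#' design, d = n1 + n2 - 2 df) are smoothed against mean log2 intensity A:
#' a tricube-weighted local linear regression (span 0.3) of
#' \eqn{\log s^2} on A gives the location of the prior variance curve
#' \eqn{s_0^2(A)}, after correcting for the mean of \eqn{\log} of a scaled
#' chi-square / F variate. The prior degrees of freedom \eqn{d_0} come
#' from closed-form moment matching on the log scale:
#' \eqn{Var[\log s^2 - \log s_0^2(A)] = \psi'(d/2) + \psi'(d_0/2)}, solved
#' for \eqn{d_0} by inverting the trigamma function (infinite when the
#' residual spread is no larger than the chi-square noise floor).
#'
#' @param es an [ExprSet-class] with >= 3 samples per group and >= 30
#'   genes (the smoother is unidentifiable below that).
#' @param span loess span for the local regression (default 0.3).
#' @return list of class \code{ModeratedVariancePrior}: \code{prior_df}
#'   (d0, possibly \code{Inf}), \code{prior_var} (s0^2 evaluated at each
#'   gene's A), \code{s2} (the raw pooled variances), \code{df_residual}
#'   (d), \code{amean}.
#' @export
fitIntensityPrior <- function(es, span = 0.3) {
    stopifnot(is(es, "ExprSet"))
    x <- exprValues(es)
    grp <- sampleGroups(es)
    n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
    if (n1 < 3 || n2 < 3)
        stop("need at least 3 samples per group to fit the prior")
    if (nrow(x) < 30)
        stop("need at least 30 genes to fit the intensity smoother")
    st <- .rowPooledT(x[, grp == "case", drop = FALSE],
                      x[, grp == "control", drop = FALSE])
    d <- n1 + n2 - 2
    s2 <- pmax((rowSums((x[, grp == "case", drop = FALSE] - st$m1)^2) +
                rowSums((x[, grp == "control", drop = FALSE] - st$m2)^2)) /
               d, 1e-12)
    A <- rowMeans(x)
    z <- log(s2)
    fit <- stats::loess(z ~ A, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    zhat <- stats::fitted(fit)
    resid_var <- stats::var(stats::residuals(fit))
    excess <- resid_var - trigamma(d / 2)
    if (excess <= 0) {
        d0 <- Inf
        log_s0 <- zhat - digamma(d / 2) + log(d / 2)
    } else {
        d0 <- 2 * .trigammaInverse(excess)
        log_s0 <- zhat - digamma(d / 2) + log(d / 2) +
            digamma(d0 / 2) - log(d0 / 2)
    }
    structure(list(prior_df = d0, prior_var = exp(log_s0), s2 = s2,
                   df_residual = d, amean = A, span = span),
              class = "ModeratedVariancePrior")
}

#' @export
print.ModeratedVariancePrior <- function(x, ...) {
    cat("ModeratedVariancePrior:", length(x$s2), "genes, residual df",
        x$df_residual, "\n")
    cat(sprintf("  prior df d0 = %s; prior variance range [%.4g, %.4g]\n",
                format(x$prior_df, digits = 4), min(x$prior_var),
                max(x$prior_var)))
    invisible(x)
}

#' Intensity-based moderated t-test per gene
#'
#' Shrinks each gene's pooled variance toward the intensity-dependent
#' prior: \eqn{\tilde{s}^2 = (d_0 s_0^2(A) + d s^2) / (d_0 + d)};
#' \eqn{t = \Delta\bar{x} / \sqrt{\tilde{s}^2 (1/n_1 + 1/n_2)}} with
#' \eqn{d_0 + d} degrees of freedom. At \eqn{d_0 = 0} this is exactly the
#' ordinary pooled two-sample t; as \eqn{d_0 \to \infty} the denominator
#' uses the prior curve alone.
#'
#' @param es the [ExprSet-class] the prior was fitted on.
#' @param prior a \code{ModeratedVariancePrior} from [fitIntensityPrior()],
#'   or \code{NULL} to fit one with defaults.
#' @return data.frame, one row per gene: \code{gene_symbol},
#'   \code{mean_case}, \code{mean_ctrl}, \code{log2fc} (case - ctrl),
#'   \code{signed_fc} (linear ratio if >= 1, else negative reciprocal),
#'   \code{t_moderated}, \code{p_value}, \code{q_value}, \code{direction}.
#' @export
moderatedT <- function(es, prior = NULL) {
    stopifnot(is(es, "ExprSet"))
    if (is.null(prior)) prior <- fitIntensityPrior(es)
    x <- exprValues(es)
    grp <- sampleGroups(es)
    n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
    d <- n1 + n2 - 2
    if (d <= 0) stop("zero residual degrees of freedom")
    if (length(prior$s2) != nrow(x))
        stop("prior was fitted on a different matrix")
    m1 <- rowMeans(x[, grp == "case", drop = FALSE])
    m2 <- rowMeans(x[, grp == "control", drop = FALSE])
    d0 <- prior$prior_df
    s2_tilde <- if (is.infinite(d0)) prior$prior_var
                else (d0 * prior$prior_var + d * prior$s2) / (d0 + d)
    tt <- (m1 - m2) / sqrt(s2_tilde * (1 / n1 + 1 / n2))
    df_total <- d0 + d
    p <- 2 * stats::pt(-abs(tt), df_total)
    log2fc <- m1 - m2
    data.frame(gene_symbol = rownames(x),
               mean_case = m1, mean_ctrl = m2,
               log2fc = log2fc,
               signed_fc = ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc)),
               t_moderated = tt,
               p_value = p,
               q_value = bhFDR(p),
               direction = ifelse(log2fc >= 0, "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' order-preserving, in \eqn{[0,1]}. Shared by the expression, methylation
#' and enrichment stages.
#'
#' @param p_values numeric vector of p-values in \eqn{[0,1]}.
#' @return q-values, same length and order as the input.
#' @export
bhFDR <- function(p_values) {
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}

#' Signed fold change from linear-scale group means
#'
#' The array-table convention: the ratio \eqn{r = case/ctrl} when
#' \eqn{r \ge 1}, otherwise \eqn{-1/r}, so |signed fold| is always >= 1
#' and down-regulation reads as a negative fold.
#'
#' @param mean_case_linear,mean_ctrl_linear positive linear-scale means.
#' @return signed fold change(s).
#' @examples
#' signedFoldChange(2.06, 1.10)   #  1.87 -> prints as 1.9
#' signedFoldChange(0.35, 1.38)   # -3.94 -> prints as -3.9
#' @export
signedFoldChange <- function(mean_case_linear, mean_ctrl_linear) {
    if (any(mean_case_linear <= 0) || any(mean_ctrl_linear <= 0))
        stop("means must be positive")
    r <- mean_case_linear / mean_ctrl_linear
    ifelse(r >= 1, r, -1 / r)
}

#' Select differentially expressed genes at an FDR cutoff
#'
#' @param results data.frame from [moderatedT()].
#' @param fdr FDR cutoff in (0,1); default 0.10.
#' @return the subset of \code{results} with \code{q_value <= fdr}.
#' @export
callDEGs <- function(results, fdr = 0.10) {
    if (fdr <= 0 || fdr >= 1) stop("'fdr' must lie in (0, 1)")
    out <- results[results$q_value <= fdr, , drop = FALSE]
    rownames(out) <- NULL
    out
}
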