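#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{term <tab> description <tab> member...}. Duplicate members within
#' a set are stored once; a line with fewer than three fields is a parse
#' error naming the line.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (term -> members), with a
#'   \code{description} attribute carrying term descriptions.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        out <- list()
        attr(out, "description") <- character()
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 3
    if (any(short))
        stop("GMT parse error: line ", which(short)[1],
             " has fewer than 3 tab-separated fields")
    terms <- vapply(fields, `[[`, character(1), 1)
    if (anyDuplicated(terms))
        stop("duplicated term id(s) in GMT: ",
             paste(unique(terms[duplicated(terms)]), collapse = ", "))
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
    if (any(vapply(members, length, integer(1)) == 0))
        stop("GMT set with no members")
    names(members) <- terms
    attr(members, "description") <-
        structure(vapply(fields, `[[`, character(1), 2), names = terms)
    members
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for drawing \code{k} members of
#' a \code{K}-gene set in a query of \code{n} genes from a universe of
#' \code{N}. The optional EASE variant tests \eqn{P(X \ge k - 1)} removing
#' one query hit, a deliberately conservative score used by some
#' annotation tools.
#'
#' @param k query-set overlap; \code{0 <= k <= min(K, n)}.
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @param ease use the EASE (k - 1) variant (default FALSE).
#' @return upper-tail p-value.
#' @examples
#' hypergeomTest(3, 5, 6, 20)
#' @export
hypergeomTest <- function(k, K, n, N, ease = FALSE) {
    if (any(k < 0 | K < 0 | n < 0 | N < 1) || any(K > N) || any(n > N) ||
        any(k > pmin(K, n)))
        stop("inconsistent counts: need 0 <= k <= min(K, n), K, n <= N")
    kk <- if (ease) pmax(k - 1, 0) else k
    stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation across a collection
#'
#' Intersects every set with the universe, tests the query against each
#' set with positive overlap by the hypergeometric upper tail, corrects
#' across tested terms by Benjamini-Hochberg and flags significance at
#' \code{q <= alpha}. Results are sorted by ascending p (stable for
#' ties).
#'
#' @param query character vector of gene symbols; must be a subset of the
#'   universe.
#' @param collection named list of gene sets (see [readGMT()]).
#' @param universe background gene symbols (conventionally all genes on
#'   the assay, not the genome).
#' @param alpha significance cutoff on the q-value (default 0.05).
#' @param ease passed to [hypergeomTest()].
#' @return data.frame: \code{term_id}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p_value}, \code{q_value}, \code{fold_enrichment}
#'   \code{= (k/n)/(K/N)}, \code{significant}.
#' @export
enrichCollection <- function(query, collection, universe, alpha = 0.05,
                             ease = FALSE) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(collection), function(term) {
        set <- intersect(collection[[term]], universe)
        k <- length(intersect(query, set))
        if (k == 0) return(NULL)
        K <- length(set)
        data.frame(term_id = term, k = k, K = K, n = n, N = N,
                   p_value = hypergeomTest(k, K, n, N, ease = ease),
                   fold_enrichment = (k / n) / (K / N),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(term_id = character(), k = integer(),
                          K = integer(), n = integer(), N = integer(),
                          p_value = numeric(), q_value = numeric(),
                          fold_enrichment = numeric(),
                          significant = logical(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out$q_value <- bhFDR(out$p_value)
    out$significant <- out$q_value <= alpha
    out <- out[order(out$p_value), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("term_id", "k", "K", "n", "N", "p_value", "q_value",
            "fold_enrichment", "significant")]
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p by summing, over all tables with the observed
#' margins, the probabilities not exceeding that of the observed table
#' (the standard definition). Used for e.g. comparing a gene's
#' literature-citation frequency against a background corpus.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (\code{a b} / \code{c d}).
#' @return two-sided exact p-value.
#' @examples
#' fisher2x2(10, 0, 0, 10)
#' @export
fisher2x2 <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
        stop("a margin of the table is zero; the test is undefined")
    stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}
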