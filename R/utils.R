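#' Round half away from zero
#'
#' Table-style rounding: halves move away from zero (so 4.375 prints as 4.4
#' at one decimal, and -4.375 as -4.4), unlike [round()]'s round-half-even.
#' Used wherever the package reproduces one-decimal published table values.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1, the table convention).
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 1) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Is a chromosome label autosomal?
#'
#' @param chromosome character vector of labels such as \code{"chr1"},
#'   \code{"7"}, \code{"chrX"}, \code{"Y"}, \code{"MT"}.
#' @return logical vector; TRUE for autosomes 1-22.
#' @export
isAutosome <- function(chromosome) {
    core <- sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
    suppressWarnings(num <- as.integer(core))
    !is.na(num) & num >= 1 & num <= 22
}

.stopifnot_fraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a single fraction in [0, 1]", name))
}

.stopifnot_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != round(x))
        stop(sprintf("'%s' must be an integer count >= %d", name, min))
}

# logit on base 2 with clipping away from {0,1}; used by the optional
# M-value probe test
.beta2m <- function(beta, eps = 1e-3) {
    b <- pmin(pmax(beta, eps), 1 - eps)
    log2(b / (1 - b))
}
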