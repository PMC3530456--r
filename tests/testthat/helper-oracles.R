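# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where possible, the distribution functions)
# they are checking.

# BH step-up by the definition: q_(i) = min_{j >= i} p_(j) * m / j
bhStepUpOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- numeric(m)
    for (i in seq_len(m))
        q_sorted[i] <- min(pmin(sort(p)[i:m] * m / (i:m), 1))
    q <- numeric(m)
    q[o] <- q_sorted
    q
}

# Upper-tail hypergeometric by direct combinatorial counting
hyperUpperOracle <- function(k, K, n, N) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher exact p by enumeration over all tables with the
# observed margins: sum of table probabilities <= observed (with the
# usual small relative tolerance for ties)
fisherTwoSidedOracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    avals <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- vapply(avals, function(x) {
        choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
    }, numeric(1))
    p_obs <- pr[avals == a]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Small complete synthetic dataset shared by several tests
tinySim <- function(seed = 101, ...) {
    cfg <- simConfig(n_probes = 300, n_genes = 150, n_case = 8,
                     n_ctrl = 8, seed = seed, ...)
    ann <- simulateAnnotation(cfg)
    meth <- simulateMethylation(cfg, ann)
    list(config = cfg, annotation = ann, betaset = meth$betaset,
         truth = meth$truth,
         exprset = simulateExpression(cfg, meth$truth))
}

# Hand-built BetaSet with explicit values
manualBetaSet <- function(beta, detp = NULL, chromosome = "1") {
    if (is.null(detp))
        detp <- matrix(0.01, nrow(beta), ncol(beta),
                       dimnames = dimnames(beta))
    ann <- data.frame(probe_id = rownames(beta),
                      gene_symbol = paste0("G", seq_len(nrow(beta))),
                      chromosome = rep(chromosome,
                                       length.out = nrow(beta)))
    grp <- ifelse(grepl("^case", colnames(beta)), "case", "control")
    BetaSet(beta, detp, ann, grp)
}
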