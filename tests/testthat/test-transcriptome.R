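test_that("quantile normalization equalises column distributions", {
    set.seed(5)
    x <- matrix(rnorm(200), 50, 4, dimnames = list(paste0("g", 1:50),
                                                   paste0("s", 1:4)))
    qn <- quantileNormalize(x)
    ref <- unname(sort(qn[, 1]))
    for (j in 2:4)
        expect_equal(unname(sort(qn[, j])), ref, tolerance = 1e-9)
    # ranks within columns preserved
    for (j in 1:4)
        expect_identical(order(qn[, j]), order(x[, j]))
    # identical columns are a fixed point
    y <- cbind(a = x[, 1], b = x[, 1])
    expect_equal(quantileNormalize(y), y, ignore_attr = TRUE)
    # single column unchanged
    expect_equal(quantileNormalize(x[, 1, drop = FALSE]),
                 x[, 1, drop = FALSE])
    x[1, 1] <- NA
    expect_error(quantileNormalize(x), "complete")
})

test_that("intensity prior recovers flat and sloped variance structure", {
    set.seed(11)
    ng <- 400; n <- 12
    grp <- rep(c("case", "control"), each = n / 2)
    ids <- paste0("s", 1:n)
    # homoscedastic: flat curve near the true variance
    x <- matrix(rnorm(ng * n, 8, 0.5), ng, n,
                dimnames = list(paste0("g", 1:ng), ids))
    es <- ExprSet(x, structure(grp, names = ids))
    pr <- fitIntensityPrior(es)
    expect_gt(pr$prior_df, 0)
    expect_equal(median(pr$prior_var), 0.25, tolerance = 0.15)
    mid <- pr$amean > quantile(pr$amean, 0.1) &
        pr$amean < quantile(pr$amean, 0.9)
    expect_lt(diff(range(log(pr$prior_var[mid]))), 0.5)
    # heteroscedastic: fitted curve decreasing over the bulk
    cfg <- simConfig(n_probes = 500, n_genes = 500, expr_sd_slope = -0.1,
                     frac_dm_probes = 0, frac_de_genes = 0,
                     frac_concordant = 0, seed = 8)
    sim <- simulateMethylation(cfg, simulateAnnotation(cfg))
    es2 <- simulateExpression(cfg, sim$truth)
    pr2 <- fitIntensityPrior(es2)
    o <- order(pr2$amean)
    bulk <- o[seq(floor(0.1 * 500), ceiling(0.9 * 500))]
    expect_lt(cor(pr2$amean[bulk], log(pr2$prior_var[bulk])), -0.9)
    # guards
    expect_error(fitIntensityPrior(ExprSet(x[1:10, ],
                                           structure(grp, names = ids))),
                 "at least 30 genes")
    small <- ExprSet(x[, 1:4], structure(grp[c(1, 2, 7, 8)],
                                         names = ids[1:4]))
    expect_error(fitIntensityPrior(small), "3 samples")
})

test_that("moderated t reduces to Student t when the prior df is zero", {
    sim <- tinySim(seed = 19)
    es <- sim$exprset
    pr <- fitIntensityPrior(es)
    pr0 <- pr
    pr0$prior_df <- 0
    res <- moderatedT(es, pr0)
    x <- exprValues(es)
    grp <- sampleGroups(es)
    for (g in sample(rownames(x), 10)) {
        ht <- t.test(x[g, grp == "case"], x[g, grp == "control"],
                     var.equal = TRUE)
        expect_equal(res$p_value[res$gene_symbol == g], ht$p.value,
                     tolerance = 1e-10)
        expect_equal(res$t_moderated[res$gene_symbol == g],
                     unname(ht$statistic), tolerance = 1e-10)
    }
})

test_that("infinite prior df uses the prior curve alone", {
    sim <- tinySim(seed = 23)
    pr <- fitIntensityPrior(sim$exprset)
    prInf <- pr
    prInf$prior_df <- Inf
    res <- moderatedT(sim$exprset, prInf)
    x <- exprValues(sim$exprset)
    grp <- sampleGroups(sim$exprset)
    n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
    m1 <- rowMeans(x[, grp == "case"])
    m2 <- rowMeans(x[, grp == "control"])
    expect_equal(res$t_moderated,
                 unname((m1 - m2) /
                        sqrt(pr$prior_var * (1 / n1 + 1 / n2))),
                 tolerance = 1e-12)
})

test_that("moderated t holds its type-I error on null data", {
    cfg <- simConfig(n_probes = 1000, n_genes = 1000,
                     frac_dm_probes = 0, frac_de_genes = 0,
                     frac_concordant = 0, seed = 3)
    sim <- simulateMethylation(cfg, simulateAnnotation(cfg))
    de <- moderatedT(simulateExpression(cfg, sim$truth))
    expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
})

test_that("moderated p-values track an established empirical-Bayes fit", {
    skip_if_not_installed("limma")
    sim <- tinySim(seed = 29)
    es <- sim$exprset
    res <- moderatedT(es)
    grp <- sampleGroups(es)
    design <- cbind(1, as.integer(grp == "case"))
    fit <- limma::eBayes(limma::lmFit(exprValues(es), design),
                         trend = TRUE)
    expect_gt(cor(-log10(res$p_value), -log10(fit$p.value[, 2]),
                  method = "spearman"), 0.98)
})

test_that("BH q-values match the step-up definition", {
    expect_equal(bhFDR(0.03), 0.03)
    expect_equal(bhFDR(c(0.01, 0.04)), c(0.02, 0.04))
    expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
    set.seed(41)
    for (i in 1:20) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhFDR(p), bhStepUpOracle(p), tolerance = 1e-12)
    }
})

test_that("signed fold change follows the array-table convention", {
    expect_equal(roundHalfAway(signedFoldChange(2.06, 1.10)), 1.9)
    expect_equal(roundHalfAway(signedFoldChange(0.35, 1.38)), -3.9)
    expect_equal(signedFoldChange(3, 3), 1)
    expect_error(signedFoldChange(-1, 2), "positive")
    set.seed(6)
    a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
    expect_equal(signedFoldChange(a, b), -signedFoldChange(b, a),
                 tolerance = 1e-12)
    expect_true(all(abs(signedFoldChange(a, b)) >= 1))
})

test_that("DEG selection is threshold-monotone", {
    sim <- tinySim(seed = 37)
    de <- moderatedT(sim$exprset)
    d05 <- callDEGs(de, 0.05)
    d10 <- callDEGs(de, 0.10)
    expect_true(all(d05$gene_symbol %in% d10$gene_symbol))
    expect_true(all(d10$gene_symbol %in% de$gene_symbol))
    de_null <- de
    de_null$p_value <- 1
    de_null$q_value <- 1
    expect_equal(nrow(callDEGs(de_null, 0.10)), 0)
    # planted DE recovered
    planted <- sim$truth@geneDE$gene_symbol[
        sim$truth@geneDE$direction != "none"]
    expect_gte(mean(planted %in% d10$gene_symbol), 0.8)
})

test_that("empirical FDR stays controlled near the nominal level", {
    fdp <- vapply(1:50, function(s) {
        cfg <- simConfig(n_probes = 300, n_genes = 300, n_case = 8,
                         n_ctrl = 8, frac_de_genes = 0.2,
                         frac_dm_probes = 0.2, frac_concordant = 0.1,
                         seed = 1000 + s)
        sim <- simulateMethylation(cfg, simulateAnnotation(cfg))
        de <- moderatedT(simulateExpression(cfg, sim$truth))
        hits <- callDEGs(de, 0.10)$gene_symbol
        if (!length(hits)) return(0)
        truth_de <- sim$truth@geneDE
        nulls <- truth_de$gene_symbol[truth_de$direction == "none"]
        mean(hits %in% nulls)
    }, numeric(1))
    expect_lte(mean(fdp), 0.15)
})
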