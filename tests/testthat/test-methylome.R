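test_that("detection masking is strict at the threshold", {
    beta <- matrix(0.5, 2, 6,
                   dimnames = list(c("cg1", "cg2"),
                                   c(paste0("case_", 1:3),
                                     paste0("ctrl_", 1:3))))
    detp <- beta * 0 + 0.01
    detp["cg1", "case_1"] <- 0.06   # masked (strictly > 0.05)
    detp["cg1", "case_2"] <- 0.05   # retained (boundary)
    bs <- manualBetaSet(beta, detp)
    out <- maskLowDetection(bs, min_per_group = 2)
    expect_true(is.na(betaValues(out)["cg1", "case_1"]))
    expect_false(is.na(betaValues(out)["cg1", "case_2"]))
})

test_that("probes with too few usable samples in a group are dropped", {
    beta <- matrix(runif(4 * 6), 4, 6,
                   dimnames = list(paste0("cg", 1:4),
                                   c(paste0("case_", 1:3),
                                     paste0("ctrl_", 1:3))))
    detp <- beta * 0 + 0.01
    detp["cg3", 1:3] <- 0.9   # entire case group fails detection
    bs <- manualBetaSet(beta, detp)
    expect_message(out <- maskLowDetection(bs, min_per_group = 3),
                   "dropped")
    expect_false("cg3" %in% rownames(out))
    expect_equal(S4Vectors::metadata(out)$n_probes_dropped, 1)
})

test_that("BetaSet construction rejects malformed input", {
    beta <- matrix(0.5, 2, 4, dimnames = list(c("cg1", "cg2"),
                                              paste0("s", 1:4)))
    expect_error(BetaSet(beta, matrix(0.01, 3, 4),
                         data.frame(probe_id = c("cg1", "cg2"),
                                    gene_symbol = "G", chromosome = "1"),
                         rep(c("case", "control"), 2)),
                 "identical dimensions")
    expect_error(BetaSet(beta, beta * 0 + 0.01,
                         data.frame(probe_id = "cg1",
                                    gene_symbol = "G", chromosome = "1"),
                         rep(c("case", "control"), 2)),
                 "absent from annotation")
})

test_that("per-probe test: null identity, symmetry, t.test agreement", {
    beta <- matrix(c(rep(0.4, 6),
                     0.2, 0.3, 0.25, 0.6, 0.7, 0.65,
                     runif(6, 0.3, 0.7)), 3, 6, byrow = TRUE,
                   dimnames = list(paste0("cg", 1:3),
                                   c(paste0("case_", 1:3),
                                     paste0("ctrl_", 1:3))))
    bs <- manualBetaSet(beta)
    res <- testProbeDM(bs)
    # identical case/ctrl values -> delta 0, p 1, DiffScore 0
    expect_equal(res$delta_beta[1], 0)
    expect_equal(res$p_value[1], 1)
    expect_equal(res$diff_score[1], 0)
    # agreement with stats::t.test per probe
    for (i in 2:3) {
        ht <- t.test(beta[i, 1:3], beta[i, 4:6], var.equal = TRUE)
        expect_equal(res$p_value[i], ht$p.value, tolerance = 1e-12)
        expect_equal(res$delta_beta[i],
                     unname(diff(rev(ht$estimate))), tolerance = 1e-12)
    }
    # swapping labels flips delta sign, leaves p unchanged
    beta_sw <- beta[, c(4:6, 1:3)]
    colnames(beta_sw) <- colnames(beta)
    res_sw <- testProbeDM(manualBetaSet(beta_sw))
    expect_equal(res_sw$delta_beta, -res$delta_beta, tolerance = 1e-12)
    expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
})

test_that("probe test holds its type-I error on null data", {
    cfg <- simConfig(n_probes = 1000, n_genes = 500, frac_dm_probes = 0,
                     frac_de_genes = 0, frac_concordant = 0,
                     detection_fail_rate = 0, seed = 3)
    sim <- simulateMethylation(cfg, simulateAnnotation(cfg))
    res <- testProbeDM(sim$betaset)
    expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.02)
})

test_that("DiffScore reproduces the published p-value equivalences", {
    expect_equal(computeDiffScore(0.001, 1), 30, tolerance = 1e-9)
    expect_equal(computeDiffScore(0.01, 1), 20, tolerance = 1e-9)
    expect_equal(computeDiffScore(0.05, -1), -13.0103, tolerance = 1e-4)
    expect_equal(computeDiffScore(1, 0.3), 0)
    expect_equal(computeDiffScore(0.5, 0), 0)
    # p = 0 capped at the documented ceiling
    expect_equal(computeDiffScore(0, 1), 350)
    expect_equal(computeDiffScore(0, -1, cap = 999), -999)
    expect_error(computeDiffScore(1.2, 1), "0, 1")
})

test_that("DiffScore/p-value transformation is a bijection", {
    p <- 10^seq(-30, 0, length.out = 200)
    ds <- computeDiffScore(p, rep(c(1, -1), 100), cap = Inf)
    expect_equal(diffScoreToP(ds), p, tolerance = 1e-12)
})

test_that("percent methylation change follows its definition", {
    expect_equal(delta5mcPercent(0.55, 0.50), 10)
    expect_equal(delta5mcPercent(0.50, 0.50), 0)
    expect_warning(out <- delta5mcPercent(0.4, 0), "undefined")
    expect_true(is.na(out))
    expect_gte(min(delta5mcPercent(runif(50), runif(50, 0.1, 1))), 0)
})

test_that("gene-level calling follows the max-|DiffScore| rule", {
    ann <- data.frame(probe_id = paste0("cg", 1:8),
                      gene_symbol = rep(c("A", "B", "C", "X"), each = 2),
                      chromosome = c(rep("1", 6), "X", "X"))
    res <- data.frame(probe_id = paste0("cg", 1:8),
                      delta_beta = c(-0.1, -0.05, -0.1, 0.1, -0.2, 0.2,
                                     0.3, 0.3),
                      diff_score = c(-14, -5, -12, 12, -20, 20, 99, 99),
                      delta_5mc_pct = 5,
                      stringsAsFactors = FALSE)
    calls <- callDMGs(res, ann)
    # A: {-14, -5} -> hypo; B: {-12, +12} -> no call;
    # C: {-20, +20} -> ambiguous; X: significant but non-autosomal
    expect_setequal(calls$gene_symbol, c("A", "C"))
    expect_equal(calls$direction[calls$gene_symbol == "A"], "hypo")
    expect_equal(calls$best_diff_score[calls$gene_symbol == "A"], -14)
    expect_equal(calls$direction[calls$gene_symbol == "C"], "ambiguous")
    expect_equal(calls$n_probes_significant[calls$gene_symbol == "A"], 1)
})

test_that("unknown probes are skipped with a message", {
    ann <- data.frame(probe_id = "cg1", gene_symbol = "A",
                      chromosome = "1")
    res <- data.frame(probe_id = c("cg1", "cgZ"), delta_beta = c(0.2, 0.2),
                      diff_score = c(20, 20), delta_5mc_pct = 5)
    expect_message(calls <- callDMGs(res, ann), "absent from annotation")
    expect_equal(calls$gene_symbol, "A")
})

test_that("the DiffScore-13 gate coincides with p < 0.05 probe-by-probe", {
    set.seed(77)
    p <- runif(500)
    db <- rnorm(500)
    ds <- computeDiffScore(p, db)
    gate_ds <- abs(ds) >= -10 * log10(0.05)
    expect_identical(gate_ds, p < 0.05)  # continuous p: ties impossible
    # sign always follows delta-beta
    nz <- db != 0 & p < 1
    expect_true(all(sign(ds[nz]) == sign(db[nz])))
})

test_that("planted methylation effects are recovered at the default gate", {
    cfg <- simConfig(n_probes = 600, n_genes = 300, seed = 31)
    sim <- simulateMethylation(cfg, simulateAnnotation(cfg))
    res <- testProbeDM(maskLowDetection(sim$betaset))
    calls <- callDMGs(res, probeAnnotation(sim$betaset))
    truth_dm <- sim$truth@geneDM
    planted <- truth_dm$gene_symbol[truth_dm$direction != "none"]
    called_ok <- calls$gene_symbol[calls$direction %in% c("hyper", "hypo")]
    expect_gte(mean(planted %in% called_ok), 0.8)
    # recovered directions match the plan
    common <- intersect(planted, called_ok)
    dirs <- structure(calls$direction, names = calls$gene_symbol)
    want <- structure(truth_dm$direction, names = truth_dm$gene_symbol)
    expect_gte(mean(dirs[common] == want[common]), 0.95)
})
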