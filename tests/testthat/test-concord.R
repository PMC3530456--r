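test_that("the direction pair mapping is total and exhaustive", {
    combos <- expand.grid(dm = c("hyper", "hypo"), de = c("up", "down"),
                          stringsAsFactors = FALSE)
    cls <- classifyConcordance(combos$dm, combos$de)
    expect_setequal(cls, c("hyper_up", "hyper_down", "hypo_up",
                           "hypo_down"))
    expect_equal(anyDuplicated(cls), 0)
    expect_identical(isConcordant(cls),
                     cls %in% c("hypo_up", "hyper_down"))
    expect_error(classifyConcordance("ambiguous", "up"), "ambiguous")
})

test_that("published example records classify as expected", {
    # MS4A7: DiffScore -19.0, FC +4.6 -> hypo_up
    expect_equal(classifyConcordance(
        ifelse(-19.0 < 0, "hypo", "hyper"),
        ifelse(4.6 > 0, "up", "down")), "hypo_up")
    # TYRP1: DiffScore +50, FC -7.2 -> hyper_down
    expect_equal(classifyConcordance(
        ifelse(50 < 0, "hypo", "hyper"),
        ifelse(-7.2 > 0, "up", "down")), "hyper_down")
    expect_equal(classifyConcordance("hyper", "up"), "hyper_up")
})

test_that("gene overlap equals brute-force membership", {
    set.seed(15)
    for (i in 1:10) {
        a <- data.frame(gene_symbol = sample(letters, sample(5:20, 1)))
        b <- data.frame(gene_symbol = sample(letters, sample(5:20, 1)))
        brute <- a$gene_symbol[vapply(a$gene_symbol,
                                      function(g) any(b$gene_symbol == g),
                                      logical(1))]
        expect_setequal(overlapGenes(a, b), brute)
    }
    expect_length(overlapGenes(data.frame(gene_symbol = c("a", "b")),
                               data.frame(gene_symbol = c("c", "d"))), 0)
    dm <- data.frame(gene_symbol = c("a", "b"))
    de <- data.frame(gene_symbol = c("a", "b", "c"))
    expect_setequal(overlapGenes(dm, de), dm$gene_symbol)
})

test_that("epigene records join layers and drop ambiguous calls", {
    dmg <- data.frame(gene_symbol = c("A", "B", "C"),
                      direction = c("hypo", "hyper", "ambiguous"),
                      best_diff_score = c(-20, 15, 30),
                      best_probe = paste0("cg", 1:3),
                      delta_beta = c(-0.1, 0.1, 0.2),
                      delta_5mc_pct = c(8, 6, 4),
                      stringsAsFactors = FALSE)
    deg <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                      signed_fc = c(2.0, -1.5, 3, 1.2),
                      direction = c("up", "down", "up", "up"),
                      stringsAsFactors = FALSE)
    expect_message(rec <- buildEpigeneRecords(dmg, deg), "ambiguous")
    expect_setequal(rec$gene_symbol, c("A", "B"))
    expect_equal(rec$concord_class[rec$gene_symbol == "A"], "hypo_up")
    expect_equal(rec$concord_class[rec$gene_symbol == "B"], "hyper_down")
    expect_true(all(rec$concordant))
    expect_warning(buildEpigeneRecords(dmg, deg, warn_unmatched = TRUE),
                   "one omics layer")
    summ <- summarizeIntegration(dmg[dmg$direction != "ambiguous", ],
                                 deg, rec)
    expect_equal(summ$n_common, 2)
    expect_equal(summ$n_concordant, 2)
    expect_lte(summ$n_common, min(summ$n_dmg, summ$n_deg))
})

test_that("summary counts are order-invariant and zero on empty input", {
    empty <- buildEpigeneRecords(
        data.frame(gene_symbol = character(), direction = character(),
                   best_diff_score = numeric(), best_probe = character(),
                   delta_beta = numeric(), delta_5mc_pct = numeric()),
        data.frame(gene_symbol = character(), signed_fc = numeric(),
                   direction = character()))
    s0 <- summarizeIntegration(data.frame(gene_symbol = character()),
                               data.frame(gene_symbol = character()),
                               empty)
    expect_equal(s0$n_concordant, 0)
    expect_equal(s0$pct_hyper_of_common, 0)
    ref <- epigeneReference()
    rec <- data.frame(gene_symbol = ref$gene_symbol,
                      dm_direction = ifelse(ref$diff_score < 0, "hypo",
                                            "hyper"),
                      concord_class = ref$set,
                      stringsAsFactors = FALSE)
    a <- summarizeIntegration(rec, rec, rec)
    b <- summarizeIntegration(rec, rec, rec[sample(nrow(rec)), ])
    expect_equal(a$n_hypo_up, b$n_hypo_up)
    expect_equal(a$n_hyper_down, b$n_hyper_down)
})

test_that("reference fixture reproduces the published 51/61 split", {
    ref <- epigeneReference()
    expect_equal(nrow(ref), 112)
    dm <- ifelse(ref$diff_score < 0, "hypo", "hyper")
    de <- ifelse(ref$fc > 0, "up", "down")
    cls <- classifyConcordance(dm, de)
    expect_equal(sum(cls == "hypo_up"), 51)
    expect_equal(sum(cls == "hyper_down"), 61)
    expect_true(all(isConcordant(cls)))
    # and the sign-derived classes agree with the published set labels
    expect_identical(cls, ref$set)
})

test_that("epigene tables sort by descending |FC| with stable ties", {
    ref <- epigeneReference()
    rec <- data.frame(gene_symbol = ref$gene_symbol,
                      dm_direction = ifelse(ref$diff_score < 0, "hypo",
                                            "hyper"),
                      diff_score = ref$diff_score,
                      delta_5mc_pct = ref$delta_5mc_pct,
                      signed_fc = ref$fc,
                      de_direction = ifelse(ref$fc > 0, "up", "down"),
                      concord_class = ref$set,
                      concordant = TRUE,
                      stringsAsFactors = FALSE)
    dir <- withr::local_tempdir()
    tabs <- writeEpigeneTable(rec, dir)
    expect_equal(tabs$hypo_up$gene_symbol[1], "MS4A7")      # FC 4.6
    expect_equal(tail(tabs$hypo_up$gene_symbol, 1), "PSAP") # FC 1.3
    expect_equal(tabs$hyper_down$gene_symbol[1], "TYRP1")   # FC -7.2
    expect_equal(nrow(tabs$hypo_up), 51)
    expect_equal(nrow(tabs$hyper_down), 61)
    # ties keep input order (stable): TXNIP (1.4) precedes the 1.3 block,
    # SLC35E1 precedes PSAP as in the input
    hu <- tabs$hypo_up$gene_symbol
    expect_lt(which(hu == "SLC35E1"), which(hu == "PSAP"))
    # files written and round-trip readable
    expect_true(file.exists(file.path(dir, "epigenes_hypo_up.tsv")))
    back <- readTsv(file.path(dir, "epigenes_hypo_up.tsv"))
    expect_equal(back$gene_symbol, hu)
})

test_that("reported concordant genes always passed both calling gates", {
    sim <- tinySim(seed = 43)
    bs <- maskLowDetection(sim$betaset)
    probe_res <- testProbeDM(bs)
    dmg <- callDMGs(probe_res, probeAnnotation(bs))
    de <- moderatedT(sim$exprset)
    deg <- callDEGs(de, 0.10)
    rec <- buildEpigeneRecords(dmg, deg)
    conc <- rec[rec$concordant, ]
    expect_true(all(abs(conc$diff_score) >= 13))
    qv <- structure(de$q_value, names = de$gene_symbol)
    expect_true(all(qv[conc$gene_symbol] <= 0.10))
})
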