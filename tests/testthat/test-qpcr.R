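test_that("standard-curve efficiency matches closed forms and oracles", {
    d <- 1 / c(20, 40, 80, 160, 320)
    # perfect doubling: slope -1/log10(2) = -3.3219 cycles per log10 input
    sc <- efficiencyFromStandardCurve(d, 30 - 3.3219 * log10(d * 20))
    expect_equal(efficiency(sc), 2, tolerance = 1e-3)
    expect_equal(sc@r2, 1, tolerance = 1e-12)

    # noisy 5-point curve against the closed-form least-squares oracle
    set.seed(1)
    cts <- 28 - 3.1 * log10(d) + rnorm(5, 0, 0.15)
    x <- log10(d)
    slopeOracle <- cov(x, cts) / var(x)
    sc2 <- suppressWarnings(efficiencyFromStandardCurve(d, cts))
    expect_equal(sc2@slope, slopeOracle, tolerance = 1e-10)
    expect_equal(efficiency(sc2), 10^(-1 / slopeOracle), tolerance = 1e-12)

    # scale invariance in dilution units
    sc3 <- suppressWarnings(efficiencyFromStandardCurve(d * 20, cts))
    expect_equal(sc3@slope, sc2@slope, tolerance = 1e-12)
    expect_equal(efficiency(sc3), efficiency(sc2), tolerance = 1e-12)

    expect_error(efficiencyFromStandardCurve(d[1:2], cts[1:2]), "3 dilution")
    expect_error(efficiencyFromStandardCurve(rep(0.05, 4), rep(20, 4)),
                 "zero variance")
    expect_error(efficiencyFromStandardCurve(d, rep(25, 5)), "slope 0|flat")
    expect_warning(
        efficiencyFromStandardCurve(d, 30 - 2.5 * log10(d * 20)),
        "outside")
})

test_that("efficiency-corrected ratios follow the power formula", {
    # one cycle earlier than calibrator at perfect doubling: twofold
    expect_equal(pfafflRatio(24, 25, 20, 20, 2, 2), 2)
    # common-mode shifts cancel when both genes move identically
    expect_equal(pfafflRatio(22, 25, 17, 20, 2, 2), 1)
    # arithmetic oracle with unequal efficiencies
    expect_equal(pfafflRatio(21.5, 24, 19, 20, 1.9, 2.1),
                 1.9^2.5 / 2.1^1, tolerance = 1e-12)
    expect_error(pfafflRatio(NA, 24, 20, 20, 2, 2), "non-finite")
    expect_error(pfafflRatio(24, 25, 20, 20, 3.5, 2), "\\(1, 3\\)")
    # adding a constant to all Cts of the sample cancels when E_t = E_r
    base <- pfafflRatio(24, 25, 20, 21, 2, 2)
    shifted <- pfafflRatio(24 + 3, 25, 20 + 3, 21, 2, 2)
    expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("Ct simulation and normalisation are mutually inverse", {
    fe <- simulateExperiment(seed = 31)
    genes <- rownames(fe)
    eff <- setNames(seq(1.85, 2.15, length.out = length(genes)), genes)
    ct <- simulateCtTable(fe, eff, seed = 1, replicateSd = 0)
    # duplicates are identical at zero replicate noise
    byRep <- split(ct$ct, paste(ct$sample_id, ct$gene))
    expect_true(all(vapply(byRep, function(v) diff(range(v)) == 0,
                           logical(1))))
    ex <- normalizeCtTable(ct, eff, referenceGene = "eef1a1",
                           calibrator = "sample:calibrator")
    d <- exprTable(fe)
    d <- d[d$gene != "eef1a1", ]
    key <- paste(d$individual_id, d$gene)
    rec <- setNames(ex$relative_expression, paste(ex$sample_id, ex$gene))
    expect_equal(unname(rec[key]), d$relative_expression, tolerance = 1e-9)
})

test_that("the day-0 geometric-mean calibrator rescales as documented", {
    fe <- simulateExperiment(seed = 37)
    genes <- rownames(fe)
    eff <- setNames(rep(2, length(genes)), genes)
    ct <- simulateCtTable(fe, eff, seed = 1, includeCalibrator = FALSE)
    day0 <- colnames(fe)[fe$day == 0]
    ex <- normalizeCtTable(ct, eff, referenceGene = "eef1a1",
                           calibrator = "day0_geomean", day0Samples = day0)
    d <- exprTable(fe)
    g <- "gdh"
    geo <- exp(mean(log(d$relative_expression[d$gene == g &
                        d$individual_id %in% day0])))
    pick <- d$individual_id[d$day > 0][1]
    one <- d[d$gene == g & d$individual_id == pick, ]
    got <- ex$relative_expression[ex$gene == g & ex$sample_id == pick]
    expect_equal(got, one$relative_expression / geo, tolerance = 1e-9)
    # calibrator pseudo-sample itself scores 1 on (geometric) average
    d0 <- ex[ex$gene == g & ex$sample_id %in% day0, ]
    expect_equal(exp(mean(log(d0$relative_expression))), 1, tolerance = 1e-9)
})

test_that("normalisation contract errors name the offender", {
    fe <- simulateExperiment(seed = 41)
    genes <- rownames(fe)
    eff <- setNames(rep(2, length(genes)), genes)
    ct <- simulateCtTable(fe, eff)
    victim <- setdiff(unique(ct$sample_id), "calibrator")[5]
    drop <- ct$sample_id == victim & ct$gene == "eef1a1"
    expect_error(normalizeCtTable(ct[!drop, ], eff,
                                  calibrator = "sample:calibrator"),
                 victim, fixed = TRUE)
    expect_error(normalizeCtTable(ct, eff[-1],
                                  calibrator = "sample:calibrator"),
                 "missing efficiency")
    expect_error(simulateCtTable(fe, eff[-3]), "missing efficiency")
})

test_that("reference stability reports CV, trend and calibrated type-I rate", {
    const <- data.frame(gene = "ref", day = rep(1:5, 2),
                        relative_expression = 1)
    st <- referenceStability(const, "ref")
    expect_equal(st$cv, 0)
    expect_equal(st$slope, 0)

    vals <- data.frame(gene = "ref", day = c(1, 2, 3),
                       relative_expression = c(1, 2, 3))
    st2 <- referenceStability(vals, "ref")
    expect_equal(st2$cv, sd(c(1, 2, 3)) / mean(c(1, 2, 3)), tolerance = 1e-12)

    # stable reference (no trend): the trend flag is a calibrated 5% test
    set.seed(99)
    flags <- vapply(1:400, function(i) {
        d <- data.frame(gene = "ref", day = rep(seq(0, 60, 10), length.out = 100),
                        relative_expression = exp(rnorm(100, 0, 0.29)))
        referenceStability(d, "ref")$trendFlag
    }, logical(1))
    expect_gt(mean(flags), 0.02)
    expect_lt(mean(flags), 0.09)

    expect_error(referenceStability(const[1, , drop = FALSE], "ref"),
                 "at least 2")
})
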