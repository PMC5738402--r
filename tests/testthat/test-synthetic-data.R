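test_that("default design yields the enumerated sacrifice schedule", {
    fe <- simulateExperiment(seed = 3)
    wt <- weightTable(fe)
    # 2 per tank x 5 tanks x 2 groups x 6 post-baseline dates
    expect_equal(sum(wt$day > 0), 120)
    # day-0 baseline drawn from the shared stock at the same per-tank rate
    expect_equal(sum(wt$day == 0), 20)
    expect_true(all(is.na(wt$temperature[wt$day == 0])))
    expect_equal(dim(relExpr(fe)), c(11L, 140L))
    # destructive sampling: every individual appears exactly once
    expect_false(anyDuplicated(wt$individual_id) > 0)
    # each tank loses exactly 2 fish per sampling date
    perTank <- table(wt$tank_id[wt$day > 0], wt$day[wt$day > 0])
    expect_true(all(perTank == 2))
})

test_that("degenerate noise reproduces the truth exactly", {
    dyn <- lapply(
        setNames(nm = c(unlist(defaultGeneRoles()[c("atg", "gdh", "cpt1")],
                               use.names = FALSE), "eef1a1")),
        function(g) list(order = 0L, mode = "none",
                         prof = list("9C" = rep(0.5, 7))))
    tr <- syntheticTruth(
        dynamics = dyn,
        sdLog = setNames(rep(0, length(dyn)), names(dyn)),
        sdW = 1e-12)
    des <- experimentDesign(genes = setdiff(names(dyn), "eef1a1"))
    fe <- simulateExperiment(des, tr, seed = 5)
    expect_equal(as.vector(relExpr(fe)),
                 rep(exp(0.5), length(relExpr(fe))), tolerance = 1e-12)
})

test_that("zero individual noise makes mean log-expression match the polynomial", {
    dyn <- eelFasting:::.defaultGeneDynamics()
    tr <- syntheticTruth(dynamics = dyn,
                         sdLog = setNames(rep(0, length(dyn)), names(dyn)))
    fe <- simulateExperiment(truth = tr, seed = 7)
    d <- exprTable(fe)
    d <- d[d$gene == "gdh" & !is.na(d$temperature), ]
    for (grp in c("9C", "12C")) {
        byDay <- tapply(log(d$relative_expression[d$temperature == grp]),
                        d$day[d$temperature == grp], mean)
        truthVal <- eelFasting:::.trueLogExpression(
            tr, "gdh", grp, as.numeric(names(byDay)), 60)
        expect_equal(as.vector(byDay), truthVal, tolerance = 1e-12)
    }
})

test_that("identical seeds give identical tables; different seeds differ", {
    a <- simulateExperiment(seed = 11)
    b <- simulateExperiment(seed = 11)
    c <- simulateExperiment(seed = 12)
    expect_identical(exprTable(a), exprTable(b))
    expect_identical(weightTable(a), weightTable(b))
    expect_false(isTRUE(all.equal(exprTable(a), exprTable(c))))
})

test_that("per-gene substreams are stable under panel extension", {
    roles <- defaultGeneRoles()
    genesA <- unlist(roles[c("atg", "gdh", "cpt1")], use.names = FALSE)
    genesB <- c(genesA, "catha")
    desA <- experimentDesign(genes = genesA)
    desB <- experimentDesign(genes = genesB)
    feA <- simulateExperiment(desA, seed = 13)
    feB <- simulateExperiment(desB, seed = 13)
    ea <- exprTable(feA)
    ea <- ea[ea$gene %in% genesA, ]
    eb <- exprTable(feB)
    eb <- eb[eb$gene %in% genesA, ]
    expect_equal(ea$relative_expression[order(ea$individual_id, ea$gene)],
                 eb$relative_expression[order(eb$individual_id, eb$gene)])
})

test_that("simulated weight loss converges to the model mean", {
    # 100 experiments x (2 x 50 tanks) = 10 000 draws at each (date, group)
    des <- experimentDesign(tanksPerGroup = 50)
    tr <- syntheticTruth(design = des)
    day <- 30; grp <- "12C"
    mu <- trueMeanWeightLoss(tr, des, day, grp)
    draws <- unlist(lapply(1:100, function(s) {
        wt <- weightTable(simulateExperiment(des, tr, seed = s))
        wt$weight_loss[wt$day == day & !is.na(wt$temperature) &
                       wt$temperature == grp]
    }))
    expect_length(draws, 10000)
    se <- tr@sdW / sqrt(length(draws))
    expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("weight-loss convention and contract errors hold", {
    fe <- simulateExperiment(seed = 17)
    wt <- weightTable(fe)
    expect_equal(wt$weight_loss,
                 100 * (wt$initial_weight_mg - wt$final_weight_mg) /
                     wt$initial_weight_mg, tolerance = 1e-9)
    # truth lacking a design gene is rejected
    tr <- syntheticTruth()
    tr@coefficients[["gdh"]] <- NULL
    expect_error(simulateExperiment(truth = tr, seed = 1), "gdh")
    # over-subscribed sacrifice schedule is rejected
    expect_error(experimentDesign(individualsPerTank = 5),
                 "exceed")
})

test_that("optional tank intercepts perturb expression only when enabled", {
    trOn <- syntheticTruth(tankSd = 0.3)
    trOff <- syntheticTruth(tankSd = 0)
    feOn <- simulateExperiment(truth = trOn, seed = 19)
    feOff <- simulateExperiment(truth = trOff, seed = 19)
    expect_false(isTRUE(all.equal(relExpr(feOn), relExpr(feOff))))
    # same tank, same gene: shared shift; noise-only columns differ freely
    expect_identical(weightTable(feOn)$initial_weight_mg,
                     weightTable(feOff)$initial_weight_mg)
})

test_that("truth config round-trips through YAML", {
    tr <- syntheticTruth()
    path <- tempfile(fileext = ".yaml")
    writeTruthConfig(tr, path)
    tr2 <- readTruthConfig(path)
    expect_equal(tr@coefficients, tr2@coefficients, tolerance = 1e-12)
    expect_equal(tr@alpha, tr2@alpha, tolerance = 1e-12)
    expect_equal(tr@gamma, tr2@gamma)
    fe1 <- simulateExperiment(truth = tr, seed = 23)
    fe2 <- simulateExperiment(truth = tr2, seed = 23)
    expect_equal(relExpr(fe1), relExpr(fe2))
})
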