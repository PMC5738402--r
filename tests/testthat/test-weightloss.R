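# Shared small fixture: one simulated experiment with its production curves.
wlFixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        fe <- simulateExperiment(seed = 71)
        genes6 <- c("ulk1", "lc3b", "atg7", "atg12", "gdh", "cpt1")
        models <- lapply(setNames(nm = genes6), function(g)
            bestModel(selectModel(fe, g)))
        nm <- nullExpressionModel(fe, models)
        pr <- productionCurves(models, nm, temperatures = c("9C", "12C"))
        cache <<- list(fe = fe, models = models, nullModel = nm, prods = pr)
        cache
    }
})

test_that("the weight model pairs observations with curve lookups", {
    fx <- wlFixture()
    wm <- buildWeightModel(fx$prods, fx$fe)
    expect_equal(colnames(wm@X), c("A", "AB", "AC", "B", "C", "null"))
    expect_equal(length(wm@W), 120)  # day-0 rows excluded by default
    wm0 <- buildWeightModel(fx$prods, fx$fe, model = "M0")
    expect_equal(colnames(wm0@X), "null")

    wt <- weightTable(fx$fe)
    wt <- wt[wt$day > 0, ]
    set.seed(73)
    for (i in sample(nrow(wt), 10)) {
        grp <- wt$temperature[i]
        d <- wt$day[i]
        row <- which(wt$individual_id[i] ==
                     wt$individual_id)  # row order preserved by build
        A <- productionAt(fx$prods[[grp]]$A, d)
        B <- productionAt(fx$prods[[grp]]$B, d)
        C <- productionAt(fx$prods[[grp]]$C, d)
        nul <- productionAt(fx$prods[[grp]]$null, d)
        expect_equal(unname(wm@X[row, ]), c(A, A * B, A * C, B, C, nul),
                     tolerance = 1e-12)
    }
    expect_error(buildWeightModel(fx$prods[1], fx$fe), "no production curves")
})

test_that("a pure-A truth makes expected weight loss track P(A) exactly", {
    alpha <- c(1, 0, 0, 0, 0, 0)
    tr <- recoveryTruth(alpha, gamma = 2, sdW = 1e-12)
    des <- experimentDesign()
    curves <- eelFasting:::.trueRegressors(tr, des)
    for (grp in c("9C", "12C")) {
        mu <- trueMeanWeightLoss(tr, des, c(10, 30, 60), grp)
        expect_equal(mu, 2 * productionAt(curves[[grp]]$A, c(10, 30, 60)),
                     tolerance = 1e-9)
    }
})

test_that("MCMC draws are reproducible and chains can be duplicated", {
    fx <- wlFixture()
    wm <- buildWeightModel(fx$prods, fx$fe)
    f1 <- quickMCMC(wm, seed = 1, nDraws = 300)
    f2 <- quickMCMC(wm, seed = 1, nDraws = 300)
    expect_identical(f1@draws, f2@draws)
    f3 <- quickMCMC(wm, seed = 2, nDraws = 300)
    expect_false(identical(f1@draws, f3@draws))
    # same RNG seed in both chains: byte-identical trajectories
    f4 <- runWeightMCMC(wm, nDraws = 300, nChains = 2, seed = 1,
                        nAdapt = 150, nBurn = 150, chainSeeds = c(42, 42))
    expect_identical(f4@draws[[1]], f4@draws[[2]])
    # every alpha draw lies on the simplex
    a9 <- do.call(rbind, f1@draws)[, grep("^alpha\\[9C", f1@paramNames)]
    expect_equal(unname(rowSums(a9)), rep(1, nrow(a9)), tolerance = 1e-9)
})

test_that("the gamma posterior concentrates as observation noise vanishes", {
    des <- experimentDesign()
    alpha <- c(0.4, 0.1, 0.1, 0.2, 0.15, 0.05)
    sdGamma <- vapply(c(0.05, 0.005), function(sw) {
        tr <- recoveryTruth(alpha, gamma = 1, sdW = sw)
        fe <- simulateExperiment(des, tr, seed = 79)
        curves <- eelFasting:::.trueRegressors(tr, des)
        wm <- buildWeightModel(curves, fe, shareTemperature = TRUE)
        fit <- quickMCMC(wm, seed = 3, nDraws = 500)
        sd(do.call(rbind, fit@draws)[, "gamma[pooled]"])
    }, numeric(1))
    expect_lt(sdGamma[2], sdGamma[1])
})

test_that("deviance is invariant to joint rescaling of curves and gamma", {
    fx <- wlFixture()
    wm <- buildWeightModel(fx$prods, fx$fe)
    theta <- setNames(rep(0, length(wm@tempLevels) * 7 + 1),
                      c(paste0("gamma[", wm@tempLevels, "]"),
                        as.vector(t(outer(wm@tempLevels,
                                          c("A", "AB", "AC", "B", "C", "null"),
                            function(g, l) paste0("alpha[", g, ",", l, "]")))),
                        "sdW"))
    theta[paste0("gamma[", wm@tempLevels, "]")] <- c(0.9, 1.1)
    for (g in wm@tempLevels)
        theta[paste0("alpha[", g, ",", c("A", "AB", "AC", "B", "C", "null"),
                     "]")] <- c(0.4, 0.1, 0.1, 0.2, 0.15, 0.05)
    theta["sdW"] <- 0.05
    d1 <- eelFasting:::.weightDeviance(theta, wm)
    # scale single-curve regressors by c, gamma by 1/c (product terms break
    # exact cancellation, so restrict to the M0 structure for exactness)
    wm0 <- buildWeightModel(fx$prods, fx$fe, model = "M0")
    th0 <- c("gamma[9C]" = 0.9, "gamma[12C]" = 1.1, sdW = 0.05)
    d0 <- eelFasting:::.weightDeviance(th0, wm0)
    wm0s <- wm0; wm0s@X <- wm0@X * 3
    th0s <- th0; th0s[1:2] <- th0[1:2] / 3
    expect_equal(eelFasting:::.weightDeviance(th0s, wm0s), d0,
                 tolerance = 1e-12)
    expect_true(is.finite(d1))
})

test_that("split R-hat follows the between/within formula and its limits", {
    set.seed(83)
    ch <- lapply(1:3, function(i)
        matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b"))))
    r <- gelmanRubin(ch, split = FALSE)
    # textbook oracle, coded independently
    for (p in c("a", "b")) {
        draws <- sapply(ch, function(m) m[, p])
        n <- nrow(draws)
        W <- mean(apply(draws, 2, var))
        B <- n * var(colMeans(draws))
        expect_equal(unname(r[p]), sqrt(1 + B / (n * W)), tolerance = 1e-10)
    }
    # duplicated chains: between-chain variance vanishes identically
    dup <- gelmanRubin(list(ch[[1]], ch[[1]]), split = FALSE)
    expect_equal(unname(dup), c(1, 1), tolerance = 1e-12)
    # grossly separated chains blow past the 1.1 convention
    far <- list(matrix(rnorm(1000, 0), ncol = 1,
                       dimnames = list(NULL, "x")),
                matrix(rnorm(1000, 10), ncol = 1,
                       dimnames = list(NULL, "x")))
    expect_gt(gelmanRubin(far, split = FALSE)["x"], 5)
    # split variant catches a drifting single chain
    drift <- list(matrix(seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1),
                         ncol = 1, dimnames = list(NULL, "x")))
    expect_gt(gelmanRubin(drift, split = TRUE)["x"], 1.1)
    expect_error(gelmanRubin(drift, split = FALSE), "2 chains")
    # consistency with the reference implementation, same magnitude
    skip_if_not_installed("coda")
    cd <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                            autoburnin = FALSE, multivariate = FALSE)
    expect_equal(unname(r), unname(cd$psrf[, 1]), tolerance = 0.01)
})

test_that("DIC decomposes exactly and matches the conjugate benchmark", {
    # point-mass posterior: no effective parameters
    drawsPt <- matrix(rep(c(1.5, 0.4), each = 50), ncol = 2,
                      dimnames = list(NULL, c("m", "s")))
    y <- c(1.2, 1.6, 1.4)
    ll <- function(th) sum(dnorm(y, th[["m"]], th[["s"]], log = TRUE))
    d <- dicFromDraws(drawsPt, ll)
    expect_equal(d$pD, 0, tolerance = 1e-10)
    expect_equal(d$DIC, -2 * ll(c(m = 1.5, s = 0.4)), tolerance = 1e-10)

    # normal mean with known variance and flat prior: pD is 1
    set.seed(89)
    n <- 25
    yy <- rnorm(n, 2, 1)
    post <- matrix(rnorm(10000, mean(yy), 1 / sqrt(n)), ncol = 1,
                   dimnames = list(NULL, "mu"))
    d2 <- dicFromDraws(post, function(th)
        sum(dnorm(yy, th[["mu"]], 1, log = TRUE)))
    expect_equal(d2$pD, 1, tolerance = 0.1)

    # identity holds exactly on a real weight-loss fit
    fx <- wlFixture()
    fit <- quickMCMC(buildWeightModel(fx$prods, fx$fe), seed = 5,
                     nDraws = 300)
    expect_equal(fit@dic$DIC, fit@dic$meanDeviance + fit@dic$pD,
                 tolerance = 1e-12)
})

test_that("model comparison checks data identity and reports DIC verbatim", {
    fx <- wlFixture()
    wm0 <- buildWeightModel(fx$prods, fx$fe, model = "M0")
    wm1 <- buildWeightModel(fx$prods, fx$fe, model = "M1")
    f0 <- quickMCMC(wm0, seed = 7, nDraws = 300)
    f1 <- quickMCMC(wm1, seed = 7, nDraws = 300)
    cmp <- compareModels(f0, f1)
    expect_equal(cmp$dic0, f0@dic$DIC)
    expect_equal(cmp$dic1, f1@dic$DIC)
    expect_equal(cmp$deltaDIC, cmp$dic1 - cmp$dic0)
    expect_true(cmp$preferred %in% c("M0", "M1"))
    tie <- compareModels(f1, f1)
    expect_true(tie$tie)
    expect_equal(tie$preferred, "tie")
    # different observations are refused
    feB <- simulateExperiment(seed = 97)
    genes6 <- names(fx$models)
    modelsB <- lapply(setNames(nm = genes6), function(g)
        bestModel(selectModel(feB, g)))
    prB <- productionCurves(modelsB, nullExpressionModel(feB, modelsB),
                            temperatures = c("9C", "12C"))
    fB <- quickMCMC(buildWeightModel(prB, feB, model = "M0"), seed = 7,
                    nDraws = 300)
    expect_error(compareModels(fB, f1), "different")
})

test_that("contribution summaries rescale after removing the linear trend", {
    # point-mass alpha: pure arithmetic
    a <- c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1)  # A, AB, AC, B, C, null
    labs <- c("A", "AB", "AC", "B", "C", "null")
    draws <- matrix(rep(c(1, a, 0.05), each = 40), ncol = 8,
                    dimnames = list(NULL, c("gamma[9C]",
                        paste0("alpha[9C,", labs, "]"), "sdW")))
    wmStub <- new("WeightLossModel", W = 1, X = matrix(1, 1, 6,
                      dimnames = list(NULL, labs)),
                  tempIndex = 1L, tempLevels = "9C", model = "M1",
                  shareTemperature = FALSE, fingerprint = c(1, 1, 1))
    fit <- new("WeightLossFit", draws = list(draws, draws),
               paramNames = colnames(draws), model = wmStub,
               rhat = numeric(), dic = list(), mode = "two_stage", seed = 1)
    cs <- summarizeContributions(fit)
    expect_equal(unname(cs@nullShare["9C"]), 10)
    tab <- contributions(cs)
    # table order: atg, atg*gdh, gdh, atg*cpt1, cpt1 = A, AB, B, AC, C
    expect_equal(tab$contribution,
                 c(0.2, 0.2, 0.2, 0.2, 0.1) / 0.9 * 100, tolerance = 1e-9)
    expect_equal(sum(tab$contribution), 100, tolerance = 1e-9)
    expect_equal(tab$process,
                 c("atg genes", "atg genes * gdh", "gdh",
                   "atg genes * cpt1", "cpt1"))

    # a real posterior also sums to 100 per temperature
    fx <- wlFixture()
    fitR <- quickMCMC(buildWeightModel(fx$prods, fx$fe), seed = 11,
                      nDraws = 300)
    csR <- summarizeContributions(fitR)
    sums <- tapply(contributions(csR)$contribution,
                   contributions(csR)$temperature, sum)
    expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
    # M0 has no contribution decomposition
    wm0 <- buildWeightModel(fx$prods, fx$fe, model = "M0")
    f0 <- quickMCMC(wm0, seed = 11, nDraws = 300)
    expect_error(summarizeContributions(f0), "M1")
})
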