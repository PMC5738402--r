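test_that("design matrices have the documented shapes", {
    days <- rep(seq(0, 60, 10), 2)
    grp <- rep(c("9C", "12C"), each = 7)
    expect_equal(ncol(designMatrix(days, grp, candidateSpec(0, "none"))), 1)
    expect_true(all(designMatrix(days, grp, candidateSpec(0, "none")) == 1))
    expect_equal(ncol(designMatrix(days, grp,
                                   candidateSpec(6, "interaction"),
                                   levels = c("9C", "12C"))), 14)
    expect_equal(ncol(designMatrix(days, grp, candidateSpec(2, "additive"),
                                   levels = c("9C", "12C"))), 4)
    expect_equal(ncol(designMatrix(days, grp,
                                   candidateSpec(0, "intercept_only"),
                                   levels = c("9C", "12C"))), 2)
    expect_error(designMatrix(c(0, 10), "9C", candidateSpec(2)),
                 "unidentifiable")
    # full column rank on 7 distinct days for the whole family
    for (sp in candidateFamily()) {
        X <- designMatrix(days, grp, sp, levels = c("9C", "12C"))
        expect_equal(qr(X)$rank, ncol(X))
    }
})

test_that("OLS recovers exact polynomial truth and the mean identity", {
    cell <- balancedDays(3)
    s <- cell$day / 60
    y <- 0.4 - 1.1 * s + 0.9 * s^2  # exact quadratic, no noise
    d <- longExpr(cell$day, cell$temperature, y)
    m <- suppressWarnings(
        fitPolynomialModel(d, "g", candidateSpec(2, "none"), duration = 60))
    expect_equal(unname(m@coefficients), c(0.4, -1.1, 0.9), tolerance = 1e-10)
    expect_lt(m@sigma2ML, 1e-20)

    set.seed(5)
    d2 <- longExpr(cell$day, cell$temperature, rnorm(nrow(cell)))
    m0 <- fitPolynomialModel(d2, "g", candidateSpec(0, "none"), duration = 60)
    expect_equal(unname(m0@coefficients),
                 mean(log(d2$relative_expression)), tolerance = 1e-12)
})

test_that("coefficients agree with an independent normal-equations oracle", {
    set.seed(7)
    cell <- balancedDays(5)  # 60 observations
    y <- rnorm(nrow(cell), 0.2 * (cell$day / 60), 0.4)
    d <- longExpr(cell$day, cell$temperature, y)
    spec <- candidateSpec(3, "interaction")
    m <- fitPolynomialModel(d, "g", spec, duration = 60)
    X <- designMatrix(cell$day, cell$temperature, spec, 60,
                      levels = m@groups)
    expect_equal(unname(m@coefficients),
                 as.vector(olsOracle(X, y)),
                 tolerance = 1e-8)
})

test_that("AIC follows the declared Gaussian convention", {
    set.seed(11)
    cell <- balancedDays(4)
    y <- rnorm(nrow(cell))
    d <- longExpr(cell$day, cell$temperature, y)
    m <- fitPolynomialModel(d, "g", candidateSpec(2, "additive"),
                            duration = 60)
    X <- designMatrix(cell$day, cell$temperature,
                      candidateSpec(2, "additive"), 60, levels = m@groups)
    rss <- sum((y - X %*% olsOracle(X, y))^2)
    expect_equal(m@aic, aicOracle(rss, nrow(cell), ncol(X)),
                 tolerance = 1e-10)

    # a redundant coefficient that leaves RSS unchanged costs exactly 2:
    # make the response orthogonal to the quadratic column's unique part
    days <- rep(c(0, 30, 60), 8)
    X1 <- cbind(1, days / 60)
    q <- (days / 60)^2
    set.seed(13)
    r <- rnorm(length(days))
    M <- cbind(X1, q)
    r <- r - M %*% solve(crossprod(M), crossprod(M, r))  # orthogonal residual
    y2 <- as.vector(X1 %*% c(0.3, -0.5) + r)
    d2 <- longExpr(days, "9C", y2)
    mLin <- fitPolynomialModel(d2, "g", candidateSpec(1, "none"), 60)
    mQuad <- fitPolynomialModel(d2, "g", candidateSpec(2, "none"), 60)
    expect_equal(mQuad@aic - mLin@aic, 2, tolerance = 1e-8)

    # nested fits can never improve AIC by more than 2 per extra parameter
    set.seed(17)
    for (i in 1:10) {
        yy <- rnorm(nrow(cell))
        dd <- longExpr(cell$day, cell$temperature, yy)
        for (o in 1:4) {
            a1 <- fitPolynomialModel(dd, "g", candidateSpec(o, "none"), 60)@aic
            a2 <- fitPolynomialModel(dd, "g", candidateSpec(o + 1, "none"), 60)@aic
            expect_lte(a2, a1 + 2 + 1e-8)
        }
    }
})

test_that("adjusted R-squared hits its anchor points and formula", {
    set.seed(19)
    cell <- balancedDays(2)
    y <- rnorm(nrow(cell))
    d <- longExpr(cell$day, cell$temperature, y)
    expect_equal(adjustedR2(fitPolynomialModel(d, "g", candidateSpec(0), 60)),
                 0, tolerance = 1e-12)

    days20 <- rep(seq(0, 60, length.out = 10), 2)
    set.seed(23)
    y20 <- 0.1 + 0.8 * days20 / 60 + rnorm(20, 0, 0.3)
    d20 <- longExpr(days20, "9C", y20)
    m1 <- fitPolynomialModel(d20, "g", candidateSpec(1), 60)
    fit <- lm(y20 ~ I(days20 / 60))
    expect_equal(adjustedR2(m1), summary(fit)$adj.r.squared,
                 tolerance = 1e-12)

    # interpolating fit: perfect
    dI <- longExpr(c(0, 30, 60), "9C", c(0.1, 0.5, 0.2))
    mI <- suppressWarnings(fitPolynomialModel(dI, "g", candidateSpec(2), 60))
    expect_equal(adjustedR2(mI), 1, tolerance = 1e-9)
})

test_that("selection is invariant to group labels and coding choices", {
    set.seed(29)
    cell <- balancedDays(4)
    y <- rnorm(nrow(cell), ifelse(cell$temperature == "9C", 0.2, -0.3) *
                   cell$day / 60)
    d <- longExpr(cell$day, cell$temperature, y)
    dRelab <- d
    dRelab$temperature <- ifelse(d$temperature == "9C", "warm", "cold")
    s1 <- selectModel(d, "g", duration = 60)
    s2 <- selectModel(dRelab, "g", duration = 60)
    expect_equal(s1@table$aic, s2@table$aic, tolerance = 1e-9)

    # interaction fitted values equal the two independent per-group fits
    m <- fitPolynomialModel(d, "g", candidateSpec(2, "interaction"), 60)
    for (grp in unique(cell$temperature)) {
        sel <- cell$temperature == grp
        cellFit <- lm(y[sel] ~ poly(cell$day[sel] / 60, 2, raw = TRUE))
        pred <- predictWithInterval(m, cell$day[sel], grp)$median
        expect_equal(log(pred), unname(fitted(cellFit)), tolerance = 1e-8)
    }
})

test_that("the selection table carries all 20 candidates and the minimum", {
    fe <- simulateExperiment(seed = 43)
    sel <- selectModel(fe, "atg12")
    expect_equal(nrow(sel@table), 20)
    expect_equal(sum(sel@table$order == 0), 2)
    expect_equal(as.integer(table(sel@table$mode)[c("additive", "interaction",
                                                    "none")]), c(6L, 6L, 7L))
    expect_equal(bestModel(sel)@aic, min(sel@table$aic))
    expect_error(selectModel(fe, "nosuchgene"), "not present")
})

test_that("prediction intervals behave like mean-response bands", {
    # interpolating fit has zero residual variance: band collapses
    dI <- longExpr(c(0, 30, 60), "9C", c(0.1, 0.5, 0.2))
    mI <- suppressWarnings(fitPolynomialModel(dI, "g", candidateSpec(2), 60))
    pI <- predictWithInterval(mI, c(0, 15, 30), "9C")
    expect_equal(pI$lower, pI$median, tolerance = 1e-9)
    expect_equal(pI$upper, pI$median, tolerance = 1e-9)

    # leverage: width grows monotonically from the design centre outwards
    set.seed(31)
    days <- rep(seq(0, 60, 10), 4)
    d <- longExpr(days, "9C", rnorm(length(days), days / 60, 0.3))
    m <- fitPolynomialModel(d, "g", candidateSpec(1), 60)
    grid <- seq(30, 60, 2.5)
    w <- with(predictWithInterval(m, grid, "9C"), log(upper) - log(lower))
    expect_true(all(diff(w) > 0))
    expect_warning(predictWithInterval(m, 75, "9C"), "extrapolates")

    # nominal 95% coverage of the true mean at design points
    set.seed(37)
    truthY <- function(s) 0.3 - 0.8 * s
    hits <- 0; total <- 0
    for (i in 1:500) {
        dd <- longExpr(days, "9C", truthY(days / 60) + rnorm(length(days), 0, 0.4))
        mm <- fitPolynomialModel(dd, "g", candidateSpec(1), 60)
        pp <- predictWithInterval(mm, seq(0, 60, 10), "9C")
        tv <- exp(truthY(seq(0, 60, 10) / 60))
        hits <- hits + sum(pp$lower <= tv & tv <= pp$upper)
        total <- total + length(tv)
    }
    expect_gt(hits / total, 0.93)
    expect_lt(hits / total, 0.97)
})

test_that("day-0 policies expand or drop the shared baseline coherently", {
    fe <- simulateExperiment(seed = 47)
    mDup <- fitPolynomialModel(fe, "gdh", candidateSpec(2, "interaction"),
                               day0Policy = "duplicate")
    mDrop <- fitPolynomialModel(fe, "gdh", candidateSpec(2, "interaction"),
                                day0Policy = "drop")
    expect_equal(mDup@n, 160)  # 120 assigned + 20 baseline entering twice
    expect_equal(mDrop@n, 120)
    # the order-6 interaction candidate stays identifiable under "duplicate"
    m6 <- fitPolynomialModel(fe, "gdh", candidateSpec(6, "interaction"),
                             day0Policy = "duplicate")
    expect_true(is.finite(m6@aic))
    # but not under "reference" (6 distinct days for the offset curve)
    expect_error(fitPolynomialModel(fe, "gdh", candidateSpec(6, "interaction"),
                                    day0Policy = "reference"), "singular")
})
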