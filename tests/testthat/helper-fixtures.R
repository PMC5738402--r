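# Fixture builders shared across the suite.  Everything is generated in code
# at test time; no stored data.

# Long-format expression table for fitting tests: one gene, arbitrary y.
longExpr <- function(days, groups, y, gene = "g") {
    data.frame(
        individual_id = sprintf("i%03d", seq_along(days)),
        tank_id = "t1",
        temperature = groups,
        day = days,
        gene = gene,
        relative_expression = exp(y),
        stringsAsFactors = FALSE)
}

# Balanced two-group destructive-sampling layout (no day-0 rows).
balancedDays <- function(nPerCell, days = seq(0, 60, 10),
                         groups = c("9C", "12C")) {
    expand.grid(day = rep(days, each = nPerCell), temperature = groups,
                stringsAsFactors = FALSE)
}

# Independent normal-equations OLS oracle (deliberately not the package path).
olsOracle <- function(X, y) {
    XtX <- t(X) %*% X
    solve(XtX, t(X) %*% y)
}

# Independent Gaussian-AIC oracle from raw residuals.
aicOracle <- function(rss, n, p) {
    ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    -2 * ll + 2 * (p + 1)
}

# Truth with the default gene panel but simple noise settings, pooled alpha.
recoveryTruth <- function(alpha, gamma, sdW,
                          design = experimentDesign()) {
    a <- rbind("9C" = alpha, "12C" = alpha)
    colnames(a) <- c("A", "AB", "AC", "B", "C", "null")
    syntheticTruth(alpha = a,
                   gamma = c("9C" = gamma, "12C" = gamma),
                   sdW = sdW, design = design)
}

# Reduced-draw MCMC settings used throughout the suite.
quickMCMC <- function(model, seed, nDraws = 800, nAdapt = 150, nBurn = 150,
                      ...) {
    runWeightMCMC(model, nDraws = nDraws, nChains = 2, seed = seed,
                  nAdapt = nAdapt, nBurn = nBurn, ...)
}
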