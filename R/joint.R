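## Joint hierarchical sampler: expression-model coefficients and weight-loss
## parameters are drawn in one MCMC, so uncertainty in the fitted expression
## curves propagates into the production regressors and the contributions.
## The production integrals are evaluated inside the model graph by the same
## composite trapezoid as the two-stage path, on a coarser grid (default
## 1 day) to keep the graph tractable; curves are unit-normalised at the
## horizon via their temperature-pooled maximum, as in the two-stage path.

.jointGeneBlock <- function(i, kg) {
    sprintf("
  for (c in 1:%1$d) { beta%2$d[c] ~ dnorm(0, 1.0E-4) }
  tauE%2$d ~ dgamma(0.001, 0.001)
  for (r in 1:NE%2$d) {
    y%2$d[r] ~ dnorm(inprod(XE%2$d[r, 1:%1$d], beta%2$d[1:%1$d]), tauE%2$d)
  }
  for (j in 1:G) {
    for (t in 1:T) {
      lE%2$d[j, t] <- inprod(GB%2$d[j, t, 1:%1$d], beta%2$d[1:%1$d])
    }
  }", kg, i)
}

.jointModelString <- function(kgs, model = "M1") {
    blocks <- paste(vapply(seq_along(kgs), function(i)
        .jointGeneBlock(i, kgs[i]), character(1)), collapse = "\n")
    paste0("model {\n", blocks, "
  for (j in 1:G) {
    for (t in 1:T) {
      fA[j, t] <- exp(lE1[j, t] + lE2[j, t] + lE3[j, t] + lE4[j, t])
      fB[j, t] <- exp(lE5[j, t])
      fC[j, t] <- exp(lE6[j, t])
    }
    PA[j, 1] <- 0; PB[j, 1] <- 0; PC[j, 1] <- 0
    for (t in 2:T) {
      PA[j, t] <- PA[j, t - 1] + h / 2 * (fA[j, t - 1] + fA[j, t])
      PB[j, t] <- PB[j, t - 1] + h / 2 * (fB[j, t - 1] + fB[j, t])
      PC[j, t] <- PC[j, t - 1] + h / 2 * (fC[j, t - 1] + fC[j, t])
    }
    PAend[j] <- PA[j, T]; PBend[j] <- PB[j, T]; PCend[j] <- PC[j, T]
  }
  denA <- max(PAend); denB <- max(PBend); denC <- max(PCend)
",
    if (model == "M1") "
  for (j in 1:GW) {
    for (k in 1:6) { e[j, k] ~ dgamma(1, 1) }
    for (k in 1:6) { alpha[j, k] <- e[j, k] / sum(e[j, 1:6]) }
    gamma[j] ~ dunif(0, 1000)
  }
  sdW ~ dt(0, 0.01, 1) T(0,)
  tau <- pow(sdW, -2)
  for (i in 1:N) {
    sA[i] <- PA[tempCurve[i], dayIdx[i]] / denA
    sB[i] <- PB[tempCurve[i], dayIdx[i]] / denB
    sC[i] <- PC[tempCurve[i], dayIdx[i]] / denC
    mu[i] <- gamma[tempW[i]] * (alpha[tempW[i], 1] * sA[i] +
             alpha[tempW[i], 2] * sA[i] * sB[i] +
             alpha[tempW[i], 3] * sA[i] * sC[i] +
             alpha[tempW[i], 4] * sB[i] +
             alpha[tempW[i], 5] * sC[i] +
             alpha[tempW[i], 6] * Pnull[dayIdx[i]])
    W[i] ~ dnorm(mu[i], tau)
  }
}" else "
  for (j in 1:GW) { gamma[j] ~ dunif(0, 1000) }
  sdW ~ dt(0, 0.01, 1) T(0,)
  tau <- pow(sdW, -2)
  for (i in 1:N) {
    mu[i] <- gamma[tempW[i]] * Pnull[dayIdx[i]]
    W[i] ~ dnorm(mu[i], tau)
  }
}")
}

#' Joint hierarchical MCMC over expression and weight-loss models
#'
#' Samples the selected expression polynomials' coefficients (Gaussian(0,
#' sd = 100) priors on the scaled-time basis, i.e. effectively
#' non-informative) jointly with the weight-loss parameters; the cumulated
#' productions are recomputed from the current coefficients inside the
#' model at every step.  Candidate selection itself stays upstream (the
#' per-gene specs are those retained by the AIC stage).
#'
#' @param fe a \linkS4class{FastingExperiment}.
#' @param models named list of fitted
#'   \linkS4class{PolynomialExpressionModel}s whose specs define the
#'   sampled curves (must cover the four autophagy genes and the two
#'   catabolic markers).
#' @param roles gene-role map.
#' @param model `"M1"` or `"M0"`.
#' @param shareTemperature pool weight-loss parameters across groups?
#' @param horizon trial length (days).
#' @param gridStep integration grid step inside the sampler (days).
#' @param day0Policy shared-baseline handling for the expression rows.
#' @param nDraws,nChains,seed,nAdapt,nBurn MCMC settings (joint-mode
#'   defaults are reduced; the graph is much larger than the two-stage one).
#' @param quiet suppress JAGS output.
#' @return A \linkS4class{WeightLossFit} with `mode = "joint"`.
#' @export
runJointWeightMCMC <- function(fe, models, roles = defaultGeneRoles(),
                               model = "M1", shareTemperature = FALSE,
                               horizon = NULL, gridStep = 1,
                               day0Policy = "duplicate",
                               nDraws = 2000, nChains = 2, seed = 1,
                               nAdapt = 300, nBurn = 300, quiet = TRUE) {
    genes6 <- c(roles$atg, roles$gdh, roles$cpt1)
    miss <- setdiff(genes6, names(models))
    if (length(miss))
        stop("missing model(s) for: ", paste(miss, collapse = ", "))
    if (is.null(horizon)) horizon <- max(fe$day)
    temps <- levels(droplevels(factor(fe$temperature)))
    G <- length(temps)
    grid <- .productionGrid(horizon, gridStep)
    T <- length(grid)
    expr <- exprTable(fe)

    dat <- list(G = G, T = T, h = gridStep,
                Pnull = grid / horizon)
    kgs <- integer(6)
    for (i in seq_along(genes6)) {
        g <- genes6[i]
        m <- models[[g]]
        spec <- m@spec
        d <- expr[expr$gene == g, ]
        pl <- .applyDay0Policy(log(d$relative_expression), d$day,
                               as.character(d$temperature), temps, day0Policy)
        if (spec@temperatureMode == "none") pl$groups[] <- temps[1]
        XE <- designMatrix(pl$days, pl$groups, spec, horizon, levels = temps)
        kgs[i] <- ncol(XE)
        GB <- array(0, c(G, T, ncol(XE)))
        for (j in seq_len(G)) {
            grp <- if (spec@temperatureMode == "none") temps[1] else temps[j]
            GB[j, , ] <- designMatrix(grid, rep(grp, T), spec, horizon,
                                      levels = temps)
        }
        dat[[paste0("XE", i)]] <- XE
        dat[[paste0("y", i)]] <- pl$y
        dat[[paste0("NE", i)]] <- length(pl$y)
        dat[[paste0("GB", i)]] <- GB
    }
    wt <- weightTable(fe)
    keep <- !is.na(wt$weight_loss) & !is.na(wt$temperature) & wt$day > 0
    wt <- wt[keep, ]
    idx <- vapply(wt$day, function(d) which.min(abs(grid - d)), integer(1))
    if (max(abs(grid[idx] - wt$day)) > 1e-8)
        stop("sacrifice days must lie on the joint-mode integration grid")
    dat$W <- wt$weight_loss
    dat$N <- nrow(wt)
    ## weight-loss parameters may pool across groups (tempW), but the curves
    ## always keep their true group (tempCurve)
    dat$tempCurve <- match(wt$temperature, temps)
    dat$tempW <- if (shareTemperature) rep(1L, nrow(wt)) else dat$tempCurve
    dat$dayIdx <- idx
    tempLevels <- if (shareTemperature) "pooled" else temps
    GW <- length(tempLevels)
    dat$GW <- GW
    mstr <- .jointModelString(kgs, model)
    chainSeeds <- (as.integer(seed) %% 1000000L) * 1013L + seq_len(nChains)
    inits <- lapply(chainSeeds, function(s) {
        ini <- list(.RNG.name = "base::Mersenne-Twister",
                    .RNG.seed = as.integer(s),
                    gamma = rep(max(mean(abs(dat$W)), 0.1), GW),
                    sdW = max(sd(dat$W), 0.01))
        if (model == "M1") ini$e <- matrix(1, GW, 6)
        for (i in seq_along(genes6))
            ini[[paste0("beta", i)]] <-
                as.vector(models[[genes6[i]]]@coefficients)
        ini
    })
    jm <- rjags::jags.model(textConnection(mstr), data = dat, inits = inits,
                            n.chains = nChains, n.adapt = nAdapt,
                            quiet = quiet)
    stats::update(jm, nBurn, progress.bar = "none")
    monitors <- c("gamma", "sdW", "mu", if (model == "M1") "alpha")
    sam <- rjags::jags.samples(jm, monitors, n.iter = nDraws,
                               progress.bar = "none")
    chains <- .mcarrayToChains(sam, tempLevels, model)
    ## DIC on the weight-loss focus: deviance per draw from the monitored mu
    nIter <- dim(sam$mu)[2]
    devDraws <- matrix(0, nIter, nChains)
    for (ch in seq_len(nChains)) {
        muM <- sam$mu[, , ch]
        sdv <- sam$sdW[1, , ch]
        devDraws[, ch] <- vapply(seq_len(nIter), function(it)
            -2 * sum(dnorm(dat$W, muM[, it], sdv[it], log = TRUE)),
            numeric(1))
    }
    muHat <- apply(sam$mu, 1, mean)
    sdHat <- mean(sam$sdW)
    dbar <- mean(devDraws)
    dhat <- -2 * sum(dnorm(dat$W, muHat, sdHat, log = TRUE))
    ## regressor matrix at the posterior-mean curves is not reconstructed
    ## here; the fingerprint ties comparisons to the same observations
    wmShell <- new("WeightLossModel", W = dat$W,
                   X = matrix(dat$Pnull[dat$dayIdx], ncol = 1,
                              dimnames = list(NULL, "null")),
                   tempIndex = as.integer(dat$tempW), tempLevels = tempLevels,
                   model = model, shareTemperature = shareTemperature,
                   fingerprint = c(length(dat$W), sum(dat$W), sum(dat$W^2)))
    fit <- new("WeightLossFit", draws = chains,
               paramNames = colnames(chains[[1]]),
               model = wmShell, rhat = numeric(),
               dic = list(DIC = dbar + (dbar - dhat), pD = dbar - dhat,
                          meanDeviance = dbar, devianceAtMean = dhat),
               mode = "joint", seed = as.numeric(seed))
    fit@rhat <- gelmanRubin(fit)
    fit
}
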