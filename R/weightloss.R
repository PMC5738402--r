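#' Assemble the weight-loss regression model
#'
#' Pairs each sacrificed individual's observed weight loss with its
#' production regressors evaluated at its own sacrifice day and temperature.
#' Model M1 uses the six terms `A`, `A*B`, `A*C`, `B`, `C`, `null` (products
#' of cumulated productions, not of expression curves); the reference model
#' M0 uses the single `null` regressor, i.e. a pure linear-trend model of
#' weight loss.
#'
#' @param productions nested curve list from [productionCurves()]
#'   (`productions[[group]][[label]]`).
#' @param weights a weight table (from [weightTable()]) or a
#'   \linkS4class{FastingExperiment}.
#' @param model `"M1"` or `"M0"`.
#' @param shareTemperature pool gamma (and alpha) across temperature groups?
#' @param includeDay0 keep day-0 rows (weight loss 0 by construction)?
#'   Default drops them.
#' @return A \linkS4class{WeightLossModel}.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' fit <- lapply(setNames(nm = c("ulk1","lc3b","atg7","atg12","gdh","cpt1")),
#'               function(g) bestModel(selectModel(fe, g)))
#' nm <- nullExpressionModel(fe, fit)
#' pr <- productionCurves(fit, nm)
#' wm <- buildWeightModel(pr, fe)
#' @export
buildWeightModel <- function(productions, weights, model = c("M1", "M0"),
                             shareTemperature = FALSE, includeDay0 = FALSE) {
    model <- match.arg(model)
    wt <- if (is(weights, "FastingExperiment")) weightTable(weights) else weights
    keep <- !is.na(wt$weight_loss) & !is.na(wt$temperature)
    if (!includeDay0) keep <- keep & wt$day > 0
    wt <- wt[keep, , drop = FALSE]
    tempLevels <- names(productions)
    bad <- setdiff(unique(wt$temperature), tempLevels)
    if (length(bad))
        stop("no production curves for temperature group(s): ",
             paste(bad, collapse = ", "))
    lookup <- function(lab, grp, day)
        productionAt(productions[[grp]][[lab]], day)
    X <- matrix(0, nrow(wt), if (model == "M1") 6L else 1L)
    for (grp in tempLevels) {
        sel <- wt$temperature == grp
        if (!any(sel)) next
        d <- wt$day[sel]
        if (model == "M1") {
            A <- lookup("A", grp, d); B <- lookup("B", grp, d)
            C <- lookup("C", grp, d); nul <- lookup("null", grp, d)
            X[sel, ] <- cbind(A, A * B, A * C, B, C, nul)
        } else {
            X[sel, 1] <- lookup("null", grp, d)
        }
    }
    colnames(X) <- if (model == "M1") c("A", "AB", "AC", "B", "C", "null")
                   else "null"
    W <- wt$weight_loss
    new("WeightLossModel", W = W, X = X,
        tempIndex = if (shareTemperature) rep(1L, nrow(wt))
                    else match(wt$temperature, tempLevels),
        tempLevels = if (shareTemperature) "pooled" else tempLevels,
        model = model, shareTemperature = shareTemperature,
        fingerprint = c(length(W), sum(W), sum(W^2)))
}

setMethod("show", "WeightLossModel", function(object) {
    cat(sprintf("WeightLossModel %s: n = %d, %d regressor(s), groups: %s\n",
        object@model, length(object@W), ncol(object@X),
        paste(object@tempLevels, collapse = ", ")))
})

## JAGS model strings.  alpha is given its Dirichlet(1,...,1) prior through
## the gamma-variate construction e_k ~ Gamma(1,1), alpha = e/sum(e), which
## keeps every stochastic node scalar (slice-sampled) while preserving the
## simplex constraint exactly.
.jagsStringM1 <- "model {
  for (j in 1:G) {
    for (k in 1:6) { e[j, k] ~ dgamma(1, 1) }
    for (k in 1:6) { alpha[j, k] <- e[j, k] / sum(e[j, 1:6]) }
    gamma[j] ~ dunif(0, 1000)
  }
  sdW ~ dt(0, 0.01, 1) T(0,)
  tau <- pow(sdW, -2)
  for (i in 1:N) {
    mu[i] <- gamma[temp[i]] * inprod(X[i, 1:6], alpha[temp[i], 1:6])
    W[i] ~ dnorm(mu[i], tau)
  }
}"

.jagsStringM0 <- "model {
  for (j in 1:G) { gamma[j] ~ dunif(0, 1000) }
  sdW ~ dt(0, 0.01, 1) T(0,)
  tau <- pow(sdW, -2)
  for (i in 1:N) {
    mu[i] <- gamma[temp[i]] * X[i, 1]
    W[i] ~ dnorm(mu[i], tau)
  }
}"

## Convert rjags mcarray output to per-chain draw matrices with flat names.
.mcarrayToChains <- function(sam, groups, model) {
    nChains <- dim(sam$gamma)[length(dim(sam$gamma))]
    alphaLabs <- c("A", "AB", "AC", "B", "C", "null")
    lapply(seq_len(nChains), function(ch) {
        cols <- list()
        g <- sam$gamma
        for (j in seq_along(groups))
            cols[[paste0("gamma[", groups[j], "]")]] <- g[j, , ch]
        if (model == "M1") {
            a <- sam$alpha
            for (j in seq_along(groups))
                for (k in 1:6)
                    cols[[paste0("alpha[", groups[j], ",", alphaLabs[k], "]")]] <-
                        a[j, k, , ch]
        }
        cols[["sdW"]] <- sam$sdW[1, , ch]
        do.call(cbind, cols)
    })
}

#' Sample the weight-loss posterior by MCMC
#'
#' Gibbs/slice sampling via JAGS under the declared priors: contribution
#' vector alpha ~ Dirichlet(1,1,1,1,1,1) per temperature (via the
#' gamma-variate construction), gamma ~ Uniform(0, 1000) per temperature,
#' observation noise sd ~ half-Cauchy(0, 10).  Draws are reproducible given
#' `seed` (per-chain RNG seeds are derived from it); split-chain R-hat and
#' the DIC decomposition are computed from the raw draws on return.
#'
#' @param model a \linkS4class{WeightLossModel}.
#' @param nDraws retained draws per chain.
#' @param nChains number of chains (>= 2 for convergence diagnostics).
#' @param seed master seed.
#' @param nAdapt,nBurn adaptation and burn-in iterations.
#' @param chainSeeds optional explicit per-chain RNG seeds (e.g. identical
#'   seeds to verify that duplicated chains are byte-identical).
#' @param quiet suppress JAGS progress output.
#' @return A \linkS4class{WeightLossFit}.
#' @examples
#' \donttest{
#' fe <- simulateExperiment(seed = 1)
#' fit <- fitWeightLossModel(fe, nDraws = 500, seed = 1)
#' }
#' @export
runWeightMCMC <- function(model, nDraws = 10000, nChains = 2, seed = 1,
                          nAdapt = 500, nBurn = 500, chainSeeds = NULL,
                          quiet = TRUE) {
    stopifnot(is(model, "WeightLossModel"))
    G <- length(model@tempLevels)
    dat <- list(W = model@W, X = model@X, N = length(model@W),
                temp = model@tempIndex, G = G)
    mstr <- if (model@model == "M1") .jagsStringM1 else .jagsStringM0
    if (is.null(chainSeeds))
        chainSeeds <- (as.integer(seed) %% 1000000L) * 1009L +
            seq_len(nChains)
    inits <- lapply(chainSeeds, function(s) {
        ini <- list(.RNG.name = "base::Mersenne-Twister",
                    .RNG.seed = as.integer(s),
                    gamma = rep(max(mean(abs(model@W)), 0.1), G),
                    sdW = max(sd(model@W), 0.01))
        if (model@model == "M1") ini$e <- matrix(1, G, 6)
        ini
    })
    jm <- NULL
    for (attempt in 1:3) {
        jm <- tryCatch(
            rjags::jags.model(textConnection(mstr), data = dat, inits = inits,
                              n.chains = nChains, n.adapt = nAdapt,
                              quiet = quiet),
            error = function(e) e)
        if (!inherits(jm, "error")) break
        inits <- lapply(inits, function(i) {
            i$.RNG.seed <- i$.RNG.seed + 7919L
            i$gamma <- i$gamma * 0.5
            i
        })
    }
    if (inherits(jm, "error"))
        stop("MCMC initialisation failed after 3 attempts: ",
             conditionMessage(jm))
    stats::update(jm, nBurn, progress.bar = "none")
    monitors <- c("gamma", "sdW", if (model@model == "M1") "alpha")
    sam <- rjags::jags.samples(jm, monitors, n.iter = nDraws,
                               progress.bar = "none")
    chains <- .mcarrayToChains(sam, model@tempLevels, model@model)
    fit <- new("WeightLossFit", draws = chains,
               paramNames = colnames(chains[[1]]),
               model = model, rhat = numeric(), dic = list(),
               mode = "two_stage", seed = as.numeric(seed))
    fit@rhat <- gelmanRubin(fit)
    fit@dic <- dic(fit)
    fit
}

## Deviance (-2 log likelihood) of the weight observation model for one
## named parameter vector.
.weightDeviance <- function(theta, model) {
    G <- length(model@tempLevels)
    gamma <- theta[paste0("gamma[", model@tempLevels, "]")]
    sdW <- theta[["sdW"]]
    if (model@model == "M1") {
        labs <- c("A", "AB", "AC", "B", "C", "null")
        alpha <- t(vapply(model@tempLevels, function(g)
            theta[paste0("alpha[", g, ",", labs, "]")], numeric(6)))
        mu <- gamma[model@tempIndex] *
            rowSums(model@X * alpha[model@tempIndex, , drop = FALSE])
    } else {
        mu <- gamma[model@tempIndex] * model@X[, 1]
    }
    -2 * sum(dnorm(model@W, mu, sdW, log = TRUE))
}

#' End-to-end weight-loss inference from an experiment
#'
#' Convenience wrapper chaining the full analysis: per-gene AIC selection
#' over the 20-candidate family, null-gene model, production-curve
#' integration, and MCMC on the weight-loss model.  `mode = "two_stage"`
#' (default) plugs the Stage-1 least-squares curves into the weight model;
#' `mode = "joint"` samples the expression-model coefficients alongside the
#' weight-loss parameters in one hierarchical model (see
#' [runJointWeightMCMC()]), propagating expression-curve uncertainty.
#'
#' @param fe a \linkS4class{FastingExperiment}.
#' @param roles gene-role map, see [defaultGeneRoles()].
#' @param model `"M1"` or `"M0"`.
#' @param mode `"two_stage"` or `"joint"`.
#' @param shareTemperature pool parameters across temperature groups?
#' @param horizon,step integration settings (days).
#' @param day0Policy passed to [selectModel()].
#' @param nDraws,nChains,seed,nAdapt,nBurn MCMC settings.
#' @param selections optional precomputed list of
#'   \linkS4class{ModelSelectionResult} (avoids refitting).
#' @param ... passed to the sampler.
#' @return A \linkS4class{WeightLossFit}.
#' @export
fitWeightLossModel <- function(fe, roles = defaultGeneRoles(),
                               model = "M1",
                               mode = c("two_stage", "joint"),
                               shareTemperature = FALSE,
                               horizon = NULL, step = 0.05,
                               day0Policy = "duplicate",
                               nDraws = 10000, nChains = 2, seed = 1,
                               nAdapt = 500, nBurn = 500,
                               selections = NULL, ...) {
    mode <- match.arg(mode)
    targetGenes <- unique(c(roles$atg, roles$lysosomal, roles$gdh, roles$cpt1))
    targetGenes <- intersect(targetGenes, rownames(fe))
    if (is.null(horizon)) horizon <- max(fe$day)
    if (is.null(selections)) {
        fitGenes <- if (mode == "two_stage") targetGenes
                    else c(roles$atg, roles$gdh, roles$cpt1)
        selections <- lapply(setNames(nm = fitGenes), function(g)
            selectModel(fe, g, day0Policy = day0Policy, duration = horizon))
    }
    models <- lapply(selections, bestModel)
    if (mode == "joint")
        return(runJointWeightMCMC(fe, models, roles = roles, model = model,
                                  shareTemperature = shareTemperature,
                                  horizon = horizon, nDraws = nDraws,
                                  nChains = nChains, seed = seed,
                                  nAdapt = nAdapt, nBurn = nBurn,
                                  day0Policy = day0Policy, ...))
    nm <- nullExpressionModel(fe, models[intersect(targetGenes, names(models))])
    temps <- levels(droplevels(factor(fe$temperature)))
    prods <- productionCurves(models, nm, roles = roles,
                              temperatures = temps,
                              horizon = horizon, step = step)
    wm <- buildWeightModel(prods, fe, model = model,
                           shareTemperature = shareTemperature)
    runWeightMCMC(wm, nDraws = nDraws, nChains = nChains, seed = seed,
                  nAdapt = nAdapt, nBurn = nBurn, ...)
}

setMethod("show", "WeightLossFit", function(object) {
    nIter <- nrow(object@draws[[1]])
    cat(sprintf("WeightLossFit (%s, %s): %d chain(s) x %d draws\n",
        object@model@model, object@mode, length(object@draws), nIter))
    all <- do.call(rbind, object@draws)
    sm <- data.frame(mean = colMeans(all), sd = apply(all, 2, sd),
                     rhat = object@rhat[colnames(all)])
    print(round(sm, 4))
    if (length(object@dic))
        cat(sprintf("DIC %.2f (pD %.2f, mean deviance %.2f)\n",
            object@dic$DIC, object@dic$pD, object@dic$meanDeviance))
})
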