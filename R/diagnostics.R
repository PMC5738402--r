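#' Gelman-Rubin potential scale reduction factor
#'
#' Per-parameter R-hat comparing between- and within-chain variability:
#' `R = sqrt(1 + B/(n W))` where `W` is the mean within-chain variance and
#' `B = n var(chain means)`.  The shrinkage-free form keeps `R >= 1` by
#' construction and makes byte-identical chains score exactly 1.  With
#' `split = TRUE` (the default, used for real diagnostics) each chain is
#' first halved so that a drifting single chain also inflates `R`.
#' Convergence is conventionally declared below 1.1.
#'
#' @param x a list of draw matrices (iterations x parameters, equal sizes)
#'   or a \linkS4class{WeightLossFit}.
#' @param split halve each chain before comparing?
#' @param ... unused.
#' @return Named numeric vector of R-hat values.
#' @examples
#' ch <- lapply(1:2, function(i) matrix(rnorm(2000), ncol = 2,
#'                                      dimnames = list(NULL, c("a", "b"))))
#' gelmanRubin(ch)
#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "list", function(x, split = TRUE, ...) {
    if (length(x) < 2 && !split)
        stop("at least 2 chains required (or use split = TRUE)")
    ns <- vapply(x, nrow, integer(1))
    if (length(unique(ns)) != 1) stop("chains must have equal length")
    if (split) {
        h <- floor(ns[1] / 2)
        x <- unlist(lapply(x, function(m)
            list(m[seq_len(h), , drop = FALSE],
                 m[seq(nrow(m) - h + 1, nrow(m)), , drop = FALSE])),
            recursive = FALSE)
    }
    n <- nrow(x[[1]])
    params <- colnames(x[[1]])
    if (is.null(params)) params <- paste0("par", seq_len(ncol(x[[1]])))
    vapply(seq_along(params), function(p) {
        draws <- vapply(x, function(m) m[, p], numeric(n))
        W <- mean(apply(draws, 2, var))
        B <- n * var(colMeans(draws))
        if (W == 0) return(if (B == 0) 1 else Inf)
        sqrt(1 + B / (n * W))
    }, numeric(1)) |> setNames(params)
})

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "WeightLossFit", function(x, split = TRUE, ...) {
    if (length(x@draws) < 2 && !split)
        stop("single chain: rerun with nChains >= 2 for diagnostics")
    gelmanRubin(x@draws, split = split)
})

#' Deviance Information Criterion from posterior draws
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters, evaluated
#' at the posterior mean of the parameters.  The decomposition identity
#' holds exactly by construction.
#'
#' @param draws matrix of draws (or list of chain matrices, row-bound).
#' @param logLikFun function(named parameter vector) -> log-likelihood.
#' @return list(DIC, pD, meanDeviance, devianceAtMean).
#' @examples
#' ## conjugate normal-mean model: pD is close to 1
#' y <- rnorm(20); draws <- cbind(mu = rnorm(1e4, mean(y), 1 / sqrt(20)))
#' dicFromDraws(draws, function(th) sum(dnorm(y, th[["mu"]], 1, log = TRUE)))
#' @export
dicFromDraws <- function(draws, logLikFun) {
    if (is.list(draws)) draws <- do.call(rbind, draws)
    dev <- apply(draws, 1, function(th) -2 * logLikFun(th))
    if (!all(is.finite(dev)))
        stop("non-finite deviance at some draws")
    dbar <- mean(dev)
    thetaHat <- colMeans(draws)
    dhat <- -2 * logLikFun(thetaHat)
    pD <- dbar - dhat
    list(DIC = dbar + pD, pD = pD, meanDeviance = dbar, devianceAtMean = dhat)
}

#' @describeIn dicFromDraws DIC of a fitted weight-loss posterior (the
#'   posterior mean of alpha lies on the simplex automatically, since every
#'   draw does).
#' @param object a \linkS4class{WeightLossFit}.
#' @param ... unused.
#' @export
setMethod("dic", "WeightLossFit", function(object, ...) {
    model <- object@model
    dicFromDraws(object@draws,
                 function(th) -0.5 * .weightDeviance(th, model))
})

#' Compare two weight-loss models by DIC
#'
#' @param fit0,fit1 \linkS4class{WeightLossFit} objects fitted on the same
#'   weight observations (checked by data fingerprint), conventionally the
#'   null-trend model M0 and the transcript model M1.
#' @return list(dic0, dic1, deltaDIC = dic1 - dic0, preferred, tie).
#' @export
compareModels <- function(fit0, fit1) {
    f0 <- fit0@model@fingerprint
    f1 <- fit1@model@fingerprint
    if (max(abs(f0 - f1)) > 1e-6 * max(1, max(abs(f0))))
        stop("models were fitted on different weight-loss data")
    d0 <- fit0@dic$DIC
    d1 <- fit1@dic$DIC
    tie <- isTRUE(all.equal(d0, d1))
    list(dic0 = d0, dic1 = d1, deltaDIC = d1 - d0,
         preferred = if (tie) "tie" else if (d1 < d0)
             fit1@model@model else fit0@model@model,
         tie = tie)
}

#' Relative-contribution summary of the transcript model
#'
#' The null-gene linear-trend share is the posterior mean of the sixth
#' contribution weight (in percent); the remaining five contributions are
#' rescaled draw-by-draw to sum to one, then summarised as mean (percent)
#' and posterior sd (on the 0-1 rescaled scale), grouped as: atg genes,
#' atg genes * gdh, gdh, atg genes * cpt1, cpt1.
#'
#' @param object a \linkS4class{WeightLossFit} for model M1.
#' @param ... unused.
#' @return A \linkS4class{ContributionSummary}.
#' @rdname summarizeContributions
#' @export
setMethod("summarizeContributions", "WeightLossFit", function(object, ...) {
    if (object@model@model != "M1")
        stop("contributions are defined for model M1 only")
    draws <- do.call(rbind, object@draws)
    groups <- object@model@tempLevels
    procLabs <- c("atg genes", "atg genes * gdh", "gdh",
                  "atg genes * cpt1", "cpt1")
    ## column order in draws: A, AB, AC, B, C; table order: A, AB, B, AC, C
    ord <- c("A", "AB", "B", "AC", "C")
    rows <- list(); nullShare <- setNames(numeric(0), character(0))
    for (g in groups) {
        cols <- paste0("alpha[", g, ",", c(ord, "null"), "]")
        miss <- setdiff(cols, colnames(draws))
        if (length(miss))
            stop("posterior lacks component(s): ", paste(miss, collapse = ", "))
        a <- draws[, cols[1:5], drop = FALSE]
        r <- a / rowSums(a)
        rows[[g]] <- data.frame(
            process = procLabs, temperature = g,
            contribution = colMeans(r) * 100,
            sd = apply(r, 2, sd), stringsAsFactors = FALSE)
        nullShare[g] <- mean(draws[, cols[6]]) * 100
    }
    tab <- do.call(rbind, rows); rownames(tab) <- NULL
    new("ContributionSummary", table = tab, nullShare = nullShare)
})

#' @rdname contributions
#' @param object a \linkS4class{ContributionSummary}.
#' @param ... unused.
#' @return The contribution table (data.frame).
#' @export
setMethod("contributions", "ContributionSummary",
    function(object, ...) object@table)

setMethod("show", "ContributionSummary", function(object) {
    cat("Relative contributions (%) after removing the linear trend:\n")
    for (g in names(object@nullShare)) {
        cat(sprintf("  [%s] linear trend (null gene): %.2f%%\n",
                    g, object@nullShare[[g]]))
        t <- object@table[object@table$temperature == g, ]
        for (i in seq_len(nrow(t)))
            cat(sprintf("    %-18s %6.2f%% (SD = %.3f)\n",
                        t$process[i], t$contribution[i], t$sd[i]))
    }
})
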