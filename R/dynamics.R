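#' Create a candidate specification
#'
#' @param order polynomial order, 0-6.
#' @param temperatureMode one of `"none"`, `"intercept_only"`, `"additive"`,
#'   `"interaction"`.
#' @return A \linkS4class{CandidateSpec}.
#' @examples
#' candidateSpec(2, "interaction")
#' @export
candidateSpec <- function(order, temperatureMode = "none") {
    new("CandidateSpec", order = as.integer(order),
        temperatureMode = as.character(temperatureMode))
}

#' The 20-candidate polynomial model family
#'
#' The null model (order 0, no temperature), the temperature-only model
#' (order 0 with a group mean shift), and polynomial orders 1-6 crossed with
#' the three temperature treatments (none, additive, interaction): exactly 20
#' candidates, in canonical table order.
#'
#' @return List of 20 \linkS4class{CandidateSpec} objects.
#' @examples
#' length(candidateFamily())
#' @export
candidateFamily <- function() {
    fam <- list(candidateSpec(0, "none"), candidateSpec(0, "intercept_only"))
    for (mode in c("none", "additive", "interaction"))
        for (o in 1:6)
            fam <- c(fam, list(candidateSpec(o, mode)))
    fam
}

## Number of free coefficients of a candidate for nGroups temperature groups.
.specNCoef <- function(spec, nGroups = 2L) {
    switch(spec@temperatureMode,
        none = spec@order + 1L,
        intercept_only = nGroups,
        additive = spec@order + nGroups,
        interaction = nGroups * (spec@order + 1L))
}

#' Polynomial/temperature design matrix
#'
#' Builds the regression design for one candidate: powers of scaled time
#' (time divided by `duration`, for numerical conditioning of high-order
#' fits) crossed with treatment-coded temperature per the candidate's mode.
#'
#' @param days numeric sampling days.
#' @param groups temperature group per observation (character or factor;
#'   length 1 recycled).
#' @param spec a \linkS4class{CandidateSpec}.
#' @param duration time-scaling constant (days).
#' @param levels group levels fixing the column layout (defaults to the
#'   distinct values of `groups`); the first level is the reference.
#' @param assertIdentifiable error when the order exceeds distinct days - 1
#'   (disabled for prediction grids, where identifiability is not at issue).
#'
#' @return Numeric matrix with named columns; `none` mode gives `order + 1`
#'   columns, `additive` adds one indicator per non-reference group,
#'   `interaction` crosses all powers with the groups.
#' @examples
#' designMatrix(c(0, 30, 60), "9C", candidateSpec(2), duration = 60)
#' @export
designMatrix <- function(days, groups, spec, duration = 60,
                         levels = unique(as.character(groups)),
                         assertIdentifiable = TRUE) {
    stopifnot(is(spec, "CandidateSpec"), all(is.finite(days)))
    groups <- rep_len(as.character(groups), length(days))
    if (!all(groups %in% levels))
        stop("groups contain values outside 'levels'")
    nDistinct <- length(unique(days))
    if (assertIdentifiable && spec@order > nDistinct - 1L)
        stop("order ", spec@order, " unidentifiable with ", nDistinct,
             " distinct day(s)")
    s <- days / duration
    P <- outer(s, 0:spec@order, `^`)
    colnames(P) <- c("(Intercept)", if (spec@order > 0)
        paste0("s^", seq_len(spec@order)))
    if (spec@temperatureMode == "none") return(P)
    G <- outer(groups, levels[-1], `==`) + 0
    colnames(G) <- paste0("grp", levels[-1])
    switch(spec@temperatureMode,
        intercept_only = cbind(P[, 1, drop = FALSE], G),
        additive = cbind(P, G),
        interaction = {
            XI <- do.call(cbind, lapply(seq_len(ncol(G)), function(j) {
                M <- P * G[, j]
                colnames(M) <- paste0(colnames(G)[j], ":", colnames(P))
                M
            }))
            cbind(P, XI)
        })
}

## Resolve the day-0 policy: returns possibly expanded (y, days, groups).
## Day-0 shared-stock rows carry NA temperature; under temperature modes they
## are a shared baseline.  "duplicate" enters them in every group's likelihood
## (each group then spans all sampling days); "reference" assigns them to the
## reference level; "drop" removes them.
.applyDay0Policy <- function(y, days, groups, levels, policy) {
    isNA <- is.na(groups)
    if (!any(isNA)) return(list(y = y, days = days, groups = groups))
    switch(policy,
        duplicate = {
            yy <- y[!isNA]; dd <- days[!isNA]; gg <- groups[!isNA]
            for (lv in levels) {
                yy <- c(yy, y[isNA]); dd <- c(dd, days[isNA])
                gg <- c(gg, rep(lv, sum(isNA)))
            }
            list(y = yy, days = dd, groups = gg)
        },
        reference = {
            groups[isNA] <- levels[1]
            list(y = y, days = days, groups = groups)
        },
        drop = list(y = y[!isNA], days = days[!isNA], groups = groups[!isNA]),
        stop("unknown day0Policy: ", policy))
}

## (X'X)^-1 via Cholesky, falling back to an SVD pseudo-inverse for
## near-singular high-order designs.
.xtxInverse <- function(X) {
    XtX <- crossprod(X)
    tryCatch(chol2inv(chol(XtX)), error = function(e) {
        s <- svd(XtX)
        pos <- s$d > max(s$d) * 1e-14
        s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    })
}

#' Fit one candidate expression model by OLS on the log scale
#'
#' Ordinary least squares of log relative expression on the candidate's
#' design.  The stored Gaussian log-likelihood uses the maximum-likelihood
#' variance RSS/n, so AIC = -2 logLik + 2k with k = coefficients + 1 (the
#' variance counts as a parameter).
#'
#' @param x a \linkS4class{FastingExperiment} (or long-format expression
#'   data.frame with columns `gene`, `day`, `temperature`,
#'   `relative_expression`).
#' @param gene gene to fit.
#' @param spec a \linkS4class{CandidateSpec}.
#' @param duration time-scaling constant; defaults to the largest observed day.
#' @param day0Policy how pre-assignment day-0 rows (NA temperature) enter fits
#'   with a temperature term: `"duplicate"` (default; shared baseline enters
#'   every group's likelihood), `"reference"`, or `"drop"`.
#'
#' @return A \linkS4class{PolynomialExpressionModel}.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' fitPolynomialModel(fe, "gdh", candidateSpec(2, "interaction"))
#' @export
fitPolynomialModel <- function(x, gene, spec, duration = NULL,
                               day0Policy = c("duplicate", "reference", "drop")) {
    day0Policy <- match.arg(day0Policy)
    d <- if (is(x, "FastingExperiment")) exprTable(x) else x
    d <- d[d$gene == gene, , drop = FALSE]
    if (!nrow(d)) stop("gene '", gene, "' not present")
    if (any(d$relative_expression <= 0))
        stop("non-positive expression for gene '", gene, "'")
    if (is.null(duration)) duration <- max(d$day)
    levels <- unique(as.character(d$temperature[!is.na(d$temperature)]))
    if (!length(levels)) levels <- "all"
    ## the policy is applied uniformly across modes so that every candidate of
    ## the family is fitted to the same expanded response vector and AICs stay
    ## comparable within a gene's selection table
    dat <- .applyDay0Policy(log(d$relative_expression), d$day,
                            as.character(d$temperature), levels, day0Policy)
    if (spec@temperatureMode == "none") dat$groups[] <- levels[1]
    X <- designMatrix(dat$days, dat$groups, spec, duration, levels = levels)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("singular design for gene '", gene, "' (order ", spec@order,
             ", mode ", spec@temperatureMode, ")")
    beta <- qr.coef(qrX, dat$y)
    res <- dat$y - as.vector(X %*% beta)
    n <- length(dat$y); p <- ncol(X)
    rss <- sum(res^2)
    tss <- sum((dat$y - mean(dat$y))^2)
    sigma2ML <- rss / n
    ll <- if (rss <= 0) Inf else -(n / 2) * (log(2 * pi * sigma2ML) + 1)
    k <- p + 1
    aic <- if (is.infinite(ll)) {
        warning("perfect fit (RSS = 0): AIC is -Inf for gene '", gene, "'")
        -Inf
    } else -2 * ll + 2 * k
    r2 <- if (tss > 0) 1 - rss / tss else 1
    adj <- if (n - p > 0) 1 - (1 - r2) * (n - 1) / (n - p)
           else if (rss <= 1e-12 * max(tss, 1)) 1 else NA_real_
    new("PolynomialExpressionModel",
        gene = gene, spec = spec,
        coefficients = setNames(as.vector(beta), colnames(X)),
        xtxInv = .xtxInverse(X),
        sigma2ML = sigma2ML,
        sigma2 = if (n - p > 0) rss / (n - p) else 0,
        n = n, k = k, logLik = ll, aic = aic, adjR2 = adj,
        groups = levels, duration = duration, day0Policy = day0Policy)
}

#' @describeIn fitPolynomialModel coefficients on the scaled-time basis
#'   (default) or per-day basis (`scale = "day"`, group-wise cell form).
#' @param object,... method arguments.
#' @param scale `"scaled"` or `"day"`.
#' @export
setMethod("coef", "PolynomialExpressionModel",
    function(object, scale = c("scaled", "day"), ...) {
    scale <- match.arg(scale)
    if (scale == "scaled") return(object@coefficients)
    ## per-group polynomial in raw days: beta_i / duration^i, cell form
    lapply(setNames(object@groups, object@groups), function(g) {
        o <- object@spec@order
        b <- .groupPolyCoef(object, g)
        b / object@duration^(0:o)
    })
})

## Cell-form polynomial coefficients (scaled basis) of one group.
.groupPolyCoef <- function(model, group) {
    spec <- model@spec
    o <- spec@order
    b <- model@coefficients
    base <- b[seq_len(o + 1)]
    if (spec@temperatureMode %in% c("none") || group == model@groups[1])
        return(base)
    if (!group %in% model@groups)
        stop("temperature group '", group, "' absent from model")
    if (spec@temperatureMode %in% c("intercept_only", "additive")) {
        base[1] <- base[1] + b[[paste0("grp", group)]]
        base
    } else {
        add <- b[paste0("grp", group, ":", names(base))]
        base + as.vector(add)
    }
}

setMethod("show", "PolynomialExpressionModel", function(object) {
    cat(sprintf(
        "PolynomialExpressionModel '%s': order %d, mode %s (n = %d)\n",
        object@gene, object@spec@order, object@spec@temperatureMode,
        as.integer(object@n)))
    cat(sprintf("  AIC %.3f | adjR2 %.3f | sigma (log) %.3f\n",
        object@aic, object@adjR2, sqrt(object@sigma2ML)))
})

#' @rdname fitPolynomialModel
#' @param k unused (AIC generic signature).
#' @export
setMethod("logLik", "PolynomialExpressionModel", function(object, ...) {
    structure(object@logLik, df = object@k, class = "logLik")
})

#' @rdname fitPolynomialModel
#' @export
setMethod("AIC", "PolynomialExpressionModel",
    function(object, ..., k = 2) object@aic)

#' Adjusted R-squared of a fitted expression model
#'
#' `1 - (1 - R2) (n - 1) / (n - p)` with p the total coefficient count, so the
#' null model scores exactly 0 and a perfect fit scores 1.
#'
#' @param object a \linkS4class{PolynomialExpressionModel}.
#' @return Numeric fraction.
#' @rdname adjustedR2
#' @export
setMethod("adjustedR2", "PolynomialExpressionModel",
    function(object, ...) object@adjR2)

#' Exhaustive AIC selection over the 20-candidate family
#'
#' Fits every candidate of [candidateFamily()] for one gene and returns the
#' full AIC table plus the minimum-AIC model.  Selection is exhaustive rather
#' than path-dependent stepwise: the family is small and the full table is
#' itself a reported object.  Ties are broken by fewer parameters, then lower
#' order, then simpler temperature mode.
#'
#' @param x a \linkS4class{FastingExperiment} or long expression table.
#' @param gene gene name.
#' @param day0Policy,duration passed to [fitPolynomialModel()].
#' @return A \linkS4class{ModelSelectionResult}.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' sel <- selectModel(fe, "cpt1")
#' bestModel(sel)
#' @rdname selectModel
#' @export
setMethod("selectModel", "ANY",
    function(x, gene, day0Policy = "duplicate", duration = NULL) {
    fam <- candidateFamily()
    fits <- lapply(fam, function(sp)
        tryCatch(fitPolynomialModel(x, gene, sp, duration = duration,
                                    day0Policy = day0Policy),
                 error = function(e) e))
    failed <- vapply(fits, inherits, logical(1), "error")
    if (all(failed))
        stop(conditionMessage(fits[[1]]))
    ## unidentifiable candidates (too few distinct days) score +Inf
    tab <- data.frame(
        order = vapply(fam, function(s) s@order, integer(1)),
        mode = vapply(fam, function(s) s@temperatureMode, character(1)),
        k = vapply(seq_along(fam), function(i)
            if (failed[i]) .specNCoef(fam[[i]]) + 1 else fits[[i]]@k,
            numeric(1)),
        aic = vapply(seq_along(fits), function(i)
            if (failed[i]) Inf else fits[[i]]@aic, numeric(1)),
        adjR2 = vapply(seq_along(fits), function(i)
            if (failed[i]) NA_real_ else fits[[i]]@adjR2, numeric(1)))
    tab$deltaAIC <- tab$aic - min(tab$aic)
    modeRank <- match(tab$mode, c("none", "intercept_only", "additive",
                                  "interaction"))
    best <- order(tab$aic, tab$k, tab$order, modeRank)[1]
    new("ModelSelectionResult", gene = gene, table = tab, best = fits[[best]])
})

#' @rdname bestModel
#' @param x a \linkS4class{ModelSelectionResult}.
#' @export
setMethod("bestModel", "ModelSelectionResult", function(x, ...) x@best)

setMethod("show", "ModelSelectionResult", function(object) {
    cat("ModelSelectionResult '", object@gene, "': 20 candidates\n", sep = "")
    b <- object@best
    cat(sprintf("  selected: order %d, mode %s (AIC %.3f, adjR2 %.3f)\n",
        b@spec@order, b@spec@temperatureMode, b@aic, b@adjR2))
})

#' Pointwise prediction with mean-response interval
#'
#' Median curve and pointwise confidence band for the mean response on the
#' anti-logged expression scale: `exp` of the fitted log-mean and of its
#' t-based interval (the lognormal median).
#'
#' @param model a \linkS4class{PolynomialExpressionModel}.
#' @param days prediction grid.
#' @param temperature group label (ignored under mode `"none"`).
#' @param level interval level, in (0, 1).
#' @return data.frame(day, temperature, median, lower, upper).
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' m <- fitPolynomialModel(fe, "gdh", candidateSpec(2, "interaction"))
#' head(predictWithInterval(m, 0:60, "9C"))
#' @export
predictWithInterval <- function(model, days, temperature = model@groups[1],
                                level = 0.95) {
    stopifnot(level > 0, level < 1)
    if (any(days < 0 | days > model@duration))
        warning("prediction outside [0, ", model@duration,
                "] extrapolates the fitted dynamics")
    grp <- if (model@spec@temperatureMode == "none") model@groups[1]
           else as.character(temperature)
    X <- designMatrix(days, rep(grp, length(days)), model@spec,
                      model@duration, levels = model@groups,
                      assertIdentifiable = FALSE)
    m <- as.vector(X %*% model@coefficients)
    se <- sqrt(pmax(rowSums((X %*% model@xtxInv) * X), 0) * model@sigma2)
    df <- model@n - (model@k - 1)
    tq <- if (df > 0) qt(1 - (1 - level) / 2, df = df) else 0
    data.frame(day = days, temperature = temperature,
               median = exp(m), lower = exp(m - tq * se),
               upper = exp(m + tq * se))
}
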