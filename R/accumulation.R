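#' Continuous expression curve of a fitted model
#'
#' The fitted dynamics anti-logged: `E(t) = exp(sum_i beta_i (t/duration)^i)`
#' for the requested temperature group.  Strictly positive and continuous.
#'
#' @param model a \linkS4class{PolynomialExpressionModel}.
#' @param temperature group label; ignored under mode `"none"`.
#' @return A vectorised function of time (days).
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' f <- expressionCurve(fitPolynomialModel(fe, "gdh", candidateSpec(1)), "9C")
#' f(c(0, 30, 60))
#' @rdname expressionCurve
#' @export
setMethod("expressionCurve", "PolynomialExpressionModel",
    function(model, temperature = model@groups[1], ...) {
    grp <- if (model@spec@temperatureMode == "none") model@groups[1]
           else as.character(temperature)
    if (!grp %in% model@groups)
        stop("temperature group '", grp, "' absent from model")
    beta <- .groupPolyCoef(model, grp)
    dur <- model@duration
    o <- model@spec@order
    function(t) {
        s <- t / dur
        exp(as.vector(outer(s, 0:o, `^`) %*% beta))
    }
})

## Shared grid constructor: ensures the horizon is a grid point.
.productionGrid <- function(horizon, step) {
    stopifnot(horizon > 0, step > 0)
    g <- seq(0, horizon, by = step)
    if (g[length(g)] < horizon) g <- c(g, horizon)
    g
}

#' Cumulated transcript production of a single expression curve
#'
#' Composite-trapezoid cumulative integral of a positive expression curve
#' from day 0 to each grid point.  The trapezoid rule is exact for constant
#' integrands, so a constant null-gene curve yields an exactly linear
#' production curve.
#'
#' @param curve positive function of time (days), e.g. from
#'   [expressionCurve()].
#' @param horizon upper integration limit (days).
#' @param step reporting-grid step (days).
#' @param refine integrand oversampling factor: the trapezoid rule is applied
#'   on a grid `refine` times finer than the reported one, then read off at
#'   the reported points.  The default (10) holds the relative error of
#'   smooth expression curves below 1e-8 at the default step while retaining
#'   the trapezoid's exactness for constants and its second-order
#'   step-refinement behaviour.
#' @param label curve label ("A", "B", "C" or "null").
#' @param temperature group label carried on the result.
#' @return A \linkS4class{ProductionCurve}.
#' @examples
#' pc <- cumulateProduction(function(t) exp(0.02 * t), horizon = 60)
#' max(pc@values)
#' @export
cumulateProduction <- function(curve, horizon = 60, step = 0.05,
                               refine = 10L, label = "B",
                               temperature = "9C") {
    refine <- max(1L, as.integer(refine))
    grid <- .productionGrid(horizon, step)
    fine <- .productionGrid(horizon, step / refine)
    y <- curve(fine)
    if (length(y) != length(fine))
        y <- vapply(fine, curve, numeric(1))
    if (!all(is.finite(y)))
        stop("expression curve is non-finite on the integration grid")
    valsFine <- as.vector(pracma::cumtrapz(fine, y))
    vals <- approx(fine, valsFine, xout = grid)$y
    new("ProductionCurve", label = label, temperature = temperature,
        days = grid, values = vals, step = step, scaled = FALSE,
        scaleFactor = 1)
}

#' Cumulated production of the four mandatory autophagy transcripts
#'
#' The autophagosome-formation exposure: each of the four transcripts is
#' mandatory, so the integrand is the pointwise product of the four curves
#' (if any one transcript vanishes, so does the product and hence the
#' accumulated exposure).
#'
#' @param curves list of exactly 4 positive expression functions, in panel
#'   order (ulk1, lc3b, atg7, atg12).
#' @inheritParams cumulateProduction
#' @return A \linkS4class{ProductionCurve} with label `"A"`.
#' @examples
#' ones <- function(t) rep(1, length(t))
#' pc <- cumulateProduct(list(ones, ones, ones, ones), horizon = 10)
#' max(pc@values)  # integral of 1 over [0, 10]
#' @export
cumulateProduct <- function(curves, horizon = 60, step = 0.05,
                            refine = 10L, temperature = "9C") {
    if (length(curves) != 4L)
        stop("exactly 4 transcript curves required, got ", length(curves))
    prodFun <- function(t) Reduce(`*`, lapply(curves, function(f) f(t)))
    cumulateProduction(prodFun, horizon = horizon, step = step,
                       refine = refine, label = "A",
                       temperature = temperature)
}

#' Constant-mean null gene model from fitted dynamics
#'
#' @param x a \linkS4class{FastingExperiment} or long expression table
#'   (target genes only are used).
#' @param fitted named list of \linkS4class{PolynomialExpressionModel}
#'   objects whose residual variances are averaged.
#' @param genes genes contributing to the grand mean (defaults to the fitted
#'   gene names).
#' @return A \linkS4class{NullGeneModel} with variance the arithmetic mean of
#'   the per-gene residual variances (log scale) and mean level
#'   `exp(mu + sigma^2/2)` of the grand mean log expression.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' m <- fitPolynomialModel(fe, "gdh", candidateSpec(1))
#' nullExpressionModel(fe, list(gdh = m))
#' @export
nullExpressionModel <- function(x, fitted, genes = names(fitted)) {
    if (!length(fitted)) stop("no fitted models supplied")
    d <- if (is(x, "FastingExperiment")) exprTable(x) else x
    d <- d[d$gene %in% genes, , drop = FALSE]
    v <- mean(vapply(fitted, function(m) m@sigma2, numeric(1)))
    mu <- mean(log(d$relative_expression))
    new("NullGeneModel", meanLevel = exp(mu + v / 2), variance = v)
}

setMethod("show", "NullGeneModel", function(object) {
    cat(sprintf("NullGeneModel: mean level %.4f, variance (log) %.4f\n",
        object@meanLevel, object@variance))
})

## Normalise a production-curve set (group -> list(A, B, C, null)) by each
## label's day-60 temperature-pooled maximum, so regressors are commensurate.
.normalizeProductionSet <- function(curves) {
    labels <- names(curves[[1]])
    for (lab in labels) {
        finals <- vapply(curves, function(cs) {
            v <- cs[[lab]]@values
            v[length(v)]
        }, numeric(1))
        denom <- max(finals)
        if (denom <= 0) denom <- 1
        for (g in names(curves)) {
            pc <- curves[[g]][[lab]]
            pc@values <- pc@values / denom
            pc@scaled <- TRUE
            pc@scaleFactor <- denom
            curves[[g]][[lab]] <- pc
        }
    }
    curves
}

#' All production curves from selected expression models
#'
#' Computes the four cumulated-production curves per temperature group: the
#' product integral of the four mandatory autophagy transcripts (`A`), the
#' single-gene integrals of the amino-acid and fatty-acid catabolic markers
#' (`B`, `C`), and the constant null gene (`null`, exactly linear).  When
#' `normalize = TRUE` (default) each label's curves are divided by their
#' day-`horizon` temperature-pooled maximum so the weight-loss regressors are
#' unit-scaled and contribution weights are comparable across labels.
#'
#' @param models named list of fitted \linkS4class{PolynomialExpressionModel}
#'   objects covering the genes named in `roles`.
#' @param nullModel a \linkS4class{NullGeneModel}.
#' @param roles gene-role map as from [defaultGeneRoles()].
#' @param temperatures group labels to evaluate.
#' @param horizon,step integration settings (days).
#' @param normalize unit-normalise each label at the horizon?
#' @return Nested list: `curves[[group]][[label]]` is a
#'   \linkS4class{ProductionCurve}.
#' @export
productionCurves <- function(models, nullModel,
                             roles = defaultGeneRoles(),
                             temperatures = c("9C", "12C"),
                             horizon = 60, step = 0.05, normalize = TRUE) {
    need <- c(roles$atg, roles$gdh, roles$cpt1)
    miss <- setdiff(need, names(models))
    if (length(miss))
        stop("missing fitted model(s): ", paste(miss, collapse = ", "))
    out <- list()
    for (grp in temperatures) {
        atgCurves <- lapply(roles$atg,
            function(g) expressionCurve(models[[g]], grp))
        out[[grp]] <- list(
            A = cumulateProduct(atgCurves, horizon, step, temperature = grp),
            B = cumulateProduction(expressionCurve(models[[roles$gdh]], grp),
                                   horizon, step, label = "B",
                                   temperature = grp),
            C = cumulateProduction(expressionCurve(models[[roles$cpt1]], grp),
                                   horizon, step, label = "C",
                                   temperature = grp),
            null = cumulateProduction(
                function(t) rep(nullModel@meanLevel, length(t)),
                horizon, step, label = "null", temperature = grp))
    }
    if (normalize) out <- .normalizeProductionSet(out)
    out
}

#' Look up a production curve at arbitrary days
#'
#' Linear interpolation on the integration grid (exact at grid points).
#'
#' @param curve a \linkS4class{ProductionCurve}.
#' @param day numeric day(s) within the curve horizon.
#' @return Numeric values.
#' @export
productionAt <- function(curve, day) {
    if (any(day < min(curve@days) - 1e-9 | day > max(curve@days) + 1e-9))
        stop("day outside the production-curve horizon")
    approx(curve@days, curve@values, xout = day, rule = 2)$y
}

setMethod("show", "ProductionCurve", function(object) {
    cat(sprintf(
        "ProductionCurve P(%s) at %s: %d grid points, step %.3g d, P(%g) = %.4g%s\n",
        object@label, object@temperature, length(object@days), object@step,
        max(object@days), object@values[length(object@values)],
        if (object@scaled) sprintf(" (unit-normalised, raw scale %.4g)",
                                   object@scaleFactor) else ""))
})
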