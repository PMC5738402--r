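#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData
#' @importMethodsFrom S4Vectors "$"
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aggregate
#' @importFrom stats lm coef sd var qt pt pnorm rnorm rlnorm runif setNames
#'   quantile integrate approx median complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Experimental design of a destructive-sampling fasting trial
#'
#' Describes the layout of the fasting experiment that the synthetic generator
#' emulates: two thermal groups held in replicate tanks, with a fixed number of
#' individuals sacrificed per tank at regular sampling intervals.  The default
#' layout is 2 groups (9 and 12 degrees C) x 5 tanks x 15 individuals, 2
#' sacrifices per tank every 10 days for 60 days, plus a day-0 baseline sample
#' taken from the shared stock before temperature assignment.
#'
#' @slot temperatures character, group labels.
#' @slot tanksPerGroup integer, replicate tanks per thermal group.
#' @slot individualsPerTank integer, fish stocked per tank.
#' @slot sacrificesPerTankPerDate integer, fish sacrificed per tank per date.
#' @slot samplingIntervalDays numeric, days between sampling dates.
#' @slot durationDays numeric, total trial length in days.
#' @slot includeDay0 logical, whether a day-0 baseline sample is taken.
#' @slot genes character, target gene names (ordered).
#' @slot referenceGene character, normalisation gene name.
#'
#' @seealso [experimentDesign()] for the user-facing constructor.
#' @export
setClass("ExperimentDesign",
    representation(
        temperatures = "character",
        tanksPerGroup = "integer",
        individualsPerTank = "integer",
        sacrificesPerTankPerDate = "integer",
        samplingIntervalDays = "numeric",
        durationDays = "numeric",
        includeDay0 = "logical",
        genes = "character",
        referenceGene = "character"
    )
)

setValidity("ExperimentDesign", function(object) {
    msg <- character()
    nd <- object@durationDays / object@samplingIntervalDays
    if (abs(nd - round(nd)) > 1e-8)
        msg <- c(msg, "durationDays must be a multiple of samplingIntervalDays")
    nDates <- round(nd)  # post-baseline dates
    if (object@sacrificesPerTankPerDate * nDates > object@individualsPerTank)
        msg <- c(msg, "total sacrifices per tank exceed individualsPerTank")
    if (length(object@temperatures) < 1 || anyDuplicated(object@temperatures))
        msg <- c(msg, "temperatures must be non-empty and unique")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene names must be unique")
    if (length(msg)) msg else TRUE
})

#' Ground-truth parameters for the synthetic experiment generator
#'
#' Houses every quantity needed to simulate an experiment: per-gene log-scale
#' polynomial coefficients for each temperature group, per-gene lognormal
#' individual noise, the simplex-valued contribution vectors and
#' temperature-specific scaling of the weight-loss model, observation noise,
#' and the initial-weight distribution.  Coefficients are stored per
#' temperature group on the scaled-time basis (time divided by the trial
#' duration), so that the generator and the fitting code share no coding
#' conventions.
#'
#' @slot coefficients named list (gene -> named list (group -> numeric beta)).
#' @slot sdLog named numeric, per-gene individual noise sd on the log scale.
#' @slot alpha numeric matrix, one row per temperature group, six columns;
#'   each row sums to one.
#' @slot gamma named numeric, per-temperature scaling of the weight-loss mean.
#' @slot sdW numeric, weight-loss observation noise sd.
#' @slot initialWeightMean,initialWeightSd numeric, initial weight (mg).
#' @slot tankSd numeric, optional tank random-intercept sd on the log scale
#'   (0 disables; the analysis model assumes none).
#' @slot cache environment, memoised true production curves.
#'
#' @seealso [syntheticTruth()]
#' @export
setClass("SyntheticTruth",
    representation(
        coefficients = "list",
        sdLog = "numeric",
        alpha = "matrix",
        gamma = "numeric",
        sdW = "numeric",
        initialWeightMean = "numeric",
        initialWeightSd = "numeric",
        tankSd = "numeric",
        cache = "environment"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (any(abs(rowSums(object@alpha) - 1) > 1e-12))
        msg <- c(msg, "each alpha row must sum to 1 within 1e-12")
    if (any(object@alpha < 0))
        msg <- c(msg, "alpha entries must be non-negative")
    if (any(object@gamma < 0) || any(object@gamma > 1000))
        msg <- c(msg, "gamma must lie in [0, 1000]")
    if (any(object@sdLog < 0))
        msg <- c(msg, "per-gene noise sds must be non-negative")
    if (object@sdW < 0) msg <- c(msg, "sdW must be non-negative")
    if (ncol(object@alpha) != 6L)
        msg <- c(msg, "alpha must have 6 columns (five transcript terms + null)")
    if (length(msg)) msg else TRUE
})

#' Container for a destructive-sampling expression/weight dataset
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay `"relexpr"`
#' holds strictly positive relative expression (genes x individuals); `colData`
#' carries `individual`, `tank`, `temperature` (factor, `NA` for day-0
#' shared-stock fish), `day`, `initialWeight`, `finalWeight` and `weightLoss`
#' (percent of initial mass).  Each individual is observed once (destructive
#' sampling), so columns are individuals.
#'
#' @seealso [FastingExperiment()], [relExpr()], [exprTable()], [weightTable()]
#' @export
setClass("FastingExperiment", contains = "SummarizedExperiment")

setValidity("FastingExperiment", function(object) {
    msg <- character()
    if (!"relexpr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'relexpr' is required")
    else if (any(SummarizedExperiment::assay(object, "relexpr") <= 0, na.rm = TRUE))
        msg <- c(msg, "relative expression must be strictly positive")
    need <- c("individual", "tank", "temperature", "day")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
    else if (anyDuplicated(object$individual))
        msg <- c(msg, "each individual may appear only once (destructive sampling)")
    if (length(msg)) msg else TRUE
})

#' One candidate of the 20-model polynomial family
#'
#' A candidate couples a polynomial order (0-6) with a temperature mode:
#' `"none"` (shared curve), `"intercept_only"` (order 0 plus a group mean
#' shift, the temperature-only model), `"additive"` (shared shape, group
#' intercepts) or `"interaction"` (fully group-specific curves).  The family
#' enumerated by [candidateFamily()] is the null model, the temperature-only
#' model, and orders 1-6 crossed with none/additive/interaction: 20 candidates.
#'
#' @slot order integer polynomial order.
#' @slot temperatureMode character mode.
#' @export
setClass("CandidateSpec",
    representation(order = "integer", temperatureMode = "character"))

setValidity("CandidateSpec", function(object) {
    modes <- c("none", "intercept_only", "additive", "interaction")
    if (!object@temperatureMode %in% modes)
        return(paste("temperatureMode must be one of:", paste(modes, collapse = ", ")))
    if (object@order < 0L || object@order > 6L)
        return("order must be between 0 and 6")
    if (object@temperatureMode == "intercept_only" && object@order != 0L)
        return("intercept_only mode is defined for order 0 only")
    TRUE
})

#' Fitted log-scale polynomial expression model for one gene
#'
#' Ordinary least squares of log relative expression on powers of scaled time
#' (time / trial duration), with temperature coded per the candidate spec.
#' Stores everything needed for AIC, adjusted R-squared and pointwise
#' mean-response intervals: coefficients (scaled basis), the unscaled inverse
#' cross-product matrix, the ML and unbiased residual variances.
#'
#' @slot gene character.
#' @slot spec CandidateSpec.
#' @slot coefficients named numeric, design-basis coefficients.
#' @slot xtxInv matrix, (X'X)^-1 of the fitted design.
#' @slot sigma2ML numeric, RSS/n (enters the Gaussian log-likelihood).
#' @slot sigma2 numeric, RSS/(n-p).
#' @slot n,k numeric, observations and parameter count (coefficients + variance).
#' @slot logLik,aic,adjR2 numeric fit summaries.
#' @slot groups character, temperature levels seen at fit time.
#' @slot duration numeric, time-scaling constant (days).
#' @slot day0Policy character, how pre-assignment day-0 rows entered the fit.
#' @export
setClass("PolynomialExpressionModel",
    representation(
        gene = "character", spec = "CandidateSpec",
        coefficients = "numeric", xtxInv = "matrix",
        sigma2ML = "numeric", sigma2 = "numeric",
        n = "numeric", k = "numeric",
        logLik = "numeric", aic = "numeric", adjR2 = "numeric",
        groups = "character", duration = "numeric", day0Policy = "character"
    )
)

#' AIC table over the 20-candidate family for one gene
#'
#' @slot gene character.
#' @slot table data.frame with one row per candidate (order, mode, k, aic,
#'   adjR2, deltaAIC) in canonical family order.
#' @slot best the selected \linkS4class{PolynomialExpressionModel}.
#' @export
setClass("ModelSelectionResult",
    representation(gene = "character", table = "data.frame",
                   best = "PolynomialExpressionModel"))

setValidity("ModelSelectionResult", function(object) {
    if (nrow(object@table) != 20L)
        return("selection table must contain exactly 20 candidates")
    if (abs(min(object@table$aic) - object@best@aic) > 1e-9)
        return("selected AIC must equal the family minimum")
    TRUE
})

#' qPCR standard curve and amplification efficiency
#'
#' Least-squares fit of mean Ct on log10 relative input over a serial dilution
#' series; the amplification factor is E = 10^(-1/slope) (2 = perfect
#' doubling).
#'
#' @slot gene character.
#' @slot dilutions,meanCt numeric, the dilution series.
#' @slot slope,intercept,efficiency,r2 numeric fit results.
#' @export
setClass("StandardCurve",
    representation(gene = "character", dilutions = "numeric", meanCt = "numeric",
                   slope = "numeric", intercept = "numeric",
                   efficiency = "numeric", r2 = "numeric"))

#' Constant-mean null gene model
#'
#' A pseudo-gene with constant expected expression, whose cumulated production
#' is exactly linear in time.  Its role downstream is to absorb the linear
#' component of weight loss so that linear trends are not attributed to real
#' transcripts.  The variance is the average of the per-gene residual
#' variances on the log scale; the mean level is the grand mean log expression
#' anti-logged with the lognormal mean correction exp(mu + sigma^2/2).
#'
#' @slot meanLevel,variance numeric.
#' @export
setClass("NullGeneModel",
    representation(meanLevel = "numeric", variance = "numeric"))

setValidity("NullGeneModel", function(object) {
    if (object@variance < 0) return("variance must be non-negative")
    if (object@meanLevel <= 0) return("meanLevel must be > 0")
    TRUE
})

#' Cumulated transcript production on a time grid
#'
#' Cumulative trapezoid integral of one fitted expression curve (labels
#' `"B"`, `"C"`, `"null"`) or of the product of the four mandatory autophagy
#' transcript curves (label `"A"`), from day 0 to each grid point, for one
#' temperature group.  Non-decreasing and zero at day 0 by construction.
#'
#' @slot label character, one of "A", "B", "C", "null".
#' @slot temperature character group label.
#' @slot days,values numeric grid and cumulative values.
#' @slot step numeric grid step (days).
#' @slot scaled logical, whether values were divided by `scaleFactor`.
#' @slot scaleFactor numeric, the day-60 temperature-pooled maximum used for
#'   unit normalisation (1 when unscaled).
#' @export
setClass("ProductionCurve",
    representation(label = "character", temperature = "character",
                   days = "numeric", values = "numeric", step = "numeric",
                   scaled = "logical", scaleFactor = "numeric"))

setValidity("ProductionCurve", function(object) {
    msg <- character()
    if (length(object@days) != length(object@values))
        msg <- c(msg, "days and values must have equal length")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "production values must be finite")
    if (length(object@values) && abs(object@values[1]) > 1e-12)
        msg <- c(msg, "production must start at 0")
    if (any(diff(object@values) < -1e-10))
        msg <- c(msg, "production must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' Assembled weight-loss regression model (pre-MCMC)
#'
#' Pairs each sacrificed individual's observed weight loss with its six
#' production regressors (or the single null regressor for M0) evaluated at
#' its own sacrifice day and temperature.
#'
#' @slot W numeric observed weight loss.
#' @slot X numeric regressor matrix (columns A, AB, AC, B, C, null for M1).
#' @slot tempIndex integer temperature group per row.
#' @slot tempLevels character group labels.
#' @slot model character, "M0" or "M1".
#' @slot shareTemperature logical, pool gamma/alpha across groups.
#' @slot fingerprint numeric, data fingerprint used by [compareModels()].
#' @export
setClass("WeightLossModel",
    representation(W = "numeric", X = "matrix", tempIndex = "integer",
                   tempLevels = "character", model = "character",
                   shareTemperature = "logical", fingerprint = "numeric"))

#' Posterior sample of the weight-loss model
#'
#' MCMC draws (>= 2 chains) of the per-temperature scaling gamma, the
#' simplex-valued contribution vector alpha (M1 only), and the observation
#' noise sd, together with split-chain R-hat, the DIC decomposition
#' (DIC = mean deviance + pD) and the model object the draws refer to.
#'
#' @slot draws list of per-chain matrices (iterations x parameters).
#' @slot paramNames character.
#' @slot model WeightLossModel.
#' @slot rhat named numeric.
#' @slot dic list(DIC, pD, meanDeviance).
#' @slot mode character, "two_stage" or "joint".
#' @slot seed numeric.
#' @export
setClass("WeightLossFit",
    representation(draws = "list", paramNames = "character",
                   model = "WeightLossModel", rhat = "numeric",
                   dic = "list", mode = "character", seed = "numeric"))

setValidity("WeightLossFit", function(object) {
    if (length(object@draws) < 1) return("at least one chain required")
    ok <- vapply(object@draws, function(d)
        identical(colnames(d), object@paramNames), logical(1))
    if (!all(ok)) return("chain columns must match paramNames")
    TRUE
})

#' Relative-contribution summary of a weight-loss posterior
#'
#' Per temperature: the null-gene linear-trend share (%), and the remaining
#' five contributions rescaled to sum to 100% with their posterior sds
#' (sd on the 0-1 scale of the rescaled contribution).
#'
#' @slot table data.frame(process, temperature, contribution, sd).
#' @slot nullShare named numeric, percent per temperature.
#' @export
setClass("ContributionSummary",
    representation(table = "data.frame", nullShare = "numeric"))

setValidity("ContributionSummary", function(object) {
    sums <- tapply(object@table$contribution, object@table$temperature, sum)
    if (any(abs(sums - 100) > 1e-9))
        return("rescaled contributions must sum to 100 per temperature")
    TRUE
})
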