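#' Amplification efficiency from a standard dilution curve
#'
#' Least squares of mean Ct on log10 relative input over a serial dilution
#' series (e.g. 1/20, 1/40, ..., 1/320).  The amplification factor is
#' `E = 10^(-1/slope)`; a perfectly doubling assay has slope -3.3219 and
#' E = 2.  Values outside the [1.8, 2.2] range typically observed for
#' well-behaved assays trigger a warning.
#'
#' @param dilutions positive dilution fractions (relative input quantities).
#' @param cts mean Ct per dilution point.
#' @param gene gene label carried on the result.
#' @return A \linkS4class{StandardCurve}.
#' @examples
#' d <- 1 / c(20, 40, 80, 160, 320)
#' sc <- efficiencyFromStandardCurve(d, 30 - 3.3219 * log10(d * 20))
#' efficiency(sc)
#' @export
efficiencyFromStandardCurve <- function(dilutions, cts, gene = "gene") {
    if (length(dilutions) < 3) stop("at least 3 dilution points required")
    if (length(dilutions) != length(cts))
        stop("dilutions and cts must have equal length")
    if (any(dilutions <= 0)) stop("dilutions must be positive")
    x <- log10(dilutions)
    if (var(x) == 0) stop("zero variance in log10 input: slope undefined")
    slope <- sum((x - mean(x)) * (cts - mean(cts))) / sum((x - mean(x))^2)
    if (abs(slope) < 1e-12)
        stop("flat standard curve (slope 0): efficiency undefined")
    intercept <- mean(cts) - slope * mean(x)
    fitted <- intercept + slope * x
    ssTot <- sum((cts - mean(cts))^2)
    r2 <- if (ssTot > 0) 1 - sum((cts - fitted)^2) / ssTot else 1
    eff <- 10^(-1 / slope)
    if (eff < 1.8 || eff > 2.2)
        warning(sprintf("efficiency %.3f outside the usual [1.8, 2.2] range",
                        eff))
    new("StandardCurve", gene = gene, dilutions = dilutions, meanCt = cts,
        slope = slope, intercept = intercept, efficiency = eff, r2 = r2)
}

#' @rdname efficiency
#' @param x a \linkS4class{StandardCurve}.
#' @param ... unused.
#' @return Numeric amplification factor (2 = perfect doubling).
#' @export
setMethod("efficiency", "StandardCurve", function(x, ...) x@efficiency)

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf(
        "StandardCurve '%s': slope %.4f, E = %.4f, r2 = %.4f (%d points)\n",
        object@gene, object@slope, object@efficiency, object@r2,
        length(object@dilutions)))
})

#' Efficiency-corrected relative expression ratio
#'
#' The efficiency-corrected delta-Ct ratio of a target gene in a sample
#' relative to a calibrator, normalised by a reference gene:
#' `E_target^(Ct_target_cal - Ct_target_sample) /
#'  E_ref^(Ct_ref_cal - Ct_ref_sample)`.
#'
#' @param ctTargetSample,ctTargetCalibrator target-gene Ct values.
#' @param ctRefSample,ctRefCalibrator reference-gene Ct values.
#' @param eTarget,eRef amplification factors, each in (1, 3).
#' @return Strictly positive ratio.
#' @examples
#' pfafflRatio(24, 25, 20, 20, 2, 2)  # one cycle earlier -> ratio 2
#' @export
pfafflRatio <- function(ctTargetSample, ctTargetCalibrator,
                        ctRefSample, ctRefCalibrator,
                        eTarget, eRef) {
    cts <- c(ctTargetSample, ctTargetCalibrator, ctRefSample, ctRefCalibrator)
    if (!all(is.finite(cts))) stop("non-finite Ct value")
    if (any(c(eTarget, eRef) <= 1) || any(c(eTarget, eRef) >= 3))
        stop("efficiencies must lie in (1, 3)")
    eTarget^(ctTargetCalibrator - ctTargetSample) /
        eRef^(ctRefCalibrator - ctRefSample)
}

## Arithmetic-mean Ct per (sample, gene) after replicate averaging.
.meanCtTable <- function(ct) {
    agg <- aggregate(ct$ct, by = list(sample_id = ct$sample_id,
                                      gene = ct$gene), FUN = mean)
    names(agg)[3] <- "ct"
    agg
}

#' Normalise a raw Ct table to relative expression
#'
#' Technical replicates are averaged on the Ct scale, then each target gene is
#' quantified against the reference gene and a calibrator by the
#' efficiency-corrected delta-Ct ratio.  The calibrator is either a named
#' pseudo-sample present in the table (`calibrator = "sample:<id>"`) or the
#' geometric-mean pseudo-sample of a set of baseline samples
#' (`calibrator = "day0_geomean"`, requiring `day0Samples`): its per-gene Ct
#' is the arithmetic mean Ct of those samples, i.e. the geometric mean on the
#' expression scale.
#'
#' @param ct data.frame(sample_id, gene, replicate, ct).
#' @param efficiencies named numeric amplification factors, or a list of
#'   \linkS4class{StandardCurve} objects.
#' @param referenceGene the normalisation gene; every sample must have it.
#' @param calibrator calibrator rule (see above).
#' @param day0Samples sample ids forming the baseline pseudo-sample.
#' @return Long data.frame(sample_id, gene, relative_expression), target
#'   genes only; the calibrator has ratio 1 for every gene by construction.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' eff <- setNames(rep(2, 11), rownames(fe))
#' ct <- simulateCtTable(fe, eff)
#' ex <- normalizeCtTable(ct, eff, calibrator = "sample:calibrator")
#' head(ex)
#' @export
normalizeCtTable <- function(ct, efficiencies, referenceGene = "eef1a1",
                             calibrator = "day0_geomean",
                             day0Samples = NULL) {
    if (is.list(efficiencies) && !is.numeric(efficiencies))
        efficiencies <- vapply(efficiencies, efficiency, numeric(1))
    genes <- unique(ct$gene)
    miss <- genes[!genes %in% names(efficiencies)]
    if (length(miss))
        stop("missing efficiency for gene(s): ", paste(miss, collapse = ", "))
    if (!referenceGene %in% genes)
        stop("reference gene '", referenceGene, "' absent from Ct table")
    m <- .meanCtTable(ct)
    wide <- tapply(m$ct, list(m$sample_id, m$gene), identity)
    samples <- rownames(wide)
    if (any(is.na(wide[, referenceGene]))) {
        bad <- samples[is.na(wide[, referenceGene])]
        stop("sample(s) missing reference-gene Ct: ",
             paste(bad, collapse = ", "))
    }
    if (startsWith(calibrator, "sample:")) {
        calId <- sub("^sample:", "", calibrator)
        if (!calId %in% samples)
            stop("calibrator sample '", calId, "' absent")
        calCt <- wide[calId, ]
        samples <- setdiff(samples, calId)
    } else if (calibrator == "day0_geomean") {
        if (is.null(day0Samples))
            stop("day0_geomean calibrator requires 'day0Samples'")
        sel <- intersect(day0Samples, rownames(wide))
        if (!length(sel)) stop("no day-0 samples found in Ct table")
        calCt <- colMeans(wide[sel, , drop = FALSE])
    } else stop("unknown calibrator rule: ", calibrator)
    targets <- setdiff(genes, referenceGene)
    out <- do.call(rbind, lapply(targets, function(g) {
        ok <- !is.na(wide[samples, g])
        data.frame(sample_id = samples[ok], gene = g,
                   relative_expression = pfafflRatio(
                       wide[samples[ok], g], calCt[[g]],
                       wide[samples[ok], referenceGene], calCt[[referenceGene]],
                       efficiencies[[g]], efficiencies[[referenceGene]]),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Reference-gene stability check
#'
#' Coefficient of variation and linear temporal trend of one gene's relative
#' expression; a reference gene is usable when its CV is acceptable and any
#' temporal trend is small relative to the target genes' dynamics.
#'
#' @param x a \linkS4class{FastingExperiment} or data.frame with columns
#'   `gene`, `day`, `relative_expression`.
#' @param gene gene to check.
#' @param level significance level for flagging a non-zero trend slope.
#' @return list(cv, slope, pValue, trendFlag, n).
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' referenceStability(fe, "eef1a1")
#' @export
referenceStability <- function(x, gene = "eef1a1", level = 0.05) {
    d <- if (is(x, "FastingExperiment")) exprTable(x) else x
    d <- d[d$gene == gene, , drop = FALSE]
    if (nrow(d) < 2) stop("need at least 2 observations")
    v <- d$relative_expression
    if (mean(v) == 0) stop("zero mean expression")
    cv <- sd(v) / mean(v)
    if (length(unique(d$day)) < 2) {
        slope <- 0; p <- 1
    } else {
        x <- d$day
        sxx <- sum((x - mean(x))^2)
        slope <- sum((x - mean(x)) * (v - mean(v))) / sxx
        res <- v - mean(v) - slope * (x - mean(x))
        n <- length(v)
        se <- sqrt(sum(res^2) / (n - 2) / sxx)
        p <- if (se == 0) { if (slope == 0) 1 else 0 }
             else 2 * pt(-abs(slope / se), n - 2)
    }
    list(cv = cv, slope = slope, pValue = p, trendFlag = p < level,
         n = length(v))
}
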