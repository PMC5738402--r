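## Delimited-table I/O.  All tables are UTF-8 comma-separated files with a
## fixed header; the column dialects match the long-format constructors.

.writeTable <- function(d, path) {
    write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

.readTable <- function(path, need) {
    d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop(basename(path), " lacks column(s): ", paste(miss, collapse = ", "))
    d
}

#' Read and write the canonical long-format tables
#'
#' Expression tables have columns `individual_id, tank_id, temperature, day,
#' gene, relative_expression`; weight tables `individual_id, tank_id,
#' temperature, day, initial_weight_mg, final_weight_mg, weight_loss`
#' (percent of initial mass); Ct tables `sample_id, gene, replicate, ct`.
#'
#' @param x a \linkS4class{FastingExperiment} or the corresponding
#'   data.frame.
#' @param path file path.
#' @return Readers return a data.frame; writers return `path` invisibly.
#' @rdname tableIO
#' @export
writeExpressionTable <- function(x, path) {
    d <- if (is(x, "FastingExperiment")) exprTable(x) else x
    .writeTable(d, path)
}

#' @rdname tableIO
#' @export
readExpressionTable <- function(path)
    .readTable(path, c("individual_id", "tank_id", "temperature", "day",
                       "gene", "relative_expression"))

#' @rdname tableIO
#' @export
writeWeightTable <- function(x, path) {
    d <- if (is(x, "FastingExperiment")) weightTable(x) else x
    .writeTable(d, path)
}

#' @rdname tableIO
#' @export
readWeightTable <- function(path)
    .readTable(path, c("individual_id", "tank_id", "temperature", "day",
                       "initial_weight_mg", "final_weight_mg", "weight_loss"))

#' @rdname tableIO
#' @export
writeCtTable <- function(x, path) .writeTable(x, path)

#' @rdname tableIO
#' @export
readCtTable <- function(path)
    .readTable(path, c("sample_id", "gene", "replicate", "ct"))

#' Persist and restore a ground-truth object
#'
#' YAML round-trip of every generator parameter (per-gene coefficients by
#' temperature group, noise sds, contribution vectors, scaling, weight
#' distribution), so that recovery tests can reload the exact truth that
#' generated a dataset.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path YAML file path.
#' @rdname truthIO
#' @export
writeTruthConfig <- function(truth, path) {
    obj <- list(
        coefficients = lapply(truth@coefficients,
                              function(g) lapply(g, as.numeric)),
        sdLog = as.list(truth@sdLog),
        alpha = lapply(seq_len(nrow(truth@alpha)), function(i)
            as.numeric(truth@alpha[i, ])),
        alphaGroups = rownames(truth@alpha),
        gamma = as.list(truth@gamma),
        sdW = truth@sdW,
        initialWeightMean = truth@initialWeightMean,
        initialWeightSd = truth@initialWeightSd,
        tankSd = truth@tankSd)
    yaml::write_yaml(obj, path, precision = 15)
    invisible(path)
}

#' @rdname truthIO
#' @return `readTruthConfig` returns a \linkS4class{SyntheticTruth}.
#' @export
readTruthConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    alpha <- do.call(rbind, lapply(obj$alpha, as.numeric))
    alpha <- alpha / rowSums(alpha)  # restore the simplex to full precision
    rownames(alpha) <- obj$alphaGroups
    colnames(alpha) <- c("A", "AB", "AC", "B", "C", "null")
    new("SyntheticTruth",
        coefficients = lapply(obj$coefficients,
                              function(g) lapply(g, as.numeric)),
        sdLog = unlist(obj$sdLog),
        alpha = alpha,
        gamma = unlist(obj$gamma),
        sdW = obj$sdW,
        initialWeightMean = obj$initialWeightMean,
        initialWeightSd = obj$initialWeightSd,
        tankSd = obj$tankSd,
        cache = new.env(parent = emptyenv()))
}

#' Write pipeline result tables
#'
#' Helpers used by [runPipeline()] to persist intermediates: the per-gene
#' 20-row selection table, production curves as `(label, temperature, day,
#' value)` rows, and posterior draws as flat `(chain, iteration, parameter,
#' value)` rows.
#'
#' @param sel a \linkS4class{ModelSelectionResult}.
#' @param path output file.
#' @rdname resultIO
#' @export
writeSelectionTable <- function(sel, path) {
    tab <- sel@table
    tab$gene <- sel@gene
    .writeTable(tab[c("gene", "order", "mode", "k", "aic", "adjR2",
                      "deltaAIC")], path)
}

#' @rdname resultIO
#' @param curves nested production-curve list from [productionCurves()].
#' @param thin keep every `thin`-th grid point.
#' @export
writeProductionCurves <- function(curves, path, thin = 20L) {
    rows <- list()
    for (g in names(curves)) for (lab in names(curves[[g]])) {
        pc <- curves[[g]][[lab]]
        i <- unique(c(seq(1, length(pc@days), by = thin), length(pc@days)))
        rows[[paste(g, lab)]] <- data.frame(
            label = lab, temperature = g, day = pc@days[i],
            value = pc@values[i])
    }
    .writeTable(do.call(rbind, rows), path)
}

#' @rdname resultIO
#' @param fit a \linkS4class{WeightLossFit}.
#' @export
writePosteriorDraws <- function(fit, path) {
    rows <- lapply(seq_along(fit@draws), function(ch) {
        m <- fit@draws[[ch]]
        data.frame(chain = ch,
                   iteration = rep(seq_len(nrow(m)), times = ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
    })
    .writeTable(do.call(rbind, rows), path)
}
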