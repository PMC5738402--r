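#' Assemble a FastingExperiment from long-format tables
#'
#' @param expr long-format expression table with columns `individual_id`,
#'   `tank_id`, `temperature`, `day`, `gene`, `relative_expression` (one row
#'   per individual x gene; `temperature` is `NA` for day-0 shared-stock
#'   fish).
#' @param weights optional weight table with columns `individual_id`,
#'   `tank_id`, `temperature`, `day`, `initial_weight_mg`, `final_weight_mg`,
#'   `weight_loss` (percent of initial mass).
#' @return A \linkS4class{FastingExperiment}.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' fe
#' @export
FastingExperiment <- function(expr, weights = NULL) {
    need <- c("individual_id", "tank_id", "temperature", "day", "gene",
              "relative_expression")
    miss <- setdiff(need, colnames(expr))
    if (length(miss))
        stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(expr[c("individual_id", "gene")]))
        stop("each (individual, gene) pair may appear at most once")
    inds <- unique(expr$individual_id)
    genes <- unique(expr$gene)
    mat <- matrix(NA_real_, nrow = length(genes), ncol = length(inds),
                  dimnames = list(genes, inds))
    mat[cbind(match(expr$gene, genes), match(expr$individual_id, inds))] <-
        expr$relative_expression
    meta <- expr[!duplicated(expr$individual_id),
                 c("individual_id", "tank_id", "temperature", "day")]
    meta <- meta[match(inds, meta$individual_id), ]
    cd <- S4Vectors::DataFrame(
        individual = meta$individual_id,
        tank = meta$tank_id,
        temperature = factor(meta$temperature),
        day = meta$day,
        initialWeight = NA_real_, finalWeight = NA_real_,
        weightLoss = NA_real_,
        row.names = inds)
    if (!is.null(weights)) {
        i <- match(inds, weights$individual_id)
        cd$initialWeight <- weights$initial_weight_mg[i]
        cd$finalWeight <- weights$final_weight_mg[i]
        cd$weightLoss <- weights$weight_loss[i]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(relexpr = mat), colData = cd)
    new("FastingExperiment", se)
}

#' Relative-expression assay
#'
#' @param x a \linkS4class{FastingExperiment}.
#' @return Numeric matrix, genes x individuals.
#' @rdname relExpr
#' @export
setMethod("relExpr", "FastingExperiment",
    function(x, ...) SummarizedExperiment::assay(x, "relexpr"))

#' @rdname samplingDays
#' @export
setMethod("samplingDays", "FastingExperiment",
    function(x) sort(unique(x$day)))

#' Long-format expression table of an experiment
#'
#' @param x a \linkS4class{FastingExperiment}.
#' @return data.frame in the canonical long dialect (one row per
#'   individual x gene, `NA` expression rows dropped).
#' @rdname exprTable
#' @export
setMethod("exprTable", "FastingExperiment", function(x, ...) {
    m <- relExpr(x)
    cd <- SummarizedExperiment::colData(x)
    out <- data.frame(
        individual_id = rep(colnames(m), each = nrow(m)),
        tank_id = rep(cd$tank, each = nrow(m)),
        temperature = rep(as.character(cd$temperature), each = nrow(m)),
        day = rep(cd$day, each = nrow(m)),
        gene = rep(rownames(m), times = ncol(m)),
        relative_expression = as.vector(m),
        stringsAsFactors = FALSE)
    out[!is.na(out$relative_expression), , drop = FALSE]
})

#' Weight table of an experiment
#'
#' @param x a \linkS4class{FastingExperiment}.
#' @return data.frame with one row per individual: identifiers, sacrifice
#'   day, initial/final weight (mg) and percent weight loss.
#' @rdname weightTable
#' @export
setMethod("weightTable", "FastingExperiment", function(x, ...) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(
        individual_id = cd$individual,
        tank_id = cd$tank,
        temperature = as.character(cd$temperature),
        day = cd$day,
        initial_weight_mg = cd$initialWeight,
        final_weight_mg = cd$finalWeight,
        weight_loss = cd$weightLoss,
        stringsAsFactors = FALSE)
})

setMethod("show", "FastingExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("FastingExperiment:", nrow(object), "gene(s) x", ncol(object),
        "individual(s)\n")
    cat("  days:", paste(sort(unique(cd$day)), collapse = ", "), "\n")
    tt <- table(as.character(cd$temperature), useNA = "ifany")
    cat("  groups:", paste(names(tt), tt, sep = ":", collapse = ", "),
        "(NA = day-0 shared stock)\n")
    if (any(!is.na(cd$weightLoss)))
        cat("  weight loss: ", sum(!is.na(cd$weightLoss)), " measured, mean ",
            round(mean(cd$weightLoss, na.rm = TRUE), 3), "\n", sep = "")
})
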