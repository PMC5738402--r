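#' @rdname relExpr
#' @export
setGeneric("relExpr", function(x, ...) standardGeneric("relExpr"))

#' @rdname samplingDays
#' @export
setGeneric("samplingDays", function(x, ...) standardGeneric("samplingDays"))

#' @rdname exprTable
#' @export
setGeneric("exprTable", function(x, ...) standardGeneric("exprTable"))

#' @rdname weightTable
#' @export
setGeneric("weightTable", function(x, ...) standardGeneric("weightTable"))

#' @rdname efficiency
#' @export
setGeneric("efficiency", function(x, ...) standardGeneric("efficiency"))

#' @rdname selectModel
#' @export
setGeneric("selectModel", function(x, gene, ...) standardGeneric("selectModel"))

#' @rdname adjustedR2
#' @export
setGeneric("adjustedR2", function(object, ...) standardGeneric("adjustedR2"))

#' @rdname bestModel
#' @export
setGeneric("bestModel", function(x, ...) standardGeneric("bestModel"))

#' @rdname expressionCurve
#' @export
setGeneric("expressionCurve",
    function(model, temperature, ...) standardGeneric("expressionCurve"))

#' @rdname gelmanRubin
#' @export
setGeneric("gelmanRubin", function(x, ...) standardGeneric("gelmanRubin"))

#' @rdname dic
#' @export
setGeneric("dic", function(object, ...) standardGeneric("dic"))

#' @rdname summarizeContributions
#' @export
setGeneric("summarizeContributions",
    function(object, ...) standardGeneric("summarizeContributions"))

#' @rdname contributions
#' @export
setGeneric("contributions", function(object, ...) standardGeneric("contributions"))
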