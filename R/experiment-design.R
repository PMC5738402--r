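#' Default target genes of the fasting panel
#'
#' The four mandatory autophagy genes whose transcript product defines the
#' autophagosome-formation exposure, the four lysosomal cathepsins, and the
#' two catabolic markers (amino-acid and fatty-acid routes).
#'
#' @return Named list of character vectors: `atg`, `lysosomal`, `gdh`, `cpt1`,
#'   `reference`.
#' @examples
#' defaultGeneRoles()
#' @export
defaultGeneRoles <- function() {
    list(
        atg = c("ulk1", "lc3b", "atg7", "atg12"),
        lysosomal = c("catha", "cathd", "cathf", "cathl"),
        gdh = "gdh",
        cpt1 = "cpt1",
        reference = "eef1a1"
    )
}

#' Construct an experimental design
#'
#' @param temperatures character group labels.
#' @param tanksPerGroup,individualsPerTank,sacrificesPerTankPerDate integers.
#' @param samplingIntervalDays,durationDays days.
#' @param includeDay0 take a day-0 baseline sample from the shared stock?
#' @param genes ordered target gene names.
#' @param referenceGene normalisation gene.
#'
#' @return An \linkS4class{ExperimentDesign}.
#' @examples
#' d <- experimentDesign()
#' samplingDays(d)
#' @export
experimentDesign <- function(temperatures = c("9C", "12C"),
                             tanksPerGroup = 5,
                             individualsPerTank = 15,
                             sacrificesPerTankPerDate = 2,
                             samplingIntervalDays = 10,
                             durationDays = 60,
                             includeDay0 = TRUE,
                             genes = unlist(defaultGeneRoles()[
                                 c("atg", "lysosomal", "gdh", "cpt1")],
                                 use.names = FALSE),
                             referenceGene = "eef1a1") {
    new("ExperimentDesign",
        temperatures = as.character(temperatures),
        tanksPerGroup = as.integer(tanksPerGroup),
        individualsPerTank = as.integer(individualsPerTank),
        sacrificesPerTankPerDate = as.integer(sacrificesPerTankPerDate),
        samplingIntervalDays = as.numeric(samplingIntervalDays),
        durationDays = as.numeric(durationDays),
        includeDay0 = isTRUE(includeDay0),
        genes = as.character(genes),
        referenceGene = as.character(referenceGene))
}

#' Sampling dates of a design
#'
#' @param x An \linkS4class{ExperimentDesign}.
#' @return Numeric vector of sampling days (includes day 0 when the design
#'   takes a baseline sample).
#' @rdname samplingDays
#' @export
setMethod("samplingDays", "ExperimentDesign", function(x) {
    post <- seq(x@samplingIntervalDays, x@durationDays,
                by = x@samplingIntervalDays)
    if (x@includeDay0) c(0, post) else post
})

setMethod("show", "ExperimentDesign", function(object) {
    cat("ExperimentDesign:",
        length(object@temperatures), "group(s) x",
        object@tanksPerGroup, "tank(s) x",
        object@individualsPerTank, "individuals\n")
    cat("  groups:", paste(object@temperatures, collapse = ", "), "\n")
    cat("  sampling:", object@sacrificesPerTankPerDate,
        "per tank every", object@samplingIntervalDays, "d over",
        object@durationDays, "d",
        if (object@includeDay0) "(+ day-0 baseline)" else "", "\n")
    cat("  genes:", paste(object@genes, collapse = ", "),
        "| reference:", object@referenceGene, "\n")
})
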