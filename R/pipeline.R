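#' Build a pipeline configuration
#'
#' One structured configuration drives the end-to-end analysis; it can also
#' be written to / read from YAML.  Defaults mirror the study settings:
#' polynomial orders up to 6, 10 000 retained draws, Dirichlet(1,...,1) and
#' Uniform(0, 1000) priors.
#'
#' @param simulate list(seed) to generate data, or `NULL` when reading files.
#' @param input list(expression, weights) of CSV paths (ignored when
#'   simulating); optionally `ct` and `standardCurves` paths plus
#'   `calibrator` to start from the Ct level.
#' @param roles gene-role map (atg quartet, gdh, cpt1, lysosomal, reference).
#' @param integrationStep quadrature step in days.
#' @param mcmc list(draws, chains, seed, mode, adapt, burn).
#' @param outputDir artifact directory.
#' @return A validated config list (class `"fastingPipelineConfig"`).
#' @export
pipelineConfig <- function(simulate = list(seed = 1), input = NULL,
                           roles = defaultGeneRoles(),
                           integrationStep = 0.05,
                           mcmc = list(), outputDir = tempfile("fastrun")) {
    mc <- utils::modifyList(list(draws = 10000, chains = 2, seed = 1,
                                 mode = "two_stage", adapt = 500, burn = 500),
                            mcmc)
    cfg <- structure(list(simulate = simulate, input = input, roles = roles,
                          integrationStep = integrationStep, mcmc = mc,
                          outputDir = outputDir),
                     class = "fastingPipelineConfig")
    .validateConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    do.call(pipelineConfig, obj[intersect(names(obj), names(formals(
        pipelineConfig)))])
}

.validateConfig <- function(cfg) {
    r <- cfg$roles
    if (length(r$atg) != 4L)
        stop("config invalid: the autophagy quartet must contain exactly 4 ",
             "genes (got ", length(r$atg), ")")
    if (length(r$gdh) != 1L || length(r$cpt1) != 1L)
        stop("config invalid: exactly one gene must fill each of the gdh ",
             "and cpt1 roles")
    if (is.null(cfg$simulate) && is.null(cfg$input))
        stop("config invalid: either a simulate block or input paths required")
    if (cfg$integrationStep <= 0) stop("integrationStep must be > 0")
    invisible(TRUE)
}

#' Validate analysis input tables
#'
#' Structural checks run before any computation; all violations are
#' collected, not just the first.
#'
#' @param expr long expression table.
#' @param weights weight table.
#' @param design optional \linkS4class{ExperimentDesign} whose sampling days
#'   define schedule membership.
#' @return data.frame(rule, context) of violations (zero rows when clean).
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' nrow(validateInputs(exprTable(fe), weightTable(fe)))
#' @export
validateInputs <- function(expr, weights = NULL, design = NULL) {
    bad <- list()
    note <- function(rule, context)
        bad[[length(bad) + 1]] <<- data.frame(rule = rule, context = context,
                                              stringsAsFactors = FALSE)
    nonpos <- which(expr$relative_expression <= 0)
    for (i in nonpos)
        note("non-positive expression",
             sprintf("row %d (%s, %s)", i, expr$individual_id[i], expr$gene[i]))
    dup <- which(duplicated(expr[c("individual_id", "gene")]))
    for (i in dup)
        note("duplicate (individual, gene) observation",
             sprintf("row %d (%s, %s)", i, expr$individual_id[i], expr$gene[i]))
    if (!is.null(design)) {
        sched <- samplingDays(design)
        off <- which(!expr$day %in% sched)
        for (i in unique(expr$individual_id[off]))
            note("day outside sampling schedule", i)
    }
    if (!is.null(weights)) {
        wbad <- which(weights$initial_weight_mg <= 0)
        for (i in wbad) note("non-positive initial weight",
                             weights$individual_id[i])
        conv <- 100 * (weights$initial_weight_mg - weights$final_weight_mg) /
            weights$initial_weight_mg
        inc <- which(abs(conv - weights$weight_loss) > 1e-6)
        for (i in inc)
            note("weight-loss convention violated (not percent of initial mass)",
                 weights$individual_id[i])
        onlyW <- setdiff(weights$individual_id, expr$individual_id)
        for (i in onlyW) note("individual in weights absent from expression", i)
        onlyE <- setdiff(expr$individual_id, weights$individual_id)
        for (i in onlyE) note("individual in expression absent from weights", i)
    }
    if (!length(bad))
        return(data.frame(rule = character(), context = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, bad)
}

#' Per-gene dynamics plot
#'
#' Observed points, fitted median and 95% mean-response band per temperature
#' (blue squares at 9C, red circles at 12C, black triangles for the day-0
#' baseline); a single black median and grey band when the selected model
#' carries no temperature term.  The adjusted R-squared of the selected
#' model is annotated on the panel.
#'
#' @param fe a \linkS4class{FastingExperiment}.
#' @param sel a \linkS4class{ModelSelectionResult} for one gene.
#' @param grid prediction grid (days).
#' @return A ggplot object.
#' @export
plotGeneDynamics <- function(fe, sel, grid = NULL) {
    m <- bestModel(sel)
    if (is.null(grid)) grid <- seq(0, m@duration, length.out = 121)
    d <- exprTable(fe)
    d <- d[d$gene == sel@gene, ]
    d$groupLab <- ifelse(is.na(d$temperature), "day 0", d$temperature)
    noTemp <- m@spec@temperatureMode == "none"
    pr <- if (noTemp) {
        p <- predictWithInterval(m, grid, m@groups[1])
        p$temperature <- "shared"; p
    } else {
        do.call(rbind, lapply(m@groups, function(g)
            predictWithInterval(m, grid, g)))
    }
    cols <- c("9C" = "blue", "12C" = "red", "day 0" = "black",
              shared = "black")
    fills <- c("9C" = "lightblue", "12C" = "lightpink", shared = "grey70")
    shapes <- c("9C" = 15, "12C" = 16, "day 0" = 17)
    ggplot2::ggplot() +
        ggplot2::geom_ribbon(data = pr,
            ggplot2::aes(x = day, ymin = lower,
                         ymax = upper, fill = temperature),
            alpha = 0.5) +
        ggplot2::geom_line(data = pr,
            ggplot2::aes(x = day, y = median,
                         colour = temperature)) +
        ggplot2::geom_point(data = d,
            ggplot2::aes(x = day, y = relative_expression,
                         colour = groupLab, shape = groupLab),
            position = ggplot2::position_jitter(width = 0.8, height = 0,
                                                seed = 1),
            size = 1.6) +
        ggplot2::scale_colour_manual(values = cols) +
        ggplot2::scale_fill_manual(values = fills) +
        ggplot2::scale_shape_manual(values = shapes) +
        ggplot2::labs(title = sel@gene,
                      subtitle = sprintf("adjusted R² = %.3f", m@adjR2),
                      x = "day of fasting", y = "relative expression",
                      colour = NULL, fill = NULL, shape = NULL) +
        ggplot2::theme_minimal()
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the full analysis under one config: obtain data (simulate, read
#' tables, or normalise a raw Ct table), validate, select per-gene dynamics
#' models, integrate production curves, fit the weight-loss models M0 and M1
#' by MCMC, compare them by DIC, and persist every intermediate artifact to
#' `config$outputDir`.  Deterministic given the config (including its seeds).
#'
#' @param config from [pipelineConfig()] (or a YAML path).
#' @param design design used for simulation and schedule validation.
#' @param truth generator truth (simulate mode).
#' @return Invisible list of artifacts: `fe`, `selections`, `nullModel`,
#'   `productions`, `fitM0`, `fitM1`, `comparison`, `contributions`,
#'   `validation`, `outputDir`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulate = list(seed = 1),
#'                       mcmc = list(draws = 300, adapt = 150, burn = 150))
#' art <- runPipeline(cfg)
#' art$comparison$preferred
#' }
#' @export
runPipeline <- function(config, design = experimentDesign(),
                        truth = syntheticTruth(design = design)) {
    if (is.character(config)) config <- readPipelineConfig(config)
    .validateConfig(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config$outputDir, ...)
    log <- file(out("pipeline.log"), open = "wt")
    on.exit(close(log), add = TRUE)
    stage <- function(msg) {
        writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), log)
    }
    roles <- config$roles

    ## data ------------------------------------------------------------------
    if (!is.null(config$simulate)) {
        stage(sprintf("simulate: seed %d", config$simulate$seed))
        fe <- simulateExperiment(design, truth, seed = config$simulate$seed)
    } else if (!is.null(config$input$ct)) {
        stage("qpcr: normalising raw Ct table")
        ct <- readCtTable(config$input$ct)
        scTab <- read.csv(config$input$standardCurves)
        eff <- vapply(split(scTab, scTab$gene), function(d)
            efficiency(efficiencyFromStandardCurve(d$dilution, d$ct,
                                                   gene = d$gene[1])),
            numeric(1))
        exprLong <- normalizeCtTable(ct, eff, referenceGene = roles$reference,
                                     calibrator = config$input$calibrator %||%
                                         "sample:calibrator")
        names(exprLong)[names(exprLong) == "sample_id"] <- "individual_id"
        wt <- readWeightTable(config$input$weights)
        ## pseudo-samples (e.g. the unit calibrator) carry no fish metadata
        exprLong <- exprLong[exprLong$individual_id %in% wt$individual_id, ]
        i <- match(exprLong$individual_id, wt$individual_id)
        exprLong$tank_id <- wt$tank_id[i]
        exprLong$temperature <- wt$temperature[i]
        exprLong$day <- wt$day[i]
        fe <- FastingExperiment(exprLong, wt)
    } else {
        stage("read: loading expression and weight tables")
        fe <- FastingExperiment(readExpressionTable(config$input$expression),
                                readWeightTable(config$input$weights))
    }
    writeExpressionTable(fe, out("expression.csv"))
    writeWeightTable(fe, out("weights.csv"))

    checkGenes <- unique(c(roles$atg, roles$lysosomal, roles$gdh, roles$cpt1))
    missGenes <- setdiff(checkGenes, rownames(fe))
    if (length(missGenes))
        stop("configured gene(s) absent from data: ",
             paste(missGenes, collapse = ", "))
    validation <- validateInputs(exprTable(fe), weightTable(fe),
                                 if (!is.null(config$simulate)) design)
    .writeTable(validation, out("validation.csv"))
    if (nrow(validation))
        warning("input validation reported ", nrow(validation), " violation(s)")

    ## dynamics --------------------------------------------------------------
    stage("dynamics: 20-candidate AIC selection per gene")
    targetGenes <- intersect(checkGenes, rownames(fe))
    selections <- lapply(setNames(nm = targetGenes), function(g)
        selectModel(fe, g))
    for (g in targetGenes)
        writeSelectionTable(selections[[g]], out(paste0("selection_", g, ".csv")))
    predGrid <- seq(0, max(fe$day), by = 1)
    preds <- do.call(rbind, lapply(targetGenes, function(g) {
        m <- bestModel(selections[[g]])
        grps <- if (m@spec@temperatureMode == "none") m@groups[1] else m@groups
        cbind(gene = g, do.call(rbind, lapply(grps, function(gr)
            predictWithInterval(m, predGrid, gr))))
    }))
    .writeTable(preds, out("predictions.csv"))

    ## accumulation ----------------------------------------------------------
    stage("accumulate: production-curve integration")
    models <- lapply(selections, bestModel)
    nullModel <- nullExpressionModel(fe, models)
    temps <- levels(droplevels(factor(fe$temperature)))
    prods <- productionCurves(models, nullModel, roles = roles,
                              temperatures = temps,
                              horizon = max(fe$day),
                              step = config$integrationStep)
    writeProductionCurves(prods, out("production_curves.csv"))

    ## inference -------------------------------------------------------------
    mc <- config$mcmc
    stage(sprintf("infer: MCMC %d draws x %d chains (%s mode)",
                  mc$draws, mc$chains, mc$mode))
    fitOne <- function(which) {
        if (mc$mode == "joint")
            runJointWeightMCMC(fe, models, roles = roles, model = which,
                               nDraws = mc$draws, nChains = mc$chains,
                               seed = mc$seed, nAdapt = mc$adapt,
                               nBurn = mc$burn)
        else
            runWeightMCMC(buildWeightModel(prods, fe, model = which),
                          nDraws = mc$draws, nChains = mc$chains,
                          seed = mc$seed, nAdapt = mc$adapt, nBurn = mc$burn)
    }
    fitM0 <- fitOne("M0")
    fitM1 <- fitOne("M1")
    writePosteriorDraws(fitM0, out("posterior_M0.csv"))
    writePosteriorDraws(fitM1, out("posterior_M1.csv"))
    if (any(fitM1@rhat > 1.1))
        warning("Gelman-Rubin R-hat above 1.1 for: ",
                paste(names(which(fitM1@rhat > 1.1)), collapse = ", "),
                " - consider more draws")
    comparison <- compareModels(fitM0, fitM1)
    contrib <- summarizeContributions(fitM1)

    artifacts <- list(fe = fe, selections = selections, nullModel = nullModel,
                      productions = prods, fitM0 = fitM0, fitM1 = fitM1,
                      comparison = comparison, contributions = contrib,
                      validation = validation, outputDir = config$outputDir)
    stage("report: rendering figures and tables")
    renderOutputs(artifacts, config$outputDir)
    stage("done")
    invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render figures and summary tables from pipeline artifacts
#'
#' Writes the per-gene dynamics figure (vector PDF), the contribution table
#' in the two-temperature layout, and the DIC comparison block.
#'
#' @param artifacts list produced by [runPipeline()].
#' @param outDir output directory.
#' @return Invisible vector of written paths.
#' @export
renderOutputs <- function(artifacts, outDir = artifacts$outputDir) {
    need <- c("fe", "selections", "fitM1", "comparison", "contributions")
    miss <- need[!need %in% names(artifacts) |
                 vapply(artifacts[need], is.null, logical(1))]
    if (length(miss))
        stop("missing artifact(s): ", paste(miss, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    figPath <- file.path(outDir, "dynamics.pdf")
    grDevices::pdf(figPath, width = 7, height = 5, onefile = TRUE)
    for (g in names(artifacts$selections))
        print(plotGeneDynamics(artifacts$fe, artifacts$selections[[g]]))
    grDevices::dev.off()

    contribPath <- file.path(outDir, "contributions.csv")
    .writeTable(contributions(artifacts$contributions), contribPath)
    reportPath <- file.path(outDir, "report.txt")
    con <- file(reportPath, open = "wt")
    sink(con); on.exit({ sink(); close(con) }, add = TRUE)
    cmp <- artifacts$comparison
    cat("== Weight-loss model comparison (DIC) ==\n")
    cat(sprintf("  DIC M0 (linear trend only): %.2f\n", cmp$dic0))
    cat(sprintf("  DIC M1 (transcript model) : %.2f\n", cmp$dic1))
    cat(sprintf("  preferred: %s (delta = %.2f)\n\n", cmp$preferred,
                cmp$deltaDIC))
    show(artifacts$contributions)
    cat("\n== Convergence (split-chain R-hat) ==\n")
    print(round(artifacts$fitM1@rhat, 4))
    invisible(c(figPath, contribPath, reportPath))
}
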