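## Deterministic substreams: each component of the simulation re-seeds from
## the master seed plus a fixed offset (and a per-gene counter for expression
## noise), so adding a gene to the panel never perturbs the draws of the
## others and identical seeds give byte-identical tables.
.substream <- function(seed, offset) {
    set.seed((as.integer(seed) %% 1000000L) * 2011L + offset)
}

## Order-independent gene key: a polynomial hash of the gene name, so a
## gene's noise substream does not depend on its position in the panel.
.geneKey <- function(gene) {
    v <- utf8ToInt(gene)
    k <- 0
    for (x in v) k <- (k * 31 + x) %% 99991
    as.integer(k)
}

#' Simulate a destructive-sampling fasting experiment
#'
#' Draws a complete synthetic dataset with the statistical structure the
#' downstream analysis assumes: each sacrificed individual contributes one
#' expression value per gene, `log E = polynomial(t; beta_group) +
#' Normal(0, sd_gene)`, and one weight-loss observation, `W = Eq.-mean(day,
#' group) + Normal(0, sd_W)` where the mean is the gamma-scaled
#' alpha-weighted combination of the true unit-normalised cumulated
#' productions.  Day-0 baseline fish are drawn from the shared stock before
#' temperature assignment (temperature `NA`, weight loss exactly 0).
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param truth a \linkS4class{SyntheticTruth} covering every design gene.
#' @param seed master seed; identical seeds give identical tables.
#' @return A \linkS4class{FastingExperiment}.
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' dim(relExpr(fe))
#' @export
simulateExperiment <- function(design = experimentDesign(),
                               truth = syntheticTruth(design = design),
                               seed = 1) {
    genes <- c(design@genes, design@referenceGene)
    miss <- setdiff(genes, names(truth@coefficients))
    if (length(miss))
        stop("truth does not cover gene(s): ", paste(miss, collapse = ", "))
    postDates <- seq(design@samplingIntervalDays, design@durationDays,
                     by = design@samplingIntervalDays)
    nPerTank <- design@sacrificesPerTankPerDate
    if (nPerTank * length(postDates) > design@individualsPerTank)
        stop("sacrifice schedule exceeds tank occupancy")

    ## sacrifice roster ------------------------------------------------------
    rows <- list()
    if (design@includeDay0) {
        n0 <- nPerTank * design@tanksPerGroup * length(design@temperatures)
        rows[[1]] <- data.frame(
            individual_id = sprintf("stock_%03d", seq_len(n0)),
            tank_id = "stock", temperature = NA_character_, day = 0,
            stringsAsFactors = FALSE)
    }
    for (gi in seq_along(design@temperatures)) {
        grp <- design@temperatures[gi]
        for (tk in seq_len(design@tanksPerGroup)) {
            .substream(seed, 101L + 97L * gi + tk)
            ord <- sample.int(design@individualsPerTank)
            for (di in seq_along(postDates)) {
                picked <- ord[seq((di - 1) * nPerTank + 1, di * nPerTank)]
                rows[[length(rows) + 1]] <- data.frame(
                    individual_id = sprintf("%s_t%d_i%02d", grp, tk, picked),
                    tank_id = sprintf("%s_t%d", grp, tk),
                    temperature = grp, day = postDates[di],
                    stringsAsFactors = FALSE)
            }
        }
    }
    roster <- do.call(rbind, rows)
    nInd <- nrow(roster)

    ## expression ------------------------------------------------------------
    expr <- vector("list", length(genes))
    for (j in seq_along(genes)) {
        g <- genes[j]
        mu <- numeric(nInd)
        for (grp in c(NA, design@temperatures)) {
            sel <- if (is.na(grp)) which(is.na(roster$temperature))
                   else which(!is.na(roster$temperature) &
                              roster$temperature == grp)
            if (length(sel))
                mu[sel] <- .trueLogExpression(truth, g, grp, roster$day[sel],
                                              design@durationDays)
        }
        .substream(seed, 100000L + .geneKey(g))
        noise <- rnorm(nInd, 0, truth@sdLog[[g]])
        if (truth@tankSd > 0) {
            tanks <- unique(roster$tank_id)
            .substream(seed, 300000L + .geneKey(g))
            tEff <- setNames(rnorm(length(tanks), 0, truth@tankSd), tanks)
            noise <- noise + tEff[roster$tank_id]
        }
        expr[[j]] <- data.frame(roster, gene = g,
                                relative_expression = exp(mu + noise),
                                stringsAsFactors = FALSE)
    }
    exprTab <- do.call(rbind, expr)

    ## weights ---------------------------------------------------------------
    .substream(seed, 30011L)
    w0 <- pmax(rnorm(nInd, truth@initialWeightMean, truth@initialWeightSd),
               truth@initialWeightMean / 10)
    meanW <- numeric(nInd)
    roleGenes <- unlist(defaultGeneRoles()[c("atg", "gdh", "cpt1")],
                        use.names = FALSE)
    if (all(roleGenes %in% names(truth@coefficients))) {
        for (grp in design@temperatures) {
            sel <- which(!is.na(roster$temperature) & roster$temperature == grp)
            if (length(sel))
                meanW[sel] <- trueMeanWeightLoss(truth, design,
                                                 roster$day[sel], grp)
        }
    } else {
        message("weight-model role genes absent from truth: ",
                "weight loss simulated as pure observation noise")
    }
    .substream(seed, 40009L)
    W <- meanW + rnorm(nInd, 0, truth@sdW)
    W[roster$day == 0] <- 0
    weightTab <- data.frame(
        roster,
        initial_weight_mg = w0,
        final_weight_mg = w0 * (1 - W / 100),
        weight_loss = W,
        stringsAsFactors = FALSE)
    FastingExperiment(exprTab, weightTab)
}

#' Simulate a raw Ct table consistent with an expression table
#'
#' Inverts the efficiency-corrected relative-quantification arithmetic: for
#' sample s and target gene g with relative expression X and per-sample
#' cDNA-loading factor L (taken from the reference gene's expression values),
#' `Ct = baselineCt - log(X * L) / log(E_g)`; the reference gene gets
#' `Ct = baselineCt - log(L) / log(E_ref)`.  A calibrator pseudo-sample with
#' all inputs equal to 1 is appended so that normalisation against it
#' reproduces the input expression exactly at zero replicate noise.
#'
#' @param x a \linkS4class{FastingExperiment} or long expression table.
#' @param efficiencies named per-gene amplification factors, each in (1, 3).
#' @param referenceGene normalisation gene (must have an efficiency).
#' @param seed seed for replicate noise.
#' @param replicateSd technical-replicate Ct noise sd (cycles); 0 gives
#'   identical duplicates.
#' @param nReplicates technical replicates per (sample, gene).
#' @param baselineCt Ct of one input unit (cycles).
#' @param includeCalibrator append the unit calibrator pseudo-sample?
#' @return data.frame(sample_id, gene, replicate, ct).
#' @examples
#' fe <- simulateExperiment(seed = 1)
#' eff <- setNames(rep(2, 11), rownames(fe))
#' ct <- simulateCtTable(fe, eff)
#' head(ct)
#' @export
simulateCtTable <- function(x, efficiencies, referenceGene = "eef1a1",
                            seed = 1, replicateSd = 0, nReplicates = 2,
                            baselineCt = 24, includeCalibrator = TRUE) {
    d <- if (is(x, "FastingExperiment")) exprTable(x) else x
    if (any(d$relative_expression <= 0)) stop("non-positive expression")
    genes <- unique(d$gene)
    miss <- genes[!genes %in% names(efficiencies)]
    if (length(miss))
        stop("missing efficiency for gene(s): ", paste(miss, collapse = ", "))
    if (any(efficiencies <= 1 | efficiencies >= 3))
        stop("efficiencies must lie in (1, 3)")
    if (!referenceGene %in% names(efficiencies))
        stop("reference gene '", referenceGene, "' lacks an efficiency")
    samples <- unique(d$individual_id)
    ## per-sample loading factor: reference gene's own relative level
    refRows <- d[d$gene == referenceGene, ]
    L <- setNames(rep(1, length(samples)), samples)
    if (nrow(refRows))
        L[refRows$individual_id] <- refRows$relative_expression
    input <- ifelse(d$gene == referenceGene, L[d$individual_id],
                    d$relative_expression * L[d$individual_id])
    ct0 <- baselineCt - log(input) / log(efficiencies[d$gene])
    out <- data.frame(sample_id = rep(d$individual_id, each = nReplicates),
                      gene = rep(d$gene, each = nReplicates),
                      replicate = rep(seq_len(nReplicates), nrow(d)),
                      ct = rep(ct0, each = nReplicates),
                      stringsAsFactors = FALSE)
    if (includeCalibrator) {
        cal <- data.frame(sample_id = "calibrator",
                          gene = rep(genes, each = nReplicates),
                          replicate = rep(seq_len(nReplicates), length(genes)),
                          ct = rep(baselineCt, length(genes) * nReplicates),
                          stringsAsFactors = FALSE)
        out <- rbind(out, cal)
    }
    if (replicateSd > 0) {
        .substream(seed, 700L)
        out$ct <- out$ct + rnorm(nrow(out), 0, replicateSd)
    }
    if (any(out$ct <= 0))
        stop("simulated Ct values are non-positive; raise baselineCt")
    out
}
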