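# eelFasting

Statistical pipeline linking long-term autophagy and lysosome gene-expression
dynamics to cumulative weight loss in fasting glass eels (*Anguilla
anguilla*) held at 9 °C and 12 °C.

Glass eels fast for weeks during estuarine migration, and measuring gene
expression destroys the fish: each individual yields one snapshot at its
sacrifice date.  The pipeline asks whether transcripts *accumulated over
time* — not expression at any single moment — drive an integrated phenotype,
cumulative weight loss, and how that effect splits between autophagosome
formation, amino-acid catabolism and fatty-acid catabolism.

## The model

**Stage 1 — expression dynamics.**  Per gene, log relative expression is a
polynomial in scaled time with temperature as a categorical factor,

log *E*<sub>j</sub>(*t*) = Σ<sub>i</sub> β<sub>i,j</sub> (*t*/*T*)<sup>i</sup>,  i ≤ 6,

fitted by OLS over a 20-candidate family (null; temperature-only; orders 1–6
× {no temperature, additive, interaction}) and selected by AIC, with
adjusted R² and 95% mean-response bands.

**Stage 2 — cumulated production.**  Fitted curves are anti-logged and
integrated from day 0: *P(A)* = ∫ E<sub>ulk1</sub>·E<sub>lc3b</sub>·E<sub>atg7</sub>·E<sub>atg12</sub> dt
(the four transcripts are each mandatory for autophagosome formation, hence
the product), *P(B)* = ∫ E<sub>gdh</sub> dt, *P(C)* = ∫ E<sub>cpt1</sub> dt,
and *P(null)* — a constant-mean pseudo-gene whose cumulated production is
exactly linear, absorbing linear weight-loss trends.

**Stage 3 — weight-loss inference.**  Weight loss of fish *i* in group *j* is

*W*<sub>i,j</sub> = γ<sub>j</sub> [α<sub>1,j</sub>P(A) + α<sub>2,j</sub>P(A)P(B) + α<sub>3,j</sub>P(A)P(C) + α<sub>4,j</sub>P(B) + α<sub>5,j</sub>P(C) + α<sub>6,j</sub>P(null)] + ε,

with α ~ Dirichlet(1,…,1) per temperature (relative contributions summing to
one), γ<sub>j</sub> ~ Uniform(0, 1000), fitted by MCMC (JAGS, 2 chains ×
10 000 draws), checked by Gelman–Rubin R̂, and compared by DIC against the
null-trend-only model M0.  A synthetic destructive-sampling experiment
generator (and a Pfaffl-style qPCR quantification layer down to raw Ct
tables) makes every stage testable by parameter recovery.

## Worked example

```r
library(eelFasting)

fe <- simulateExperiment(seed = 1)          # default: the study design
fe
#> FastingExperiment: 11 gene(s) x 140 individual(s)
#>   days: 0, 10, 20, 30, 40, 50, 60
#>   groups: 12C:60, 9C:60, NA:20 (NA = day-0 shared stock)
#>   weight loss: 140 measured, mean 0.423

selectModel(fe, "cpt1")                     # 20-candidate AIC selection
#> ModelSelectionResult 'cpt1': 20 candidates
#>   selected: order 2, mode interaction (AIC -86.414, adjR2 0.833)

genes6 <- c("ulk1","lc3b","atg7","atg12","gdh","cpt1")
models <- lapply(setNames(nm = genes6), function(g) bestModel(selectModel(fe, g)))
prods  <- productionCurves(models, nullExpressionModel(fe, models),
                           temperatures = c("9C","12C"))
prods[["9C"]]$A
#> ProductionCurve P(A) at 9C: 1201 grid points, step 0.05 d,
#>   P(60) = 0.879 (unit-normalised, raw scale 65.79)

fitM1 <- runWeightMCMC(buildWeightModel(prods, fe),               nDraws = 10000, seed = 1)
fitM0 <- runWeightMCMC(buildWeightModel(prods, fe, model = "M0"), nDraws = 10000, seed = 1)
compareModels(fitM0, fitM1)
#> DIC M0 = -327.0, DIC M1 = -379.9, preferred: M1

summarizeContributions(fitM1)
#> Relative contributions (%) after removing the linear trend:
#>   [9C] linear trend (null gene): 21.33%
#>     atg genes           10.40% (SD = 0.083)
#>     atg genes * gdh     10.57% (SD = 0.098)
#>     gdh                 28.29% (SD = 0.204)
#>     atg genes * cpt1    12.52% (SD = 0.113)
#>     cpt1                38.22% (SD = 0.212)
#>   [12C] linear trend (null gene): 33.61%
#>     ...
```

The posterior means of the temperature scalings in this run are γ(9 °C) =
0.897 and γ(12 °C) = 1.138 against generator truth 0.874 and 1.104; the DIC
difference correctly prefers the transcript model M1 over the pure linear
trend.  The six production regressors are strongly collinear, so individual
contribution weights carry wide posteriors (see the methods vignette); γ, in
contrast, is sharply identified.

The whole analysis can also be driven by one YAML config via `runPipeline()`
(subsumed stages: simulate/read → qPCR normalisation → dynamics →
accumulation → inference → report, every intermediate persisted), or from
the shell through `inst/scripts/run-pipeline.R`.

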