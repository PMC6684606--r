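# beemetab

Metabolomics-based biomarker discovery for nutritional stress in
bumblebees (*Bombus terrestris*), implemented as a tested, fully
simulated R pipeline.

## The problem

Bee pollinators face many interacting stressors, and low carbohydrate
availability is among the most consequential. Hemolymph — the insect
"blood" — carries a metabolic fingerprint of that stress. The workflow
implemented here discovers and validates hemolymph biomarkers of a
low-carbohydrate diet from a 2 × 2 × 2 cohort design: diet (25% vs 50%
sugar syrup), sampling day (6 vs 12) and social hierarchy (worker vs
dominant pseudo-queen), with 26 queen-less microcolonies housing 130
bees and 84 hemolymph samples. Because no public dataset accompanies the
design, the package ships a synthetic-cohort generator with exported
ground truth, so every stage of the analysis can be tested for recovery
of known, planted effects.

The pipeline stages are:

1. **Simulation** — an untargeted LC-MS feature table (2197 components)
   with pooled-QC injections in duplicate after every nine experimental
   injections, per-component exponential injection-order drift,
   log-normal biological and analytical noise, and planted diet/age
   effects; plus a 64-metabolite targeted panel in which the syrup
   sugars (sucrose, fructose) decrease, trehalose stays stable, and key
   amino acids increase under stress.
2. **Preprocessing** — per-component %CV over internal QC injections
   (components kept when %CV < 30), then drift normalization by dividing
   every sample by the mean of the *following two* internal QC
   injections.
3. **Chemometrics** — PCA and orthogonal partial least squares
   discriminant analysis (OPLS-DA), written from scratch. For a centered
   class vector *y* and scaled matrix *X*, orthogonal components
   (variation in *X* uncorrelated with *y*) are stripped one at a time,
   then a single predictive component *t*ₚ = *X*w is extracted with
   w ∝ *X*ᵀ*y*. Models report R²X, R²Y, cross-validated
   Q² = 1 − PRESS/SS, CV-ANOVA (an F-test on cross-validated
   residuals), a label-permutation test, VIP scores
   (VIPᵢ = √p·|wᵢ|/‖w‖, so mean VIP² = 1) and S-plot coordinates.
   A model is *validated* when Q² > 0.5, CV-ANOVA p < 0.05 and the
   permutation test passes.
4. **Biomarker selection** — OPLS-DA models over the stratified dataset
   suite (day-12 workers n=48; day-12 bees n=64; all workers n=58; full
   cohort n=84; per-arm age contrasts n=42; hierarchy contrasts); the
   untargeted biomarker set is the intersection of VIP > 1 components
   across the four validated diet datasets, and the targeted set comes
   from per-metabolite two-way ANOVA (diet × day on log intensities,
   diet-term P < 0.05, Tukey HSD reported) plus stress/control abundance
   ratio tables.
5. **Classification** — biomarker panels (targeted, untargeted,
   combined) evaluated with five standard learners (random forest,
   decision tree, ridge logistic, naive Bayes, multilayer perceptron)
   under stratified 10-fold cross-validation, reporting
   class-frequency-weighted precision ("specificity"), weighted recall
   ("sensitivity") and the ROC area of pooled out-of-fold scores.
6. **Pathway analysis** — hypergeometric over-representation and
   relative-betweenness-centrality impact of the significant metabolites
   against a bundled *synthetic* pathway library (five nutritional-stress
   pathways plus decoys).

## Worked example

```r
library(beemetab)

cfg <- study_config(seed = 1)          # the default 84-sample cohort
design <- generate_design(cfg)
sim <- generate_untargeted_table(design, effect = NULL, config = cfg)

cv_report <- compute_qc_cv(sim$table)
filtered <- filter_components(sim$table, cv_report)
#> filter_components: kept 2157 of 2197 components (%CV < 30)
normalized <- qc_bracket_normalize(filtered)

ds <- build_dataset(normalized, dataset_specs()$T_diet)
model <- fit_oplsda(ds$table$intensity, ds$class, n_orth = 0)
model
#> OPLS-DA model: 1 predictive + 0 orthogonal component(s)
#>   classes: control_50 vs stress_25
#>   R2X = 0.073  R2Y = 0.997

val <- validate_oplsda(ds$table$intensity, ds$class, n_orth = 0,
                       n_permutations = 100, seed = 1)
sprintf("Q2 = %.3f, CV-ANOVA p = %.2e, permutation p = %.3f -> %s",
        val$q2, val$cv_anova_p, val$permutation$p_value, val$verdict)
#> "Q2 = 0.969, CV-ANOVA p = 1.86e-63, permutation p = 0.010 -> good"

vip <- compute_vip(model)
sum(vip$vip > 1)
#> [1] 272
```

The diet model explains nearly all class variance (R²Y = 0.997) with
strong cross-validated predictive ability (Q² = 0.969), passes all three
validation criteria, and 7 of the 8 planted core biomarkers sit in the
top 8 components by VIP. The full pipeline — all stages, ending in the
classifier grid and pathway results — runs from one call:

```r
res <- run_pipeline(default_pipeline_config(seed = 1))
```

and writes TSV/JSON artifacts plus a checksummed run manifest to the
configured output directory.

## Vignette

`vignettes/biomarker-workflow.Rmd` documents the signal/noise model
behind the generator, every tunable parameter with its default and
rationale, the numerical choices inside the chemometrics code, and known
limitations (including the residual within-bracket drift sawtooth that
QC-pair normalization cannot remove).
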