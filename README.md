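# netscore

Coexpression network modules and a convolutional survival score for
transcriptomic risk stratification.

Gene-expression signatures for cancer prognosis built from individually
significant genes validate poorly across cohorts. `netscore` implements a
system-level alternative: survival-relevant structure is first sought at the
level of coexpression *modules*, and a deep survival network is then trained
only on each module's most representative (hub) genes, yielding a scalar
prognostic score — **NetScore** — that can be validated in independent
cohorts and tested against clinical covariates.

## The method

1. **Network construction.** From a training cohort, the Pearson correlation
   matrix over genes is soft-thresholded into an unsigned weighted adjacency
   `a_ij = |r_ij|^β` (default β = 6, or chosen by the scale-free topology
   fit), converted to the topological overlap matrix

   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,  `ℓ_ij = Σ_u a_iu a_uj`,

   and clustered by average linkage on `1 − TOM`. Modules are extracted by a
   dynamic (adaptive-height) tree cut (height cutoff 0.99, deep split 2,
   minimum size 30); unassigned genes are labeled `gray`.
2. **Module screening.** Each module is summarized by its eigengene (first
   principal component of the module's standardized expression). A univariate
   Cox proportional-hazards model of overall survival on each eigengene flags
   survival-related modules at uncorrected p < 0.05; flagged modules are
   re-screened in every test cohort (eigengenes recomputed from the test
   cohort's own expression), and only modules significant everywhere advance.
3. **Representative genes.** Within each advanced module the genes are
   ranked by gene module membership kME (correlation with the eigengene) and
   the top 10 per module form the model input (2 modules × 10 = 20 genes).
4. **NetScore.** A small convolutional survival network: per-module
   one-dimensional filters whose length equals the module's gene block
   (stride = block), three fully connected layers, and a linear scalar
   output. It is trained full-batch by minimizing the negative Cox log
   partial likelihood (Breslow ties) with Adam and decoupled weight decay;
   hyperparameters are chosen by 5-fold cross-validation maximizing the mean
   held-out Harrell C-index.
5. **Survival analytics.** Per cohort: univariate Cox on the continuous
   score, median dichotomization into high/low risk, Kaplan–Meier curves and
   log-rank test, multivariate Cox against clinical covariates, and subgroup
   analyses — plus a C-index comparison against a conventional Cox model on
   the same 20 genes.

Because real multi-cohort microarray collections are not shipped, the package
includes a first-class synthetic generator: block-correlated modules
(`x = λf + ε` around latent module factors), background noise genes, and
exponential proportional-hazards survival whose log-hazard is a linear (or
optionally product-interaction) function of chosen module factors, with
calibrated uniform censoring. Every stage is tested against this planted
ground truth.

## Worked example

```r
library(netscore)

# a two-cohort study with six planted modules, two of them prognostic
sim <- simulation_config(
  n_genes = 240, n_samples_per_cohort = c(300, 200),
  n_modules = 6, module_sizes = rep(30, 6),
  module_loading = rep(0.8, 6),
  survival_effect = c(1, 1, 0, 0, 0, 0),
  censoring_rate_target = 0.3, seed = 42)

cfg <- pipeline_config(simulation = sim, power = 6, genes_per_module = 10,
                       seed = 42)
res <- run_full_pipeline(cfg, "netscore_demo")
#> cohorts: training(n=300), test1(n=200)
#> modules: turquoise=30, blue=30, brown=30, yellow=30, green=30, red=30; gray=60
#> significant in training: turquoise, blue; advanced: turquoise, blue
#> chosen CV config 1 (mean C = 0.677)

res$selected_modules
#> [1] "turquoise" "blue"

head(res$screen[, c("module", "hr", "p", "significant")])
#>      module        hr            p significant
#> 1 turquoise 1.8016563 1.189490e-16        TRUE
#> 2      blue 2.0906343 1.150068e-20        TRUE
#> 3     brown 0.9075091 1.620945e-01       FALSE
#> 4    yellow 1.1209487 1.001303e-01       FALSE
#> 5     green 0.9612754 5.524848e-01       FALSE
#> 6       red 0.9429075 3.770224e-01       FALSE

st1 <- res$analysis$test1
c(c_index = st1$c_index$c_index, se = st1$c_index$se,
  logrank_p = st1$logrank$p)
#>      c_index           se    logrank_p
#> 7.166788e-01 2.396703e-02 2.586238e-13
```

The six 30-gene blocks are recovered as modules with the 120 noise genes
left gray; exactly the two modules whose latent factors drive the hazard
(hazard ratios 1.80 and 2.09 per eigengene SD) are screened in and
validated; their 20 hub genes feed the network; and the resulting score
stratifies the held-out test cohort (C-index 0.72, log-rank p ≈ 3e-13).
The run directory (`netscore_demo/`) contains every stage as TSV, a
markdown report, and a manifest with seeds, parameters and output
checksums; rerunning with the same config and seed reproduces the
checksums bit-for-bit.

A thin command-line wrapper over the same functions is installed at
`inst/cli/netscore.R` (`simulate`, `run-all`, `report` subcommands, YAML
configs).

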