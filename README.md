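# metaboKin

Kinship-aware analysis of the aging plasma metabolome in genetically
structured cohorts.

## The problem

Companion-dog aging cohorts measure targeted LC-MS metabolite panels on
hundreds of dogs spanning wide ranges of age, size, breed ancestry and
environment. Estimating how the plasma metabolome changes with age in such
data requires, in order:

1. **Technical normalization** of peak intensities: filters for
   missingness (>10% of samples) and severe hemolysis (grade 4), natural
   log transform with per-sample mean centering, removal of extraction
   batch and LC-MS run-order drift by residualizing on the
   batch x run-order interaction, per-batch unit-variance scaling,
   10-nearest-neighbour mean imputation, and regression on the remaining
   technical covariates (travel time, arrival temperature, hemolysis
   grade).
2. **Genetic relatedness**: a variance-standardized genomic relatedness
   matrix (GRM) from SNP dosages,
   `K[i,j] = (1/m) * sum_k (g_ik - 2p_k)(g_jk - 2p_k) / (2p_k(1-p_k))`,
   after MAF (> 1%) and call-rate (> 95%) filters.
3. **Mixed-model association**: for each metabolite `y`,

   `y = X beta + Z u + e`, with `u ~ N(0, sigma_g^2 K)`,
   `e ~ N(0, sigma_e^2 I)`

   fitted exactly by one eigendecomposition of K and 1-D optimization of
   the profiled (restricted) likelihood in `delta = sigma_e^2/sigma_g^2`.
   The design X carries the intercept, sqrt(age), sqrt(weight), sex,
   sterilization, fasting duration, CBC covariates and the
   sex x sterilization (and, two-stage, age x weight) interactions.
   SNP-heritability is `H_SNP = sigma_g^2/(sigma_g^2 + sigma_e^2)`;
   fixed effects get Wald t-tests with Benjamini-Hochberg FDR across
   metabolites, per coefficient.
4. **Multivariate structure**: PCA of the column-standardized matrix,
   Tracy-Widom (beta = 1) selection of non-random leading components,
   Type III ANCOVA variance partitioning per PC, and per-PC H_SNP.
5. **Residual covariation**: full adjustment `y' = y - BLUEs - BLUPs`,
   pairwise Pearson correlation with exact-t p-values and FDR, and UPGMA
   clustering on the distance 1 - r (Newick export).
6. **Causal mediation**: how much of the age effect travels through a
   clinical kidney marker (serum creatinine, urine specific gravity):
   ACME by the product of coefficients, case-resampling bootstrap CIs,
   proportion mediated, and a closed-form sensitivity analysis giving
   the residual correlation `rho0` at which the ACME vanishes.

Every stage is exercised end to end by a **synthetic cohort generator**
(`simulate_cohort()`) that emulates the statistical structure of such a
study — ~784 dogs, 137 metabolites, breed-block + admixture relatedness,
injected batch/run-order drift, missingness, hemolysis grades, and an
age -> creatinine -> metabolite mediator chain — with exact ground truth
for effects, heritabilities and mediated proportions.

## Worked example

```r
library(metaboKin)

cfg <- sim_config(n_dogs = 250, n_metabolites = 60, n_snps = 2000,
                  n_breed_blocks = 10, seed = 1)
sim <- simulate_cohort(cfg)
sim$kinship
#> <kinship_matrix> 250 dogs, 2000 markers, mean diag 1.073

mm <- preprocess_pipeline(sim$metabolites)
mm
#> <metab_matrix> 216 samples x 60 metabolites, state = tech_adjusted
#>   missing cells: 0 (0.00%)

scan <- mwas(mm, sim$cohort, sim$kinship)
scan$interaction_removed          # no true age x weight interaction
#> [1] TRUE
length(scan$significant[["sqrt_age"]])
#> [1] 33                          # age-associated metabolites at FDR 0.05

pc <- tracy_widom_select(pca(mm), alpha = 0.05)
pc
#> <pca_decomp> 216 samples, 60 components; leading var explained: 10.2%, ...
#>   Tracy-Widom significant components: 2

hits <- scan$significant[["sqrt_age"]]
med <- mediate_panel(mm, sim$cohort, mediator = "creatinine",
                     metabolites = intersect(hits,
                                             tail(colnames(mm$values), 7)),
                     n_boot = 2000, seed = 1)
med$table[, c("metabolite", "prop_mediated", "q", "rho0")]
#>  metabolite prop_mediated        q    rho0
#>      met054        0.5109 0.000583  0.6043
#>      met055        0.5189 0.000583  0.5539
#>      met056        0.5444 0.000583  0.6815
#>      met057        0.7096 0.000583  0.6872
#>      met058        0.5168 0.000583  0.5305
#>      met059        0.7338 0.000583  0.6074
#>      met060        0.0643 0.386000 -0.0556
```

Reading the output: 216 of 250 dogs survive the hemolysis filter; 33 of
60 metabolites are declared age-associated (the generator plants direct
age effects plus a 7-metabolite mediated block). Of the 7 metabolites in
the mediated block, the six with a true creatinine path (planted
proportions 0.45-0.68) are declared mediated at FDR < 5% with estimated
proportions 0.51-0.73 and large sensitivity roots `rho0` (robust); the
seventh, whose age effect is direct by construction, is correctly
non-significant (q = 0.39) with `rho0` near zero.

The whole pipeline is one call:

```r
run_all(sim_config(), out_dir = "results/run1", seed = 1)
```

which writes every intermediate as TSV, a JSON run manifest, figures plus
their data tables under `results/run1/figures/`, and is byte-reproducible
under a fixed seed. A command-line front end with the same stages lives
at `inst/cli/mwas.R` (subcommands `simulate`, `preprocess`, `grm`,
`run-all`).

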