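---
title: "Models and methods behind metaboKin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaboKin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

metaboKin analyzes targeted LC-MS plasma metabolomics in genetically
structured cohorts: it normalizes intensities, builds a genomic
relatedness matrix (GRM), fits one kinship-structured linear mixed model
per metabolite, partitions multivariate variance, clusters residual
covariation, and quantifies mediation of age effects through clinical
kidney markers. This vignette records the models, the numerical choices,
and the places where the design was genuinely open.

## 1. Technical normalization

The normalization state machine is `raw -> filtered -> logged ->
batch_corrected -> scaled -> imputed -> tech_adjusted`, and operations
refuse to run out of order.

**Filters.** A metabolite is dropped when missing in strictly more than
`max_missing` (default 10%) of samples — a metabolite at exactly the
threshold is retained. Samples with hemolysis grade 4 (plasma hemoglobin
above 500 mg/dL on the CDC reference palette) are removed; the grade is
an ordinal 0–4 score and the threshold (`max_grade = 3`) is config.

**Transform.** Intensities are natural-log transformed and centered by
sample (row means over non-missing cells), which removes per-sample
loading differences. A consequence worth stating: row centering also
subtracts the *average metabolite signal* of each sample, so signal
shared across many metabolites (including covariate effects) is slightly
attenuated. This is inherent to the convention, not an artifact of the
implementation.

**Batch and run-order drift.** LC-MS intensity drifts with the
within-batch processing order. The model `metabolite ~ batch x runorder`
is read as batch-specific intercepts plus batch-specific linear run-order
slopes — the standard meaning of a factor-by-numeric interaction — and,
because batches partition samples, is fitted batch by batch; values are
replaced by residuals. Batches with fewer than 3 non-missing values fall
back to mean removal with a warning. Run order is the within-batch
processing index (1-based); whether correction happens on centered or
uncentered logs is not externally fixed, so the order log -> center ->
drift correction is fixed here and documented.

**Scaling, imputation, technical regression.** Each metabolite is scaled
to unit variance within batch using the n−1 sample SD (a convention fixed
for bit-reproducibility). Missing cells are then imputed by 10-nearest-
neighbour mean imputation: the distance between two samples is the mean
squared difference over metabolites observed in both, neighbours are
drawn from samples observing the target metabolite, and ties break by
sample order. Finally each metabolite is residualized on travel time,
arrival temperature and hemolysis grade (additive linear fit;
rank-revealing solve; constant covariates dropped with a warning).
Missing cells are excluded — never zero-filled — from every fit prior to
imputation. The same k-NN routine serves both the metabolite and
CBC-style imputation passes.

## 2. Relatedness

`compute_grm()` builds the variance-standardized GRM
$K_{ij} = m^{-1}\sum_k z_{ik}z_{jk}$, $z_{ik} = (g_{ik}-2p_k)/
\sqrt{2p_k(1-p_k)}$, with allele frequencies from the analyzed sample
(no external panel is assumed). Residual missing dosages after the
call-rate filter are imputed at $2p_k$ (i.e. $z=0$). K is returned as
computed: it is *not* forced positive semi-definite; model code floors
tiny negative eigenvalues at zero and reports the count. Two properties
matter downstream: the centering makes K singular (the all-ones vector is
a null eigenvector), and with in-sample frequencies the expected
off-diagonal is $-1/(n-1)$, vanishing only as the cohort grows.

Purebred classification labels a dog with its maximum-ancestry breed when
that proportion is at least 0.85 (inclusive), and keeps a breed as an
analysis level only with at least 8 qualifying dogs and, optionally,
both sexes represented.

## 3. The mixed model

Each response is modelled as $y = X\beta + u + e$ with
$u \sim N(0, \sigma_g^2 K)$, $e \sim N(0, \sigma_e^2 I)$. K is
eigendecomposed once; the likelihood is profiled down to one dimension in
$\delta = \sigma_e^2/\sigma_g^2$ and maximized on the log scale over
$\log\delta \in [-25, 25]$ by a 101-point grid scan plus Brent
refinement, with the $\sigma_g^2 = 0$ boundary checked explicitly
(preferred on flat profiles, so K = I reduces exactly to OLS with zero
BLUPs). The RSS term of the profiled likelihood is evaluated in the
eigenbasis of $SKS$ (S the projection off the column space of X).

**Why REML is the default.** The exact ML profile is degenerate for a
centered GRM: $\log|\sigma_g^2(K+\delta I)|$ diverges to $-\infty$ as
$\delta \to 0$ along the K-null direction, and because that direction is
the intercept, the corresponding data coordinate is fitted exactly — the
likelihood density blows up and $\hat h_{SNP} \to 1$ on every fit. REML
works with error contrasts $A'y$ ($A'X = 0$), which removes the
degenerate direction from both likelihood terms; it is well-posed, and
matches what the established mixed-model association tools actually
compute. ML remains available (`reml = FALSE`) and is exact on strictly
positive-definite kinship; the test suite verifies it against a dense
brute-force grid oracle there.

**Inference.** $\hat\beta$ is the GLS solution at the optimum with
covariance $\sigma_g^2 (X'H^{-1}X)^{-1}$, $H = K + \delta I$; t-tests use
n − p degrees of freedom (no Satterthwaite correction — the simple Wald/t
convention). The fixed-effect test is two-sided: age effects run in both
directions. FDR (Benjamini–Hochberg) is applied per coefficient across
metabolites, not pooled across coefficients. The metabolome-wide scan
applies a two-stage rule: fit with the age x weight interaction, and if
no metabolite's interaction survives FDR, refit all without it. Identity
of note: $\hat h_{SNP} = 1/(1+\hat\delta)$, and BLUPs are
$\hat u = K H^{-1}(y - X\hat\beta)$.

The design matrix applies square-root transforms to age and weight
*before* interactions, codes factors 0/1, and standardizes extra numeric
covariates (urinalysis measures, mediators) to zero mean and unit
variance. Degenerate columns are pruned by rank-revealing QR with a
warning. Which CBC covariates enter is a plain argument (`cbc_cols`),
since no fixed enumeration is externally given.

## 4. Multivariate analysis

PCA is the exact SVD of the column-standardized (per-metabolite unit
variance) matrix; component signs are fixed by making the
largest-magnitude loading positive, so results are bit-stable.

**Tracy–Widom selection.** Leading eigenvalues are tested sequentially
against the Tracy–Widom $\beta=1$ null, stopping at the first
non-significant component (matching a "first k components" reading).
Since the observations (samples) are independent by design, the Wishart
degrees of freedom are known (n − 1) and are used directly in the
edge-location/scale normalization; the moment-matched "effective size"
estimator from population-structure testing targets correlated markers
and proved measurably anticonservative here (12% empirical false-positive
rate at $\alpha = 0.05$ on null 500 x 137 matrices, versus ~3–5% for the
known-df normalization). Tail probabilities use the shifted-gamma moment
approximation to TW1 (accurate to ~1e-4, ample for $\alpha$-level
selection).

**ANCOVA.** Type III (marginal) sums of squares per covariate use
sum-to-zero contrasts (Type III is ill-defined under treatment coding)
via single-term deletions. Marginal SS are not additive in non-orthogonal
designs, so reported fractions are normalized against the sum of all
marginal SS plus the residual SS; covariate fractions plus the residual
fraction then sum to 1 by construction. ANCOVA fractions (fixed-effects
only) and per-PC $H_{SNP}$ (mixed model) are reported side by side
without reconciliation — they answer different questions and need not be
additive.

## 5. Residual covariation

Full adjustment is $y' = y - X\hat\beta - \hat u$ (BLUEs and BLUPs both
subtracted, from the age-*inclusive* model by default, with the
alternative available by refitting without age). Pairwise Pearson
correlations get exact-t p-values on n − 2 df (preferred over Fisher's z
for small-sample correctness) and BH-FDR over unordered pairs. UPGMA
clustering uses the distance 1 − r, *not* 1 − |r|: the protein-catabolism
argument concerns positive covariation, so sign matters. The
full-distance height convention is used (a merge is recorded at the
average inter-cluster distance; two items merge at their distance), rows
are sorted lexicographically before agglomeration so ties break by label
order, and the dendrogram exports to Newick.

## 6. Mediation

For mediator M (creatinine-like), two OLS fits share the covariate
design: $M \sim \text{age} + X$ (coefficient $a$) and
$y \sim \text{age} + M + X$ (coefficients $d$, $b$). The ACME is
$\gamma = \hat a \hat b$; the total effect is the age coefficient without
M; in the linear no-interaction model $\gamma + d = \text{total}$ exactly
(verified to 1e-6 on every fit). The kinship random effect is
intentionally absent from mediation models. Inference is nonparametric
case-resampling bootstrap (resample dogs, refit both models; percentile
CIs; default 10,000 resamples with the desk-scale tests at 1,000–2,000);
a permutation-of-age null is available since "bootstrap randomizations of
age" admits both readings. Bootstrap p-values are floored at 1/B.

**Sensitivity.** For an assumed correlation $\rho$ between the structural
errors of the two models, the linear closed form is
$\gamma(\rho) = \hat a\,(\hat\sigma_2/\hat\sigma_1)\,
\bigl(\tilde\rho - \rho\sqrt{(1-\tilde\rho^2)/(1-\rho^2)}\bigr)$,
where $\tilde\rho$ is the observed correlation between mediator-model and
total-effect-model residuals. The curve is monotone, equals the
unadjusted ACME at $\rho = 0$, and crosses zero exactly at
$\rho_0 = \tilde\rho$. A mediation is flagged *sensitive* when
$|\rho_0| \le 0.3$ — an explicit config default, since no numeric cut is
externally fixed. Non-significant rows are reported, never suppressed.

## 7. The synthetic cohort: what it does and does not emulate

Defaults state the world the pipeline targets: 784 dogs, 137
metabolites, ages 0.7–18 years, extraction batches of up to 40 samples
over 5 LC-MS runs, ~87% sterilized, kibble as the 86% reference diet,
travel times log-normal around a 26.3 h median, arrival temperatures
around 18.8 °C, hemolysis grades with ~8% grade 4.

Genetics: 40 breed-like ancestral blocks under a Balding–Nichols model
(Fst 0.2) with Zipf-weighted popularity, 19% purebred dogs, and admixed
dogs mixing 2–8 blocks (median ~5 ancestries) — reflecting a cohort in
which ancestry traces to on the order of a hundred breeds but a handful
dominate. This matters statistically: the number of distinct ancestral
components controls how many informative GRM eigen-directions exist, and
with only 8 equal blocks $h^2$ is too weakly identified at n = 500 for
unbiased recovery. Dosages are binomial given individual allele
frequencies; SNPs failing the 1% MAF floor are regenerated.

Phenotypes are built on the log scale —
$y = X\beta_{true} + bM + d\sqrt{age} + u + \varepsilon$ with
$u \sim N(0, h^2 K)$ — then exponentiated, because the pipeline
log-transforms (round-trip consistency). The mediator chain uses
$a = 0.5$ per $\sqrt{\text{year}}$, unit mediator noise, and a
7-metabolite "ptmAA-like" block: six mediated with true proportions
0.45–0.68 and one age-associated but unmediated, so the mediation module
has an analytic oracle ($\gamma = ab$ exactly, mediator noise Gaussian
and independent of the polygenic term). True heritabilities are spaced
evenly over [0.05, 0.6] (mean ≈ 0.32). Drift draws standard normals and
scales them, so the RNG stream — and hence everything downstream — is
identical whatever the drift SDs, including zero. Hemolysis grade 4 is
independent of metabolite values by default; an optional contamination
mode shifts a configurable metabolite subset, so both the filter and its
motivation are testable.

Not emulated: LC peak shapes, isotopes or spectra; sequencing reads or
imputation error; non-Gaussian metabolite distributions; relatedness
beyond the block/admixture continuum (no explicit litters); missingness
is MCAR. A green test therefore establishes that the *statistical
machinery* behaves as claimed under the stated structure — not that any
particular biological effect size in a real cohort is recovered.

## 8. Numerical conventions and degenerate inputs

* State transitions only advance; imputation guarantees completeness;
  scaling guarantees within-batch unit variance (±1e-8) where estimable.
* Variance-ratio search space: $\log\delta \in [-25, 25]$, tolerance
  1e-10; boundary fits are flagged (`boundary` field), never silent.
* Negative K eigenvalues are floored at zero with a logged count.
* A sample sharing no observed metabolite with any other sample is an
  input error; a metabolite missing everywhere cannot be imputed.
* Collinear design columns are pruned (QR, warning); an absent factor
  reference level is an error.
* Empirical caveat (tested, not assumed): $\hat\sigma_e$ carries
  $\chi^2$ sampling noise of order $n^{-1/2}$, so "zero-noise" fixtures
  approach, but do not hit, $y' = 0$; the adjustment is instead verified
  against the exact identity
  $y' = \delta(K+\delta I)^{-1}(y - X\hat\beta)$.
* All thresholds live in one config namespace; the manifest records
  seeds, counts and checksums, and wall-clock timings are confined to the
  log file so that result files are byte-reproducible.

## 9. Known limitations

Single random effect only (no multi-component or GxE models); Gaussian
responses only; no per-SNP association; mediation is single-mediator,
linear, no treatment–mediator interaction. Tracy–Widom p-values rely on
an approximation unsuitable for extreme tail probabilities (fine for
component counting). The ANCOVA fraction normalization, the UPGMA height
convention, the k-NN tie rule and the sensitivity flag threshold are
conventions — fixed, documented, and configurable where it matters.
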