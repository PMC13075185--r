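---
title: "Methods: stage-specific salinity-tolerance scoring, prediction and allele mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific salinity-tolerance scoring, prediction and allele mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricesalt)
```

`ricesalt` quantifies salinity tolerance in a rice diversity panel screened
in replicate under control and salt-stress conditions at two developmental
stages, classifies genotypes, predicts the multi-trait score from trait
indices, and mines SNP data for favourable alleles. This vignette is the
package's account of the science: the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## 1. Indices and classification

### Stress tolerance index

For every genotype, stage and trait, the STI is the ratio of the
stress-condition replicate mean to the control-condition replicate mean:

$$\mathrm{STI} = \frac{\overline{x}_{\text{stress}}}{\overline{x}_{\text{control}}}.$$

This orientation is deliberate. The inverse ratio (control over stress)
circulates in the screening literature, but it reverses the reading that
higher values mean stronger tolerance and that values above 1 mean stressed
performance above the non-stressed mean — both of which are how tolerance
indices are interpreted in practice and throughout this package. The
inverse orientation remains available via
`compute_sti(..., orientation = "control_over_stress")` for comparison with
legacy analyses. STIs are computed from per-condition replicate means rather
than averaged per-replicate ratios, which keeps the estimator well-defined
when replicates are unpaired between conditions.

Two special cases:

- **SES**, the IRRI visual salt-injury score (integer 1–9, recorded under
  stress only because controls show no symptoms), has no control reading.
  The package uses the convention $\mathrm{SESSTI} = 1/\overline{\mathrm{SES}}$,
  the best attainable score divided by the observed one, so a symptom-free
  genotype (SES = 1) scores exactly 1 and scores decay toward 1/9.
- A zero or missing denominator makes the STI undefined; such records are
  returned flagged, with a warning, and are dropped before scaling.

Ion concentrations feeding the seedling-stage traits are converted from
flame-photometer readings by
`reading (mg/L) × digest volume (L) / (dry weight (g) × molar mass (g/mol))`,
giving mmol per g dry weight (molar masses 23 for Na, 39.1 for K).

Replicate-level comparisons against check genotypes use a one-sided Welch
two-sample t-test per trait (`compare_to_checks()`). No specific test is
canonical for this step; Welch's unequal-variance form is the safest default
for small replicate groups, and pairs with fewer than two replicates on
either side are reported untestable rather than significant.

### Membership functions and classes

Within each stage, each trait's STI is min–max scaled across genotypes
(`MFV = (X − Xmin)/(Xmax − Xmin)`); the genotype's AMFV is the unweighted
mean of its trait MFVs. All traits enter equally, including the ion traits;
no trait-direction flipping is applied, since the STI orientation already
encodes performance (a caveat for sodium-accumulation traits is noted in
§6). A trait that is constant across genotypes has no defined scaling and is
reported as an error naming the trait, not silently imputed.

Classification uses cut points at the AMFV mean ± 1 SD and ± 1.64 SD
(sample SD, $n-1$ denominator), giving the five ordered classes
HS < S < MT < T < HT with inclusive lower bounds. Cut points are always
computed from full-precision mean and SD, never from rounded displays —
rounded thresholds are not reproducible and can misclassify boundary
genotypes. Classification is monotone in AMFV and invariant under shared
affine shifts of the score distribution; the test suite asserts both over
randomized panels.

Cross-stage dynamics compare each genotype's class at the two stages under
the ordinal class order and summarise improved / declined / stable counts
with percentages to one decimal.

## 2. Regularized prediction of AMFV

The trait STIs of a stage are strongly collinear (composite traits such as
TSL, SVI and SVII are built from the same measurements), so ordinary
regression of AMFV on STIs is unstable. The package therefore:

1. Diagnoses collinearity with VIFs (`1/(1 − R²)` of each predictor on the
   rest; values above 10 are flagged; exact collinearity reports `Inf` with
   the column named).
2. Splits genotypes into train/test sets stratified by tolerance class
   (default 80% training, `floor` per class). A class with a single genotype
   goes to training with a warning: an empty training class harms the
   stratification more than an empty test class.
3. Fits the elastic net
   $$\min_{\beta_0,\beta} \tfrac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
   + \lambda\left(\alpha\lVert\beta\rVert_1 +
   \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$
   by cyclic coordinate descent on internally standardized predictors
   (mean 0, population SD 1), returning coefficients on the original scale
   for reportable prediction equations.

Numerical choices for the solver: coordinate updates run in moment space
(the standardized Gram matrix and cross-moments), compiled in C++, so a
full sweep costs $O(p^2)$ regardless of $n$; convergence is declared when
the largest standardized-coefficient change in a sweep falls below `1e-7`
(cap $10^5$ sweeps); coefficients start at zero, or warm-start from the
previous lambda along a path. The penalized objective is non-increasing
across sweeps (asserted in tests), and the solver is oracle-checked against
ordinary least squares at $\lambda = 0$, the soft-threshold closed form on
orthonormal designs at $\alpha = 1$, the ridge closed form at $\alpha = 0$,
and an independent elastic-net implementation.

`cv_select()` evaluates a grid of mixing parameters (default
$\alpha \in \{0, 0.1, \ldots, 1\}$) with $k$-fold cross-validation (default
$k = 10$; no single $k$ is canonical, and 10 is the common default at
panel-scale $n$). For each $\alpha$ a 100-point descending lambda path is
fitted with warm starts (path from $\lambda_{\max}$, the smallest lambda
that zeroes all coefficients, down four decades); folds are seeded and
shared across the grid. The winner minimizes CV MSE; $\lambda_{1se}$, the
largest lambda within one standard error of the minimum, is also reported
with its simpler model. "Significant predictors" of the final model are its
nonzero-coefficient (active) set — no coefficient inference is attempted.

Fit metrics are MSE, RMSE, `NMSE = MSE / population variance of the
observations` (so a constant mean predictor scores exactly 1, and
NMSE ≈ 1 − R²), R² and adjusted R². Single-trait predictive strength is the
squared Pearson correlation between AMFV and one trait's STI.

A note on expectations: AMFV is, by construction, exactly an affine
function of the trait MFVs, and each MFV is affine in its STI. A linear
model of AMFV on the full STI set can therefore fit near-perfectly; test-set
R² close to 1 on synthetic data is a property of the score's construction,
not evidence of biological signal.

## 3. Genotype QC

`apply_qc()` filters a biallelic SNP matrix with the screening defaults:
samples with more than 20% missing calls, then markers with more than 10%
missing calls, minor allele frequency below 5%, or heterozygosity above 50%
(computed per marker over non-missing calls, the signature of paralogous or
erroneous loci in an inbreeding crop). Thresholds quoted with strict
inequalities are honoured strictly — a marker exactly at a threshold is
retained — because QC dialects differ on boundary handling and the choice
must be documented. MAF uses allele counts over non-missing calls:
$p = (2\,\text{homAlt} + \text{het})/(2\,\text{called})$.

Marker statistics are recomputed after sample removal. Because removing
markers in turn changes per-sample missingness, a single pass is not a fixed
point: on marginal matrices a second pass can remove further samples. The
filter cycle therefore repeats until a full pass removes nothing, making
`apply_qc()` idempotent by construction; on clean data the first cycle
already converges, and the report records every cycle with removed/retained
counts per filter. QC is verified against a brute-force per-entry recount
oracle on randomized matrices.

I/O: VCF reading (GT field; multi-allelic and indel records skipped with a
count) and a plain-text VCF writer; a HapMap reader accepting two-letter
diploid calls and single-letter IUPAC heterozygote codes.

## 4. Association scan and allele mining

The scan is a per-marker additive fixed-effect regression: trait on
alt-allele dosage (0/1/2) over non-missing samples, two-sided p-value from
the slope t-statistic, PVE = 100 × R². This is a deliberately transparent
stand-in for multi-locus iterative GWAS models (BLINK-class methods), whose
machinery is out of scope here; everything downstream — Bonferroni
thresholding at $\alpha/m$ (default $\alpha = 0.05$, configurable), MTA
naming (`q<TRAIT><chrom>.<index>`, position-ordered within trait and
chromosome), PVE, and allele mining — sits on top of any scan. No kinship or
structure covariates are fitted by default; a covariate matrix can be
supplied and is residualized out of trait and dosage. Raw trait values
measured under stress (not the composite STI) are what the pipeline scans,
since a ratio index has no per-marker additive interpretation. Markers that
are monomorphic or have fewer than 3 informative samples yield `NA`
statistics and are excluded from significance.

Favourable-allele calls compare mean trait values between the two
*homozygote* classes only (heterozygotes excluded, matching the homozygous
semantics of multilocus combinations); the favourable allele (FA) is the
better-mean allele under the configured trait direction (default: higher is
better for every trait; per-trait overrides exist for traits like sodium
accumulation where lower is better). Allelic advantage is
$100 \times (\mu_{FA} - \mu_{AA})/\mu_{AA}$ — the formula is stated because
published percentages are not always reconstructible from printed class
means, and this package does not attempt to force such agreement. Ties are
broken alphabetically with a warning; an empty homozygote class flags the
record rather than guessing.

Combination analysis groups genotypes homozygous at *every* listed locus by
their allele string (one letter per locus, locus order as given) and ranks
groups by mean trait value. Candidate-gene windows report every annotated
gene (GFF3, feature type `gene`, 1-based inclusive intervals) intersecting
±150 kb around a significant SNP — the default window reflecting typical
linkage-disequilibrium decay in rice panels — with distance 0 for SNPs
inside a gene and nearest-boundary distance in kb otherwise; the nearest
gene per MTA is flagged, and `within_gene` implies distance 0 by definition.
Superior-genotype intersection keeps only genotypes carrying at least one
trait's top-ranked combination, in an UpSet-ready membership table.

## 5. The synthetic-data generator

`sim_config()` defaults encode the screening design the package targets:
201 genotypes, 3 replicates, two stages with 8 germination traits and 16
seedling traits, control vs. 120 mM NaCl stress, 500 SNPs with 5 causal
loci. Structure:

- **Latent tolerance.** Stage 1: the standardized sum of causal-allele
  dosages plus an independent standard-normal residual (so
  `causal_effect_sizes` are in residual-SD units; default 0.8 per locus).
  Stage 2: $\rho\,\ell_1 + \sqrt{1-\rho^2}\,z$ with independent $z$, giving
  between-stage correlation $\rho$ exactly in expectation for any
  $\rho \in [-1, 1]$, including degenerate equality at $\rho = 1$. The
  default $\rho = 0.7$ reflects a panel where most genotypes keep their
  class across stages. Causal loci are drawn among markers with allele
  frequency in [0.2, 0.8] so planted effects are detectable at panel-scale
  $n$.
- **Traits.** Control replicate = trait baseline × lognormal noise with CV
  `noise_cv` (default 10%, a typical replicate CV for controlled assays; no
  empirical replicate variance components were available to calibrate
  against, so this is a stated choice, not an estimate). Stress replicate =
  control expectation × $(1 - s\,(1 - \sigma(\ell)))$ × noise, with
  $\sigma$ the logistic function and `stress_severity` $s = 0.45$ by
  default — a substantial but non-lethal mean reduction consistent with
  screening at 120 mM NaCl. Higher latent tolerance thus means smaller
  stress reduction, monotonically. SVI and SVII are computed per replicate
  as GP × TSL and GP × DW so the composite traits stay internally
  consistent; SES is an integer 1–9 decreasing in latent tolerance, emitted
  under stress only. Trait baselines are arbitrary positive constants —
  every downstream index is scale-free, so units need no biological
  calibration.
- **Genotypes.** Allele frequencies from Beta(0.5, 0.5) truncated to
  [0.05, 0.95] (a U-shaped spectrum with the QC-relevant tails),
  Hardy–Weinberg calls, positions strictly increasing within 12
  chromosomes, heterozygote excess injected by resampling calls to het
  (exercising the >50% heterozygosity filter), and
  missing-completely-at-random calls from independent per-marker and
  per-sample rates.

What the generator does **not** emulate: linkage-disequilibrium blocks,
population structure, genotype-by-environment interaction beyond the single
stress factor, dominance, or informative missingness. Passing tests on this
generator therefore demonstrate that the pipeline's computations are
correct and calibrated under an additive, structure-free model — not that
the association scan is robust to confounding by relatedness, which real
panels exhibit and which the optional covariate hook only partially
addresses.

Determinism: a config seed fixes every draw; the pipeline derives per-stage
seeds from its master seed by fixed offsets, so stages can be rerun in
isolation and a full rerun reproduces all outputs bit-identically.

## 6. Known limitations and open points

- The association scan fits no population-structure correction by default;
  on structured panels its p-values will be inflated relative to
  mixed-model or multi-locus methods.
- Sodium-accumulation STIs enter AMFV as-is (higher stressed Na relative to
  control raises the score). Whether they should be direction-inverted
  before scaling is a genuine modelling choice; the package keeps the
  literal rule and exposes per-trait direction overrides in the mining
  step, where the choice is explicit.
- NMSE uses the population-variance convention; analysts expecting the
  sample-variance version will see values larger by $n/(n-1)$.
- Problem sizes in the test suite (panels of 60–300 genotypes, 20–1000
  markers, 20–200 simulation replicates) were chosen so the full suite and
  the acceptance script each run in minutes on one CPU while keeping
  Monte-Carlo error bands (3 SE) meaningful; they are stated in the tests
  themselves.
- The five-class thresholds assume an approximately unimodal AMFV
  distribution; on strongly bimodal panels the ±1 SD band can swallow most
  genotypes, which is a property of the published rule, not of this
  implementation.
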