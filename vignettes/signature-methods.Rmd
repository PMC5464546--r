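---
title: "Multi-protein survival signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-protein survival signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnbcsig)
```

This vignette is the package's own account of the science it
implements: the statistical model behind each stage, the tunable
parameters with their defaults and rationale, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite does not itself
compute.

## The problem

Triple-negative breast cancer is treated with adjuvant chemotherapy
alone, and relapse risk after surgery approaches one half in
node-positive disease. The pipeline implemented here asks whether a
small set of proteins, quantified by label-free mass spectrometry in
archival FFPE tissue, separates patients by distant metastasis-free
survival (DMFS, years from surgery to distant relapse or last
follow-up, censored), and whether a signature frozen on a discovery
cohort transfers to other quantification platforms — targeted
proteomics (parallel reaction monitoring, PRM) and transcriptomics
arrays.

## Preprocessing chain

The stage order is fixed and enforced: outlier-sample exclusion →
quantifiable-protein filter → log2 → imputation → z-score → batch
correction. Each stage's dimensions are recorded in a
`preprocess_report`.

**Quantifiable proteins.** A protein is kept when it has at least
`min_unique_peptides = 2` unique peptides and is detected (LFQ > 0) in
at least `min_detect_frac = 0.75` of samples. Both boundaries are
inclusive, reading "at least" literally; a protein detected in exactly
75% of samples with exactly 2 peptides survives. An LFQ intensity of
zero means "not quantified" in label-free practice and is treated as
missing everywhere, as is an empty cell.

**Outlier samples.** A sample whose identified-unique-peptide count
falls strictly below mean − 2·SD (sample SD) of all samples is
excluded. The rule is applied once, not iterated — it is a gross
acquisition-failure guard, not an outlier model. With very few samples
the threshold can go negative and nothing is excluded; the test suite
documents this insensitivity deliberately.

**Imputation.** Missing label-free values are left-censored: low
abundance makes a protein drop below the detection limit. Each masked
entry is drawn from `Normal(mean_p − 1.8·sd_p, (0.3·sd_p)^2)` where
`mean_p`, `sd_p` are the protein's observed moments — the widely used
downshifted-Gaussian convention with its published default width (0.3)
and downshift (1.8). Both are exposed in the run configuration. Row
(protein) moments are the primary convention; a protein with fewer than
two observed values falls back to the sample's column moments, and the
fallback is logged. The method the convention originates from operates
per column of a samples × features matrix; we fix row = protein
semantics and document the orientation here. Whether the original
study imputed before or after batch correction is not stated anywhere;
imputation-first is this package's declared convention (ComBat requires
a complete matrix).

**Standardization and batch correction.** Protein-wise z-scores use the
sample SD (n − 1); that convention is applied globally wherever an SD
is unspecified. Batch effects are removed with a parametric
empirical-Bayes location/scale adjustment (the ComBat algorithm):
standardize each protein against the batch-size-weighted grand mean and
pooled variance, estimate per-batch location and scale effects, shrink
them toward batch-level normal / inverse-gamma priors by the iterative
conditional solution, remove, restore. No covariates and no reference
batch. A single batch is an exact identity with a notice. Two
properties of the estimator worth knowing: (i) when the true batch
effect is homogeneous across proteins, the across-protein variance of
the batch-mean estimates is pure sampling noise, the prior is tight,
and the shrunken correction retains roughly half of that per-batch
noise (about `0.5·sqrt(1/n_k)` per protein SD) — exact mean-centering
removes more in that artificial case; (ii) the weighted grand mean is
preserved only approximately (drift well below 0.01 of a protein SD in
the tested regimes), because shrinkage redistributes noise between
batches.

## Univariate Cox screen

Each protein is fit in a univariate Cox proportional-hazards model
against DMFS by Newton–Raphson on the partial likelihood (Efron tie
handling by default, Breslow available; tolerance 1e-8, at most 50
iterations). The per-protein p-value is the Wald statistic
`(β/se)²` against chi-square(1); proteins with p < 0.01 (strict) are
selected, with no multiplicity correction — the screen is a feature
selector feeding a validated predictor, not an inferential endpoint.
Monotone likelihoods (separation) and constant covariates yield flagged
results with `NA` estimates rather than errors, and flagged proteins
are excluded from selection with a log entry. The screen shares the
risk-set bookkeeping across proteins (one vectorized Newton–Raphson
over matrix columns), which is what makes permutation testing with full
refits affordable. Whether the original analysis used Wald, score, or
likelihood-ratio p-values is unstated; Wald is the declared,
configurable convention. At moderate event counts the Cox Wald test
runs slightly liberal (fractions nearer 1.3% than 1.0% pass a 1%
screen under the null); the acceptance suite therefore checks
calibration as the seed-set mean count against the single-cohort
binomial band.

## Correlation groups and reduced profiles

Screened proteins are grouped by expression correlation: an edge joins
any pair with Pearson r > 0.5 (strict), and groups are the connected
components — the transitive closure is the minimal structure consistent
with "proteins correlated above 0.5 are grouped together", since no
linkage rule was specified. Reduced candidate signatures of 3–7
proteins are sampled by drawing 1–2 proteins from each of several
distinct groups; profiles are de-duplicated as sets and deterministic
under the run seed. Restricting redundancy this way is the point: a
group contributes at most two correlated readouts, so a small profile
spans independent information.

## Supervised principal-component risk score

Supervision is the screening step (features already filtered by
survival association); the risk score is then the first principal
component of the survivors, one component by design. Concretely: rows
are standardized by training mean/SD; each row is sign-aligned by its
univariate Cox coefficient; the first right singular vector of the
samples × proteins matrix becomes the loading (unit norm, signs folded
back so scoring uses the original values); the score is the inner
product of loading and standardized profile; the orientation is fixed
so that higher score implies higher hazard (ties broken by making the
first loading coordinate positive).

The sign-alignment step deviates from a plain first singular vector
and deserves its rationale. Supervised PC assumes the screened
features share one latent risk factor. When survivors instead span
several mutually independent correlation groups — precisely the
structure the grouping step is designed to find — the top two singular
values come close, and the raw first PC can capture the between-group
*contrast*, a direction orthogonal to risk. During development this
produced training log-rank chi-square ≈ 0.5 on cohorts where the
screen had recovered the planted signal completely. Flipping rows so
every feature points in its own direction of higher hazard restores
the shared-factor geometry (it is a no-op when effects already share a
sign, e.g. in the package's closed-form tests) while keeping the score
a single principal component.

**Cutoff.** The split is decided a priori, before validation: with
low-risk fraction `f` (0.5 for "50:50", 0.7 for "70:30") and n
training samples, the `⌈f·n⌉`-th smallest training score is the last
low-risk sample; a score strictly above that threshold is high-risk,
a score exactly at it is low-risk. Rank-based, stable under ties in
sample order.

## Validation machinery

**Leave-one-out cross-validation** is honest: each fold re-runs the
screen (the protein list is refit), refits the supervised PC and its
cutoff, and assigns only the held-out sample with the fold's frozen
constants. Folds with zero events or fewer than two screened proteins
are flagged `NA`. This mirrors the documented cross-validation
behavior of the array-analysis tool the original study used.

**Permutation testing** permutes the (time, event) pairs jointly
against the samples, refits inside each permutation, and uses the
add-one estimator `(1 + #{χ²_perm ≥ χ²_obs})/(B + 1)`. For the
all-survivors signature the permutation closure re-runs the screen —
protecting against selection bias — with a degenerate refit (fewer
than two survivors) scored as statistic 0. For a *named* reduced
profile the composition is held fixed and loadings, orientation, and
cutoff are refit: re-screening would change the hypothesis from "this
profile separates risk" to "some profile separates risk". The null
calibration test uses a fixed-profile closure for a related reason: a
screen-gated statistic has a large null atom at zero (the screen
rarely fires on null data at small n), making the p-value distribution
conservative rather than uniform; uniformity is the property of the
continuous-statistic regime.

**Cross-platform transfer** never refits loadings. PRM peptide ratios
are `log2(Σ light areas / Σ heavy areas)` per peptide and sample (a
zero in either channel leaves the cell missing with a QC flag),
aggregated to proteins by the median across peptides (robust to one
interfered peptide; mean available); the aggregation never
manufactures a value. Transcriptomics matrices pass through per-gene
probe selection (highest coefficient of variation on the native log2
scale, ties to the lexicographically smallest probe id), the
triple-negative expression filter (exclude ESR1 > 12 or ERBB2 > 11.8,
boundaries kept; units presumed log2 array scale, thresholds
configurable), and per-gene median normalization to discovery medians.
In both cases the model proteins are re-standardized *within the
validation cohort* and the cutoff is re-derived from the validation
score distribution at the stated fraction — mirroring the cohort-level
50:50 / 70:30 cutoffs of the original analysis rather than
transplanting a threshold across platforms whose scales do not align.

## Survival statistics

The product-limit estimator processes deaths before censorings at tied
times (standard convention; at-risk counts at an event time include
samples censored exactly then). t-year DMFS is read off the KM step
function, right-continuous, with an explicit extrapolation flag past
the last observed time. The two-group log-rank test uses the
hypergeometric variance; on tie-free data it equals the score test of
the group-indicator Cox model, which the suite asserts as a
cross-module consistency check. Group hazard ratios come from the
group-indicator Cox fit with a normal 95% CI on the log scale.
Multivariate Cox models take data frames of covariates, expanding
factors against their first level (T1 / N0 as references in natural
level order), and refuse rank-deficient designs naming the aliased
columns.

## The synthetic world

`simulate_cohort()` generates the structure the analysis assumes, so
every downstream stage is testable offline:

- **Factor model.** A latent score u ~ N(0,1) drives an exponential
  hazard `h0·exp(b·u)`; censoring is an independent exponential. Each
  planted protein is a noisy readout of u: planted proteins form
  `n_signal_blocks = 2` correlation blocks with within-block
  correlation `corr_rho = 0.6` and cross-block correlation
  `signal_cross_rho = 0.25` (their shared loading on u). The defaults
  put within-block correlations above the r > 0.5 grouping threshold
  and cross-block ones safely below it, so the grouping stage has
  several genuine prognostic groups to find. `beta_per_sd` is the
  *marginal* per-protein log hazard ratio per SD: the latent
  coefficient is `beta_per_sd / sqrt(loading)` so the stated effect
  size holds exactly at the protein level. Exponential rather than
  Weibull times: the simplest model satisfying proportional hazards,
  which is all the screen assumes.
- **Missingness** is missing-not-at-random with logistic probability
  `plogis(missing_intercept − missing_slope·x)` on the log2 intensity,
  slope 1 per log2 unit. With abundances uniform on 20–30 the default
  intercept 20 yields ≈ 7% missing entries concentrated in the
  low-abundance tail — a match-between-runs-like regime in which the
  75% detection filter then removes roughly the lowest decile of
  proteins. Event/censor exponentials use common random numbers per
  seed, so the event fraction is monotone in the baseline hazard by
  construction.
- **Rates.** Baseline hazard and censoring rate both default to 0.1
  events/year, giving ≈ 50% events over a follow-up distribution
  comparable to a 5–8-year clinical series.
- **Derived platforms.** PRM transition tables give each monitored
  peptide 3–6 product ions with lognormal base areas; the light
  channel is proportional to `2^(protein level)` with lognormal noise,
  the heavy channel constant per peptide — so summed-area log2 L/H
  recovers the protein level up to a per-peptide offset, exactly at
  zero noise. Array cohorts map protein levels into probe space with
  probe-specific offsets and noise and add ESR1/ERBB2 genes spanning
  the exclusion thresholds.

What the generator does **not** emulate: peptide detectability and
interference models, retention-time structure, correlated censoring,
non-proportional hazards, heterogeneous per-protein batch effects, and
cohort-level confounding between batch and outcome. A green test
establishes that the implementation does what the model says on data
satisfying the model's assumptions — not that the assumptions hold in
any particular clinical series.

## Effect sizes used in the tests

The screen-power world uses a marginal effect of 0.7 log HR per SD
(20 planted among 1000 proteins, n = 150, ≈ 50% censoring); the
predictor-recovery world uses 0.9, anchored to the published screen
table of the study this pipeline re-implements, whose 18 hits have
|log HR| between 0.28 and 1.5 (median ≈ 0.9) on z-scored data. Null
calibration worlds set the planted effect to zero and protein
correlation to zero, since binomial bands and KS uniformity presume
independent tests.

## Numerical conventions and degenerate inputs

- Cox Newton–Raphson: tolerance 1e-8 on the step, 50 iterations,
  damped early steps; separation flags the fit (`NA` estimates) rather
  than erroring. The multivariate fitter adds step-halving on the
  partial log-likelihood.
- Quantile splits break ties by stable sample order; the boundary
  sample is low-risk.
- Text round-trips are bit-exact: matrices are written at 17
  significant digits, locale-independent (decimal point only), and
  signature models serialize to JSON at full precision, so a frozen
  model scores identically after a round-trip.
- Single-batch ComBat, empty filter results, zero-event folds,
  all-missing aggregation cells, and samples missing model proteins
  all follow documented identity/`NA`/warning paths rather than
  failing silently.

## Known limitations

- One principal component only; cohorts whose risk structure needs
  two or more latent directions are out of scope by design.
- The permutation test for named reduced profiles conditions on the
  profile composition; it does not re-randomize the earlier screening
  and grouping steps.
- ComBat is the parametric-prior variant without covariates or
  reference batch; non-parametric priors and kNN/MinProb imputation
  alternatives are out of scope.
- The published cohorts' clinical outcomes are not public, so the
  original hazard ratios are shipped as reference fixtures
  (`tnbc_screen_table()`, `tnbc_predictors()`) and are not
  recomputable targets; all quantitative validation runs on synthetic
  cohorts with planted truth.
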