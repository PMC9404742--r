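---
title: "Indirect methane phenotypes and their genetic parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect methane phenotypes and their genetic parameters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkCH4)
```

## The problem

Enteric methane is the dominant greenhouse-gas output of dairy production,
but measuring it directly (respiration chambers, SF6 tracers, sniffers)
is expensive and impossible at the scale needed for genetic evaluation.
`milkCH4` implements the indirect route: per-lactation methane is predicted
from routinely recorded milk yield and composition, and the predicted
phenotype is then treated like any other production trait in a pedigree-based
variance-component analysis.  The package covers the whole chain — phenotype
construction, pedigree algebra, REML estimation, and reporting — plus a
synthetic-herd generator so that every step can be validated by parameter
recovery without access to herd-book data.

## Phenotype construction

Three published prediction equations are used, all in g methane per
lactation:

* `mpe1 = 299 + 2.73 * MY` — from milk yield (kg/lactation),
* `mpe2 = 259 + 3.86 * ECM` — from energy-corrected milk,
* `mpe3 = 150 + 4.31 * ECM + 28.3 * CPC` — from ECM and protein
  concentration,

with `ECM = 0.327 * milk + 12.95 * fat + 7.2 * protein` (kg/lactation) and
`CPC = 100 * protein / milk` (%).  CPC is defined here explicitly as protein
yield over milk yield, since only its name and unit are given where the
equations are published.  The equations are applied to per-lactation totals;
dividing by lactation length gives g/day, reported as integers.

Two structural facts matter for interpretation:

* `mpe1` is an *exact affine function* of milk yield, so its phenotypic and
  genetic correlations with milk are 1 by construction.  Published sub-unit
  correlations between milk-only methane predictions and milk yield cannot
  be reproduced from these definitions; the simulator offers an optional
  independent noise term (`methane_noise_sd`) for exploring that regime, but
  the package makes no attempt to match such values.
* The standard errors published with the equation coefficients are carried
  as metadata in `methane_equations()` only; they are not propagated into
  the phenotypes.

## The repeatability animal model

For records `y` (one per cow-parity):

`y = Xb + Za + Wpe + e`

* `b`: fixed effects — parity (1–6), herd, year, season of calving as
  factors, lactation length (200–400 d) as a single linear covariate.
  Treatment contrasts drop the first level of each factor; covariates are
  centred at their sample mean (estimates are invariant to affine rescaling
  of a covariate).  Factors with a single observed level are dropped with a
  message.  Herd, year and season enter as separate main effects; no
  interactions.
* `a ~ N(0, A * sigma2_a)`: additive genetic effects, one per pedigree
  animal, with `A` the numerator relationship matrix.
* `pe ~ N(0, I * sigma2_pe)`: permanent environment, one per recorded cow,
  shared by her repeated lactations.
* `e ~ N(0, I * sigma2_e)`.

Derived parameters: heritability `h2 = sigma2_a / sigma2_P`, repeatability
`r = (sigma2_a + sigma2_pe) / sigma2_P` with
`sigma2_P = sigma2_a + sigma2_pe + sigma2_e`; for two traits,
`rg = cov_a / sqrt(var_a_x * var_a_y)` and the phenotypic analogue on the
summed blocks.  `r >= h2` always; both are reported at 2 decimals in the
tables, full precision internally.

## Pedigree algebra

Pedigrees are topologically sorted (parents first, stable tie-break by input
order); animals appearing only as parents are inserted as founders; cycles
and duplicates are hard errors.  Unknown parents are treated as unrelated,
non-inbred base animals — the conventional choice, stated here because the
interplay of unknown parents and pruning with inbreeding is a convention,
not something the data dictate.  `prune_generations()` keeps a configurable
number of ancestral generations (default 6) above the recorded cows, one
parent-link per generation; parents outside the cut become unknown.

`build_nrm()` uses the recursive tabular method and is intended for tests
and small pedigrees.  The estimation path never forms `A`:
`build_nrm_inverse()` builds the sparse `A^-1` directly by Henderson's
rules, with inbreeding-corrected diagonals from the Meuwissen–Luo
algorithm, and also returns `log|A|` (a by-product of the same
factorisation) for the likelihood.  Tests verify the tabular `A` against an
independent recursive-kinship oracle to 1e-12 and `A %*% A^-1 = I` to 1e-8
on ~500-animal pedigrees.

## REML

Variance components are estimated on Henderson's sparse mixed-model
equations.  Each iteration factorises the coefficient matrix with a sparse
Cholesky (`Matrix`), and the traces needed by the updates come from a
Takahashi selected inverse of the factor (compiled code); nothing dense is
ever formed, so a fit with ~6,000 equations takes well under a second per
iteration.

The update strategy is EM with average-information (AI) acceleration:

* two EM warm-up iterations, then AI (Newton) steps using the exact REML
  gradient and the AI matrix;
* an AI step is accepted only if it does not decrease the REML
  log-likelihood, with step-halving (1, 1/2, 1/4, 1/10) before falling back
  to the guaranteed-ascent EM step;
* parameters pinned at the variance floor (`1e-8` of the trait's phenotypic
  variance) or at the correlation clamp (|correlation| 0.9995 within a
  block) are frozen out of the AI step — the AI quadratic is unreliable on
  the boundary;
* 2x2 blocks are kept symmetric positive semidefinite by flooring
  diagonals, clamping block correlations, and eigenvalue clipping;
* convergence: relative parameter change < 1e-8 or log-likelihood change
  < 1e-6, maximum 500 iterations; non-convergence is returned with
  `converged = FALSE` and a warning, never silently.

The log-likelihood is the standard REML form
`-2 logL = log|R| + log|G| + log|C| + y'Py + (n - p) log 2pi`, evaluated
from the sparse factor; it matches a dense-matrix evaluation to 1e-8 in the
tests.  `AIC = -2 logL + 2 k` counts only the (co)variance parameters —
REML likelihoods are comparable here because the fixed structure is the
same across the methane traits being ranked.  Standard errors of components
come from the inverse AI matrix at convergence, and standard errors of
`h2`, `r`, `rg`, `rp` by the first-order delta method; published standard
errors were produced by an unstated method, so they are treated as
plausibility checks, not targets.

Bivariate models stack two traits observed on the same records
(`cbind(t1, t2)` on the left-hand side).  Degenerate inputs are handled
predictably: with `A = I` the additive/permanent-environment split is
unidentifiable and only the sum is meaningful (the balanced-design tests
check the sum against the closed-form one-way ANOVA estimator); with one
record per cow, `pe` and `e` are confounded; an exact affine copy of a
trait drives the block correlations to the 0.9995 clamp, reported as 1.00
— such fits may legitimately end at the iteration cap.

## The synthetic-herd generator

`sim_config()` fixes the study conditions once:

* paternal half-sib pedigree: founder sires and dams, random mating, no
  selfing; `"study"` preset 1,747 sires x 10 daughters (~17,470 cows,
  ~38,000 records), `"small"` preset 200 sires (2,000 cows) for tests;
* 28 herds, 12 year levels, 4 seasons, parities 1–6 with a
  truncated-geometric count per cow calibrated to 2.176 records/cow;
  lactation length ~ N(310, 35) truncated to [200, 400] d;
* trait means and total SDs on the published summary scale (milk
  11,221 ± 2,353 kg, fat 428 ± 92, protein 375 ± 74, lactose 546 ± 114 kg);
* milk variance components are the published MPE1 methane components
  divided by 2.73^2.  Because `mpe1` is affine in milk, the generated
  methane phenotype then carries *exactly* those components
  (6,771,940 / 3,371,540 / 12,418,000; h2 = 0.30, r = 0.45) — this is the
  calibration anchor for all parameter-recovery checks.  Other traits use
  the same variance fractions, scaled so the a+pe+e sum is the same share
  (~55%) of their squared SD, the remainder coming from the fixed effects;
* fixed-effect values are drawn once per level from normal distributions
  (SD per factor as a fraction of the trait SD: herd 0.25, year 0.15,
  season 0.05, parity 0.20 — chosen as plausible magnitudes, since no
  effect sizes are published);
* cross-trait genetic and environmental correlations default to one
  plausible dairy matrix (e.g. milk–protein 0.85, milk–lactose 0.95,
  milk–fat 0.50); dry matter is fat + protein + lactose plus an
  independent positive "other solids" latent trait, so the record
  invariants (component yields below dry matter below milk) hold by
  construction.

Breeding values are gene-dropped: founders `N(0, G)`, offspring the parent
average plus a Mendelian-sampling deviation with variance
`(1/2 - (F_s + F_d)/4) G`, so the population covariance converges to
`A (x) G`.  Methane is produced from the simulated milk traits by the same
prediction code used for real data.

What the generator does *not* emulate: selection and culling, genotypes,
heterogeneous herd sizes, test-day (within-lactation) structure, and any
real sub-unit methane–milk correlation (see above).  Passing the recovery
tests therefore shows the estimator is correct under the stated model, not
that the published point estimates would be reproduced on the original
herd data — those depend on data that are available on request only.

## Problem sizes used in validation

The recovery experiments fit the small preset: 200 sires x 10 daughters,
2 records per cow (4,000 records, ~4,200 pedigree animals), intercept-only
fixed effects, and average `h2` and `r` estimates over 10 simulation
replicates; truth is recovered within ±0.03.  A single replicate at this
size has a sampling SD of about 0.053 on `h2` (measured over 40
replicates), which is why single-seed checks use a 2-sigma band and the
±0.03 criterion applies to the replicate mean.  Bivariate recovery uses
the same design (true `rg` 0.85 between milk and protein; null checks with
diagonal correlation matrices).  These sizes were chosen as the smallest
designs at which the Monte-Carlo error of the mean is comfortably below
the tolerances being asserted.

## Reporting

`report_tables()` produces the three standard tables — trait summary
statistics; per-trait components with `h2`, `r`, AIC and an AIC rank
(smallest AIC preferred); and bivariate genetic/phenotypic correlations —
rounding ratios to 2 decimals at the reporting layer only.
`run_pipeline()` chains simulate/load → methane prediction → 6-generation
pruning → univariate and bivariate fits → tables, writes a run log with
versions, seed and iteration counts, and is exactly reproducible for a
fixed configuration and seed.  This package is a library, not a shell
tool: the orchestration entry points are these exported functions.

## Known limitations

* Absolute AIC values omit no data-dependent terms but are only meaningful
  for ranking fits on the same records with the same fixed structure.
* The AI-matrix standard errors (and the delta-method SEs built on them)
  are asymptotic; near a variance floor they understate uncertainty.
* Single-trait and two-trait models only; no test-day/random-regression
  models, no genomic relationships, no Bayesian estimation.
* The generator draws herd/year/season/parity effects from normal
  distributions with configured SDs; real fixed-effect structures
  (confounded herd-year patterns, seasonal calving waves) are not emulated.
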