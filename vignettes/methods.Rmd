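---
title: "Models and methods in switchgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in switchgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(switchgs)
```

`switchgs` implements whole-genome prediction for clonally replicated,
multi-population perennial-grass trials. This vignette is the package's
account of the statistical models it fits, the conventions and defaults it
adopts where the analysis admits choices, and what its simulation-based
tests do and do not demonstrate.

## Thermal time

Phenology dates are expressed in growing degree days. Accumulation begins
the day after the first run of five consecutive days whose average
temperature exceeds 32 °F — strictly: a day averaging exactly 32 °F resets
the run. Daily accrual is

$$\mathrm{GDD} = \max\!\Big(0,\ \frac{\max(t_{\min}, 32) + \min(t_{\max}, 86)}{2} - 32\Big)$$

in Fahrenheit, i.e. a base temperature of 32 °F with the recorded minimum
and maximum clamped to 32 °F and 86 °F. The base follows the onset rule's
threshold; the clamps saturate, so temperatures beyond them cannot change
the accrual. The scan starts at the first day of the supplied series
(January 1 when a full calendar year is given), and cumulative GDD at an
event date sums daily accrual from the onset day through the event day
inclusive.

## Outlier screening

Each trait is screened once, across all environments, with a
random-effects model containing year, block nested in year, field and
population (`flag_outliers()`). The statistic is a studentized deleted
residual: the conditional residual of the lme4 fit, internally studentized
by the residual standard deviation and externalized through
$t_i = r_i \sqrt{(\nu-1)/(\nu-r_i^2)}$ with $\nu$ the residual degrees of
freedom. Exact mixed-model leave-one-out leverages are not computed; for
the balanced designs this package targets, the per-record leverage is
nearly constant and the approximation changes no screening decision at the
default cutoff. The cutoff $|t| > 4$ is configurable; no threshold is
canonical for this screen, and 4 keeps the false-flag rate below 1% on
clean data while still catching a single record shifted by a few residual
SDs. Screening is per trait over all years jointly (not per trait-year), a
deliberate reading of "screen, then fit".

## Variance components, BLUPs, repeatability

`fit_blup_model()` fits, by REML (lme4),

$$y = \mu + \mathrm{year} + \mathrm{block(year)} + \mathrm{field} +
\mathrm{genotype} + \mathrm{genotype}\times\mathrm{year} + \varepsilon,$$

all non-intercept terms random. Population is *not* a term: population
structure is removed downstream by principal-component residualization,
and fitting both would correct it twice (`include_population = TRUE`
restores it for users who skip the PC step). Terms that the data cannot
separate (a single year, a single field) are dropped and reported as zero
variance; components estimated at the zero boundary raise a warning, not
an error.

Clone-mean repeatability, the fraction of clone-mean variance that is
genetic and an upper bound on broad-sense heritability, is

$$H = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gy}/y + \sigma^2_e/(y\,r)}$$

for $y$ years and $r$ replicates, the standard clone-mean convention. Its
standard error comes from the delta method: the analytic gradient of $H$
in $(\sigma^2_g, \sigma^2_{gy}, \sigma^2_e)$ propagated through the
asymptotic covariance of the estimates. lme4 does not expose that
covariance, so the package evaluates the restricted log-likelihood
directly (`reml_loglik()`, a Woodbury-identity implementation on the
sparse random-effects design) and inverts a central finite-difference
Hessian at the optimum. Components pinned at zero are held out of the
differentiation and contribute zero covariance. The same evaluator serves
as an independent oracle: tests verify that lme4's optimum beats a dense
grid of the restricted likelihood.

Box-Cox transformation of the BLUPs (`boxcox_optimal()`) maximizes the
profile log-likelihood over $\lambda \in [-2, 2]$ in steps of 0.01 (the
grid is recorded in the result). Non-positive BLUPs are shifted by
$1 - \min(y)$ when `shift = TRUE`, and the applied shift is returned.
Downstream prediction consumes the transformed BLUPs by default; the raw
scale is kept alongside.

## Genotypes

Dosages are real-valued in $[0, 2]$ — counts of the tracked allele, with
fractional values representing diploidized calls from mixed-ploidy
material and mean-imputed entries. Missing calls are `NA`, never silently
zero. Imputation defaults to the marker mean, which preserves each
marker's allele frequency and is what a real-valued ridge/lasso consumes
most gracefully; marker mode and kNN (k = 5, Euclidean distance on shared
non-missing markers, per-marker scale) are options. Haplotype-model
imputation is out of scope: it requires phased reference semantics that
are ill-defined for the octoploid material this design targets.

MAF is computed from non-missing calls and is orientation-free
(min(p, 1−p)); filtering keeps the ≥ threshold boundary. Structure PCs are
computed on the **full** imputed marker set, centered but not
variance-scaled (the common GBS convention; `scale. = TRUE` flips it),
while MAF filtering applies only to the markers entering the prediction
models, mirroring the analysis this package reimplements. The PC sign
convention — the largest-magnitude loading positive — makes scores
reproducible across platforms.

## Prediction models

**RR-BLUP.** $y = 1\mu + Zu + \varepsilon$ with
$u \sim N(0, \sigma^2_u I)$. The restricted likelihood is profiled in one
dimension over $\delta = \sigma^2_e/\sigma^2_u$ on the spectrum of the
column-centered marker kernel $ZZ^\top$, computed on an explicit
orthonormal basis of the intercept's orthocomplement (a detail that
matters: when the kernel is rank-deficient its null space would otherwise
mix with the intercept direction and bias the profile). A coarse grid over
$\log\delta \in [-12, 12]$ brackets the optimum before 1-D refinement;
negative kernel eigenvalues are floored at zero with a warning. Marker
effects are the BLUPs at the optimum — the ridge solution with penalty
$\lambda = \delta$.

**LASSO / elastic net.** Cyclic coordinate descent with soft-thresholding
on the objective

$$\tfrac{1}{2n}\lVert y - \mu 1 - Zb\rVert^2 +
\lambda\big[\alpha\lVert b\rVert_1 + \tfrac{1-\alpha}{2}\lVert b\rVert_2^2\big],$$

markers standardized to unit variance internally and effects returned on
the dosage scale. The $1/(2n)$ loss scaling makes $\lambda$ comparable
across fold sizes. Coordinate order is fixed (marker index), so fits are
deterministic given data; convergence is a maximum standardized
coefficient change below $10^{-7}$ on a full sweep. $\alpha = 0.5$ — equal
weight on the two penalties — is the elastic-net default throughout.

**Penalty selection** (`select_lambda()`) builds 100 log-spaced values
from $\lambda_{\max}$ (smallest all-zero penalty) down to
$10^{-3}\lambda_{\max}$ and minimizes mean squared error over inner random
folds of the *training* data only (5 by default), so held-out phenotypes
never touch the penalty. The inner path is solved at a looser tolerance
($10^{-3}$, capped sweeps): held-out MSE is insensitive to coefficient
changes at that scale, while the deep end of the path is severely
ill-conditioned and dominates runtime at strict tolerance. The final
returned fit at the selected penalty is always solved at $10^{-7}$.

## Cross-validation and accuracy

Trait values (transformed BLUPs by default) are first residualized on the
leading two PCs by OLS. Folds are assigned to whole source populations —
shuffled by seed, then greedily placed into the currently smallest fold —
so clones of one population never straddle the training/prediction split;
the disjointness is asserted on every run. The three models are compared
on identical fold partitions (per-model refolding would add comparison
noise). Fold-level Pearson correlations between observed and predicted
residualized values are averaged; their SD across folds is reported as the
spread (divide by $\sqrt{k}$ for the SE convention). Accuracy is
$\bar r / \sqrt{H}$, never clipped — negative and >1 values are
meaningful. A fold with constant predictions (e.g. an all-zero lasso)
contributes $r = 0$ with a warning. MAF filtering is computed once on each
trait's full evaluated sample set, matching the original analysis; a
fold-wise variant is a one-line change for leakage-sensitive users, and
penalty selection is already strictly fold-internal.

## The simulator

`simulate_panel()` emulates the statistical structure of a diverse clonal
association panel: ancestral allele frequencies uniform on
$[\text{floor}, 1-\text{floor}]$; cluster frequencies Balding–Nichols at
Fst; population frequencies Balding–Nichols around their cluster at
Fst/5; binomial(2) dosages; an additive trait over `n_qtl` markers with
normal effects scaled to unit genetic variance; year, block-in-year and
genotype-by-year effects at configurable SDs; and the residual variance
solved so the clone-mean repeatability hits its target (an unattainable
target given $\sigma_{gy}$ errors with the feasible bound). Defaults are
the panel conditions the package targets: 66 populations × 10 clones, 3
clusters at Fst 0.2, 12,000 markers with frequency floor 0.05 and a 10%
missing-call rate (a mild GBS-like rate), 2 replicates × 3 years, target
repeatability 0.85 (the published panel's morphology repeatabilities run
0.75–0.93), effect SDs 0.5 / 0.25 / 0.25 (year / block / g×y) on the
unit-genetic-SD scale. One master seed reproduces the whole panel.

What the simulator deliberately does *not* model: linkage disequilibrium
(markers are exchangeable given population frequencies), sequence-level
error, octoploid dosage genetics (ploidy enters only through cluster
structure, matching how diploidized GBS dosages are consumed), and
spatial field trends. Consequences for interpreting the tests: with
exchangeable markers, cross-population prediction can rely only on
directly estimated QTL effects, not on LD tagging, so simulated
accuracies at a given heritability are conservative relative to a real
panel with dense LD — a noiseless 50-QTL trait at $n = 300$, $p = 2000$
cross-validates near $\bar r \approx 0.5\text{–}0.6$, not near 1, and
passing tests demonstrate correct machinery and calibration, not the
accuracy ceiling of real data.

## Numerical choices and problem sizes

Convergence and tolerance defaults: coordinate descent $10^{-7}$ (path
selection $10^{-3}$ as above); REML via lme4's bobyqa with singular fits
tolerated; kernel eigenvalue floor 0; Box-Cox grid step 0.01. Ties in
k-nearest-neighbour imputation break by a seeded random order; ties in
fold balance break toward the lowest fold index.

The test suite sizes its simulations to what the properties need rather
than to the largest panel the code handles: parameter-recovery runs use
300 genotypes × 3 years × 2 replicates over 20 seeds; the
heritability-monotonicity check runs 60 populations × 5 clones at 2,000
markers over 20 seeds with 5 outer and 3 inner folds (fold counts scale
runtime, not the monotone ordering under test); the acceptance script runs
the full 66 × 10 panel at 12,000 markers with ten outer folds, 3 inner
folds for penalty selection. Measured end to end, these settings keep the
suite and the script in the minutes range on a single core.

## Known limitations

- The studentized-deleted-residual screen uses the constant-leverage
  approximation described above; strongly unbalanced designs would
  warrant exact leverages.
- The delta-method SE of repeatability inherits the quality of the
  finite-difference observed information; near-boundary components get a
  conservative zero-covariance treatment rather than a profile interval.
- RR-BLUP assumes a single common marker-effect variance; no Bayesian
  alphabet, dominance or epistasis terms are provided.
- The simulator's exchangeable-marker assumption understates the LD-driven
  component of real-panel accuracy (see above).
- VCF input is GT-only and biallelic by design; dosage (DS) fields and
  multi-allelic sites are not consumed.
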