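---
title: "Methods: two-stage factor-analytic MET analysis with drought envirotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage factor-analytic MET analysis with drought envirotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famet)
```

# The problem

Multi-environment trials (MET) test a common set of genotypes across
locations and years. Yield rankings change across environments —
genotype-by-environment interaction (GEI) — and part of that change is
driven by water deficit. `famet` implements a two-stage weighted
analysis that (i) cleans each trial of its spatial field trend, (ii)
models the between-environment genetic covariance with a small number
of latent factors, and (iii) interprets those factors through
independently measured drought indices. This vignette documents the
models, the numerical choices, and what the synthetic-data experiments
do and do not demonstrate.

# Stage one: single-trial models

Each trial is a row–column layout. The candidate catalog is the full
factorial of

* random row effect: absent / present,
* random column effect: absent / present,
* residual: iid, AR1 along rows, AR1 along columns, or AR1×AR1
  (separable),

with terms removed when a grid dimension is degenerate (a random
effect needs ≥ 2 levels, an AR1 parameter ≥ 3). The genotype effect is
always present and is random during the model search. For an 8×4
layout this gives 16 candidate models; the baseline (genotype only,
iid residual) is always first.

Fitting is REML with the residual variance profiled out analytically:
the remaining parameters are variance ratios on the log scale and AR1
correlations on the Fisher-z scale, maximized by bounded L-BFGS-B
(start: equal variance split, AR1 at 0.1; at most 500 iterations).
Variance components estimated below `1e-8` of the total (or `1e-12`
absolute) are reported as zero and flagged as boundary estimates.

Model selection uses the generalized heritability
$H^2 = 1 - \overline{\mathrm{PEV}} / (2\hat\sigma^2_g)$, computed from
the per-genotype prediction error variances of the genotype BLUPs,
clipped to $[0,1]$ and defined as 0 when $\hat\sigma^2_g = 0$. Ties
(within `1e-8`) go to the model with fewer variance parameters, then
catalog order.

**BLUE refit.** The selected structure is refitted with genotype
fixed to obtain un-shrunken generalized-least-squares means and
standard errors. The non-genotype variance parameters are *carried
over* from the random-genotype fit rather than re-estimated: with as
many genotype fixed-effect columns as plots (e.g. 8 hybrids × 4
replicates = 32 plots), the fixed-genotype REML has no residual
degrees of freedom of its own. In the balanced unreplicated iid case
this reduces to BLUE = plot value and SE = residual SD, which is the
intended behaviour of an "un-shrunken" prediction.

# Stage two: weighted factor-analytic MET model

Stage-one BLUEs from all maturity groups are pooled into one genotype
× environment table. The model is

$$y_{ij} = \mu_j + u_{ij} + e_{ij}, \qquad
u_{i\cdot} \sim N(0,\; \Lambda\Lambda^\top + \mathrm{diag}(\Psi)),
\qquad e_{ij} \sim N(0,\; se_{ij}^2),$$

where the cell error variances $se_{ij}^2$ are fixed at the stage-one
values — the two-stage weighting. Each genotype contributes a
multivariate normal over its *observed* environments, so missing cells
are handled by marginalization, and genotypes sharing an observation
pattern share one covariance factorization.

* **Identification.** During fitting $\lambda_{jm} = 0$ for $j < m$
  (upper-triangle constraint), giving
  $n_{vc} = J(k+1) - k(k-1)/2$ variance parameters. AIC
  $= -2\,\mathrm{logLik} + 2 n_{vc}$ counts only variance parameters;
  the environment means are profiled out by REML.
* **Optimization.** Free loadings and log-scale specific variances,
  L-BFGS-B, deterministic initialization from the eigendecomposition
  of the error-corrected sample covariance of the BLUEs (rotated into
  the triangular form by an LQ decomposition); at most 2000
  iterations. Specific variances may reach zero (Heywood cases); they
  are flagged, not forbidden.
* **Rotation.** The reported loadings are principal-axis rotated (SVD;
  $\Lambda^\top\Lambda$ diagonal with non-increasing diagonal) with
  the sign convention that every column sums to a non-negative value.
  Scores co-rotate, so all BLUPs, $\Lambda\Lambda^\top$, genetic
  correlations and variance percentages are rotation-invariant.
* **Derived quantities.** Genetic correlations come from
  $G = \Lambda\Lambda^\top + \mathrm{diag}(\Psi)$; the per-factor
  percentage of genetic variance is
  $100\sum_j \lambda_{jm}^2 / \sum_j G_{jj}$ and the per-environment
  cumulative percentage $100\sum_m \lambda_{jm}^2 / G_{jj}$.
  `invert_env_cumpct()` inverts the latter, which lets a published
  loading table (loadings + cumulative %) be completed into a full
  parameter set — the package's worked example does exactly this.
  Environments are clustered by average-linkage agglomeration on
  $1 - r$.

The genotype scores $f_{im}$ are simultaneously the slopes of the
latent regressions: the fitted decomposition
$u_{ij} = \sum_m f_{im}\lambda_{jm} + \delta_{ij}$ holds exactly at
the estimates, so plotting BLUPs (factor-m residual BLUPs for m > 1)
against loadings gives a line with slope $f_{im}$ through the origin.

# FAST summaries

Predicted yield per hybrid is the mean of the stage-two fitted values
$\mu_j + u_{ij}$ over all environments, which fills missing cells
model-based. Shukla's stability variance is computed on that complete
fitted table:
$\sigma^2_i = \frac{I}{(I-2)(J-1)}\sum_j w_{ij}^2 -
\frac{SS_{GE}}{(I-1)(I-2)(J-1)}$ with double-centred residuals
$w_{ij}$. The estimator can be slightly negative; values are clipped
at zero and flagged. Exactly five top- and five bottom-yielding
hybrids are labelled when 32 are present; boundary ties resolve by
hybrid id with a warning. Computing stability from fitted rather than
raw values is a deliberate design choice (the stability plot coexists
with the FA fit and must cover cells the raw data may miss).

# Envirotyping

* **VPD** = $e_s(T)\,(1 - RH/100)$ with the Tetens saturation curve
  $e_s = 0.6108\exp(17.27T/(T+237.3))$ kPa. Hourly records are
  converted pointwise and then averaged (10-day, monthly or seasonal
  windows) — never from window-mean T and RH, because $e_s$ is convex.
  The 1.7–2.5 kPa band is reported as the maize
  transpiration-sensitivity class.
* **PET** is Thornthwaite's temperature-only formulation with
  day-length correction from solar geometry (`geosphere::daylength`),
  chosen because the stations measure only temperature, humidity and
  precipitation. The heat index uses the record's mean temperature per
  calendar month; months ≤ 0 °C contribute zero; above 26.5 °C the
  standard high-temperature polynomial applies.
* **Palmer water balance**: two layers, surface capacity fixed at
  25.4 mm (Palmer's inch) and an underlying layer of
  `awc_mm − 25.4`; default available water capacity 150 mm (a typical
  loam profile; it is a per-location configuration input). Mass is
  conserved each period to numerical precision.
* **CAFEC and Z.** Coefficients are calibration-window ratios
  ($\alpha = \overline{ET}/\overline{PET}$, etc.; 0/0 falls back to 1
  for $\alpha$ and 0 for $\beta,\gamma,\delta$). The CAFEC
  precipitation subtracts the loss term, mirroring the balance
  identity $P = ET + R + RO - L$. Palmer's climatic characteristic
  $K$ uses his published constants, which are calibrated for inches —
  departures therefore enter that formula (and the Z-index) divided
  by 25.4.
* **Self-calibration.** Duration factors $p, q$ are re-derived from
  the local record by regressing the most extreme accumulated Z on run
  length (dry and wet separately, clamped to the stable region
  $p < 1$), replacing Palmer's fixed 0.897 and 1/3. The index then
  runs through the X1/X2/X3 spell bookkeeping with
  probability-of-ending backtracking, and the anomaly scale is
  iteratively adjusted so the 2nd/98th percentiles of the index sit at
  −4/+4 over the calibration record. Duration factors are *not*
  re-derived after rescaling — the extreme-run regression
  self-normalizes, so re-deriving would undo the calibration.
  A degenerate (constant) climate returns an all-zero index with a
  flag. The published class scale (±0.49 near normal, then incipient,
  slight, moderate, severe, extreme per unit step) and the water
  deficit threshold < −0.49 are applied to seasonal means.
* **Resolution.** Monthly is primary: the percentile targets of the
  self-calibration are defined on long climatologies, and monthly
  records of 30–100 years are the realistic input. Seasonal
  (May–September) aggregates feed the environment covariate table.

# Tolerance linkage

Stress and normal environment sets (default 3 + 3) are chosen by a
composite rank: mean of the rank by seasonal scPDSI ascending and by
seasonal VPD descending, ties broken by environment id. This
operationalizes the joint use of the two indices, which is otherwise a
judgment call. `Yp`/`Ys` are means of stage-two fitted yields over the
normal/stress sets; GMP $= \sqrt{Y_p Y_s}$ and RDY
$= 100 (Y_p - Y_s)/Y_p$ (percent decrease; a ratio convention
$Y_s/Y_p$ is selectable). RDY's literature contains several variants
and directions; the package documents its convention rather than
adjudicating. Linkage reports are plain Pearson correlations of
loadings with covariates (across environments) and of scores with
tolerance indices (across hybrids); degenerate inputs yield missing
entries rather than errors.

# The synthetic-data generator

`make_truth()` draws a complete parameter set mirroring the targeted
study design: 32 hybrids in 4 maturity groups of 8, 12 environments (6
locations × 2 years), FA(2) genetic covariance, per-trial error
variances log-uniform with a guaranteed max:min ratio above 5, row and
column variances of 0.05 (t/ha)² and AR1 plot correlations of 0.25,
environment means 8–14.5 t/ha. First-factor loadings are positive
(mean ≈ 0.85, non-crossover interaction); the second factor flips sign
between years (±0.45); per-environment explained percentages are drawn
from 35–85%. Columns beyond the first are Gram–Schmidt-orthogonalized
so the truth is expressed in the same principal-axis form the fitted
model identifies — without this, a designed loading–covariate
correlation would refer to an unidentifiable representation. When a
covariate link is requested, the first-factor loadings are constructed
to have *exactly* the designed empirical correlation with the
generated covariate.

`simulate_met()` lays each (environment × group) trial on an 8×4 grid
with 4 replicates per hybrid — 48 trials × 32 plots = 1536 records,
the arithmetic forced by 8 hybrids per group in 32-plot trials.
`simulate_met_table()` bypasses stage one for experiments that target
the factor-analytic stage directly. `simulate_weather()` produces
hourly May–September series plus a multi-decade monthly climatology,
with drought episodes expressed as precipitation multipliers, relative
humidity depression and a temperature anomaly. All generators are pure
functions of their seed.

**What the generator does not emulate:** real spatial fertility
trends beyond stationary AR1, genotype-specific error variances,
phenology (drought timing interacts with flowering in real maize),
or any physiological yield–weather coupling — simulated yields come
from the statistical model the analysis assumes. Passing recovery
experiments therefore demonstrate the estimator's correctness under
its own model, not robustness to model misspecification.

# Problem sizes and numerical tolerances

The recovery experiments in the test suite run at the sizes the
package treats as its reference conditions: 200 genotypes × 12
environments for loading recovery (median Procrustes RMSE over 20
seeds), order selection (20 seeds, orders 1–3) and loading–covariate
recovery (20 seeds, designed r = −0.8). At the field scale of 32
hybrids the same quantities are noisier for purely statistical
reasons — loading noise is then comparable to the loading spread — and
the corresponding checks are run as sign-recovery tests. The scPDSI
calibration experiment uses a 100-year stationary monthly climate.
Small-instance REML optima (6-plot trials; 30 × 4 FA tables) are
verified against independent direct optimization of the same
criterion built from full covariance matrices, to 1e-4. Optimizer
tolerances: stage one `factr = 1e6`, stage two `factr = 1e5` (both
L-BFGS-B); nested-order log-likelihood monotonicity is asserted to
1e-6.

# Known limitations

* Stage two treats stage-one standard errors as exact; no
  degrees-of-freedom adjustment is made for their estimation.
* The FA order search stops at `fa_k_max` (default 5) and compares
  only converged fits.
* A rank-1 factor can absorb a single specific variance without
  changing the likelihood, so "no-GEI" recovery is asserted on the
  genetic correlation matrix, not on the loadings themselves.
* The Palmer spell logic implements the standard probability-of-ending
  bookkeeping, but published scPDSI implementations differ in minor
  backtracking details; the package pins down behaviour by its
  calibration targets (tail fractions, degenerate climates, mass
  conservation) rather than byte-level agreement with any one code.
* Environment covariates are seasonal summaries; within-season timing
  of stress is out of scope.
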