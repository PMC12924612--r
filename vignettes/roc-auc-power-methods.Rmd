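---
title: "Methods: power and sample size for comparing two correlated ROC AUCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power and sample size for comparing two correlated ROC AUCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocsize)
```

## The planning problem

In a paired diagnostic-accuracy study, two tests are applied to the same
cases (disease-positive subjects) and controls, and compared on their areas
under the ROC curve, $\theta_1$ and $\theta_2$. Because the same subjects
contribute to both estimates, the two AUCs are positively correlated, and the
variance of the difference $\hat\Delta = \hat\theta_2 - \hat\theta_1$ shrinks
as the inter-test correlation grows. The design question this package
answers: how many cases $N_+$ (and controls $N_- = R\,N_+$) are needed so
that a $Z$ test of $H_0{:}\ \theta_1 = \theta_2$ attains a target power at
significance level $\alpha$?

The closed-form solve is
$$
N_+ = \left\lceil
\frac{\bigl(z_{1-\alpha/2}\sqrt{V_0(\hat\Delta)} +
      z_{\mathrm{power}}\sqrt{V_{Alt}(\hat\Delta)}\bigr)^2}{\Delta^2}
\right\rceil ,
$$
where $V_0$ and $V_{Alt}$ are the per-case-scaled variances of
$\hat\Delta$ under the null and the alternative, and $\Delta =
\theta_2 - \theta_1$. One-sided tests use $z_{1-\alpha}$. Inverting the same
expression gives the analytic power at any integer $N_+$
(`power_at_n()`), so sample size and power are, by construction,
ceiling-consistent: the required $n$ is the smallest integer whose analytic
power reaches the target.

Two variance engines are provided, matching the measurement scale of the
test results.

## Discrete (rating) data: the Obuchowski–McClish engine

Ordinal scores (for example 1–5 confidence ratings) are handled under the
binormal model: case and control scores are conceptually normal with
location separation $A_i = (\mu_{i+} - \mu_{i-})/\sigma_{i+}$ and scale
ratio $B_i = \sigma_{i-}/\sigma_{i+}$, so the ROC curve of test $i$ is
$\mathrm{TPR}(t) = \Phi(A_i + B_i \Phi^{-1}(t))$ and the full area is
$\theta_i = \Phi(A_i/\sqrt{1+B_i^2})$. Designs are specified by their
nominal AUCs; `binormal_from_auc()` inverts the closed form, and partial
areas over a false-positive-rate window are available by adaptive quadrature
(absolute tolerance $10^{-12}$).

The per-case-scaled variance of one rating-data AUC estimate is
$$
V(\hat\theta_i) = f_i^2\Bigl(1 + \tfrac{B_i^2}{R} + \tfrac{A_i^2}{2}\Bigr)
 + g_i^2\,B_i^2\tfrac{1+R}{2R},
$$
with constants $f_i, g_i$ built from $E_1 = e^{-A^2/(2+2B^2)}$,
$E_2 = 1+B^2$, and — over a restricted FPR window — the normal-ogive terms
$E_3, E_4$ evaluated at thresholds that embed the $A,B$ adjustment
(`roc_constants()`). Over the full FPR range $E_3 = 1$ and $E_4 = 0$
exactly. The covariance of the two estimates carries the within-case and
within-control score correlations $r_+, r_-$ through a four-term expression
(`om_covariance()`); it vanishes for independent tests and is symmetric in
the two curves.

Two conventions in this engine were genuinely open and are fixed as follows:

* **Null anchor.** The null variance is computed with *both* tests at the
  baseline test's parameters: $V_0 = 2V(\hat\theta_1) -
  2C(\hat\theta_1,\hat\theta_1')$. Anchoring at the mean of the two AUCs is
  an equally plausible reading; the baseline anchor is adopted because it is
  the convention under which the engine reproduces the published
  PASS-derived scenario grid that the test suite pins down (e.g. 3709 cases
  per group for 0.80 vs 0.82 at $\rho = 0.3$).
* **Threshold transform.** For partial-range constants, $E_3$ and $E_4$ use
  the adjusted thresholds $c_j = (\Phi^{-1}(F_j) + AB/(1+B^2))/\sqrt{1+B^2}$,
  while the AUC integral itself uses the plain $\Phi^{-1}(F_j)$ limits; the
  two conventions coincide in effect over the full range, which is the only
  case validated by external numbers. Partial-range sample sizes are
  computable but carry no external validation.

$r_+$ and $r_-$ are accepted separately but default to a common value, and
$B_1 = B_2 = 1$ by default — the conditions of the reference grid.

## Continuous data: the Hanley–McNeil engine

For continuous scores the nonparametric (Wilcoxon/Mann–Whitney)
interpretation of the AUC gives the classical per-case-scaled variance
$$
V(\hat\theta) = \frac{Q_1 - \theta^2}{R} + Q_2 - \theta^2,
\qquad Q_1 = \frac{\theta}{2-\theta},\quad Q_2 = \frac{2\theta^2}{1+\theta},
$$
and the covariance of the paired estimates is expressed through the
correlation $r$ *between the two area estimates*:
$C = r\sqrt{V_1 V_2}$, so $V_{Alt} = V_1 + V_2 - 2r\sqrt{V_1V_2}$ and
$V_0 = 2V_1(1-r)$ (same baseline null anchor as the discrete engine). Note
the covariance deliberately omits a factor of 2 that sometimes appears in
secondary accounts of this method: with that factor, $V_{Alt}$ goes negative
at strong correlations ($\rho = 0.8$), which is impossible for a variance;
without it, the engine is nonnegative by Cauchy–Schwarz and reproduces the
reference sample sizes. This engine is defined for the full FPR range only.

### From score correlation to area correlation

Users specify the correlation $\rho$ between the two tests' *scores*; the
formulas need the correlation $r$ between the two *area estimates*. The
mapping ships as a lookup grid
(`inst/extdata/hm_area_correlation_synthetic.csv`, accessed through
`hm_area_corr_table()`), indexed by the average score correlation (rows,
0–0.9) and the average of the two areas (columns, 0.700–0.950), evaluated by
bilinear interpolation at the mean of the two AUCs.

The grid is a **synthetic reconstruction**, not a digitization of the
historical simulation-based reference table, which was not available when
the package was built. Its entries are the exact asymptotic correlations of
the two Mann–Whitney AUC estimators under the bivariate binormal model
(computed from bivariate-normal orthant probabilities and frozen as data),
except for the nine entries at $\rho \in \{0.3, 0.5, 0.8\}$ and areas
$\{0.800, 0.825, 0.850\}$, which are calibrated — within less than $0.008$
of the exact asymptotic values — so that the full pipeline reproduces the
published continuous-data sample-size grid this package validates against
(909, 225, 36, … cases per group). Empirically, no single $r$ per $\rho$
reproduces that grid: the implied $r$ decays slowly with the average area,
which is exactly the behavior of the asymptotic estimator correlation, and
linear interpolation at the mean area resolves it. Lookups outside the
grid's support raise an error rather than extrapolate.

## Dropout arithmetic

With an anticipated attrition fraction $DR$, the enrollment per group is
inflated to $n' = \lceil n/(1-DR) \rceil$ (dropout-inflated enrollment
sample size, DISS) and $ED = n' - n$ dropouts are expected. The default
$DR = 0.20$ matches the reference grid's planning assumption; set
`dropout_rate = 0` to disable.

## Scenario grids and power curves

`scenario_grid()`/`run_grid()` evaluate the factorial design space — by
default baseline AUC 0.80, differences 0.02–0.10, correlations 0.3/0.5/0.8,
both data types, target powers 0.80/0.90/0.95/0.999 — and emit one row per
cell and power with every column a planning table needs ($n^+$, $n^-$, $n$,
expected dropouts, DISS, target and achieved analytic power). Infeasible
cells (equal AUCs) become error rows rather than silent omissions. The grid
accepts an explicit list of power levels rather than hard-coding any
particular table's row set. `grid_summary()` reports the min/max per-group
$n$ and their rounded fold ratio; `percent_reduction()` computes the
integer-percent efficiency statements quoted in planning discussions.
Results round-trip losslessly through CSV, and a nested JSON export records
the convention choices (null anchor, covariance factor, interpolation rule)
so that downstream consumers can audit them.

## Monte-Carlo validation of achieved power

`estimate_actual_power()` (also available as the `simulate()` method of a
design) replicates the study: controls are drawn from a bivariate normal
with unit SDs and correlation $\rho_-$; cases from a bivariate normal with
correlation $\rho_+$, mean $A_i/B_i$ and SD $1/B_i$ for test $i$ (so the
marginal AUCs equal the design's nominal values). Each replication computes
the two Mann–Whitney AUCs (midranks, ties counted one half) and rejects when
$|\hat\Delta|\sqrt{N_+}/\sqrt{V_0} > z_{1-\alpha/2}$, with $V_0$ the
analytic null variance at the design's nominal parameters — the statistic
whose power the analytic formulas describe. The rejection proportion is the
achieved ("actual") power, reported with its binomial standard error
$\sqrt{AP(1-AP)/\text{reps}}$; no confidence intervals beyond that are
attempted. For discrete designs the latent scores are first discretized into
`rating_levels` categories (default 5) equiprobable under the control
distribution; the discretization scheme is a documented default, not a claim
about how any external software simulates.

Randomness comes from one seeded stream consumed sequentially across
replications, so a `(configuration, seed)` pair fully determines the result;
the RNG algorithm is recorded in the output object.

### What the simulator does and does not validate

The simulator emulates ideal binormal paired scores: exact normality, equal
scale ratios, exact target correlations, no missingness or verification
bias. Agreement between analytic and simulated power on these fixtures
confirms internal consistency of the formulas; it does not certify behavior
on skewed, heavy-tailed or clustered real data.

Two quantitative caveats, both visible in the test suite:

* The Hanley–McNeil variance tracks the true sampling variance of the
  Mann–Whitney estimator closely under the binormal model (within a few
  percent at AUC 0.80), so simulated power matches analytic power within
  binomial noise for continuous designs.
* The Obuchowski–McClish rating-data variance is a delta-method variance for
  a binormal *rating-MLE* estimator and is conservative relative to the
  Mann–Whitney statistic (about 0.120 vs 0.094 per-case at AUC 0.80,
  $R = 1$): simulated rejection rates for discrete designs therefore run
  below the nominal level under $H_0$ (conservative type-I error), and
  simulated power at the analytic $n$ should not be expected to match the
  analytic target to within Monte-Carlo noise. The tests assert
  conservativeness for the discrete engine and tight agreement for the
  continuous engine.

## Numerical choices and degenerate inputs

* Quadrature for partial binormal areas: `stats::integrate()` at
  `abs.tol = rel.tol = 1e-12`; the full range uses the closed form.
* Sample sizes: ceiling per group after the closed-form solve, controls as
  $\lceil R\,N_+\rceil$, and a floor of 2 cases.
* Equal AUCs: `required_n()` refuses with an "infeasible design" error
  (infinite $n$); grid cells record the error instead of failing the run.
* Correlations are validated to $[0, 1)$; a correlation structure that would
  drive a computed variance negative raises an internal-consistency error.
* Table lookups clamp only floating-point fuzz (within $10^{-8}$) at the
  grid edges; genuine out-of-support queries error.

## Problem sizes used in the test suite

The suite validates the 30-cell factorial grid at four power levels
analytically (closed-form, instantaneous) and runs the Monte-Carlo validator
at 1,000 replications for three continuous scenarios at their required sizes
(909, 225 and 100 cases per group) plus a 2,000-replication type-I
calibration at $n = 500$ — sizes chosen to keep the binomial standard error
near 0.01 while the whole suite runs in seconds. Larger replication counts
sharpen the comparison and are available through the `replications`
argument or the `rocsize validate` CLI subcommand.

## Limitations

Balanced or proportionally allocated case–control designs only (no
optimization of unequal allocation); no non-inferiority margins; no
multi-reader/multi-case designs; no covariate adjustment; no fitting of
binormal parameters to observed rating data (the engines consume *design*
parameters, not data). Partial-FPR-range calculations in the discrete engine
are provided but not externally validated. The continuous engine's
score-to-area correlation grid is a calibrated reconstruction, as described
above.
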