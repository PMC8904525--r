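---
title: "Methods: penalized and Bayesian shrinkage construction of polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized and Bayesian shrinkage construction of polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`penprs` builds polygenic risk scores (PRS) for a binary trait,

$$\mathrm{PRS}_i = \sum_{j=1}^{p} x_{ij}\,\beta_j,$$

where $x_{ij} \in [0,2]$ is the effect-allele dosage of variant $j$ in
individual $i$ and $\beta_j$ is a per-dose log odds ratio.  Three
estimators of the weight vector are provided — a penalized logistic
regression family fit to individual-level dosages, a continuous-shrinkage
Gibbs sampler ("select and shrink") fit to GWAS summary statistics with a
block LD reference, and approximate conditional-and-joint stepwise
selection from summary statistics — together with scoring and evaluation
(AUC, odds ratio per standard deviation, percentile-band odds ratios) and
projection of a per-SD odds ratio onto absolute, age-specific cumulative
risk under competing mortality.  A synthetic-data module generates
LD-structured case-control panels with known truth so that every method
is testable end to end without external data.

# The penalized family

## The thresholding operator

All four penalized members are generated by one scalar thresholding
operator applied to a standardized effect $x$:

$$
\mathrm{plr}(x;\lambda,\kappa)=
\begin{cases}
0 & |x| < \lambda,\\
x & \kappa > 0 \text{ and } |x| \ge \lambda/\kappa,\\
\dfrac{x - \lambda\,\mathrm{sign}(x)}{1-\kappa} & \text{otherwise.}
\end{cases}
$$

* $\kappa = 0$ is exact soft thresholding — the lasso.
* $0 < \kappa < 1$ is firm thresholding — the minimax concave penalty
  (MCP) with concavity $\gamma = 1/\kappa$; as $\kappa \to 1^-$ it
  approaches hard thresholding pointwise.
* $\kappa = 1$ is the hard threshold: best-subset / p-value selection at
  $|z| \ge \lambda$.
* $\kappa < 0$ is soft thresholding followed by proportional shrinkage
  by $1/(1-\kappa)$ — the elastic-net coordinate update with ridge
  weight $-\kappa$.

The region conditions as printed in piecewise form are contradictory for
$\kappa \le 0$ (the unshrunk region $|x| \ge \lambda/\kappa$ is vacuous);
we resolve the operator as above, which is the unique reading under which
$\kappa = 0$ is exactly the lasso and $\kappa = -2.2$ is an elastic net.
The operator is odd, continuous in $x$ for $\kappa < 1$, and
non-expansive outside the dead zone; all three properties are asserted in
the test suite, and the $\kappa<0$ branch is checked against numerical
minimization of its penalized quadratic objective.

## Scale of the penalty and rare-variant behavior

$\lambda$ acts on the *standardized* (per-standard-error, i.e. z-score)
scale: coordinate updates are computed on dosages standardized to unit
variance, where each coordinate's per-observation curvature bound gives a
common standard error $2/\sqrt{n}$.  Equal penalization on this scale
translates into a *larger* raw-dosage-scale penalty for rarer variants
(whose dosage SD $\sqrt{2f(1-f)}$ is smaller), which counteracts
winner's-curse inflation of rare-variant effects.  It also makes
$\lambda$ directly interpretable: the hard-threshold member at
$\lambda = 5.45$ is selection at genome-wide significance
($p < 5\times10^{-8}$).

## Optimization

`fit_penalized_logistic()` runs cyclic coordinate descent on the
quadratic majorization of the logistic log-likelihood with fixed
curvature bound $1/4$ (the logistic variance bound), an unpenalized
intercept, glmnet-style active-set cycling, convergence at a maximum
per-sweep standardized coefficient change below `tol = 1e-7`, and
`max_iter = 1000` sweeps.  For the convex members the fixed-point
condition of the update is exactly the KKT condition of the penalized
likelihood regardless of the curvature bound used, so the solution does
not depend on the majorizer; this is verified against an independent
$\ell_1$-penalized logistic solver (glmnet at the matching penalty
$\lambda_{\mathrm{glmnet}} = \lambda/(2\sqrt n)$) to $10^{-4}$.  For the
nonconvex members ($\kappa > 0$) the solution can depend on the starting
point; the path protocol below supplies the warm starts.

## Two-stage selection and cross-validation

Stage 1 reduces dimension: windows of 5.5 Mb with 500 kb overlap tile
each chromosome starting at its first variant position; within each
window, after excluding variants with Wald $\chi^2 < 2.25$, models are
fit at $\lambda = 3.0$ and $\kappa \in \{0, 0.2, 0.4, 0.6, 0.8, 1.0\}$,
and the union of variants active anywhere is carried forward
(deduplicated).  The $\chi^2$ prefilter is applied before both stages.

Stage 2 fits, on the stage-1 set, the full grid $\lambda \in
\{3.0, 3.1, \dots, 5.5\} \times \kappa \in \{-3.0, -2.9, \dots, 1.0\}$
(26 × 41 = 1,066 fits).  At each $\lambda$ the lasso ($\kappa = 0$) is
fit first — its optimum is unique — and $\kappa$ is then moved stepwise
outward toward $+1$ and toward $-3$, each fit warm-started from its
neighbor, so the nonconvex fits follow a continuous solution path.

`cross_validate_grid()` wraps both stages in stratified $k$-fold
cross-validation (default 5 folds, case/control proportions preserved,
seeded; stratification is our choice and guards against degenerate
folds).  The selection criterion is the mean held-out AUC per
$(\lambda,\kappa)$; the best specification is reported per family
(lasso $\kappa=0$, MCP $0<\kappa<1$, elastic net $\kappa<0$, hard
$\kappa=1$) and globally, and the final model is refit on all data.
Mean-AUC ties are broken toward the sparser model and then the smaller
$\lambda$ (parsimony).

# Select and shrink from summary statistics

The summary-statistic method places a continuous-shrinkage (gamma-gamma
global-local) prior on standardized effects and samples the posterior by
Gibbs, block by block over an LD reference.  With $\hat\beta^{std}_j =
\hat\beta_j \cdot sd_j$ the marginal effect on the standardized scale
(the "standard-deviation correction": working on this scale penalizes
rare variants more heavily on the raw scale, exactly as in the penalized
family), $R$ a block correlation matrix, $N$ the GWAS sample size, the
conditionals are:

* $\beta \mid \psi, \sigma^2 \sim \mathcal N\!\left(
  (R + D)^{-1}\hat\beta^{std},\; \tfrac{\sigma^2}{N}(R + D)^{-1}\right)$
  with $D = \mathrm{diag}\{1/(\phi\psi_j)\}$;
* $\psi_j \mid \beta_j, \delta_j \sim \mathrm{GIG}\!\left(a - \tfrac12,\;
  2\delta_j,\; N\beta_j^2/\sigma^2\right)$;
* $\delta_j \mid \psi_j \sim \mathrm{Gamma}(a + b,\ \psi_j + \phi)$;
* $\sigma^2$ from its inverse-gamma conditional.

`a` controls shrinkage of effects near zero, `b` the shrinkage of larger
effects, and $\phi$ the global scale.  The generalized-inverse-Gaussian
sampler is a C++ port of Devroye's rejection construction, driven by R's
RNG so chains are reproducible under `set.seed()`.  Positivity of
$\psi$, $\delta$, $\sigma^2$ is asserted at every iteration and sampler
parameters are floored at $10^{-12}$.

The output weight is the posterior-mean standardized effect divided by
$sd_j$; variants whose posterior-mean standardized effect falls below
`sparsify_tol` (default $10^{-5}$) in magnitude are dropped — this is
the "select" step that yields sparse models rather than all-SNP models.
Input variants are prefiltered with the same $\chi^2 \ge 2.25$ rule by
default (configurable off).

Defaults: 1,000 burn-in plus 4,000 kept iterations thinned by 5.  The
chain length is our choice; the single-site conditional is validated
against the conjugate closed form
$\hat\beta/(1 + 1/(\phi\psi))$ and the weak-shrinkage limit
($\phi \to \infty$) against the marginal estimates.

A note on the global scale: in this parametrization $\phi$ multiplies
$\psi_j$ *inside* the prior precision, so its natural operating range
(order $10^{-2}$–$10^{1}$ for standardized effects) differs from
superficially similar samplers that place the global scale elsewhere.
The tuning grid of `s4_tune()` therefore spans $3\times10^{-6}$ to
$10^{2}$, and cross-validated AUC — not a nominal value — selects the
operating point, mirroring how `(a, b, φ)` are selected on training
summary statistics and validated on held-out folds.

# Stepwise conditional-and-joint selection

The hard-threshold member is awkward to fit by coordinate descent on
individual-level data (local optima), so the package implements the
summary-statistic equivalent: approximate conditional and joint analysis
with a reference-panel LD correction.  On the standardized scale with
per-variant sampling variance $1/n$:

* the conditional effect of candidate $c$ given selected set $S$ is
  $\hat\beta_c - R_{cS} R_{SS}^{-1} \hat\beta_S$ with variance
  $(1 - R_{cS}R_{SS}^{-1}R_{Sc})/n$;
* joint effects of $S$ solve the LD-weighted normal equations
  $R_{SS}\beta_S = \hat\beta_S$, with variances
  $\mathrm{diag}(R_{SS}^{-1})/n$.

Forward selection adds the candidate with the largest conditional $|z|$
while it exceeds `z_select` (default 5.4, i.e. a variable p-value
threshold; $z = 5.45 \leftrightarrow p = 5\times10^{-8}$), refitting the
joint system after each addition.  Candidates with $r^2 > 0.9$ to a
selected variant are withheld as collinear; an ill-conditioned joint
system causes the most recent addition to be dropped with a warning.
Variants in different LD blocks are treated as independent (blocks stand
in for the 10 Mb LD horizon).  On orthogonal designs the procedure
reduces exactly to thresholding marginal $|z|$, and joint betas are
validated against individual-level multiple logistic regression within
two joint standard errors — the approximation is linear-model-based, so
exact agreement is not expected.

`meta_region_select()` implements the meta-analysis region rule: LD
blocks containing a genome-wide-significant variant
($p < 5\times10^{-8}$) define regions; each region contributes its lead
variant plus conditionally independent secondary signals passing
$p < 10^{-5}$ in any supplied stratum, with joint effects from the same
machinery.  "Region" is not defined numerically in the source
description; contiguous LD blocks are our operationalization.

# Evaluation

Scoring imputes missing dosages as $2f_j$ (the Hardy–Weinberg mean) at
scoring time only — I/O never modifies data — and reports unmatched
weights rather than silently dropping them.  Standardization centers and
scales by a reference group, conventionally the controls of the same
population (an external mean/SD pair may be supplied to put one cohort
on another's scale, and per-population standardization is how
transfer across ancestries is handled).

* **AUC**: Mann–Whitney estimator with ties counted one half; DeLong
  placement variance for the confidence interval.  Checked against
  exhaustive pair counting.
* **OR per SD**: univariate logistic regression of outcome on the
  standardized score, Wald interval.
* **Band ORs**: samples are assigned to percentile bands (default 0–5,
  5–10, 10–20, 20–40, 40–60, 60–80, 80–90, 90–95, 95–100; reference
  40–60) by percentile rank on the combined cohort's scores.  Cuts on
  the combined sample — rather than controls only — are the default
  because published per-band control counts are not exactly proportional
  to band widths, which indicates combined-sample cuts; both are
  available.  ORs are crude ratios of case:control odds against the
  reference band with Woolf (log-scale) intervals; a zero cell triggers
  a flagged 0.5 continuity correction.  The crude-OR choice is verified
  by reproducing published band ORs from their published counts to two
  decimals.
* **Theoretical band ORs**: under the multiplicative model the
  standardized PRS is $Z \sim \mathcal N(0,1)$ and the relative odds of
  a band $(a,b)$ follow
  $E[e^{\beta Z} \mid a < Z < b] = e^{\beta^2/2}
  \{\Phi(b-\beta)-\Phi(a-\beta)\}/\{\Phi(b)-\Phi(a)\}$, checked against
  numerical quadrature.

# Absolute risk under competing mortality

Given a per-SD log odds ratio $\beta$ (treated as a log hazard ratio
under the rare-disease approximation) the relative risk across the
population is log-normal: $RR(Z) = e^{\beta Z}$, $Z \sim \mathcal
N(0,1)$.  The baseline hazard is constrained on the *hazard scale* so
the population-average hazard reproduces the supplied incidence
schedule: $\lambda_0(t) = \lambda_{pop}(t)/E[RR] =
\lambda_{pop}(t)e^{-\beta^2/2}$.  Cumulative risk for percentile $q$
(relative risk $e^{\beta\Phi^{-1}(q/100)}$) accumulates over one-year
bands with piecewise-constant hazards by the cause-specific
competing-risk recursion

$$F(t_k) = F(t_{k-1}) + S(t_{k-1})\,
\bigl(1 - e^{-(h+\mu)\Delta}\bigr)\,\frac{h}{h+\mu},$$

with $h = RR\,\lambda_0$, $\mu$ the competing mortality rate and $S$ the
all-cause event-free probability.  The recursion satisfies
disease + death + event-free = 1 to $10^{-9}$ and matches fine-grid
numerical integration of the same hazards.  Because the constraint holds
on the hazard scale, the Gauss–Hermite average of percentile-specific
*risks* differs from the population risk by a small higher-order amount
(< 1% of the age-80 risk at $\beta = \ln 1.38$; exactly zero at
$\beta = 0$), and the population mean risk exceeds the median-percentile
risk for $\beta > 0$ because the relative-risk distribution is skewed.
Rate tables are user-supplied CSVs (age bands, incidence and mortality
per person-year); a synthetic schedule with plausible orders of
magnitude for a rare cancer ships for tests and examples — it is
synthetic, so published absolute-risk figures are not reproduced
numerically.

# Synthetic data

`simulate_panel()` draws haplotypes per LD block from a first-order
Markov chain: per-block base allele frequency from `maf_range`
(default 0.05–0.5) with ±10% relative within-block jitter — tightly
linked variants share allele-frequency histories, and near-equal
adjacent frequencies keep the transition probabilities feasible for any
`r_adjacent` < 1 (an infeasible frequency/correlation pair raises an
error).  Correlation decays geometrically with lag, $r^k$, and is zero
across block boundaries; block positions map onto 1 Mb genomic windows
so LD blocks align with the reference-panel blocks.  Dosage is the sum
of two independent haplotypes.

`simulate_phenotype()` assigns disease by a logistic model whose
standardized true-score effect equals `log(target_or_per_sd)`; the
intercept is tilted so the expected in-sample case fraction matches
`case_fraction`.  This tilt *is* the case-control design: under a
logistic model, retrospective (case-control) sampling changes only the
intercept and preserves every odds ratio, so fixing the intercept to hit
the case quota on a fixed panel is equivalent to rejection sampling from
a rarer population — `simulate_case_control()` provides the literal
rejection-sampling generator (population batches, attempt cap) when
genotype ascertainment must also be modeled.  Defaults emulate a
consortium-style study: case fraction 0.37, per-SD OR 1.38, 5% causal
variants, prevalence 1%.

What the generator does *not* emulate: realistic human LD maps and
demographic history (no long-range LD, no allele-frequency spectrum from
drift/selection), imputation-uncertainty dosage noise, covariate and
population structure.  Passing tests therefore demonstrate correctness
of the estimators under their stated models, not performance on real
cohort data.

# Numerical choices

* Coordinate descent: curvature bound 1/4, `tol` $10^{-7}$ (tests use
  down to $10^{-9}$ when comparing to oracles), `max_iter` 1000 sweeps;
  non-convergence is reported, never silently accepted.
* LD matrices carry a $10^{-6}$ ridge jitter on the diagonal; a block
  that is still non-PSD raises an error naming the block.
* GIG sampler parameters are floored at $10^{-12}$.
* Stratified CV folds and every stochastic routine are seeded;
  determinism under a fixed seed is tested for the generators, the CV
  grid and the Gibbs chain.
* Tie-breaks: best-grid-point ties go to the sparser model, then the
  smaller $\lambda$; tied scores share a percentile band via average
  ranks.
* Degenerate inputs: monomorphic variants get $\beta = 0$,
  $se = \infty$ and are flagged; complete separation falls back to
  Firth's bias-reduced fit; zero-variance score references and
  single-class AUCs are errors.

# Problem sizes in the shipped tests

The test and benchmark suites run at deliberately modest sizes chosen to
exercise every code path with stable statistics: oracle comparisons at
$n$ = 300–4,000 and $m$ = 12–60; the null cross-validation benchmark at
$n$ = 2,000, $m$ = 500 on a reduced grid; shrinkage parameter recovery
at $m$ = 2,000 variants with 5% causal and nominal $n$ = 20,000 summary
statistics; the OR-to-AUC benchmark at $n$ = 500,000 over five seeds.
Grid sizes, chain lengths and sample sizes are all arguments, so the
full published-scale grids (the 26 × 41 stage-2 grid, 5,000-iteration
chains) are available unchanged on larger hardware.

# Known limitations

* The penalized family fits a single block in memory; biobank-scale
  out-of-core fitting is out of scope.
* The stepwise and S4 methods assume the LD reference matches the GWAS
  population; mismatch propagates directly into joint effects.
* Hazard-ratio evaluation for carrier cohorts (weighted Cox with
  retrospective likelihood) is out of scope; per-SD hazard ratios are
  treated as externally supplied when projecting absolute risk.
* The OR ≈ RR (rare disease) approximation underlies the absolute-risk
  module; it is inappropriate for common outcomes.
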