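---
title: "Latent-variable models of grandparental investment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable models of grandparental investment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Surveys of adolescent grandchildren record, for each of the four grandparent
types (maternal grandmother MGM, maternal grandfather MGF, paternal
grandmother PGM, paternal grandfather PGF), whether the grandparent is alive
and -- only for living grandparents -- a small battery of ordinal Likert items
about that grandparent's involvement: contact frequency (Q15, 4 categories),
having looked after the child (Q26, 4 categories, recorded on a reversed
scale), dependability (Q27, 4 categories) and financial assistance (Q38,
3 categories). The scientific question is how the *survival status of the
other grandparent types* shifts a focal grandparent's investment, within and
between lineages.

Because no single item measures "investment" reliably, investment is modelled
as a latent variable per grandparent type, measured by the four items through
an ordinal probit link. `kinvest` implements the full Bayesian workflow:
model specification, a Gibbs sampler with data augmentation, convergence
diagnostics, probit marginal effects, a phantom-variable sensitivity analysis
for unmeasured confounding, and a synthetic cohort generator with known truth
for recovery studies.

## Model

For grandchild $i$ and grandparent type $g \in \{$MGM, MGF, PGM, PGF$\}$, the
latent investment $\eta_{ig}$ follows the structural model

$$\eta_{ig} = \alpha_g + \sum_{h \neq g} \beta_{gh}\,\mathrm{alive}_{ih}
  + \beta_{g,\mathrm{age}}\,(\mathrm{age}_i - \overline{\mathrm{age}})
  + \zeta_{ig}, \qquad
  \boldsymbol\zeta_i \sim \mathcal N_4(\mathbf 0, \boldsymbol\Psi),$$

with a full $4 \times 4$ latent error covariance $\boldsymbol\Psi$ capturing
unmeasured within- and between-lineage correlation. Each observed item $j$
arises from an underlying normal response
$y^*_{igj} = \lambda_{jg}\,\eta_{ig} + \varepsilon_{igj}$,
$\varepsilon \sim \mathcal N(0, 1)$, categorised by strictly increasing
thresholds $\tau_j$: observed category $c$ iff
$\tau_{j,c-1} < y^* \le \tau_{j,c}$.

Identification and invariance:

* the marker item Q38 has its loading fixed to 1 in every group, setting the
  latent scale;
* thresholds are shared across the four grandparent types;
* one loading (default Q15, configurable) is free per type, the remaining
  loadings are shared (partial measurement invariance);
* indicator residual variances are fixed to 1 (probit/theta scale);
* the structural intercept of the reference type (default MGM) is fixed to 0,
  which together with shared thresholds makes latent locations comparable
  across types.

The reference-intercept rule and the theta-scale residuals are this package's
identification choices: shared thresholds make latent means comparable across
types, so one fixed location suffices, and unit residual variances are the
standard identification for ordinal probit factor models. Which loading is
non-invariant is genuinely open; it is exposed as a configuration rather than
hidden, and it must never be the marker.

All structural predictors -- the alive flags as well as age -- enter the
design centred at their sample means. Slopes are unchanged by centring;
intercepts refer to a grandchild with average covariates, and the reference
factor's latent location is pinned at the covariate means. Besides the usual
numerical-stability argument under diffuse priors, centring decouples the
regression coefficients from the slowly mixing threshold location in the
Gibbs sampler: with raw 0/1 predictors, the intercept-free reference
equation lets a drift in the shared thresholds leak into its coefficients.

Items of deceased grandparents are entirely missing and contribute no
likelihood terms; the grandchild stays in the model and the remaining
factors' full conditionals absorb the information through
$\boldsymbol\Psi$ -- the full-information treatment of missing-at-random
ordinal responses. A factor with no observed indicators for a child is still
drawn, from (at the limit) its structural distribution.

Default priors: $\mathcal N(0, 100^2)$ for structural
coefficients and free intercepts, $\mathcal N(0, 5)$ for free loadings,
$\mathcal N(0, 1)$ for thresholds, and an inverse-Wishart with identity scale
and 5 degrees of freedom for $\boldsymbol\Psi$ (the element-wise IW notation
of commercial SEM software is mapped to this single matrix prior).

## Gibbs sampler

One sweep updates, in fixed order:

1. $y^*$ cells from truncated normals on their category interval
   (Albert-Chib data augmentation);
2. factor scores $\boldsymbol\eta_i$ from their exact 4-variate normal full
   conditional (precision = $\boldsymbol\Psi^{-1}$ + the diagonal loading
   information of the observed cells);
3. free loadings from conjugate normal conditionals, pooling sufficient
   statistics across equality-constrained cells;
4. thresholds from their $\mathcal N(0,1)$ prior truncated to
   $(\max y^* \text{ in } c,\ \min y^* \text{ in } c+1)$, pooled over the
   type-invariant cells; empty categories fall back to the neighbouring
   thresholds as bounds, so ordering holds by construction;
5. the stacked structural block $(\boldsymbol\beta, \boldsymbol\alpha)$ from
   its seemingly-unrelated-regressions multivariate normal conditional;
6. phantom-confounder blocks, when present (below);
7. $\boldsymbol\Psi$ from the conjugate inverse-Wishart.

The update order affects only mixing, not the stationary distribution.
Initialisation is deterministic given the seed: free loadings 1, thresholds
at inverse-normal cuts of the pooled marginal category proportions,
$\boldsymbol\beta = \boldsymbol\alpha = 0$, $\boldsymbol\Psi = I$,
$\boldsymbol\eta = 0$, $y^*$ drawn from its category interval at mean zero.
The threshold sampler is the truncated-prior full conditional; it is known to
autocorrelate strongly (the bounds tighten as $O(1/n)$), which is why the
default chain settings -- three chains of 300,000 iterations, burn-in
150,000, thinning 50, interpreted per chain -- thin heavily. Joint
Metropolis-style threshold updates are out of scope. Structural coefficients
mix much faster; reduced settings (e.g. 20,000 iterations, burn-in 10,000,
thin 10) are adequate for recovery studies at $n \approx 1400$ and are what
the packaged workflows default to.

The sweep is implemented in C++ (RcppArmadillo). All randomness comes from
R's RNG, so runs are bitwise reproducible from `(seed, chain_id)`. Each
full-conditional block can be updated in isolation through an update-mask
argument; the test suite uses this to compare every block against an
independent oracle (closed forms, grid integration, rejection samplers).
Degenerate modes used by the oracle tests -- continuous indicators that
bypass augmentation, fixed thresholds, fixed $\boldsymbol\Psi$ -- are
configurations of the same code path, not forks.

Numerical choices: the truncated-normal sampler tries two plain normal draws
(rejection) before falling back to CDF inversion; inversion uses an
erfc-based normal CDF and Acklam's inverse with ~1e-9 relative accuracy,
far below Monte-Carlo resolution. The per-child 4x4 factor-precision solves
use a hand-coded Cholesky. Threshold bound inversions (which would indicate
corrupted state) raise errors rather than being silently repaired.

## Reported summaries

Point estimates are posterior medians; intervals are 95% highest posterior
density intervals (shortest sorted-sample window, ties broken at the lowest
start). The one-tailed posterior p is the mass on the far side of zero from
the median (draws exactly at zero count in neither tail; they are
measure-zero for continuous parameters). Convergence is assessed by the
Gelman-Rubin potential scale reduction factor on the thinned retained draws
of the (unsplit) chains, with 1.1/1.2 as strict/lenient flags; parameters
fixed by identification are reported as degenerate. Latent correlations are
computed per draw from $\boldsymbol\Psi$ and then summarised -- the nonlinear
transform is applied before summarising, not after.

Marginal effects report the marker item's category probabilities under a
scenario (one alive flag at 0/1, other covariates at sample means):
$P(c) = \Phi\!\big((\tau_c - \lambda\mu)/s\big) -
\Phi\!\big((\tau_{c-1} - \lambda\mu)/s\big)$ with
$s = \sqrt{\lambda^2 \zeta_g + 1}$, i.e. population-averaged over the focal
latent's residual. Averaging is the default because the scenario describes a
randomly drawn grandchild rather than one with a zero latent residual; the
conditional ($s = 1$) mode is exposed as an option. Parameters enter at
posterior medians by default; full per-draw propagation is a flag.

## Phantom-variable sensitivity analysis

Unmeasured within-lineage resource availability plausibly raises both a
grandparent's survival and the spouse's investment. Its effect is mimicked
by a phantom latent variable: mean 0, variance 1, no indicators, with two
*fixed* paths of equal magnitude $\gamma$ -- one into the focal latent's
structural equation and one onto the spouse-survival flag, which becomes
endogenous through a linear auxiliary equation (free intercept and residual
variance). The default $\gamma$ is the largest absolute within-lineage
coefficient of the base fit, recomputed per dataset, and the scan doubles it
for the second scenario. One independent phantom is wired per ordered
within-lineage pair (four in total), which matches the generator's
confounding mechanism exactly; between-lineage phantoms are rejected, since
cross-lineage resource confounding is not considered plausible.

Modelling the path onto the 0/1 survival flag linearly (rather than through
a probit auxiliary) mirrors the fixed-constant path logic of phantom
analysis and makes the implied exposure-confounder covariance exactly
$\gamma$; the synthetic generator induces confounding on the
linear-probability scale for the same reason, so the adjusted model is
correctly specified for generator-embedded confounding. A probit auxiliary
is a plausible alternative wiring; it would make the covariance
$\gamma$-dependent on the survival rate and is deliberately not the default.

## Synthetic cohorts

`default_truth()` encodes the study conditions the generator emulates:
survival proportions 83.7/68.8/73.2/57.1% (MGM/MGF/PGM/PGF), grandchild age
truncated-normal with mean 13.39 and sd 1.41 on [11, 16], cohort size 1411
after exclusions, the reference structural coefficient medians as true
$\boldsymbol\beta$, and the reference latent correlations as the true
$\boldsymbol\Psi$ correlation structure. Loadings (0.9 for non-marker
items), thresholds, latent error variances (1) and the age coefficient
(-0.05/year) are *synthetic plumbing values* -- no survey estimates are
available for them -- chosen once to give non-degenerate category
frequencies, and flagged as such in the truth object. Item nonresponse for
living grandparents is 5%. Age is kept continuous (the covariate enters
linearly; integer rounding would only coarsen it).

The at-least-one-living-grandparent inclusion rule is implemented by row
rejection, which shifts the marginal survival proportions upward by at most
the all-dead probability (~1.2% at the default rates); the tests measure and
bound this shift. Spouse-survival correlation is off by default: the
analysis model treats survival flags as exogenous data. Q26 is emitted in
its raw reversed orientation so the preprocessing reverse-scaling step is
genuinely exercised.

What the generator does *not* emulate: selection into the sample by
grandparental investment (non-random missingness), three-generation
households, item-level response styles, or clustering by school. Passing
recovery tests therefore demonstrates that the estimator recovers the
parameters of its own data-generating process at realistic scale -- not that
any particular estimates are correct for the real survey.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to make the Monte-Carlo error small
relative to the tolerances while keeping a full run practical on a single
core: the conjugate linear-Gaussian oracle at $n = 200$ with 20,000 draws;
the binary ordinal-probit grid oracle at $n = 300$ with 50,000 draws
(total-variation tolerance 0.03); study-scale recovery at $n = 1411$ with
3 chains x 20,000 iterations (burn-in 10,000, thin 10) over 10 replicates;
HPD calibration over 20 replicates at $n = 400$ with 2 chains x 5,000
(burn-in 2,500, thin 5); and the confounder-recovery study at $n = 1000$
with 2 chains x 5,000 (burn-in 2,500, thin 5), with the embedded and
modelled confounding both at $\gamma = 0.157$.

## Known limitations

* Commercial SEM software parameterises ordinal-probit latent models in
  ways that are not always printed (latent response variances,
  intercept/threshold handling); the identification choices here are
  documented assumptions, so numerical agreement with estimates from such
  software is not guaranteed even given the same data.
* The threshold sampler's slow mixing makes threshold PSRFs -- and, through
  the shared location they identify, the free intercepts' -- the last to
  converge; structural regression coefficients converge far earlier. Judge
  runs by the per-parameter convergence report, not a single global factor,
  and use the full default settings when threshold or intercept estimates
  themselves matter.
* No model-fit indices, no formal invariance testing sequence, no MNAR
  selection models: the stated partial-invariance constraints are imposed,
  not re-derived.
* Ordinal items support 2-7 categories; other measurement types are out of
  scope.
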