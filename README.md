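# kinvest

Bayesian structural equation models of **grandparental investment**: how the
survival status of the other grandparent types shifts a focal grandparent's
investment in a grandchild, within and between lineages.

The package is aimed at researchers analysing grandchild-report kin-investment
surveys in which each of the four grandparent types (maternal grandmother
`MGM`, maternal grandfather `MGF`, paternal grandmother `PGM`, paternal
grandfather `PGF`) is rated on a small battery of ordinal Likert items —
contact frequency (Q15), having looked after the child (Q26, reverse-coded),
dependability (Q27) and financial assistance (Q38) — with items missing
entirely for deceased grandparents.

## Model

Investment is a latent variable per grandparent type, measured through an
ordinal probit link and regressed on the other types' survival flags plus
grandchild age:

```
eta[i,g] = alpha_g + sum_{h != g} beta_{gh} * alive[i,h]
           + beta_{g,age} * (age_i - mean(age)) + zeta[i,g]
zeta[i,] ~ N_4(0, Psi)                       (full latent error covariance)
y*[i,g,j] = lambda_{jg} * eta[i,g] + e,  e ~ N(0, 1)
observed category c  iff  tau_{j,c-1} < y* <= tau_{j,c}
```

Identification: the Q38 loading is fixed to 1 (marker), thresholds are shared
across grandparent types, one loading (default Q15) is free per type
(partial measurement invariance), indicator residual variances are 1 and the
reference type's structural intercept (`alpha[MGM]`) is 0. Estimation is by
Gibbs sampling with ordinal data augmentation (compiled core); summaries are
posterior medians, 95% highest-posterior-density intervals, one-tailed
posterior p-values and Gelman–Rubin convergence factors. A phantom-variable
sensitivity analysis gauges how unmeasured within-lineage resource
confounding of chosen strength would change the conclusions, and a synthetic
cohort generator with known truth supports parameter-recovery studies.

See the methods vignette (`vignettes/kinvest-methods.Rmd`) for the full
model, priors, sampler and design rationale.

## Worked example

Simulate a cohort of 800 grandchildren under the default truth (survival
proportions 83.7/68.8/73.2/57.1%, the reference effect sizes as true
coefficients), fit with two short chains, and summarise:

```r
library(kinvest)
coh    <- generate_cohort(default_truth(), n = 800, seed = 11)
design <- encode_design(apply_exclusions(coh$survey)$table)
cfg    <- chain_config(n_chains = 2, iterations = 4000, burnin = 2000,
                       thin = 4, seed = 12)
fit    <- fit_bsem(design, spec = default_model_spec(), config = cfg)
s      <- summary(fit)
s[s$parameter %in% c("beta[MGM<-MGF_alive]", "beta[PGM<-MGM_alive]",
                     "beta[PGF<-MGM_alive]"), ]
```

```
            parameter block median hpd_lower hpd_upper p_one_tailed  psrf n_draws
 beta[MGM<-MGF_alive]  beta  0.291     0.123     0.433        0.000 1.000    1000
 beta[PGM<-MGM_alive]  beta -0.228    -0.462     0.034        0.044 1.004    1000
 beta[PGF<-MGM_alive]  beta -0.015    -0.281     0.252        0.444 0.999    1000
```

Each row is a structural coefficient: e.g. `beta[MGM<-MGF_alive]` is the
shift in the maternal grandmother's latent investment (in marker-item probit
units) when the maternal grandfather is alive rather than dead. The true
values behind this cohort are 0.157, -0.207 and -0.207; at n = 800 with
short chains the posterior medians scatter around them and the HPD intervals
cover them. `latent_correlations(fit)` gives the residual investment
correlations (here 0.89 within the maternal and 0.91 within the paternal
lineage, 0.21–0.27 across lineages, true values 0.881/0.958 and
0.219–0.303), and marginal effects translate a coefficient onto the marker
item's category probabilities:

```r
marginal_effect_table(fit, scenarios = data.frame(focal = "PGM",
                                                  predictor = "MGM_alive"))
```

```
  focal predictor value category probability
    PGM MGM_alive     0        1  0.08309314
    PGM MGM_alive     0        3  0.50039052
    PGM MGM_alive     1        1  0.11135078
    PGM MGM_alive     1        3  0.43478380
```

With the maternal grandmother dead (`value = 0`) the simulated grandchild's
probability of scoring "never" on financial assistance from the paternal
grandmother is 8.3% and of "usually" 50.0%; with her alive, 11.1% and 43.5%
— the negative coefficient made visible on the outcome scale.
`sensitivity_scan()` refits with phantom within-lineage confounders at 1x
and 2x strength and tabulates which coefficients survive.

The packaged workflows are also scriptable:
`inst/cli/kinvest.R <simulate|fit|sensitivity|recover> --seed 1 --out dir`.

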