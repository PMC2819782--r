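---
title: "Small-area prevalence from aggregated totals: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area prevalence from aggregated totals: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevfactor)
```

## The problem

Chronic-disease prevalence is often recorded only for large administrative
units (in England, treated CHD prevalence is reported per Primary Care
Trust), while correlated outcomes — deaths, hospital admissions — are
available for much smaller areas (wards). Health-need profiling requires
prevalence at the small-area scale. `prevfactor` estimates it by pooling
the small-area collateral indicators through a single latent morbidity
factor and disaggregating the observed higher-area totals along that
factor.

## The model

Index small areas by $j = 1,\dots,N_L$, nested in higher areas
$i = 1,\dots,N_H$ with membership $H_j$. For each of $P$ indicators with
age–sex-standardised expected counts $O_{jp}$ (rescaled so
$\sum_j y_{jp} = \sum_j O_{jp}$),

$$y_{jp} \sim \text{Po}(\mu_{jp}), \qquad
\log \mu_{jp} = \log O_{jp} + \lambda_p f_j + u_{jp},
\qquad u_{jp} \sim N(0, \sigma_u^2).$$

No intercepts appear; that fixes the location of the shared factor $f$.
The $u_{jp}$ absorb residual overdispersion and indicator-specific
structure unrelated to morbidity (e.g. admission-policy differences).

The factor follows a Leroux-type conditional autoregressive prior with a
multiple-cause regression mean $\eta_j = \beta' x_j$ over $L$
standardised area risk factors (no intercept), so that with residuals
$r_j = f_j - \eta_j$ and $m_j$ adjacent areas,

$$E(f_j \mid f_{[-j]}) = \eta_j +
  \frac{\kappa \sum_{h \in \partial_j} r_h}{1 - \kappa + \kappa m_j},
\qquad
\text{Var}(f_j \mid f_{[-j]}) = \frac{\sigma_f^2}{1 - \kappa + \kappa m_j}.$$

These conditionals are generated by the multivariate normal joint with
precision $\sigma_f^{-2}\,[\kappa (D - W) + (1-\kappa) I]$, where $W$ is
the 0/1 adjacency matrix and $D$ its degree diagonal; the package uses
that joint both as the inference prior and for exact synthesis. $\kappa$
mixes exchangeable ($\kappa = 0$) and intrinsic CAR ($\kappa \to 1$)
dependence; for $\kappa < 1$ the joint is proper, also on disconnected
graphs (islands simply have $m_j = 0$).

Prevalence outcomes $q = 1,\dots,Q$ are observed only as higher-area
totals $Z_{iq}$. Small-area prevalence means $\delta_{jq}$ follow

$$\log \delta_{jq} = \log E_{jq} + \gamma_{q,H_j} + \lambda_{P+q} f_j
\qquad \text{(constrained mode)},$$

with $E_{jq}$ the expected prevalence from an external rate schedule
(rescaled so the region-wide standard prevalence ratio is 1), and the
totals are fitted as $Z_{iq} \sim \text{Po}(\Delta_{iq})$,
$\Delta_{iq} = \sum_{H_j = i} \delta_{jq}$. One free intercept per higher
area makes the small-area split conditionally multinomial within each
observed total — the Poisson–multinomial equivalence — so posterior means
of $\Delta_{iq}$ reproduce the observed $Z_{iq}$ almost exactly.
Unconstrained mode replaces $\gamma_{q,H_j}$ by a single $\gamma_q$,
preserving only the region-wide total; it is preferable when the recorded
totals themselves may be biased (e.g. differential case-finding in
deprived areas). The latent small-area counts are never imputed as
integers: every prevalence summary is a posterior functional of
$\delta_{jq}$, which the equivalence makes sufficient.

Priors: $\text{Ga}(1,1)$ on $1/\sigma_f^2$ and on every free loading,
$N(0, 100)$ on $\beta$ and $\gamma$, $U(0,1)$ on $\kappa$. The prior on
$1/\sigma_u^2$ is taken $\text{Ga}(1,1)$ by symmetry with the stated
factor-variance prior (the source protocol does not state one).
$\lambda_{P+1} = 1$ is fixed for identification.

## Identification: what the data do and do not pin down

The location of $f$ is identified by the intercept-free indicator
equations. The *scale split* between $f$ and the loadings deserves
honesty: because a free intercept per higher area (constrained mode)
absorbs any per-area level of $e^{f}$, the aggregated totals carry almost
no information about the scale of $f$ beyond the formal anchor
$\lambda_{P+1} = 1$. The indicator likelihood identifies the products
$\lambda_p f_j$ only; along the ridge
$(\lambda/c,\; c f,\; c\beta,\; c^2\sigma_f^2)$ the posterior is shaped
by the Ga(1,1) and normal priors. Consequently single loadings and
$\sigma_f^2$ have wide, prior-sensitive posteriors, while ratios of
loadings, $\kappa$, relative risks and SRRs — the quantities the method
exists for — are well identified. The sampler treats the ridge as a first-
class direction (below), and the synthetic generator places its truth at
the standardized-factor scale $\sigma_f^2 = 1$, commensurate with the unit
prevalence loading, so that generated truths live where the model's own
priors put mass.

## Posterior computation

`fit_prevalence()` runs a Metropolis-within-Gibbs sampler (C++ core):

- $f_j$: single-site random walks against the Leroux full conditional,
  with the fitted totals $\Delta$ maintained incrementally;
- $u_{jp}$: single-site random walks;
- loadings: random walks on the log scale (positivity built in);
- $\beta$: exact conjugate Gibbs ($f$ is Gaussian given $\beta$);
- $\gamma_{q,i}$: independence proposals from the flat-prior conditional
  $e^{\gamma} \sim \text{Ga}(Z_{iq}, S_{iq})$, corrected by the $N(0,100)$
  prior (acceptance essentially 1), with a random-walk fallback when
  $Z_{iq} = 0$;
- $\kappa$: logit-scale random walk; the log-determinant uses the
  eigenvalues of $D - W$, computed once per fit;
- $1/\sigma_f^2$, $1/\sigma_u^2$: Gibbs from their Gamma full
  conditionals;
- two global moves: a location move $f \to f + a$ (the field's level is a
  slow mode under single-site updates) and a scale move along the ridge
  described above, with the first-outcome intercepts co-shifted so every
  $\Delta_{iq}$ is unchanged. Both are exact Metropolis–Hastings steps
  with analytic Jacobians; without the scale move, split-chain $\hat R$
  for the loadings stalls around 1.5–1.7 at moderate run lengths, with it
  all $\hat R \approx 1.00$.

Random-walk step sizes adapt toward 44% acceptance (30% for the global
moves) during burn-in only, so retained draws come from a fixed Markov
kernel. Chain 1 starts from a deterministic null state with the
intercepts warm-started at $\log(Z_{iq} / \sum_{H_j=i} E_{jq})$; further
chains jitter every block for overdispersed starts. Defaults follow the
two-chains-of-10,000, second-half-retained protocol; everything is
configurable. The prior-only mode (`likelihood = FALSE`) reruns the full
kernel against the priors and is used in the tests to verify that
$\kappa$ recovers $U(0,1)$ and the loadings Ga(1,1).

Numerical safeguards: proposals whose means overflow are rejected;
$\kappa$ is clipped to $[10^{-6}, 1 - 10^{-6}]$ (the $U(0,1)$ endpoints
give an improper joint); zero cross-area variance draws are skipped in
SRR computation with a warning; validation rejects non-positive expected
counts rather than guessing at zero-population areas.

## Model checking and summaries

- **DIC**: $\bar D + p_D$ with the plug-in at the posterior mean of the
  log-scale linear predictor (the standard choice for log-linear models;
  the plug-in parameterisation is a documented convention, not a
  likelihood fact). Scope `"y"` uses only the indicator likelihood —
  constrained mode fits the totals by construction, so comparing modes on
  the totals would be uninformative; scope `"full"` adds them.
- **Mixed predictive p-values**: at each retained draw both random-effect
  blocks ($f$ and $u$) are re-drawn from their priors given the sampled
  hyperparameters, data are replicated, and
  $p = \Pr(y^{rep} > y) + \tfrac12 \Pr(y^{rep} = y)$. About 10% of
  values outside $(0.05, 0.95)$ is the calibrated reference level.
- **Relative risks** $\xi_j = \delta_j / E_j$ are summarised as means of
  per-draw ratios (not ratios of means; the distinction is documented
  because the source leaves it open). **SRRs**
  $(\xi_j - \bar\xi)/\omega$ use the $n-1$ cross-area standard deviation
  at each draw, so per-draw SRRs have mean 0 and sd 1 by construction;
  areas are classed high/middle/low at thresholds $\pm 1$ (or $\pm 2$).
  Exceedance probabilities are reported alongside the posterior-mean
  classification since both are standard in disease mapping.
- **Aggregation check**: per-higher-area $|\bar\Delta_{iq} - Z_{iq}|/Z_{iq}$,
  plus the global total for unconstrained fits.
- Monte Carlo standard errors use batch means with $\lfloor\sqrt T\rfloor$
  batches per chain (a reporting convention; the source states MCSEs
  without a method).

## The synthetic generator

`simulate_prev_data()` draws from the model itself on a rook-adjacency
lattice with rectangular-block higher areas: standardised Gaussian
covariates, an exact Leroux field (Cholesky of the joint precision),
log-normal expected counts (median 20 per area-indicator, log-sd 0.5,
giving ward-like count sizes), Poisson indicators, latent Poisson
small-area prevalence counts, and their higher-area sums. Defaults mirror
the magnitudes estimated in the London CHD application: $\kappa = 0.9$,
$\beta = (-0.2, 0.18, 0.05)$, $\lambda_y = (0.45, 0.41, 0.72, 0.77)$,
$\lambda_z = 1$, with $\sigma_f^2 = 1$ (the standardized-factor scale,
see above), $\sigma_u^2 = 0.05$ (mild overdispersion) and higher-area
intercepts drawn $N(0, 0.2^2)$ so recorded totals deviate realistically
from what area structure alone would predict. Age–sex standardisation is
exercised separately through `compute_expected_counts()`; the default
generator draws offsets directly.

What the generator does *not* emulate: irregular ward geographies and
island structure, spatially correlated covariates, measurement bias in
the recorded totals (under-recorded prevalence in deprived areas), and
multi-factor latent structure. Passing recovery tests therefore show the
estimator is correct under the stated model, not that the model is right
for any particular registry.

```{r example, eval = FALSE}
sim <- simulate_prev_data(seed = 1)          # 20x20 wards, 16 higher areas
fit <- fit_prevalence(sim$data, chains = 2, iter = 4000, seed = 2)
tidy(fit)                                    # posterior summaries + Rhat
glance(fit)                                  # DIC decomposition
head(area_summary(fit))                      # xi, SRR, hotspot labels
aggregation_check(fit)                       # totals reproduced?
```

## Problem sizes used for verification

The test-suite fits use a 20×20 lattice (400 small areas, 16 higher
areas, $P = 4$, $Q = 1$, $L = 3$) with 2 chains of 4,000 iterations, ten
replicate datasets for interval coverage, and 400 retained draws for the
mixed predictive check — sizes chosen so the full verification cycle runs
in about a minute while keeping Monte Carlo error well inside the
tolerances being checked. The London-scale protocol (625 areas, 2×10,000
iterations) remains the fitting default.

## Limitations

- $R = 1$: a single shared factor; multi-factor extensions would need
  loading-matrix identification constraints beyond scope here.
- 0/1 adjacency only; distance-decay weights are not implemented.
- Poisson measurement only (appropriate for rare outcomes); binomial
  variants are not implemented.
- Higher-area intercepts are fixed effects; exchangeable or spatial
  random-effect priors for them (a variant noted in the source
  literature) are not implemented.
- Individual loadings and $\sigma_f^2$ are reported but should be read
  with the identification caveat above.
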