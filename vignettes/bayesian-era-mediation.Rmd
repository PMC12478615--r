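---
title: "Bayesian extended redundancy analysis with mediators and mixed outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian ERA with mediators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bera)
```

## The model

Extended redundancy analysis (ERA) handles many collinear predictors by
reducing each substantively defined block of predictors to a single
*component* — a weighted composite $f_k = X_k w_k$ — and regressing the
outcomes on the components rather than on the raw predictors. The weights
and the regression coefficients are estimated jointly, so the composites
are formed to explain the outcomes, not merely to summarize the
predictors (the contrast with principal-component regression). Each
predictor loads on exactly one component (the weight matrix $W$ is
block-sparse), and each component is constrained to unit sample variance
for identifiability.

`bera` extends this component model in three directions, all estimated
jointly in one Bayesian model:

1. **Multiple mediators.** $R$ continuous mediators $m_i$ sit between the
   components and the outcomes:
   $$m_i = a_1 + A_2^\top [c_i; f_i] + e_i, \qquad
     e_i \sim t_{\nu_M}(0, \Sigma_M),$$
   with $c_i$ optional covariates and $f_i$ the component scores.
2. **Mixed outcomes.** $Q$ outcomes split into $T$ continuous ones and
   $Q-T$ ordinal ones. Ordinal outcome $q$ with $J_q$ categories is driven
   by a latent continuous $z_{iq}$ through cutpoints
   $\gamma_{q,0} = -\infty < \gamma_{q,1} = 0 < \cdots < \gamma_{q,J_q} =
   \infty$: category $j$ is observed when $z_{iq} \in
   (\gamma_{q,j-1}, \gamma_{q,j}]$.
3. **A joint, unstructured error law.** Writing $u_i$ for the stacked
   vector of continuous outcomes and ordinal latents,
   $$u_i = a_0 + A_3^\top [c_i; f_i] + A_4^\top m_i + \varepsilon_i,$$
   with a correlated error whose continuous block is multivariate $t$ with
   unknown df $\nu_C$ and whose ordinal block is multivariate $t$ with df
   fixed at $\nu_0 = 7.3$ and scale $\sigma_0^2$ chosen so each latent
   margin approximates the standard logistic. The full error covariance is
   unstructured ($\Sigma_Y$), so dependence between continuous and ordinal
   outcomes is modeled rather than assumed away.

The mediation (indirect) effect of component $k$ on outcome $q$ through
mediator $m$ is the product of coefficients $a_{2[k,m]} \cdot a_{4[m,q]}$,
computed per posterior draw so that its full posterior (mean and credible
interval) is available. The difference method — the drop in the
component-to-outcome coefficient when mediators are added — is provided as
a cross-check (`difference_method()`), with the caveat that pairing draws
from two independent chains by index is an approximation (it is labeled as
such in the output).

## Why a t distribution with 7.3 degrees of freedom

A logistic likelihood for the ordinal latents would break the conjugacy
that makes Gibbs sampling clean. A Student-$t$, however, is a scale
mixture of normals: with $\phi \sim \mathrm{Gamma}(\nu/2, \nu/2)$ and
$z \mid \phi \sim N(\mu, \Sigma/\phi)$, $z$ is marginally $t_\nu$. The
$t$ with $\nu_0 = 7.3$ and scale variance $\sigma_0^2 =
\pi^2(\nu_0-2)/(3\nu_0) \approx 2.389$ — the scale that matches the
$t$ variance to the logistic variance $\pi^2/3$ — is numerically almost
indistinguishable from the standard logistic. The package re-derives this
constant rather than hard-coding trust in it: `optimal_logistic_df()`
minimizes the integrated squared distance between the variance-matched
$t$ density and the logistic density by adaptive quadrature on $(-40,40)$
(both densities are numerically zero beyond) and bounded golden-section
search with tolerance $10^{-4}$; the minimizer is 7.3 to one decimal.
The payoff: identified ordinal coefficients can be read as log odds
ratios, and the simulator can generate *exactly* logistic latents by the
quantile transform $F_L^{-1}(T_{\nu_0}(z/\sigma_0))$
(`t_to_logistic()`), which is strictly increasing and maps the $t$
margin onto the logistic one.

$\nu_0$ and $\sigma_0^2$ are constants of the ordinal block, never
sampled. The dfs of the mediator errors ($\nu_M$) and of the continuous
outcome block ($\nu_C$) are unknown and estimated.

## Priors

All priors are conjugate and deliberately diffuse (`era_priors()`):

* Coefficients ($W$, $a_1$, $A_2$, $a_0$, $A_3$, $A_4$): independent
  $N(0, 100)$. The variance 100 is large relative to identified
  coefficient scales (components have unit variance; ordinal coefficients
  are log odds ratios), so the data dominate.
* Precision matrices $\Sigma_M^{-1}$, $\Sigma_Y^{-1}$: Wishart with
  $\dim + 2$ degrees of freedom and scale $I/(\dim+2)$ — the smallest df
  giving a finite prior covariance mean, centered on the identity.
* Unknown dfs: uniform on $1/\nu$ over $(0, 1]$. The reciprocal scale
  puts the normal limit at 0 and the Cauchy at 1, covers that whole range
  in a finite interval, and mildly favors longer tails. The bounds are
  configurable (`nu_inv_lo`, `nu_inv_hi`).
* Cutpoints beyond the fixed $\gamma_{q,1}=0$: flat, constrained to
  ordering.

## The MCMC cycle

`era_fit()` runs, per iteration:

1. **Weights.** All free weights are drawn jointly from their normal full
   conditional, combining the mediator likelihood (through the component
   rows of $A_2$) and the response likelihood (through $A_3$). The drawn
   components are then standardized to unit sample variance with the
   compensating rescale applied to the component rows of $A_2$ and $A_3$
   — a move along the scale direction that leaves the likelihood
   untouched — and the sign convention (first weight of each block
   nonnegative) is applied the same way. Sign flips are needed because
   negating a column of $W$ together with its coefficient rows leaves the
   likelihood invariant; the convention picks one representative.
2. **Mediator block.** $(a_1, A_2)$ jointly from their matrix-normal
   conditional; $\Sigma_M^{-1}$ from its Wishart conditional on
   precision-scaled residuals; the per-subject precisions $\phi_{M,i}$ and
   the df $\nu_M$ by Metropolis (below).
3. **Latent ordinal variables.** Each $z_{iq}$ from its univariate normal
   full conditional given the other outcomes' residuals — mean and
   variance from the conditional of the joint error law — truncated to
   the interval of the observed category. The truncated-normal sampler
   uses inverse-CDF draws in the bulk and an exponential rejection
   sampler beyond six standard deviations, so far-tail truncations (which
   occur under diffuse initialization) stay finite.
4. **Response block.** $(a_0, A_3, A_4)$ jointly from the matrix-normal
   conditional under the per-subject error covariance; free cutpoints
   one-at-a-time from their uniform full conditionals (bounded by the
   adjacent latents and cutpoints), the simplest scheme consistent with
   the zero-anchored first cutpoint; $\Sigma_Y^{-1}$ from its Wishart
   conditional; $\phi_{1i}, \phi_{2i}, \nu_C$ by Metropolis.

### The per-subject error covariance

The precisions enter the joint error covariance symmetrically:
$\mathrm{cov}(\varepsilon_i) = D_i \,\Sigma_Y\, D_i$ with
$D_i = \mathrm{diag}(\phi_{1i}^{-1/2} 1_T,\;
\sigma_0\,\phi_{2i}^{-1/2} 1_{Q-T})$. This choice preserves the marginal
multivariate-$t$ law of each block while allowing arbitrary cross-block
correlation in $\Sigma_Y$, and it keeps every conditional above tractable.
It is a genuine design decision: other placements of the mixing variables
(e.g., one common precision) would give different cross-block tail
dependence. With the symmetric form, the conditionals of $\phi_{1i}$ and
$\phi_{2i}$ are *not* gamma (cross-block terms contribute
$\sqrt{\phi}$), which is why they are updated by a vectorized random-walk
Metropolis on the log scale (default step 0.5, no adaptation). The df
updates are random walks on $1/\nu$ inside the prior support; proposals
outside are rejected.

### Identification and parameter expansion

The latent scale of each ordinal outcome is not identified: multiplying
$z_{\cdot q}$, its intercept, coefficients, cutpoints and the
corresponding row/column of $\Sigma_Y$ by a constant changes nothing
observable. The sampler deliberately leaves $\Sigma_Y$ unconstrained (a
parameter-expanded representation — constraining $\sigma_{qq}=1$ inside
the chain would force Metropolis updates for correlations), and
`identified_rescale()` maps every stored draw to the identified scale by
dividing ordinal intercepts, coefficient columns and cutpoints by
$\sigma_{qq}^{1/2}$ and normalizing the corresponding rows/columns of
$\Sigma_Y$ to unit diagonal. On that scale ordinal coefficients are log
odds ratios; `summarize_effects(..., as_odds_ratio = TRUE)` exponentiates
per draw before summarizing. In addition, an explicit expansion move — a
Metropolis step on the unidentified scale itself, rescaling the whole
coordinate group at once — keeps the working scale from drifting and
improves mixing (`era_control(expand = TRUE)`, default). Because the move
acts purely along the unidentified direction, identified quantities are
invariant to it by construction.

### Initialization, burn-in, reproducibility

Initial values are drawn from the priors (default), with $W$ standardized
immediately; cutpoints start unit-spaced and latents are drawn truncated
around the initial mean structure. A data-driven least-squares start
(`init = "ls"`: equal weights, OLS coefficients on crude logistic-scale
latents) is available and converges faster, but the prior start is the
default to keep chains overdispersed relative to the posterior. Defaults
are 30,000 iterations, 2,000 burn-in, thinning 5. One seeded RNG stream
drives the whole run in a fixed draw order, so a fit is bit-for-bit
reproducible given its settings; the run manifest (`write_manifest()`)
records settings, seed, runtime and Metropolis acceptance rates.

Numerical guards: CDF values are clamped to $[10^{-12}, 1-10^{-12}]$
before quantile inversion; nearly-singular conditional precision or
covariance draws are retried with escalating diagonal jitter; covariance
draws are symmetrized; a non-finite state aborts with the iteration
number. A value exactly on a cutpoint (a probability-zero event) is
assigned to the lower category — a convention only.

## The synthetic-data generator

`default_scenario(n)` emulates the model's own generative process, at the
reference topology used throughout the tests: two components formed from
blocks of three predictors (multivariate normal, within-block correlation
0.5, between-block 0), no covariates, two mediators, two continuous and
two three-category ordinal outcomes. True values are package choices,
fixed once and documented here: every path coefficient is nonzero with
magnitude in $[0.2, 1.0]$ (so all paths are recoverable but not
trivially strong); $\Sigma_M$ and $\Sigma_Y$ have unit diagonals and 0.3
off-diagonals (modest, realistic residual dependence); $\nu_M = \nu_C =
5$ (clearly heavier-tailed than normal, finite variance); cutoff sets
$(0, 1.1)$ and $(0, 1.6)$, near the logistic upper quartile so that all
categories stay populated. Ordinal latents are generated by drawing the
correlated $t$ errors, transforming each margin to *exact* logistic with
`t_to_logistic()`, and discretizing; the latent matrix is returned for
testing but is never an input to the fitting API.

What the generator does *not* emulate: skewed or discrete predictors,
measurement error in mediators, missing data, covariates (supported by
the fitting API but absent from the reference scenario), cluster
structure, or model misspecification (the fitted error family matches the
generating one up to the t-vs-logistic approximation). A green
parameter-recovery test therefore establishes internal consistency of the
sampler with its stated model — not robustness to real-data violations
of it.

## Summaries

Credible intervals are equal-tailed posterior quantile intervals (2.5%
and 97.5% for the default level), the standard Bayesian reporting
default; highest-posterior-density intervals are not implemented. An
effect is flagged when its interval excludes the null — 0 on the raw
scale, 1 on the odds-ratio scale; the two flags agree for the same path
because $\exp$ is monotone. Diagnostics (`ess_geweke()`) use the
initial-positive-sequence autocorrelation truncation for ESS and the
first-10%-vs-last-50% mean comparison for the Geweke $z$, computed on the
identified scale.

## Known limitations

* Single chain; multi-chain workflows are run as independent seeded fits.
* The difference method pairs independent chains by draw index — an
  approximation adequate for posterior means, not for joint draws.
* No missing-data handling, no mediator selection, no multi-group or
  mixture structure.
* Metropolis steps are not adapted; for unusual data scales the step
  sizes in `era_priors()` may need manual tuning (acceptance rates are
  reported in the fit object).
* With an empty top ordinal category the highest cutpoint has an
  unbounded uniform conditional and is kept at its current value for that
  iteration; extremely sparse categories will mix slowly.
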