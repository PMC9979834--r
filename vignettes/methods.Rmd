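---
title: "Models and methods: polyp-competitor interactions on settlement panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: polyp-competitor interactions on settlement panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polypcomp` analyses removal experiments on settlement panels in which
polyps of *Aurelia aurita* interact with the other sessile organisms
("potential competitors") colonising the same substrate. This vignette is
the package's own account of the two models it fits, the choices that were
genuinely open, and what the synthetic-data tests do and do not establish.

## The experimental design the package assumes

Sixty panels hang in 10 spatial blocks, three panels at each of two depths
(1 m and 3 m) per block, one panel per removal treatment: control (C),
weekly removal of about half the polyps (A, applied once polyps appear,
typically from the third weekly sampling), and weekly removal of every
second individual or colony of the other sessile organisms (O, typically
from the second sampling). Each panel is photographed weekly for 8 weeks,
before and after treatment; percent cover is estimated by recording the
organism under each of 100 random points. A one-off mistaken application
(an A-type removal applied to a control panel in week 2) is part of the
recorded design: that panel is analysed as a control in the
final-composition model but its application enters the time-series
likelihood. Paired weekly measurements of dissolved oxygen, temperature and
salinity at the two depths are summarised by central 95% credible intervals
for the mean depth difference, which under a noninformative prior on the
mean and log standard deviation of normal differences coincide with
one-sample t-intervals.

## Track 1: final composition

Cover is compositional: only ratios of parts are informative, so the final
pre-treatment counts are modelled on the simplex. With `y_jkl` the 5-part
counts (polyps on panel, bare panel, *Botrylloides*, *Bugula*, *Molgula*;
parts chosen by the "at least 20 points on at least one panel" rule
evaluated on the data) for depth `j`, treatment `k`, block `l`:

$$ y_{jkl} \sim \text{multinomial}(n_{jkl}, \rho_{jkl}), \qquad
   \text{ilr}(\rho_{jkl}) = \mu + \alpha_j + \beta_k\ [+ \gamma_{jk}]
   + \delta_l + \epsilon_{jkl} $$

with $\delta_l \sim N(0, Z)$ and $\epsilon_{jkl} \sim N(0, \Sigma)$ in the
4-dimensional ilr space. Because the analysis is subcompositionally
coherent, excluded rare taxa cannot change the conclusions about the
retained parts.

**Basis.** Any orthonormal logratio basis gives the same fitted
compositions and contrasts; the package's default is the sequential binary
partition ((polyps, bare) vs competitors; polyps vs bare; *Botrylloides* vs
(*Bugula*, *Molgula*); *Bugula* vs *Molgula*). This choice makes the two
ternary displays of treatment effects — the geometric-mean amalgamation
(polyps, bare, gm(competitors)) and the competitor subcomposition — exact
orthogonal blocks of coordinates, so the decomposition is lossless (a test
asserts the reconstruction).

**Coding and priors.** Effects are sum-to-zero coded over the 2 depths and
3 treatments (interaction doubly centred), which identifies $\mu$ as an
overall mean. Fixed-effect coordinates have N(0, 2.5²) priors. For the
covariance matrices the package uses inverse-Wishart(6, I) priors rather
than a scale-times-correlation decomposition: with no Hamiltonian Monte
Carlo engine available, the sampler is written in the package, and the
inverse-Wishart is conjugate, giving an exact Gibbs step where a decomposed
prior would need slow Metropolis updates of a 4×4 covariance. The prior has
mean I on the ilr scale — weakly informative at the scale of the data — and
the reported quantities (logit contrasts, fitted compositions) are
insensitive at their reported precision.

**Sampler.** Metropolis-within-Gibbs: vectorised random-walk updates of the
60 panel effects (conditionally independent) and the block effects; blocked
random-walk updates of $\mu$, depth, treatment and interaction effects;
recentring moves that shift $\mu$ against all panel effects, and each block
effect against its panels, to break the funnel-like correlation between
hierarchy levels; conjugate inverse-Wishart draws for $Z$ and $\Sigma$.
Proposal scales adapt during warmup (Robbins-Monro toward 23-30%
acceptance). Defaults are 4 chains × 2000 post-warmup iterations; split
R-hat and a basic autocorrelation ESS are reported for all fixed-effect
coordinates and log-variances, and should be checked (R-hat below about
1.05 at the defaults).

**Model comparison.** The natural "new observation" is a new block of
panels, so variants (full, no interaction, no treatment, no depth) are
compared by leave-one-cluster-out cross-validation on marginal likelihoods:
for each held-out block, fresh $\delta \sim N(0, Z)$ and
$\epsilon \sim N(0, \Sigma)$ are simulated per posterior draw (100
replicates by default) and the joint multinomial likelihood of the block is
averaged on the likelihood scale. The standard error of an elpd difference
is $\sqrt{B}$ times the standard deviation of per-block differences. The
effective sample size of the integration weights is monitored; a warning
suggests raising `mc_reps`.

**Summaries.** Treatment-cell compositions set random effects to zero
(posterior of the cell mean, not of a new panel); responses are posterior
logit differences, e.g. logit(*A. aurita*) between O and C at a depth.
Credible regions for ternary displays are computed by a Gaussian kernel
density in the 2-D ilr coordinates of the 3-part composition (normal
reference bandwidth), thresholded at the sample (1-level) density quantile
and mapped back to the ternary triangle; whether the original analysis used
the same convention is unknown, but the contained-mass property is what the
tests assert.

## Track 2: community dynamics

The time series aggregate each photograph to (polyps on panel, bare,
potential competitors); the few points with polyps growing on competitors
are excluded from all three categories and from the totals. State variables
are competitor cover $x \in [0,1]$ and polyp density $y_1$, occupying area
$\delta$ per polyp; free space is $1 - x - \delta y_1$. The basic model is
preemptive competition for space: settlement onto free space ($a_0$, $b_0$),
growth/budding into free space ($a_1$, $b_1$), and density-independent death
($a_2, b_2 < 0$). Its community matrix — partial derivatives of
proportional growth rates of the relative abundances $(x, \delta y_1)$ —
is negative in all four entries, so positive effects of polyps on
competitors require an extra mechanism. Four one-parameter extensions
provide them: settlement facilitation ($a_0 + m_0\delta y_1$), growth
facilitation ($a_1 + m_1\delta y_1$), overgrowth of polyps by competitors
($+\,a_{1,y_1} x y_1$ to competitor cover, $-\,(a_{1,y_1}/\delta)x y_1$ to
polyps — which conserves occupied space exactly, a machine-precision test),
and protection from predators ($a_2 e^{-m_2 \delta y_1}$). Each collapses to
the basic model when its parameter is zero.

**Identifiability and reparameterization.** Cover data cannot separate
$y_1$ from $\delta$, so fitting works in relative-abundance coordinates
(equivalently $\delta = 1$): the reported polyp settlement rate is the
product $\delta b_0$ (`db0`) and the overgrowth rate is $a_{1,y_1}/\delta$.
Proportional rates ($b_1$, $b_2$) are unchanged.

**Events and likelihood.** Removal is an instantaneous proportional
reduction at the sampling instant: an A application multiplies polyp
density by $1-r_A$, an O application multiplies competitor cover by
$1-r_O$; the removal fractions are estimated, shared across panels, weeks
and depths (the design targeted 0.5 for both). Trajectories are
deterministic per depth × schedule (Dormand-Prince RK45, rtol 1e-8, atol
1e-10, stop-update-restart at events; the integrator is compiled in the
package because no ODE solver package is available in the environment).
Counts are multinomial with probabilities $(\delta y_1,\ 1-x-\delta y_1,\ x)$,
floored at 1e-9 and renormalised so that exact zeros in early weeks (before
any polyp has settled) keep the likelihood finite. Control panels enter
once per week; treated panels contribute pre and post records in
application weeks. Rate parameters per depth are independent a priori, with
half-normal(1 per week) priors on magnitudes and signs imposed by
construction; $r_A, r_O$ are uniform(0,1).

**Sampler.** Adaptive Metropolis on log/logit-transformed parameters
(Haario-style covariance adaptation during warmup, 23% target acceptance),
initialised at a posterior mode found by Nelder-Mead + BFGS. Defaults are
3 chains × 1500 kept draws from 5000 iterations. Weakly informed parameters
(polyp rates at 1 m where polyps are scarce; competitor death at 3 m)
mix slowly and stay close to their priors — the same behaviour the original
analysis reported — so the convergence diagnostics printed by the fit
should be read before interpreting those parameters.

**Comparison and checks.** Models are compared by PSIS-LOO on the pointwise
log-likelihood draws; the Pareto-smoothing (generalized-Pareto tail fit by
the Zhang-Stephens posterior-mean method, expected-order-statistic
replacement, truncation at the raw maximum) is implemented in the package
and verified in tests against exact leave-one-out refits on a small
instance. Posterior predictive simulation, typical-panel trajectories
(posterior mean with 95% HPD bands under the typical schedules) and
post-versus-pre removal diagnostics (slopes $1-r_A$, $1-r_O$ through the
origin, with the untargeted competitor pairs checking against accidental
removal) complete the picture. Because the dynamics are deterministic and
shared within a depth, predictive simulations understate between-panel
variability — a known, documented deficiency of this model class, not a
bug.

## The synthetic world

The generator reproduces the design exactly (60 panels, 8 samplings of 100
points, typical schedules, the mistaken week-2 application) and its default
preset is chosen once to match the study's qualitative final state:
competitors dominate at 1 m, panels at 3 m keep more polyps and bare space,
overall polyp cover is low, and removal fractions are at their experimental
target 0.5. Competitor counts are split among named taxa by a fixed
per-panel Dirichlet draw (concentrations favouring *Botrylloides*, *Bugula*
and *Molgula*) so the 20-point taxon-inclusion rule is exercised; a small
share (0.2% of competitor cover) is recorded as polyps-on-competitors. The
preset lives in `inst/extdata/preset_default.json` as versioned
configuration. The MANOVA preset defines effects as ilr images of explicit
perturbation compositions, with diagonal block (sd 0.15) and panel (sd
0.25) covariances.

What a green test establishes: the estimators recover the parameters of
their own generating processes at the design's size and noise level, the
algebraic identities hold, and cross-validation ranks models correctly when
the generating mechanism is present. What it does not establish: anything
about photograph noise, mis-identification, spatial structure, or
between-panel stochasticity — the generator, like the fitted model, is
deterministic within a depth × schedule cell.

## Numerical choices

- Closure/orthonormality tolerance 1e-12; ilr round-trips asserted to 1e-10.
- Zero counts are replaced by 1/2 only for display (ternary plots);
  likelihoods act on raw counts.
- ODE tolerances rtol 1e-8 / atol 1e-10; simplex grids exclude an
  $\epsilon = 10^{-3}$ boundary margin.
- Multinomial probability floor 1e-9 with renormalisation.
- LOCO integration: 100 random-effect replicates per posterior draw
  (user-adjustable), weight-ESS monitored.
- HPD regions: `MASS::kde2d` with normal-reference bandwidths, grid 151².
- Week indexing: deployment is week 0 (empty panels, the ODE initial
  condition); observations at weeks 1-8.

## Open choices resolved here

- Whether reported contrasts marginalise over random effects or set them to
  zero is not documented in the source analysis; the package sets them to
  zero (the contrast of cell means). Marginalising would widen the
  intervals but leave posterior means almost unchanged under the symmetric
  random-effect distributions.
- The exact contrast matrix of the original analysis is not printed; all
  reported quantities are basis-invariant (asserted by test), so only plot
  orientation could differ.
- Removal events are placed exactly at the observation instant, between the
  pre- and post-treatment photographs.
- The `cli_reporting` surface is provided as exported functions
  (`run_pipeline()`, `run_config()`, `read_config()`) plus a thin Rscript
  wrapper in `inst/scripts/`; an analysis package's natural interface is
  its functions.

## Known limitations

- The samplers are random-walk based; they are calibrated for the design
  size shipped here, and very different designs may need longer runs
  (check the printed R-hat/ESS).
- Deterministic dynamics understate panel-to-panel variability
  (underdispersion relative to real data).
- Weakly informed rate parameters are prior-dominated; their posteriors
  should not be over-interpreted.
- The three-state model with polyps living on competitors is out of scope.
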