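# polypcomp

Interactions between jellyfish polyps and their potential competitors in
marine sessile communities, analysed from settlement-panel removal
experiments.

Sessile invertebrates on hard substrate are a canonical example of a
community structured by competition for space, and polyps of the moon
jellyfish *Aurelia aurita* are an under-studied member of such communities.
`polypcomp` implements the two analysis tracks for a blocked removal
experiment (60 panels in 10 blocks, two depths, weekly photographic point
counts over 8 weeks, with weekly removal of half the polyps in an "A"
treatment or half the other sessile organisms in an "O" treatment):

1. **Final community composition.** Point counts of the 5-part final
   composition (*A. aurita* on panel, bare panel, *Botrylloides* spp.,
   *Bugula* spp., *Molgula tubifera*) are modelled by a Bayesian latent
   hierarchical compositional MANOVA with a multinomial observation model:

       y_jkl ~ multinomial(n_jkl, rho_jkl)
       ilr(rho_jkl) = mu + alpha_j + beta_k [+ gamma_jk] + delta_l + eps_jkl
       delta_l ~ N(0, Z),  eps_jkl ~ N(0, Sigma)

   in isometric-logratio coordinates, with depth effects `alpha`, removal
   treatment effects `beta`, block effects `delta` and panel effects `eps`.
   Model variants (with/without treatment, depth, interaction) are compared
   by leave-one-cluster-out cross-validation, integrating block and panel
   effects out by Monte Carlo. Treatment responses are summarized by
   posterior logit contrasts (e.g. logit *A. aurita* between O and C) and by
   two orthogonal ternary projections with 95% HPD credible regions.

2. **Community dynamics.** Weekly 3-category time series (polyps, bare,
   potential competitors) are fitted by five ODE models of preemptive
   competition for space; the basic model is

       dx/dt  = a0 (1 - x - d y1) + a1 x (1 - x - d y1) + a2 x
       dy1/dt = b0 (1 - x - d y1) + b1 y1 (1 - x - d y1) + b2 y1

   with one extra mechanism per variant (settlement facilitation, growth
   facilitation, overgrowth of polyps by competitors, protection from
   predators) and instantaneous proportional removal events at the treatment
   applications. Models are fitted by adaptive MCMC (deterministic
   trajectories, multinomial observation model), compared by PSIS-LOO, and
   interrogated via the community matrix of interaction strengths (partial
   derivatives of proportional growth rates with respect to relative
   abundances), whose (1,2) entry is the effect of polyps on competitors.

A synthetic-experiment generator reproduces the full design (including the
one-off mistaken treatment application the study recorded), so every stage
is testable offline.

## Worked example

```r
library(polypcomp)

sim <- generate_dynamics_experiment(seed = 7)   # 60 panels x 8 weeks
dd  <- dynamics_dataset(sim$table)

fit <- fit_dynamics(dd, "overgrowth", chains = 3, iter = 16000,
                    warmup = 8000, thin = 8, seed = 11)
print(fit)
#> Space-competition model fit (overgrowth)
#>   741 observations, 3 chains x 1000 kept draws, acceptance 0.20
#>   max split R-hat 1.164, min ESS 42
head(summary(fit)$table[, 1:5], 3)
#>  parameter     mean       sd    lower   upper
#>      a0_1m  0.09327 0.004480  0.08435 0.10183
#>      a1_1m  1.12736 0.036552  1.05689 1.19936
#>      a2_1m -0.11937 0.006515 -0.13204 -0.10678
```

`a0_1m` is the weekly settlement rate of potential competitors at 1 m
(posterior mean 0.093, 95% HPD 0.084-0.102; the generating value was 0.10),
`a1_1m` their growth rate over free space, and `a2_1m` their death rate.
Polyp parameters are reported as the products identifiable from cover data
(`db0` = delta x b0); `r_A`, `r_O` are the removal fractions, with
target 0.5 in the synthetic design. On the composition side:

```r
md   <- manova_subset(sim$table)
mfit <- fit_manova(md, "no_interaction", seed = 3)
logit_contrast(mfit, "aurita", c("O", "C"), depth = 1)
#> logit(aurita), O - C at 1 m: posterior mean 2.82, 95% CI (2.37, 3.28)
```

a strong positive response of polyps to removal of their competitors
(the synthetic preset builds one in). `loco_cv()` compares the four model
variants, `effect_ternaries()` + `hpd_region_2d()` produce the ternary
displays, `psis_loo_compare()` the dynamic-model table, and
`run_pipeline(run_config(...))` writes the whole report bundle as CSV files.

## Acceptance script

`scripts/acceptance.R` re-runs the main computation from scratch against the
installed package — simulating the study design, fitting the compositional
MANOVA and two dynamic models, comparing them by PSIS-LOO — and writes the
machine-readable results object to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
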