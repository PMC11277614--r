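---
title: "Multicomponent latent trait models for diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent latent trait models for diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmltmd)
```

## The model family

Item response data from rule-based tests (figural analogies, abstract
reasoning matrices, and similar instruments) are binary person-by-item
matrices in which each item is built from a known combination of composition
rules. A binary **Q matrix** (items by features) records which rules each
item contains, and this package estimates a nested family of models that
decompose item difficulty through Q:

* **LLTM.** A Rasch model whose item difficulty is a linear combination of
  feature difficulties, $\beta = Q\eta$:
  $P(y_{ij}=1) = \mathrm{logistic}(\theta_i - \textstyle\sum_k q_{jk}\eta_k)$.
* **Constrained 2PL.** The LLTM with a free nonnegative slope per item:
  $P = \mathrm{logistic}(\alpha_j(\theta_i - \sum_k q_{jk}\eta_k))$.
* **MLTM-D.** Features are grouped into $M$ latent components (here, global
  versus local figural characteristics). Each component contributes a
  Rasch-type success probability and an item requires *all* of its
  components:
  $P(y_{ij}=1) = \prod_m \mathrm{logistic}(\theta_{im} - b_{jm})^{C_{jm}}$,
  with $b_{jm} = \sum_k q_{jk}\eta_{mk}$ over the component's features and
  $C$ the item-by-component incidence derived from Q. The product makes the
  model noncompensatory: ability on one component cannot buy back failure on
  another, and a component absent from an item ($C_{jm}=0$) cannot influence
  it at all.
* **GMLTM-D.** The three-parameter generalization:
  $P(y_{ij}=1) = c_j + (1-c_j)\prod_m
  \mathrm{logistic}(\alpha_{jm}(\theta_{im} - b_{jm}))^{C_{jm}}$.
  The guessing floor $c_j$ captures success without mastery (multiple-choice
  distractors), and the discriminations $\alpha_{jm}$ are *shared across
  items with the same feature pattern within a component*: discrimination is
  treated as a property of the rule combination, not of the individual item.
  With $\alpha \equiv 1$ and $c \equiv 0$ the model is exactly the MLTM-D;
  with $M = 1$ the MLTM-D is exactly the LLTM. These reductions are enforced
  by tests to $10^{-12}$.

### Structural conventions

* An item with no features is rejected at validation: its product over
  components would be empty, forcing success probability 1 regardless of
  ability.
* The C matrix is always derived from Q and the feature-to-component
  assignment. Cross-loadings are expressed by assigning a feature to several
  components (the assignment table may repeat a feature), which re-derives C;
  a direct C override can only add entries consistent with the assignment
  and can never remove a derived 1, because a removed entry would contradict
  C's definition.
* Discrimination groups are labelled deterministically: within a component,
  groups are ordered by their feature pattern read as a bit string in Q
  column order. Parameter indexing is therefore reproducible across runs and
  machines.
* All matrices are addressed by person/item/feature labels at the API
  boundary; responses are matched to the Q matrix by column name, not
  position.

## Priors and estimation

Default priors: $\theta_{im} \sim N(0,1)$, $\eta_{mk} \sim N(0,1)$,
$\alpha_{jm} \sim N(0,1)$ truncated to $[0,\infty)$, and
$c_j \sim \mathrm{Beta}(3,20)$ (mean 0.13, mass below 0.3 — plausible
guessing for items with working distractors). All four are configurable.
Ability components are a priori independent; no further identification
constraint is needed because the $\theta$ scale is fixed by its prior.
Guessing is parameterized directly on $(0,1)$; no logit transform.

Estimation is by Markov chain Monte Carlo, implemented in C++ as an adaptive
Metropolis-within-Gibbs sampler with three kinds of moves per sweep:

1. **Scalar random-walk updates** of every ability $\theta_{im}$, feature
   difficulty $\eta_{mk}$, discrimination $\alpha_g$ (proposals below 0 are
   rejected against the truncated prior), and guessing value $c_j$
   (proposals outside $(0,1)$ rejected). Proposal scales adapt during warmup
   by Robbins–Monro recursion toward a 0.44 acceptance rate.
2. **A joint adaptive-Metropolis update** of the full structural block
   (all $\eta$, $\alpha$, $c$ together), using the empirical covariance of
   the block accumulated during warmup (Haario-style), scaled adaptively
   toward 0.234 acceptance. This move is what walks the correlated ridges —
   difficulty against slope against guessing — that scalar moves cross only
   by diffusion; without it the structural block mixes an order of magnitude
   more slowly.
3. **Thinning**: `iter` counts kept draws and `thin` sweeps are run per
   kept draw, so long runs needed by slow directions do not inflate memory.

The likelihood is accumulated through per-cell caches of the component
log-probabilities, so a scalar update touches only the cells it can change.
All tail computations stay in log space (`log(1-p)` via `expm1`), so
abilities beyond $\pm 700$ neither overflow nor produce `NaN`. Missing
responses are treated as ignorable and drop out of the likelihood. A single
integer seed determines chain sub-seeds, initial values, and every proposal,
so runs are exactly reproducible.

Because the sampler is a Metropolis scheme, the divergent-transition
diagnostic of Hamiltonian samplers does not exist here; the divergence count
in reports is identically zero and is retained only for workflow
compatibility. Convergence is judged on split R-hat (threshold 1.01 by
default) and effective sample size (via `coda`), computed for every
parameter including the abilities.

## Model checking

* **Prior predictive checks** simulate whole datasets from the priors and
  summarize item marginal success proportions — a coherence check that the
  priors do not force degenerate response patterns.
* **Posterior predictive checks** simulate one replicate per posterior draw,
  using that draw's abilities and item parameters (full uncertainty
  propagation, not EAP plug-in), with the observed missingness pattern. Each
  item's observed proportion is compared with the central 2.5–97.5% interval
  of the replicated proportions. The **discordance rate** is the fraction of
  items strictly outside their interval; the **interval bias** is defined
  here as the mean exceedance beyond the interval (zero for items inside).
  The literature reports "bias" for such tables without a formula; the
  exceedance definition is explicit, well-defined, and preserves the
  orderings such tables are used for.
* **SRMR** for binary data is defined over the $J$ item marginal proportions
  plus the $J(J-1)/2$ inter-item product-moment correlations (the
  residual-correlation convention common in item response modelling; the
  exact residual set behind published SRMR values for such models is
  generally unstated). Observed statistics are compared with their
  posterior-predictive means as one pooled root mean square. Items with zero
  observed variance are excluded from the correlation set with a warning.
* **WAIC** uses the single person–item response as the pointwise unit:
  $\mathrm{lppd} = \sum \log \mathrm{mean}_s e^{\ell_s}$,
  $p_\mathrm{waic} = \sum \mathrm{var}_s(\ell_s)$,
  $\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{waic})$; lower is better.
  Model comparison tables are ranked by WAIC with ties broken by model name.

## The synthetic-data generator

`study_fixture()` emulates the motivating study: a 27-item figural-analogies
test built from five composition rules (principal figure rotation, trapezium
rotation, whole-figure reflection, line subtraction, point movement), with
rules 1–3 forming a global component and rules 4–5 a local one. The true
parameters are the published GMLTM-D posterior-mean estimates (a single
canonical, citable parameter set, rather than draws), abilities are standard
normal, and the default sample size is the study's 383 examinees. The
generator reproduces the model's own assumptions — independent persons,
independent components a priori, no local item dependence, no speededness,
no response styles — so passing recovery tests demonstrates correctness of
the implementation, not robustness to the violations real data bring.

`recovery_study()` is the validation harness: simulate, refit, and measure
bias, RMSE, 95% interval coverage, and EAP–truth correlation per parameter
block, with one master seed spawning an independent sub-seed per
replication.

## Problem sizes and numerical choices

The package's own validation runs at desk scale, chosen so the full suite
reproduces the science without heroic compute: recovery uses $N = 500$
persons and a single replication with 2 chains, 1200 warmup sweeps and 2500
kept draws at thinning 8; model-comparison ordering uses the study's
$N = 383$ with 5 seeded replications and shortened chains (2 × 400/400),
which is ample for WAIC separations of the size the generating model
produces. Full-length runs are one `sampler_config()` away. Other defaults:
4 chains × 1000/1000 for interactive fits, 1000 posterior predictive
replicates, quadrature via `stats::integrate` when tests need analytic
marginals.

Degenerate inputs are rejected early (all-zero Q rows/columns, non-binary
entries, duplicate labels, negative slopes, guessing outside $[0,1)$), and
ties in comparison tables break by name so output is deterministic.

## Known limitations

* Ability recovery is bounded by the test's information, not by the
  estimator. On the fixture design the local component is weakly determined:
  only 17 of the 27 items carry local features, their local difficulties
  cluster at two values, and the noncompensatory product censors local
  information whenever the global component fails. The acceptance suite
  makes this explicit by comparing the fitted EAP abilities against the
  exact-posterior EAP computed by quadrature under the true generating
  parameters: the fit attains that ceiling, and the ceiling itself sits well
  below the global component's.
* The sampler is random-walk based; for much larger tests (hundreds of
  items) a gradient-based sampler would scale better.
* Interval bias and SRMR follow the explicit definitions above; published
  values computed under other conventions need not match numerically, though
  orderings across nested models are preserved in simulation.
* Polytomous responses, compensatory multidimensional IRT, and hierarchical
  attribute structures beyond the component level are out of scope.
* The rebuilt-from-disk fit (`read_draws()`) restores all posterior draws
  but not sampler adaptation state; it supports summaries and checks, not
  chain continuation.
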