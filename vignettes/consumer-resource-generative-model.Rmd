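---
title: "A consumer/resource latent-variable generative model for host-associated microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A consumer/resource latent-variable generative model for host-associated microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crlatent)
```

## The model

Consumer/resource ecology describes a community of $O$ species feeding
on $K$ resources:

$$\frac{1}{n_o}\frac{dn_o}{dt} = \sum_k r_k(t)\,\theta_{ko} - \delta_o,
\qquad
\frac{dr_k}{dt} = J_k(t) - r_k(t)\sum_o n_o(t)\,\theta_{ko}\gamma_{ko},$$

with preferences $\theta_{ko}$, consumption efficiencies $\gamma_{ko}$,
death/dilution rates $\delta_o$ and resource inflows $J_k$. Formally
integrating the growth equation shows that log abundances are *linear*
in the time-integrated resource abundances
$z_k = -\int_0^t r_k\,d\tau$. The death term folds into one extra
latent dimension ($z_{K+1} = t$, $\theta_{K+1,o} = \delta_o$), which is
why fits to simulated C/R snapshots in this package use one dimension
more than the number of raw resources. The observable consequence is a
log-linear, low-rank model of compositions:

$$q_{so} = \frac{1}{\Omega_s}\exp\Big(-\sum_{k=1}^{K} z_{sk}\theta_{ko}\Big),$$

where the $z_{sk}$ are sample-specific latent variables and the
preference matrix $\Theta$ is assumed universal across hosts of the
same system. The latent variables are *effective* resources: aggregated
positive and negative influences integrated over time, not identifiable
nutrients. For that reason $\theta$ is fitted unconstrained, even
though the raw C/R equations assume $\theta_{ko} \ge 0$.

Host phenotypes enter through a linear head on the same coordinates,
$m_{sp} \approx \sum_k z_{sk} L_{kp}$ (identity link), with phenotypes
z-scored per column over their observed entries and missing entries
masked out of the loss and all gradients.

### Identifiability

Only the product $Z\Theta$ (and hence the compositions) is identified:
any invertible $A$ gives $(ZA)(A^{-1}\Theta) = Z\Theta$. Every
comparison in the package and its tests is therefore made on
compositions, reconstruction divergences, or the singular spectrum of
$Z\Theta$ — never on raw factor entries.

## Fitting

The objective is $C = \alpha\,C_e + (1-\alpha)\,C_m$, where
$C_e = \sum_{s,o} x_{so}\log(x_{so}/q_{so})$ is the KL divergence of
the measured compositions from the model (with $0\log 0 := 0$) and
$C_m$ the masked squared phenotype error. $\alpha$ always weights the
microbiome term: $\alpha = 1$ is the microbiome-only fit, and values
like $0.975$ keep the joint fit dominated by the composition term while
still shaping the latent space with phenotypes. Optimization is plain
constant-step gradient descent with the analytic gradients

$$\partial C_e/\partial z_{sk} = \sum_o (x_{so} - q_{so})\,\theta_{ko},
\qquad
\partial C_e/\partial \theta_{ko} = \sum_s (x_{so} - q_{so})\,z_{sk},$$

and the corresponding $-2\,(\text{residual})\cdot(\text{factor})$ terms
for the phenotype head. Descent stops when
$\sum_{\text{matrices}} \lVert\nabla\rVert_2 / \lVert\text{matrix}\rVert_2 < 10^{-2}$
(configurable) or at the iteration cap.

Parameters that matter, with defaults:

- `K` — latent dimension; chosen by `dimension_scan()` in practice.
- `alpha` — microbiome weight in $[0,1]$, default 1.
- `eta` — step size, default $10^{-3}$ (dimensionless; the losses are
  sums over samples, so larger cohorts need smaller steps, down to
  $10^{-5}$). A diverging loss aborts with advice to reduce it; a
  transient increase is recorded as a flag, since constant steps can
  overshoot.
- `grad_tol` — relative-gradient stopping threshold, default $10^{-2}$.
- `init_scale` — SD of the seeded Gaussian initialization of $Z$,
  $\Theta$, $L$, default 0.1: small enough that the initial composition
  is near-uniform and the first steps are stable.
- Rare-taxon aggregation (`aggregate_rare_taxa()`) pools taxa with mean
  relative abundance below 0.1% into one `OTHER` taxon, the
  conventional threshold below which abundance variation is dominated
  by technical noise.

`embed_samples()` re-optimizes only $Z$ for new samples under a fixed
$\Theta$ — the operation behind transfer tests, paired with
`scramble_preferences()` (a seeded column permutation) as the null.

## The generative layer

`fit_latent_gmm()` models the fitted latent coordinates with a full
covariance Gaussian mixture, fit by EM from seeded random restarts for
1–5 components, selecting the lowest BIC ($-2\ell + \mathrm{df}\log S$;
ties go to fewer components). EM restarts matter because the likelihood
is multimodal; the default of 100 restarts follows common practice for
this model class, and the covariance eigenvalues are floored at
$10^{-6}$ so degenerate components cannot collapse. Sampling the
mixture and composing abundances (optionally with multinomial read
noise at a chosen depth) yields in-silico cohorts; with a phenotype
head, generated phenotypes are $ZL$ mapped back to original units, by
default noiseless (an optional Gaussian residual is available but off,
since the magnitude of real observation noise is dataset-specific).

### Community design

Targets on (z-scored) phenotypes bias the latent density:

$$\log p(z) = \log p_0(z) - \sum_t \gamma\,\big(\hat m_t(z) - m^*_t\big)^2 .$$

`sample_biased()` runs independent Metropolis random-walk chains (100
by default, each started from a fresh $p_0$ draw; isotropic Gaussian
proposals with scale defaulting to a quarter of the mean component SD;
5,000 steps, 1,000 burn-in, thinning 10). $\gamma = 0$ recovers
unbiased sampling exactly; $\gamma = 2$ gives a strong pull without
degenerating the sampler. Chain order is preserved in the pooled
output, so chain-level standard errors are available.

`predict_from_partial_phenotypes()` instead filters unbiased draws to
those whose predicted phenotypes fall within 0.2 SD of all constrained
values and averages the surviving compositions — the natural
conditional-expectation estimate when only part of a host's phenotype
profile is known. `phenotype_constraint_profile()` quantifies how much
a single phenotype constrains the community (within-bin Bray-Curtis
normalized by unconstrained pairs; 10 quantile bins and 1,000 pairs per
bin by default), and `local_correlations()` contrasts taxon-phenotype
correlations inside Bray-Curtis neighborhoods of individual hosts (500
neighbors by default) with the global correlation, exposing
context-dependent associations that global analysis averages away.

## What the synthetic generators emulate

`model_based_cohort()` draws data exactly from the model class:
mixture-Gaussian latent variables, Gaussian preferences and loadings,
optional multinomial counts and phenotype noise. It is the right tool
for recovery tests because the truth is known, but passing them shows
only that the machinery works *when the model is correct*.

`simulate_cr()` integrates the raw C/R equations (via `deSolve`'s
adaptive lsoda, relative tolerance $10^{-8}$), and `snapshot_cohort()`
builds cross-sectional cohorts of hosts sharing $\Theta$ but differing
in resource inflows (log-normal host-to-host variation, the canonical
way environments differ). Because the integrated dynamics are exactly
log-linear in the latent integrals, a snapshot cohort is representable
by the latent model with $K_{\text{cr}} + 1$ dimensions — these data
test the derivation, not just the optimizer.

Neither generator emulates compositional zeros from detection limits,
taxonomic misassignment, cross-host preference variation, or
longitudinal autocorrelation; agreement on synthetic data therefore
bounds, but does not guarantee, performance on real surveys.

## Numerical choices

- Softmax composition uses a per-row maximum shift; entries can
  underflow to exactly 0 only beyond $\sim$700 nats of dynamic range.
- $0\log 0 := 0$ throughout; predicted compositions are strictly
  positive by construction, so no pseudo-counts enter the loss.
- In `kl_and_jsd()`, a support violation in the *forward* KL is an
  error naming the offending index; a violation only in the reverse
  direction makes the symmetric KL `Inf` while forward KL and the
  (always finite) Jensen-Shannon distance are still returned. Natural
  logs everywhere except the log10 axes of the SAD power-law fit.
- `dimension_scan()` runs fits in ascending `K`, warm-starting each
  from the previous solution padded with small random dimensions. With
  independent cold starts, a larger model stopped at a fixed relative
  gradient can end at a *slightly* worse loss than a smaller one; warm
  starts make the scan monotone up to optimization tolerance while also
  being cheaper. Cold starts remain available (`warm_start = FALSE`).
- The stopping ratio treats a zero-norm parameter matrix as
  contributing zero (with a warning) rather than dividing by zero.
- BIC ties break toward fewer components; EM restarts that collapse a
  component are discarded rather than regularized into existence.
- All stochastic operations take explicit seeds; scrambles, multinomial
  draws, restarts and chains derive deterministic substreams from them.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run at desk scale, chosen
so each check is decisive for its property while the whole suite stays
quick: recovery and transfer tests use cohorts of 40–60 samples and
15–25 taxa at $K = 2$–4; mixture-selection tests use 300–1,000 latent
points; MCMC checks pool 100 chains of 2,000 steps in a $K = 1$ world
with a closed-form posterior; design analyses use generated cohorts of
3,000–6,000 samples. These sizes are the package's own validation
choices, not limits of the methods.

## Known limitations

- The latent model is cross-sectional; temporal structure within hosts
  is integrated out by construction.
- The phenotype head is linear; strongly nonlinear phenotype-latent
  relationships will be underfit (by design — the model is meant to be
  interpretable and sampleable).
- Biased sampling explores the fitted density; it proposes *plausible*
  communities compatible with a target state and makes no causal claim
  that imposing the community would produce the state.
- Constant-step descent is deliberately simple; very ill-conditioned
  tables may need smaller `eta` and more iterations rather than a line
  search, to keep runs exactly reproducible.
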