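---
title: "Methods: spatio-temporal smoothing of survey prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal smoothing of survey prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgpr)
```

## The problem

Household-survey programmes measure child- and maternal-health indicators —
vaccination coverage, breastfeeding, bed-net use, water and sanitation —
with cluster samples that are powered for national or provincial precision.
Health planning, however, happens in smaller administrative units, and a
region may be visited by one survey in one year and skipped entirely by the
next. Raw design-weighted estimates at the region level are therefore noisy
where samples are small and missing where surveys did not go. `stgpr`
produces a complete annual region-level surface with honest uncertainty by
pooling all surveys through a spatio-temporal model.

## Model

For observation $i$ (one survey's design-weighted estimate) in region $k$
and year $t$,

$$\mathrm{logit}(Q_{ikt}) = \alpha + S_{kt} + Z_{ikt},$$

where $S$ is a mean-zero Gaussian field over the $K \times T$ region-year
lattice with separable covariance
$\Sigma = \sigma^2 (R_S \otimes R_T)$, and
$Z_{ikt} \sim N(0, \tau^2 / \log n^{\mathrm{eff}}_{ikt})$ is independent
survey noise. The model assumes: (i) one common intercept, no covariates;
(ii) spatial dependence that follows the adjacency graph, not distance;
(iii) stationary temporal dependence; and (iv) observation noise that is a
function of effective sample size only, so surveys differ only through how
much data they contribute, not through systematic instrument biases (the
recall-window filter is what aligns instruments before modelling).

**Spatial factor.** $R_S$ comes from a *proper* CAR model: precision
$D - \rho_s W$ with $W$ the 0/1 adjacency and $D$ the diagonal of neighbour
counts, inverted and rescaled to unit diagonal. A proper CAR was chosen
over the intrinsic variant because the separable covariance needs $R_S$ to
be a genuine correlation matrix, and the intrinsic CAR precision is
singular, so no such matrix exists. The rescaling costs the closed
spectral form of the precision but keeps $K \times K$ operations, which is
all the sampler needs. The graph must be connected: across disconnected
components the rescaled inverse is block-diagonal and $\rho_s$ loses its
meaning, so a disconnected graph is an error rather than a warning.

**Temporal factor.** $R_T(t, t') = \phi^{|t-t'|}$, the AR(1) correlation.
The year axis is the full consecutive analysis window; years without
surveys remain in the lattice and are predicted, not skipped.

**Noise.** The variance $\tau^2 / \log n_{\mathrm{eff}}$ makes precision
grow with the logarithm of the effective sample size: a census with tens of
thousands of respondents anchors its cell, a 30-respondent survey cell is
heavily shrunk toward the field. The *effective* (Kish) size
$(\sum w)^2 / \sum w^2$ is used rather than the raw count because design
weights inflate sampling variance; this is also why no separate
design-based variance estimator is carried — the design enters the model
solely through $n_{\mathrm{eff}}$. The guard $n_{\mathrm{eff}} > 1$ keeps
the log positive.

**Empirical logit.** Observations are the logits of weighted proportions.
At $q \in \{0, 1\}$ the logit diverges, so a continuity correction
$q^* = (q\,n_{\mathrm{eff}} + 0.5)/(n_{\mathrm{eff}} + 1)$ — half a
pseudo-respondent on the effective-sample-size scale — keeps it finite with
minimal shrinkage toward 0.5; such rows carry a `v_floor` flag for audit.

## Priors

The source analyses of this model family do not pin priors down, so the
package's defaults are weakly informative on the logit scale and
user-configurable through `stgpr_priors()`:
$\alpha \sim N(0, 10^2)$; half-Normal$(0, 5^2)$ on the standard deviations
$\sigma$ and $\tau$ (flat near zero, heavy enough not to truncate realistic
logit-scale variation); $\rho_s \sim U(0,1)$ and $\phi \sim U(-1,1)$. On
the logit scale a standard deviation of 5 already spans essentially the
whole (0,1) probability range, so these priors are vague for any real
indicator.

## Sampler

`stgpr()` runs Metropolis-within-Gibbs with the following blocks per
iteration:

1. **Latent field, jointly.** Given hyperparameters, the field's full
   conditional is Gaussian with precision
   $\sigma^{-2}(R_S^{-1} \otimes R_T^{-1}) + \mathrm{diag}(d)$, where
   $d_{kt} = \sum_{i \in kt} \log(n^{\mathrm{eff}}_i)/\tau^2$. The
   conditional precision is formed densely and solved by Cholesky — exact,
   and cheap at the lattice sizes the package targets (the factor inverses
   are $K \times K$ and $T \times T$; the dense solve is
   $KT \times KT$). A single-site Gibbs scan was rejected: with
   $\rho_s, \phi$ near 1 it mixes far too slowly.
2. **Intercept.** Conjugate Gibbs (Gaussian prior, Gaussian likelihood).
3. **$\sigma^2$, $\rho_s$, $\phi$, $\tau^2$.** Random-walk Metropolis on
   $\log \sigma^2$, $\mathrm{logit}\,\rho_s$, $\mathrm{atanh}\,\phi$,
   $\log \tau^2$, each with its transform Jacobian. The field-prior density
   these steps need is evaluated through the two factor matrices
   (log-determinants and a $T \times K$ quadratic form), never through the
   dense $KT \times KT$ covariance.

Proposal scales adapt only during burn-in (log-scale Robbins–Monro step
$\min(0.05, t^{-1/2})(a - 0.44)$ toward 0.44 acceptance) and are frozen
afterwards, so the retained chain satisfies detailed balance. Post-burn-in
acceptance outside $[0.05, 0.8]$ triggers a warning. A failure of the
conditional Cholesky aborts with the iteration number — it indicates an
inconsistent dataset rather than something to paper over.

The default configuration (110 000 iterations, 10 000 burn-in, thinning 10)
retains exactly 10 000 draws; `stgpr_control()` enforces that
$(n_{\mathrm{iter}} - n_{\mathrm{burn}})/\mathrm{thin}$ is a positive
integer rather than silently truncating.

All draws of $\mathrm{logit}^{-1}(\alpha + S_{kt})$ form the posterior
surface; cells with no observations get their predictive distribution from
the field, which is exactly the interpolation the model exists for.

## Degenerate and edge cases

* A single-region graph (no edges) is allowed and gets the trivial
  $1\times 1$ CAR correlation. This exists to support the conjugate
  single-cell check of the sampler; multi-region graphs must be connected.
* An empty dataset is valid and yields the prior predictive.
* Multiple surveys in one (region, year) cell enter as separate likelihood
  terms sharing one $S_{kt}$ — this is how same-year surveys are combined.
* The hold-out split uses `round(fraction * N)` under R's round-half-even
  rule; with constant predictions or fewer than two held-out points the
  correlation is reported as `NA` with a warning while MAE and RMSE are
  still returned, because a hard error would discard metrics that remain
  well defined.
* Octile classes use fixed 12.5-point bins of the 0–100 scale with
  half-open boundaries assigned upward (87.5 is class 8), not empirical
  quantiles; non-percentage factors are min–max rescaled across regions
  first. A constant factor rescales to a single lowest class rather than
  dividing by zero.
* Change reports recompute changes from the anchor-year endpoints;
  interval summaries are draw-wise 2.5/97.5 percentiles of per-draw
  changes. The absolute change of the draw means equals the mean absolute
  change (linearity); the percentage change does not, so the draw-mean
  version is reported in a separate column.

## Synthetic data: what it does and does not emulate

The generator reproduces the *statistical structure* the pipeline assumes:
a connected planar-like region graph (random geometric graph plus minimum
spanning tree); a latent field drawn exactly from
$\sigma^2(R_S \otimes R_T)$ via the factor Cholesky roots; surveys of two
families with different recall windows plus censuses; partial region
coverage per survey; cluster-level log-normal design weights with
configurable dispersion (dispersion zero makes Kish $n_{\mathrm{eff}}$
collapse to $n$); and binary outcomes drawn from the true surface. Event
years include one lag beyond each family's recall window so the
harmonisation filter has real work to do.

`study_scale_plan()` mirrors a two-decade archive: 47 regions, 22 years,
twenty surveys (seven DHS-like, eleven MICS-like) plus two census-like
enumerations, per-region samples of 20–2000. The routine test fixture,
`reference_scenario()`, is deliberately smaller — 12 regions, 10 years,
seven surveys, samples of 30–800, truth
$\alpha=-0.5,\ \sigma^2=1,\ \rho_s=0.9,\ \phi=0.8,\ \tau^2=1.5$ — so that
full MCMC experiments stay fast; roughly an eighth of its cells end up
with no observations.

Two things the generator does *not* emulate, and what that means for the
tests. First, real microdata noise is binomial, while the model's noise
term is Gaussian with variance $\tau^2/\log n_{\mathrm{eff}}$; on
microdata-based scenarios the fitted $\tau^2$ therefore converges to
whatever value makes the two match on average (about 0.5 in the reference
scenario) rather than to the generator's nominal $\tau^2$. Recovery checks
consequently target $\alpha$, $\sigma^2$ and $\phi$; calibration
experiments instead use `simulate_observations()`, which draws from the
observation model itself. Second, no attempt is made to mimic real county
geography, population sizes or actual indicator levels, so passing tests
demonstrate correctness of the machinery under the model's assumptions,
not the real-world accuracy of any particular indicator estimate.

## Validation experiments and the problem sizes used

The package's own evaluation, in `tests/testthat/test-acceptance.R` and
reproducible via `scripts/acceptance.R`, uses these scales:

* **Prior oracle.** 50 random cases with $K, T \le 8$: the factor-spectral
  field prior agrees with a dense multivariate-normal evaluation to
  $10^{-8}$ (observed discrepancies are at machine precision).
* **Conjugate check.** One region, one year, one observation,
  hyperparameters fixed: the sampler's mean and SD of $\alpha + S$ match
  the closed-form normal posterior within three batch-means Monte-Carlo
  standard errors at 10 000 retained draws.
* **Recovery.** The reference scenario fitted with a 21 000/1 000/2 chain
  (again 10 000 retained draws): posterior means of $\alpha$, $\sigma^2$,
  $\phi$ fall within three posterior SDs of truth, and the posterior-mean
  surface beats the raw design-weighted estimates in RMSE against the true
  surface for each of five scenario seeds.
* **Calibration.** 100 replicates at $K = T = 6$ with observations from
  the observation model itself, each fitted with a 5 000/1 000/4 chain:
  95% intervals cover the true prevalence within $95 \pm 5$ percentage
  points (observed around 92–94%; the small shortfall is the price of the
  deliberately short chains).
* **Hold-out.** A 10% random hold-out of reference-scenario observations:
  held-out correlation well above 0.6.

These sizes were chosen as the smallest at which each property is
convincingly demonstrated; all of them, and the experiment seeds, are
fixed in code.

## Limitations

* No covariates, by design: the model interpolates, it does not explain.
* The dense conditional field update is cubic in $KT$; lattices beyond a
  few thousand cells would need a sparse or spectral sampler variant.
* Hyperparameter chains (especially $\sigma^2$ and $\alpha$, which compete
  with the field's overall level and scale) mix more slowly than the field
  itself; short chains shave interval coverage slightly, as the
  calibration experiment shows.
* The hold-out is a single unstratified random split, matching the
  validation design it mirrors; k-fold machinery is deliberately out of
  scope.
* Orientation of the octile colour convention (whether high values are
  favourable) is indicator knowledge the user must supply; the package
  defaults to favourable-high.
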