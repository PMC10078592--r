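---
title: "Point process models for spatial capture-recapture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point process models for spatial capture-recapture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppscr)
```

## The model

Spatial capture-recapture (SCR) estimates the abundance and density of a
wildlife population from spatially referenced detections of identified
individuals — here, the setting of area searches for non-invasive genetic
samples (scat, hair), where a detection can occur anywhere in the searched
region rather than at fixed traps. `ppscr` expresses both levels of the
standard SCR hierarchy as spatial point processes in continuous space.

**Activity centers.** Each individual carries a latent activity center (AC)
$s_i$ summarizing its home-range location. The population of ACs over the
habitat region $\tilde o$ follows an inhomogeneous Poisson point process
with intensity $\tilde\lambda(s \mid \beta)$ (ACs per km$^2$). The habitat
is tiled by $H$ non-overlapping rectangular windows on which covariates —
and hence the intensity — are constant, with the log-linear model
$\log \tilde\lambda_h = \beta_0 + \sum_j \beta_j \xi_{jh}$. The expected
population size is $\tilde\Lambda = \sum_h \tilde\lambda_h a_h$ with $a_h$
the window area. The log-density of a configuration of $N$ ACs is
$-\tilde\Lambda + \sum_i \log\tilde\lambda(s_i)$, stored without the
constant $-\log N!$ (every MCMC use is invariant to it). Conditioning the
Poisson process on one point gives the Bernoulli point process
$P(s_i) = \tilde\lambda(s_i)/\tilde\Lambda$, the AC prior for a single
individual; because the intensity is piecewise constant, this density
normalizes exactly and evaluating it is a window lookup, so the per-window
intensities are computed once per parameter update no matter how many
individuals are in the model. A categorical baseline
(`log_categorical_ac`, and `ac_model = "categorical"` in the sampler), in
which the AC lives on a habitat cell approximated by its centroid, is
provided for comparison; its Gibbs update iterates over all $H$ cells per
individual per iteration, which is the cost the point process formulation
avoids.

**Detections.** Given its AC, the detections of individual $i$ over the
searched region $o$ follow a Poisson point process with intensity
$\lambda(y \mid s_i) = b(y)\,\tau(y \mid s_i, \sigma)$: a baseline
intensity $b$, piecewise constant on $L$ detection windows with
$\log b_l = \theta_0 + \sum_j \theta_j \zeta_{jl}$, times an isotropic
Gaussian distance-decay kernel
$\tau(y \mid s, \sigma) = \exp(-\lVert y - s\rVert^2 / 2\sigma^2)$.
The kernel is deliberately *unnormalized* ($\tau = 1$ at the AC), the SCR
half-normal convention: $e^{\theta_0}$ is then the detection intensity at
zero distance, in detections per km$^2$. The normalized-Gaussian
alternative differs only by the factor $2\pi\sigma^2$ absorbed into
$\theta_0$; anyone comparing $\theta_0$ values across implementations
should check which convention is in use. The expected detection count is
$\Lambda(o \mid s) = \sum_l b_l \int_{w_l} \tau$, with the rectangle
integrals available in closed form through the normal CDF, and the
log-density of the $M_i$ observed locations is
$-\Lambda(o \mid s_i) + \sum_j \log\lambda(y_{ij} \mid s_i)$. Setting
$M_i = 0$ gives the conditional void probability
$\exp(-\Lambda(o \mid s_i))$. Variants: a single-detection
(normalized Bernoulli) model for samplings where at most one detection per
individual is possible, its independent-occasion (binomial point process)
product, and a discrete-detector Poisson model treating each detection
cell's center as a point detector.

ACs may lie in the buffer $\tilde o \setminus o$ outside the searched
area; their detection intensity integrates over the detection windows
only, so the model accounts for individuals whose home ranges straddle
the survey boundary.

## Fitting

Two strategies are implemented, both as adaptive Metropolis-within-Gibbs
samplers with identical likelihood kernels.

**Semi-complete data likelihood (SCDL).** The ACs of the $N - n$ never
detected individuals are integrated out through the marginal void
probability
$p^* = \tilde\Lambda^{-1}\int_{\tilde o} \tilde\lambda(s)
\exp(-\Lambda(o \mid s))\,ds$,
yielding the likelihood
$\binom{N}{n} (p^*)^{N-n} \prod_i P(s_i) P(y_i \mid s_i)$.
Since the AC intensity is window-constant, $p^*$ reduces to one definite
integral per window, evaluated by the midpoint rule on a regular
$\sqrt K \times \sqrt K$ sub-lattice per habitat window (weights sum
exactly to the window area). Nodes are placed per window; a total-budget
mode is available behind `void_config(mode = "total")`. $p^*$ is common to
all individuals (no individual heterogeneity) and is recomputed only when
$(\theta, \sigma)$ change — once per iteration at most, which the sampler
records (`meta$p_star_evals`).

The prior on $N$ is pluggable. The default is
$N \sim \text{Poisson}(\tilde\Lambda(\beta))$ — the prior the Poisson
point process itself induces — under which $\beta_0$ is identifiable and
the number of undetected individuals has the conjugate full conditional
$u \sim \text{Poisson}(\tilde\Lambda p^*)$, drawn by Gibbs. The
alternative flat prior on $N$ uses an adaptive integer random walk on $u$;
under it $\beta_0$ cancels from the posterior (as under data augmentation)
and simply follows its prior. The flat prior is exactly the marginal prior
that data augmentation with $\psi \sim U(0,1)$ induces on $N$, which makes
it the right choice when comparing the two fitting strategies on shared
data; the comparison tests do this.

**Data augmentation (DA).** The population is embedded in $M =
\lceil \text{factor} \times n \rceil$ individuals (factor 2-5 in
practice, default 3) with inclusion indicators $z_i$, inclusion
probability $\psi \sim \text{Beta}(1,1)$, and ACs for all $M$
individuals. $\psi$ and $z$ have Gibbs updates; $N = \sum z_i$. Under DA
the density intercept $\beta_0$ is not estimable and is held fixed
(default 0); density is recovered post hoc from $N$ and the normalized
intensity surface.

**Samplers and adaptation.** Each AC is updated by a joint $(x, y)$
block random walk with a per-individual proposal scale; regression
coefficients update in blocks ($\beta$; $\theta$ together with $\sigma$).
All scales adapt by Robbins-Monro towards 0.234 acceptance during burn-in
and are frozen afterwards, so the post-burn-in chain is a fixed Markov
kernel. Proposals falling outside the habitat get a $-\infty$ target and
are rejected, which handles irregular or buffered regions without any
ones/zeros device. Runs are bit-reproducible given configuration and seed.

**Priors (defaults, all overridable).** The model priors are not dictated
by the likelihood and default to weakly informative choices: Normal(0,
$10^2$) on every $\beta$ and $\theta$ component, Uniform(0, $U_\sigma$) on
$\sigma$ with $U_\sigma$ defaulting to half the shorter side of the
detection extent, Beta(1, 1) on $\psi$.

**Initial values.** The default strategy is data-driven: observed ACs
start at their detection centroids, $\sigma$ at the root-mean-square
within-individual detection spread (falling back to half a detection
window side when every individual has a single detection), and the
intercepts at method-of-moments values from the observed counts; a
`"prior_mean"` strategy (all coefficients 0, $\sigma = U_\sigma/2$) is
available. The data-driven start was adopted because a prior-mean
$\sigma$ can sit orders of magnitude from the posterior and waste most of
a short adaptation window; with the long runs typical in production the
two strategies agree.

## Numerical choices

* Window membership is half-open, $[{\rm lower}, {\rm upper})$, with the
  global upper boundary absorbed by the last window of each row/column: no
  point is counted twice and the closed extent is fully covered.
* The Gaussian window integrals use the closed form
  $2\pi\sigma^2\,[\Phi(\cdot)-\Phi(\cdot)][\Phi(\cdot)-\Phi(\cdot)]$
  (compiled, via `erfc`), verified against adaptive 2-D quadrature to
  $10^{-8}$.
* During MCMC, detection windows whose nearest point is farther than
  $6\sigma$ from the AC are skipped; the neglected kernel mass is below
  $e^{-18} \approx 1.5\times10^{-8}$ relative. Setting
  `trunc_mult = Inf` restores the exact sum, and the exported likelihood
  functions default to exact.
* $p^*$ node counts trade accuracy for speed: on the benchmark
  configurations the midpoint rule is already within $10^{-3}$ of a dense
  reference at 100 nodes per window, and within a few $10^{-4}$ at 9. The
  fitting default is 25; the calibration studies below use 9.
* `log_poisson_pp_acs` omits $-\log N!$; `scdl_log_likelihood` computes
  $\log\binom{N}{n}$ via `lgamma` to avoid overflow.
* Degenerate inputs: out-of-habitat evaluation returns $-\infty$ (strict
  mode raises); zero-area windows integrate to 0 with a warning; constant
  chains report `NA` ESS with a warning.

## The simulator

`simulate_scr()` generates data exactly from the generative model:
Uniform(-1, 1) window covariates drawn under a dedicated sub-seed (so
covariate surfaces and data realizations vary independently), ACs window-
sampled from the intensity surface and placed uniformly within windows,
and detections drawn per (individual, window) as Poisson counts with the
analytic mean, located by rejection sampling against the kernel with the
envelope taken at the window point nearest the AC — the simulator is
continuous, matching the model with no grid approximation. A truth table
(all ACs, observed flags) accompanies every dataset.

Presets reproduce the three study designs used throughout the tests —
`sim1` (model validation: 10 km square habitat, 100 windows, 0.6 km
buffer, 25 detection windows, $\beta_0 = 1$, $\theta_0 = 2$,
$\sigma = 0.2$, slope variants in $\{-1, 0, 1\}$, $N \sim$
Poisson($\tilde\Lambda$) since the design pins only the intensity),
`sim2` (density benchmark: fixed $N = 100$, 2 km buffer, 64 detection
windows, habitat at 1/2/4/6 km resolution), and `sim3` (fitting-strategy
benchmark: $\beta_0 = 1$, $\theta_0 = -1$, $\beta_1 = -1$,
$\theta_1 = 2$, $\sigma = 1$, 144/36/9/4 habitat and 64/4 detection
windows) — plus `wolverine_like`, a synthetic stand-in with the survey
geometry of the wolverine case study (195 detection windows of
20 km, 40 habitat windows of 60 km) and parameters chosen to give a
population of roughly 130-140 females with about half observed and
~3 detections per observed individual — the magnitudes typical of
regional wolverine NGS monitoring. It is labelled "like" because it is
synthetic, sharing only geometry and scale with a real survey: field
covariates (den counts, GPS search effort, snow cover, road distance)
are replaced by generic Uniform(-1, 1) surfaces.

What the simulator does *not* emulate — and what passing recovery tests
therefore do not certify for field data: individual heterogeneity in
detectability, behavioral responses, temporal occasion structure or
movement, non-Gaussian home ranges, identification error in the genetic
samples, and spatially structured (rather than independent-uniform)
covariates.

## Validation scale

The test suite and the acceptance script keep runtimes at desk scale by
choice of problem size, not by weakening the checks: the calibration study
runs 30 replicate datasets of the `sim1` design (populations of ~250-400,
~60-70% observed) with 4,000-iteration single chains (1,000 burn-in, 9
$p^*$ nodes per window), which reproduces unbiasedness of the population
size estimator (mean relative bias well under 5%) at 95% credible-interval
coverage within [0.85, 1]. The SCDL/DA comparison uses 6,000-iteration
chains on a shared `sim3` dataset with matched (flat) priors on $N$.
Production analyses would simply raise these sizes; nothing in the
implementation is tied to them.

## Known limitations

* Rectangular, axis-aligned windows only; no raster ingestion or
  irregular polygons (an irregular habitat can still be emulated by
  near-zero intensity covariates).
* No individual heterogeneity in detection: $p^*$ is population-common;
  heterogeneous models would need a per-individual $p^*$ each iteration.
* Closed population only; the SCDL construction as implemented does not
  extend to open-population SCR, whereas DA does.
* Single Gaussian kernel; other distance-decay shapes would slot into the
  same window-integral interface but are not provided.
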