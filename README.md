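# ppscr — point process models for spatial capture–recapture

`ppscr` estimates the abundance and density of wildlife populations from
spatial capture–recapture (SCR) data collected in continuous space — the
situation of area searches for non-invasive genetic samples (scat or hair
DNA), where an identified individual can be detected anywhere in the
searched region rather than at a fixed trap array. It is aimed at
ecologists and biostatisticians who want a Bayesian SCR fit with spatial
covariates on both density and detectability, without projecting
detections onto an artificial detector grid.

## The model

Both levels of the SCR hierarchy are spatial point processes:

* **Activity centers.** The ACs follow an inhomogeneous Poisson point
  process over the habitat region õ with log-linear intensity
  `log λ̃_h = β₀ + Σ βⱼ ξⱼₕ` on H rectangular habitat windows with
  window-constant covariates; `Λ̃ = Σ λ̃_h a_h` is the expected population
  size. Conditional on existing, one individual's AC has the Bernoulli
  point process density `λ̃(s)/Λ̃`.
* **Detections.** Given an AC `s`, detections follow a Poisson point
  process over the searched region o with intensity
  `λ(y|s) = b(y)·exp(−‖y−s‖²/2σ²)`, a piecewise-constant baseline
  `log b_l = θ₀ + Σ θⱼ ζⱼₗ` on L detection windows times an isotropic
  Gaussian (half-normal) kernel. The expected detection count
  `Λ(o|s)` has a closed form through the normal CDF.

Models are fitted by adaptive MCMC under either **data augmentation**
(latent inclusion indicators; `N = Σ z`) or the **semi-complete data
likelihood** (SCDL), in which the ACs of never-detected individuals are
integrated out through the marginal void probability
`p* = Λ̃⁻¹ ∫ λ̃(s)·exp(−Λ(o|s)) ds`, computed by midpoint-rule quadrature.
A generative simulator, single-detection/binomial and discrete-detector
observation variants, a categorical-AC baseline, ESS/R-hat diagnostics and
CSV/GeoJSON I/O are included. See the vignette
(`vignettes/point-process-scr.Rmd`) for the full method description.

## Worked example

Simulate a benchmark dataset (12×12 km habitat in 36 windows with a 2 km
buffer around an 8×8 km detection region in 64 windows, one habitat and
one detection covariate, N = 100, σ = 1 km) and fit it by SCDL:

```r
library(ppscr)

scenario <- preset("sim3", habitat_res = 2, detection_res = 1, seed = 42)
sim <- simulate_scr(scenario)
sim$detections
#> <scr_detections: 61 individuals, 186 detections (per-individual range 1-10)>

model <- scr_model(sim$habitat, sim$detgrid, sim$detections)
fit <- run_mcmc(model, mcmc_config("scdl", iterations = 6000,
                                   burnin = 1000, chains = 2, seed = 1))
summary(fit)
#>   parameter    mean     sd   q2.5  median   q97.5   ess rhat
#> 1         N 103.500 9.7498 86.000 103.000 125.000 577.5 1.01
#> 2     beta0  -0.407 0.1579 -0.733  -0.410  -0.106 413.0 1.00
#> 3     beta1  -0.370 0.3623 -1.130  -0.365   0.300 276.6 1.00
#> 4    theta0  -1.024 0.1711 -1.395  -1.015  -0.701 105.0 1.01
#> 5    theta1   2.003 0.2146  1.595   1.996   2.477  92.6 1.02
#> 6     sigma   1.006 0.0593  0.899   1.003   1.139 217.4 1.01
#> 7    p_star   0.412 0.0241  0.362   0.412   0.457 234.5 1.01
```

The true population size was 100, of which 61 individuals were detected:
the posterior for `N` is 103.5 (95% CrI 86–125), the kernel scale σ
(true 1 km) is recovered at 1.01 (0.90–1.14), and the detection-covariate
slope (true 2) at 2.00 (1.60–2.48). `p_star` is the posterior of the
marginal void probability — the chance an individual in the population
was never detected (~0.41, consistent with observing 61 of 100).
`beta1` (true −1) is weakly identified from a single 100-AC realization,
and its credible interval is correspondingly wide. Fitting the same data
with `mcmc_config("da", ...)` gives a data-augmentation fit with
comparable `N`.

### Command line

```sh
Rscript inst/cli/ppscr.R simulate --config sim.yaml --seed 3 --out runs/sim
Rscript inst/cli/ppscr.R fit      --config fit.yaml --out runs/fit
Rscript inst/cli/ppscr.R summarize --config sum.yaml --out runs/summary
```

where the YAML configs name the mode, file paths and MCMC settings; every
run writes a `manifest.json` (seed, config hash, package version) that
makes it bit-reproducible.

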