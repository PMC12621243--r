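# rdfgp — nonstationary GP inference of liquid structure from scattering data

`rdfgp` infers the radial distribution function g(r) of a liquid — with
full uncertainty quantification — from a noisy, binned, windowed
structure-factor measurement S(q), for people who analyze X-ray or
neutron total-scattering data or benchmark molecular simulations
against it.

The structure factor and the RDF are Fourier duals under the radial
transform

    S(q) − 1 = 4πρ ∫ (g(r)−1) sinc(qr) r² dr,
    g(r) − 1 = 1/(2π²ρ) ∫ (S(q)−1) sinc(qr) q² dq,   sinc(x) = sin(x)/x,

and a direct discrete transform of detector data produces truncation
ripples and noise amplification. `rdfgp` instead places a
physics-informed Gaussian-process prior on g(r) — mean = sigmoid
excluded volume + Gaussian bonded peaks; covariance = symmetrized Gibbs
kernel whose width function σ(r) vanishes at r → 0 and r → ∞ — maps it
to q-space through the discretized transform, conditions on the data
under Gaussian noise, selects hyperparameters by type-II maximum
likelihood, and propagates the posterior back to r-space exactly
(Gaussians are closed under linear maps). Posterior samples then give
distributions over derived observables: peak locations/heights and
coordination numbers.

## Worked example

Simulate an argon-like measurement (ρ = 0.02125 atoms/Å³, detector
window 0.5–15 Å⁻¹, bins of 0.05 Å⁻¹, noise variance 0.04), fit, and
derive observables:

```r
library(rdfgp)

truth <- synthetic_rdf("argon")                       # ground-truth g(r)
meas  <- corrupt_measurement(rdf_to_sq(truth),
                             delta_q = 0.05, q_min = 0.5, q_max = 15,
                             noise_var = 0.04, seed = 1)

init <- rdf_hyperparams(
  mean   = mean_params(r0 = 2.5, s0 = 10),
  kernel = kernel_params(l = 0.1, max = 5, slope = 8, loc = 3, decay = 0.5),
  noise  = 0.2)
fit <- fit_rdf_gp(meas, init, n_restarts = 2, seed = 1,
                  control = gp_control(r_step = 0.05, maxit = 60))
glance(fit)

rq     <- seq(0, 10, by = 0.01)
post   <- posterior_r(fit, rq)                        # latent g(r) posterior
draws  <- sample_posterior(post, 400, seed = 1)
r0_hat <- fit$hyperparams$mean$r0                     # exclude the core region
peak_statistics(draws, rq, search_min = r0_hat)
coordination_distribution(draws, rq, attr(meas, "density"),
                          search_min = r0_hat)
```

Output from this exact script (seed 1):

```
#> glance(fit):  logLik 45.0   lml_init 35.8   d 291   n_restarts 2
#> <peak_stats> 400 samples used, 0 excluded
#>   quantity  mean    sd
#>   loc1      3.71  0.0565    # first solvation-shell radius (Å)
#>   height1   2.14  0.107     # first-peak height
#>   loc2      6.97  0.105
#>   height2   1.28  0.0476
#> <coordination_result> n = 12.764 +/- 0.714 atoms (400 samples, 0 excluded)
#>   cutoff: first local minimum after first peak
#>   definition: n(r_cut) = 4 pi rho int_0^r_cut g(r) r^2 dr
```

The generator's ground truth for this system has its first peak at
3.70 Å with height 2.19 and a first-shell coordination number of 13.6
at its own first minimum — the posterior recovers the peak to a
fraction of a bin and brackets the shell count, while the direct
truncated transform of the same noisy data has RMSE 0.907 against the
true g(r) versus 0.076 for the GP posterior mean (both over r in
[0, 10] Å). `autoplot(post)` and `plot_fit(fit)` draw the bands;
`tidy(post)` returns the band table.

A thin command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/rdfgp simulate --system argon --seed 1 --out run1
Rscript inst/cli/rdfgp fit --input run1/measurement.tsv --out run1/fit --seed 1
Rscript inst/cli/rdfgp observables --fit-dir run1/fit --out run1/obs
```

Every run writes a `run_summary.json` sufficient to reproduce it
bit-identically.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch against the
installed package: it simulates the argon-like benchmark measurement at
the stated density, window, binning and noise level for the given seed,
fits the nonstationary GP by type-II maximum likelihood, propagates the
posterior to g(r), and computes peak statistics and the
coordination-number distribution, logging each stage's numbers and
writing the results JSON to `--out`.

## Method details

See the methods vignette (`vignettes/rdf-inference.Rmd`) for the model,
its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, numerical choices
(quadrature, jitter, FFT fast path), and known limitations.
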