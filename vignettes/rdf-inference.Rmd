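---
title: "Physics-informed GP inference of liquid structure: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed GP inference of liquid structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfgp)
```

## The problem

X-ray and neutron scattering measure the static structure factor
$S(q)$ of a liquid; the real-space radial distribution function $g(r)$
follows from the spherically symmetric ("radial") Fourier transform

$$ S(q) - 1 = 4\pi\rho \int_0^\infty (g(r)-1)\,\frac{\sin qr}{qr}\,r^2\,dr,
\qquad
g(r) - 1 = \frac{1}{2\pi^2\rho} \int_0^\infty (S(q)-1)\,\frac{\sin qr}{qr}\,q^2\,dq, $$

with $\rho$ the atomic number density. Real detectors bin $q$ in steps
$\Delta q$, cover only a finite window $[q_\min, q_\max]$, and add
counting noise, so the naive discrete transform of measured data is
corrupted by truncation ripples and amplified noise. `rdfgp` treats the
problem as Bayesian regression: a Gaussian process (GP) prior encodes
what every liquid's $g(r)$ must do — vanish inside the excluded volume,
decay to 1 at long range, stay smooth — and conditioning on the noisy
$S(q)$ observations produces a posterior over $g(r)$ with honest
uncertainty, because the transform is linear and Gaussians are closed
under linear maps.

## The prior

All structure is imposed in $r$-space, where it is interpretable, and
mapped to $q$-space by the discretized transform (trapezoid quadrature
of the integral above, implemented as an explicit matrix so covariances
transform by congruence).

**Mean.** A sigmoid excluded-volume onset plus optional Gaussian bonded
peaks:

$$ \mu(r) = \sum_b h_b\,\mathcal N(r \mid r_b, s_b) +
\frac{1}{1 + e^{-s_0 (r - r_0)}}. $$

$r_0$ (Å) is the onset radius, $s_0$ (Å$^{-1}$) its sharpness; each
bonded peak has amplitude $h_b$, center $r_b$ and width $s_b$ —
intramolecular features (an O–H bond at 0.96 Å, the water H–H distance
near 1.6 Å) that survive in $g(r)$ even though they are not
"solvation" structure. Simple liquids use zero peaks.

**Kernel.** A Gibbs (nonstationary squared-exponential) kernel with a
constant squared length scale $l$ (Å$^2$) and a spatially varying width

$$ \sigma(r) = \mathrm{Max}\,\frac{e^{\mathrm{Decay}\cdot\mathrm{Loc}}}
{1 + e^{-\mathrm{Slope}\,(r - \mathrm{Loc})}}\, e^{-r\,\mathrm{Decay}}, $$

so the prior variance vanishes at both boundaries ($r \to 0$ and
$r \to \infty$), pinning the GP to its mean exactly where the physics is
certain, and peaks in the first-shell region where the data must speak.
The kernel is implemented verbatim from its printed form, so $l$
carries units Å$^2$ and the diagonal is $\sigma(r)^2\sqrt{l}$ — the
$\sqrt{l}$ normalization is absorbed into the amplitude interpretation
of Max.

**Symmetrization.** $g$ is only defined for $r \ge 0$, but the GP lives
on the whole line; evenness about $r = 0$ is imposed by
$K_\mathrm{sym}(r, r') = K(r, r') + K(-r, r')$. Two numerical points,
both invisible at the printed-formula level but load-bearing in code:

* the width at negative arguments behaves as
  $e^{(\mathrm{Decay}-\mathrm{Slope})r}$, so the symmetrized kernel is
  bounded only when Slope > Decay — enforced at parameter validation;
* the two-term sum is exactly *even* but only approximately *symmetric*
  under argument exchange (the discrepancy is of order
  $e^{-(\mathrm{Slope}-\mathrm{Decay})r}$, i.e. far below jitter for
  valid parameters); all Gram builders therefore use its transpose
  average, which is exactly symmetric and agrees with the two-term form
  to that same order.

Exponentials are evaluated as single clamped exponents (±700), so no
parameter combination inside the bounds can overflow.

## Likelihood, evidence, optimization

Observations carry homoscedastic Gaussian noise $\omega^2 I$ (the
reactor-source assumption); a per-point `sd` column in the data instead
fixes a heteroscedastic diagonal (never inferred). Hyperparameters
$\theta = [r_0, s_0, l, \mathrm{Max}, \mathrm{Slope}, \mathrm{Loc},
\mathrm{Decay}, \omega]$ (plus $(h_b, r_b, s_b)$ per bonded peak) are
chosen by maximizing the log marginal likelihood via L-BFGS-B in
log-parameter space inside physically motivated box bounds
(`default_bounds()`), with seeded uniform restarts in the log box. The
bounds stand in for the hyperpriors of a full hierarchical scheme, and
gradient probes count as real evaluations: the fit returns the best
point ever evaluated, never worse than the initial value. Cholesky
factorizations start jitter-free and escalate a relative jitter from
1e-10 to 1e-4 before failing with a conditioning error.

Costs are dominated by $K_{qq} = A \bar K A^\mathsf{T}$ per evaluation
($A$ = discretized transform to the $d$ data points, $\bar K$ = kernel
Gram on the internal $r$ grid). Because $l$ is constant and the grid
uniform, $\bar K X$ splits into a difference-kernel convolution and a
sum-kernel convolution, both done by FFT in $O(dn\log n)$; this fast
path is property-tested against the dense product to 1e-7.

### Numerical defaults

| quantity | default | why |
|---|---|---|
| transform grids | $r \in [0, 25]$ Å, $q \in (0, 30]$ Å$^{-1}$, step 0.005 | resolves kernel lengths ≥ 0.05 Å² and bond widths ≥ 0.02 Å; prior decay makes longer tails negligible |
| fit-time $r$ grid | step 0.02 Å (`gp_control()`), 0.05 in tests | the log marginal likelihood is stable to ~1e-3 between steps 0.05 and 0.01 on the argon fixture |
| jitter | 1e-10 → 1e-4 relative, ×10 | zero-jitter attempted first so exact closed forms are reproduced |
| sinc threshold | $|qr| < 10^{-8}$ → series | below double-precision series error |
| restarts / maxit | 10 / 100 | scaled down (2 / 60) in tests and the acceptance script to fit single-CPU budgets |

## Posteriors and the noise flag

`posterior_q()` returns, by default, the predictive distribution of new
*observations* (latent covariance plus $\omega^2$ on the diagonal) —
the band one plots against the noisy data. `noise_free_posterior()`
(equivalently `include_noise = FALSE`) is the latent-function
posterior, whose band at the training points lies strictly inside the
noisy one; it is the version for which the two structural guarantees
hold and are tested: conditioning only ever shrinks the prior
covariance (Schur complement), and pushing the latent $q$-space
posterior through the forward transform reproduces the $r$-space
posterior (Gaussian closure, verified to 1e-6). `posterior_r()` is
always latent: observation noise lives on the detector, not in real
space.

Hyperparameter uncertainty is *not* propagated into the posterior
— the point estimate $\hat\theta$ is plugged in. This is a known
limitation discussed below.

## The synthetic world

The generator (`synthetic_rdf()`) stands in for molecular-dynamics
ground truth. It is a damped-cosine family:
sigmoid excluded volume × (1 + A e^{-(r-r_p)/\xi} cos(2π(r-r_p)/λ))
beyond the first-shell radius $r_p$ (held at its crest value below
$r_p$), plus bonded Gaussians where the pair demands them. It
reproduces the statistical *structure* of liquid data — excluded
volume, a dominant first shell, decaying oscillations, sharp
intramolecular peaks — not literal argon or water curves. Defaults:

* `argon`: $\rho = 0.02125$ atoms/Å³ (the printed argon density),
  $r_0 = 3.0$ Å, $s_0 = 8$ Å$^{-1}$, $r_p = 3.7$ Å, $A = 1.2$,
  $\xi = 2.5$ Å, $\lambda = 3.4$ Å — onset, first-peak position/height
  and oscillation period in the range reported for liquid argon near
  85 K.
* `water-OO`, `water-OH`, `water-HH`: 1 g/cm³ water (0.03343
  molecules/Å³; $\rho$ is the number density of the pair's shell
  species), O–H bond peak at 0.96 Å, H–H intramolecular peak at 1.6 Å.

`corrupt_measurement()` applies the detector model: bin-center
resampling at $\Delta q$, cropping to $[q_\min, q_\max]$, i.i.d.
Gaussian noise (the argon benchmark uses variance 0.04), all seeded.
What the generator does **not** emulate: inelasticity, multiple
scattering, background subtraction residuals, $q$-dependent X-ray form
factors, or correlated noise — so a green recovery test establishes
that the *inversion* machinery works at realistic S/N, not that every
experimental systematic is handled.

## What the recovery benchmark shows — and its honest edge

On the argon-like fixture (window [0.5, 15] Å$^{-1}$, $\Delta q$ =
0.05, noise variance 0.04), the GP posterior mean beats the direct
truncated discrete transform of the same noisy data by an order of
magnitude in RMSE for every seed tested, and its 95% band covers the
ground truth over most of $[0, 10]$ Å. Coverage is, however, sensitive
to the noise realization: type-II maximum likelihood sometimes selects
a sharper excluded-volume onset ($s_0$ at its bound) than the truth's,
and wherever the width function $\sigma(r)$ has already collapsed the
band cannot cover a soft-onset truth, concentrated in the ~0.5 Å
transition region below the first peak. This is the textbook cost of
plugging in $\hat\theta$ instead of integrating over $p(\theta \mid
Y)$ — hyperposterior propagation is deliberately out of scope here, as
in the method this package implements. The evidence itself is
grid-stable (the selection is not a quadrature artifact; checked across
fit grids 0.05/0.02/0.01 Å), so the miscalibration is a property of
the model class at this S/N, and the recovery test reports it honestly
rather than widening its bands.

## Derived observables

Posterior samples (seeded symmetric-eigendecomposition draws) propagate
to:

* **peak statistics** — per-sample first/second peak location and
  height (strict local maxima above `search_min`, default the fitted
  $r_0$, refined by 3-point quadratic interpolation — sub-grid
  precision is required because peak-location spreads are of order
  0.002 Å); marginal means/sds and the 4×4 Pearson correlation matrix,
  with zero-variance marginals reported as correlation 0 plus a
  degeneracy flag;
* **coordination numbers** — $n(r_c) = 4\pi\rho \int_0^{r_c} g r^2 dr$
  by trapezoid quadrature; the cutoff is either fixed or the
  first local minimum after the first peak, per sample (samples without
  one are excluded and counted). The integrand convention and cutoff
  rule are recorded in the result object, since other conventions
  exist.

## Design decisions that were genuinely open

* **Trapezoid quadrature, pairwise form.** The discretization is
  trapezoid on $f \cdot \mathrm{sinc} \cdot x^2$; the printed pairwise
  form telescopes if read with a minus sign, which we take as a
  typographical slip since it also contradicts its own prefactor.
* **Evaluating $\sigma$ at $-r$** for the symmetrization uses the same
  formula; nothing in the source fixes the negative branch, and this
  choice plus the Slope > Decay constraint keeps it bounded.
* **Gibbs prefactor as printed.** $\sqrt{2ll'/(l+l')}$ with constant
  $l$ gives $\sqrt l$; we do not silently normalize it away.
* **Noise flag semantics** (above): the printed posterior covariance is
  latent; the package exposes both latent and predictive, because the
  "noise-free" visualization only makes sense against a noisy default.
* **CLI**: a thin `simulate` / `fit` / `observables` pipeline
  (`run_cli()`, `inst/cli/rdfgp`) with a flat-key JSON config, flags
  overriding, and a `run_summary.json` sufficient to re-run any output
  bit-identically.

## Known limitations

* No hyperparameter-uncertainty propagation (see above) and no MCMC;
  bounds stand in for hyperpriors.
* One partial correlation at a time: the Faber–Ziman composition of
  partials into a total is generator-side only; joint inversion of
  underdetermined multi-component totals is not attempted.
* Constant (neutron-like) Faber–Ziman weights; no $q$-dependent X-ray
  form factors.
* Homoscedastic noise by default; the heteroscedastic hook accepts a
  fixed diagonal only.
* No thermodynamic constraints (e.g. fixing $S(0)$ to the
  compressibility limit), though the low-$q$ prior variance would
  benefit from them.
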