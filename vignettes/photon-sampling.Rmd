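---
title: "Photon sampling and early gain control in microvillar photoreceptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon sampling and early gain control in microvillar photoreceptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randpam)
```

## The model and its assumptions

A fly photoreceptor samples light with the microvilli of its rhabdomere:
tens of thousands of finger-like membrane protrusions, each housing one
complete phototransduction cascade and each able to convert the photons
that hit it within one time bin into a single quantum bump (QB). `randpam`
models only this first, purely statistical stage — how a fixed number of
photons per time bin distributes over the microvillus population — and the
gain consequences of photons sharing a microvillus. Downstream biophysics
(refractoriness, cascade dynamics, bump waveforms, membrane voltage) is out
of scope; where a bump-charge curve is needed it is a user-supplied input.

The model rests on five assumptions:

1. The input is the number of photons *absorbed* per bin, treated as a
   fixed count: external Poisson flux variation is deliberately excluded so
   that the sampling statistics themselves can be isolated.
2. Light varies only in intensity; spectral sensitivity is folded into the
   effective photon rate (each absorbed photon elicits a similar bump
   regardless of wavelength).
3. Microvilli absorb independently.
4. All microvilli have the same absorption probability, so position in the
   rhabdomere carries no information and units are exchangeable.
5. Hits are independent across time bins.

Under these, the hit count $x$ of one microvillus in a bin with $N_{ph}$
photons and $N_u$ microvilli is binomial with success probability $1/N_u$,
and for $N_{ph} \ll N_u^2$ Poisson with rate
$\lambda_M = N_{ph}/N_u$. The package exposes both forms
(`binomial_hit_pmf()`, `poisson_hit_pmf()`) and reports the validity
diagnostics (`poisson_approx_valid()`); the default validity rule,
$N_{ph}/N_u^2 \le 0.01$ and $N_u \ge 100$, keeps two orders of margin on
the bright-daylight regime of a 30,000-microvillus cell, where the ratio is
below $10^{-5}$ even at $5\times 10^6$ photons per integration window.

## Hit statistics

All headline quantities are functions of $\lambda_M$ alone:

* `multi_photon_fraction()`: the share of *hit* microvilli that received
  two or more photons, $P_M = 1 - \lambda_M / (e^{\lambda_M} - 1)$.
* `activated_per_photon()`: activated microvilli per photon,
  $N_A/N_{ph} = (1 - e^{-\lambda_M})/\lambda_M$.

Both are $0/0$ at $\lambda_M = 0$ and are defined there by their continuous
limits (0 and 1). They are computed with `expm1()` so the small-rate
expansions $P_M \approx \lambda_M/2$ and
$N_A/N_{ph} \approx 1 - \lambda_M/2$ hold to full precision; above
$\lambda_M \approx 40$ the correction $e^{-\lambda_M}$ underflows double
precision and $P_M$ is numerically exactly 1.

`multi_photon_table()` tabulates $P_M$ (percent, two display decimals, raw
values alongside) over a photon-rate × microvillus grid, with rows as
photons per millisecond and columns as microvillus counts. Six cells of the
published reference grid for this table — (100, 300), (1 k, 300),
(100, 1500), (1 k, 1500), (10 k, 6 k) and (100 k, 6 k) — differ from the
Poisson closed form by 0.01–0.17 percentage points. They match neither the
Poisson nor the exact binomial evaluation (we checked both; the binomial
reproduces only the (1 k, 1500) cell), so they were most plausibly produced
by simulation. The package reports the closed-form values; the acceptance
checks use only the Poisson-consistent cells.

## The simulator

Realising the allocation per bin must respect a hard physical constraint:
the photon hits of all microvilli must add up to the input count, exactly.
Drawing each microvillus independently from its Poisson marginal violates
this (the sum would itself be Poisson), so two conserving allocators are
provided:

* **Multinomial** (default): each photon independently picks a microvillus
  uniformly. Conservation holds by construction, the per-microvillus
  marginal is exactly $\mathrm{Binomial}(N_{ph}, 1/N_u)$, and the scheme is
  also the cheaper one. This is the reference allocator.
* **Compound binomial**: for each multiplicity $x$ from the digitisation
  limit $x_n$ (the largest $x$ with $N_u P(x) > 1$) down to 1, draw
  $\mathrm{round}(N_u P(x))$ distinct microvilli — at least one per class —
  to absorb $x$ photons. Expected counts need not sum to $N_{ph}$, so a
  residual-correction step follows: surplus photons are placed as
  single-photon hits on unoccupied microvilli; a deficit removes
  single-photon events first and decrements multi-photon events only when
  those are exhausted. This is the smallest perturbation of the drawn
  configuration consistent with exact conservation. Rounding is
  half-away-from-zero, and the at-least-one floor applies only for
  $x \le x_n$. When the residual cannot be settled (very small populations
  under heavy load, where the truncation at $x_n$ discards substantial
  photon mass), the allocator raises an infeasibility error naming the bin
  rather than silently violating conservation.

Microvilli drawn for different multiplicities are kept distinct within a
bin (a microvillus absorbs exactly one $x$ value per bin); whether the
original drawing scheme permits overlap is not specified anywhere we could
find, and distinctness is the reading consistent with "$y$ microvilli
absorb exactly $x$ photons".

Bins are processed independently (assumption 5), all randomness flows from
one run seed, and events are stored sparsely as (bin, microvillus, hits)
triples — occupancy is $\le N_{ph}/N_u \ll 1$ in the fly regime.
`reconstruct_stimulus()` inverts the allocation by summing hits per bin and
equals the input exactly, which the tests assert bin for bin for
white-noise and naturalistic inputs under both allocators.

## Gain control

The input–output gain of the sampling stage is the bump charge delivered
per photon. With $C_x$ the charge of an $x$-photon bump and $P(x)$ the
Poisson hit pmf, the normalized gain (relative to linear summation of
single-photon bumps) is

$$G(\lambda_M) = \frac{1}{\lambda_M}\sum_{x\ge 1} P(x)\,\frac{C_x}{C_1},
\qquad Q_g = 1 - G,$$

and every physically sensible bump model satisfies
$C_1 \le C_x < x C_1$, which brackets $G$ between the no-summation gain
$(1-e^{-\lambda_M})/\lambda_M$ and the linear-summation value 1.
`bump_charge_model()` supplies the two extremes plus two sublinear forms: a
user-tabulated $(x, C_x)$ curve (e.g. from a full phototransduction model)
and a one-parameter family $C_x = C_1(1 + s(x-1))$, $0 \le s < 1$. Charges
are carried in fC but cancel from every reported ratio, which a test
asserts. Published sublinear-curve gain values depend on bump-charge tables
that are not available numerically, so the package verifies the bound and
limit properties rather than reproducing specific sublinear curves.

Numerical choices: the sum over $x$ is truncated where the Poisson tail
mass falls below $10^{-15}$ (increasing the truncation further moves
results by less than $10^{-12}$); tabulated charges beyond the last table
entry are held constant, which is conservative — it keeps the model
sublinear; $Q_g$ is computed as $1 - G$, and a test checks this against the
independent hit-count expansion
$1 - P(0) - \sum_{x\ge2} (C_x/C_1) P(x)/\lambda_M$ (they agree to
$10^{-12}$ via the identity $P(1)/\lambda_M = P(0)$). The temporal shape of
bumps is excluded by construction: gain is a per-bin charge ratio pooled
over bins.

`empirical_gain()` evaluates the same quantities from a realised
allocation: $C_{out} = \sum_x N_x C_x$ over realised hit multiplicities
against the linear reference $C_1 L_{in}$. Under no summation it reduces
exactly to counted activated microvilli per photon.

## Stimulus generators

The generator defaults encode the study conditions: 1 kHz sampling (1 ms
bins; a warning is issued below 200 Hz, which would undersample fly
photoreceptor dynamics), and reference light levels of $10^5$ photons/s for
dynamic stimuli and $10^6$ photons/s (1000 photons/ms) for the
bright-daylight constant condition.

* `constant_stimulus()` rounds the per-bin rate half-to-even and reports
  the rounding residual as metadata rather than re-normalising: the
  integer counts are the ground-truth input (assumption 1).
* `white_noise_stimulus()` synthesises a flat spectrum up to a cutoff
  (20 Hz band-limited in the reference condition) with Gaussian Fourier
  amplitudes, scales to mean and `contrast`·mean standard deviation, clips
  at zero and rounds. The reference white-noise contrast is not stated in
  the source material, so contrast is a required user parameter.
* `naturalistic_stimulus()` synthesises a $1/f$ power spectrum in
  *log*-intensity and exponentiates. The log-domain route was chosen
  because it guarantees positivity and gives the skewed, occasionally very
  bright intensity distribution typical of natural scenes; a plain Gaussian
  $1/f$ series clipped at zero would distort the spectrum at realistic
  contrasts. The default log-sd of 0.5 yields a fitted log–log spectral
  slope near $-1$ (tested within $[-1.3, -0.7]$ over 0.5–100 Hz) and a
  positively skewed count distribution.

Both generators are deterministic per seed. What the generators do *not*
emulate: the exact amplitude distribution of any recorded natural-light
trace, photon shot noise on the input (excluded by assumption 1), and any
spectral content above the synthesis band. Passing tests therefore show
that the sampling machinery behaves correctly on inputs with the stated
second-order statistics, not that the generators reproduce any particular
recorded stimulus.

## Problem sizes and test design

The statistical tests run the multinomial allocator at $10^4$ replicate
bins for distributional checks (chi-square against the binomial marginal at
$\alpha = 0.001$, with a fixed seed so the suite is deterministic) and
$10^4$ bins for Monte-Carlo convergence of the multi-photon fraction, which
puts three binomial standard errors at about 0.01 percentage points —
tight enough to distinguish the published two-decimal percentages.
Conservation and determinism checks use second-long stimuli; these sizes
make the full suite run in well under a minute while leaving the
Monte-Carlo comparisons statistically meaningful.

## Limitations

* Refractoriness is absent by design: every photon is absorbed, none is
  lost to a recovering microvillus. Real gain control includes large
  refractory contributions downstream of this model.
* The compound-binomial residual-correction rule is this package's own
  reconciliation of expected-count drawing with exact conservation; the
  drawing scheme alone does not determine one. The allocation method and
  seed are recorded in run metadata so results can be traced to it.
* The analytic layer assumes Poisson hit statistics; for very small
  populations (hundreds of microvilli) at bright light the binomial and
  Poisson forms separate, and the simulator (whose marginals are exactly
  binomial) is the more faithful route.
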