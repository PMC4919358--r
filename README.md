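# randpam

Stochastic photon-sampling model for microvillar photoreceptors.

Fly photoreceptors sample light with tens of thousands of independent
sampling units, the microvilli of the rhabdomere (about 30,000 in a
*Drosophila* R1–R6 cell, about 90,000 in a blowfly). Each microvillus
converts the photon(s) that hit it in a time bin into a single electrical
event, a quantum bump (QB). When two or more photons land on the same
microvillus in the same millisecond, the resulting bump is smaller than the
linear sum of single-photon bumps, so multi-photon hits reduce the charge
delivered per photon. `randpam` quantifies this earliest stage of gain
control: it distributes a fixed per-bin photon count over the microvillus
population, computes the closed-form hit statistics, and bounds the
resulting input–output gain.

## The model

With `N_ph` photons in a time bin falling uniformly on `N_u` equivalent,
independent microvilli, the hit count `x` of one microvillus is binomial,

    P(x) = C(N_ph, x) (1/N_u)^x (1 - 1/N_u)^(N_ph - x),

which for `N_ph << N_u^2` is Poisson with rate `lambda_M = N_ph / N_u`, the
mean photon hits per microvillus per bin. Everything else follows from
`lambda_M`:

* fraction of hit microvilli receiving 2+ photons (multi-photon hits):
  `P_M = 1 - lambda_M / (e^lambda_M - 1)`;
* activated microvilli per photon (the gain of pure sampling when
  multi-photon hits collapse to one bump):
  `N_A / N_ph = (1 - e^(-lambda_M)) / lambda_M`;
* normalized gain for a bump-charge model `C_x` (charge of an x-photon
  bump): `G = (1/lambda_M) * sum_x P(x) C_x / C_1`, bounded between
  `N_A/N_ph` (no summation) and 1 (linear summation) for every sublinear
  model `C_1 <= C_x < x C_1`; the quantum-gain factor is `Q_g = 1 - G`.

The simulator realises the allocation per bin under exact photon
conservation — every photon of the input lands on exactly one microvillus,
so summing hits per bin reconstructs the stimulus bit for bit — either by
multinomial assignment (default) or by the compound-binomial drawing scheme
(draw `round(N_u P(x))` microvilli to absorb `x` photons, for `x` up to the
digitisation limit `x_n`, then settle the rounding residual with
single-photon corrections). Stimulus generators provide constant,
20 Hz-style band-limited Gaussian white-noise and 1/f naturalistic
photon-count time series at 1 kHz.

## Worked example

```r
library(randpam)

geom  <- sampling_geometry(30000)                      # Drosophila R1-R6
stim  <- naturalistic_stimulus(1e5, duration_s = 1, seed = 7)
stim
#> Light stimulus: 1000 bins at 1000 Hz (1 s)
#>   photons/bin: mean 100, range [20, 385]

alloc <- simulate_photons(stim, geom, seed = 42)
alloc
#> Photon allocation (multinomial, seed 42)
#>   1000 bins over 30,000 microvilli
#>   photons: 100007 total, 99791 hit events (216 multi-photon)

identical(as.integer(reconstruct_stimulus(alloc)), as.integer(stim))
#> [1] TRUE

eg <- empirical_gain(alloc, bump_charge_model("no_summation"))
round(unlist(eg[c("lambda", "normalized_gain",
                  "quantum_gain_factor", "multi_photon_fraction")]), 5)
#>               lambda       normalized_gain   quantum_gain_factor
#>              0.00333               0.99784               0.00216
#> multi_photon_fraction
#>              0.00216
```

At a naturalistic 10^5 photons/s the mean hit rate is `lambda_M ~ 0.0033`:
only 0.2% of hit microvilli receive more than one photon, the sampling gain
is 99.8% of linear, and even the worst-case (no-summation) quantum-gain
factor is 0.2% — sublinear bump summation barely matters for a cell with
30,000 microvilli. The analytic percentages over the published photon-rate
and microvillus grid come from `multi_photon_table()`:

```r
multi_photon_table(c(10, 100, 1000, 10000, 100000),
                   c(300, 1500, 6000, 15000, 30000, 90000))$percent
```

A command-line interface (`exec/randpam`) exposes the same operations as
`stimulus`, `simulate`, `reconstruct`, `table` and `gain` subcommands with
seeded, metadata-stamped CSV outputs.

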