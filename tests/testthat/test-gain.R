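test_that("bump charge models implement the three summation regimes", {
  lin <- bump_charge_model("linear")
  ns <- bump_charge_model("no_summation")
  expect_identical(charge_of(lin, 3), 3)
  expect_identical(charge_of(ns, 3), 1)
  par <- bump_charge_model("parametric", c1 = 2, s = 0.25)
  expect_equal(charge_of(par, 1:4), 2 * (1 + 0.25 * 0:3))
  tab <- bump_charge_model("tabulated",
                           table = data.frame(x = 1:3,
                                              charge = c(8, 10, 13)))
  expect_equal(charge_of(tab, c(1, 2, 3)), c(8, 10, 13))
  # beyond the table: held at the last tabulated charge (stays sublinear)
  expect_equal(charge_of(tab, 10), 13)
  expect_error(charge_of(tab, 0), ">= 1")
})

test_that("invalid bump tables are rejected with the offending x", {
  expect_error(
    bump_charge_model("tabulated",
                      table = data.frame(x = 1:3, charge = c(8, 20, 21))),
    "x = 2")
  expect_error(  # non-monotone
    bump_charge_model("tabulated",
                      table = data.frame(x = 1:3, charge = c(8, 12, 9))),
    "sublinearity")
  expect_error(
    bump_charge_model("tabulated",
                      table = data.frame(x = 2:3, charge = c(8, 9))),
    "x = 1")
  expect_error(bump_charge_model("parametric", s = 1), "slope")
  expect_error(bump_charge_model("linear", c1 = -1), "positive")
})

test_that("normalized gain closed forms: no-summation and linear limits", {
  ns <- bump_charge_model("no_summation")
  lin <- bump_charge_model("linear")
  expect_equal(normalized_gain(1, ns, x_max = 50), 1 - exp(-1),
               tolerance = 1e-12)
  lam <- c(1e-3, 0.01, 0.1, 1, 5, 10)
  expect_equal(normalized_gain(lam, ns), activated_per_photon(lam),
               tolerance = 1e-12)
  expect_equal(normalized_gain(lam, lin), rep(1, length(lam)),
               tolerance = 1e-10)
  expect_lt(max(abs(quantum_gain_factor(lam, lin))), 1e-8)
  expect_error(normalized_gain(0, ns), "positive")
})

test_that("quantum-gain factor matches its hit-count expansion", {
  # the direct form 1 - P(0) - sum_{x>=2} (C_x/C_1) P(x) / lambda,
  # written independently of normalized_gain()
  direct_qg <- function(lambda, model, x_max = 200) {
    x <- 2:x_max
    1 - dpois(0, lambda) -
      sum(dpois(x, lambda) * model$charge_of(x) / model$c1) / lambda
  }
  set.seed(61)
  models <- list(bump_charge_model("no_summation"),
                 bump_charge_model("parametric", s = 0.5),
                 bump_charge_model("tabulated",
                                   table = random_sublinear_table(12)))
  for (m in models) {
    for (lam in c(0.01, 0.3, 2)) {
      expect_equal(quantum_gain_factor(lam, m, x_max = 200),
                   direct_qg(lam, m), tolerance = 1e-12)
    }
  }
})

test_that("every valid sublinear model is bracketed by the analytic bounds", {
  set.seed(62)
  lam <- exp(seq(log(1e-3), log(10), length.out = 40))
  for (rep in 1:5) {
    m <- bump_charge_model("tabulated", table = random_sublinear_table(15))
    g <- normalized_gain(lam, m)
    expect_true(all(g >= activated_per_photon(lam) - 1e-12))
    expect_true(all(g <= 1 + 1e-12))
  }
  mpar <- bump_charge_model("parametric", s = 0.7)
  g <- normalized_gain(lam, mpar)
  expect_true(all(g >= activated_per_photon(lam) & g <= 1 + 1e-12))
})

test_that("gain sweep is monotone for no-summation and self-consistent", {
  lam <- exp(seq(log(0.01), log(10), length.out = 30))
  sw <- gain_sweep(lam, bump_charge_model("no_summation"))
  expect_true(all(diff(sw$normalized_gain) < 0))
  expect_true(all(diff(sw$quantum_gain_factor) > 0))
  expect_equal(sw$normalized_gain + sw$quantum_gain_factor,
               rep(1, nrow(sw)), tolerance = 1e-15)
  expect_equal(sw$lower_bound, activated_per_photon(lam), tolerance = 1e-15)
  expect_true(all(sw$normalized_gain >= sw$lower_bound - 1e-12))
})

test_that("truncation beyond the Poisson tail does not move results", {
  m <- bump_charge_model("parametric", s = 0.4)
  for (lam in c(0.1, 1, 5)) {
    base <- normalized_gain(lam, m)
    expect_equal(normalized_gain(lam, m, x_max = 400), base,
                 tolerance = 1e-12)
  }
})

test_that("headline single-photon charge cancels from all ratios", {
  lam <- c(0.05, 0.5)
  for (c1 in c(1, 8.3, 120)) {
    m <- bump_charge_model("parametric", c1 = c1, s = 0.3)
    expect_equal(normalized_gain(lam, m),
                 normalized_gain(lam, bump_charge_model("parametric",
                                                        c1 = 1, s = 0.3)),
                 tolerance = 1e-12)
  }
})

test_that("empirical gain matches counts and the analytic prediction", {
  ns <- bump_charge_model("no_summation")
  # hand-built allocations exercise the counting directly
  single <- simulate_photons(light_stimulus(3L), sampling_geometry(1000),
                             seed = 70)
  if (all(single$events$hits == 1L)) {
    expect_equal(empirical_gain(single, ns)$normalized_gain, 1)
    expect_equal(empirical_gain(single,
                                bump_charge_model("linear"))$normalized_gain,
                 1)
  }
  pair <- simulate_photons(light_stimulus(2L), sampling_geometry(1),
                           seed = 71)
  expect_equal(empirical_gain(pair, ns)$normalized_gain, 0.5)
  expect_error(empirical_gain(simulate_photons(0L, sampling_geometry(10)),
                              ns), "no photons")

  # Monte-Carlo convergence to the Poisson prediction, all three kinds
  al <- simulate_photons(rep(1000L, 2000L), sampling_geometry(30000),
                         seed = 72)
  lam <- 1 / 30
  for (m in list(ns, bump_charge_model("linear"),
                 bump_charge_model("parametric", s = 0.5))) {
    eg <- empirical_gain(al, m)
    se <- sqrt(activated_per_photon(lam) * (1 - activated_per_photon(lam)) /
                 eg$n_photons)
    expect_lt(abs(eg$normalized_gain - normalized_gain(lam, m)),
              3 * se + 2e-4)
  }
  # no-summation empirical gain IS activated microvilli per photon
  eg <- empirical_gain(al, ns)
  expect_equal(eg$normalized_gain, eg$n_activated / eg$n_photons,
               tolerance = 1e-15)
})
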