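# Shared test utilities.

# Chunked Monte-Carlo tally of activated / multi-photon-hit microvilli for a
# constant stimulus, so large runs never hold the full event table at once.
mc_hit_tally <- function(n_photons, n_microvilli, n_bins, seed,
                         chunk = 1000L, method = "multinomial") {
  geom <- sampling_geometry(n_microvilli)
  n_act <- 0L
  n_multi <- 0L
  done <- 0L
  i <- 0L
  while (done < n_bins) {
    i <- i + 1L
    nb <- min(chunk, n_bins - done)
    al <- simulate_photons(rep(as.integer(n_photons), nb), geom,
                           seed = seed + i, method = method)
    n_act <- n_act + nrow(al$events)
    n_multi <- n_multi + sum(al$events$hits > 1L)
    done <- done + nb
  }
  list(n_activated = n_act, n_multi = n_multi,
       fraction = n_multi / n_act)
}

# Random valid sublinear bump-charge table: C_1 <= C_x < x*C_1,
# non-decreasing.
random_sublinear_table <- function(x_max = 10, c1 = 1) {
  x <- seq_len(x_max)
  # fractional progress of C_x between the bounds, non-decreasing in x
  lo <- c1
  hi <- x * c1
  u <- sort(runif(x_max, 0, 0.95))
  charge <- lo + u * (hi - lo)
  charge <- cummax(charge)
  data.frame(x = x, charge = charge)
}

# Log-log periodogram slope of a stimulus over a frequency band.
spectral_slope <- function(stim, f_lo = 0.5, f_hi = 100) {
  sr <- attr(stim, "sampling_rate_hz")
  x <- as.numeric(stim) - mean(stim)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * sr / n
  sel <- f >= f_lo & f <= f_hi
  unname(stats::coef(stats::lm(log(p[sel]) ~ log(f[sel])))[2])
}

# Fraction of (mean-removed) power above a cutoff frequency.
out_of_band_power <- function(stim, above_hz) {
  sr <- attr(stim, "sampling_rate_hz")
  x <- as.numeric(stim) - mean(stim)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * sr / n
  half <- f > 0 & f <= sr / 2
  sum(p[half & f > above_hz]) / sum(p[half])
}
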