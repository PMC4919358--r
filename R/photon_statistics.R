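#' Binomial photon-hit probability for a single microvillus
#'
#' Probability that one microvillus absorbs exactly `x` photons out of the
#' `n_photons` arriving in one time bin, when each photon independently lands
#' on one of \eqn{N_u} equivalent microvilli:
#' \deqn{P(x) = \binom{N_{ph}}{x} (1/N_u)^x (1 - 1/N_u)^{N_{ph}-x}.}
#' Evaluated in log space (via [stats::dbinom()]) so large photon counts do
#' not overflow.
#'
#' @param x Hit count (vectorised); integer(s) in `0..n_photons`.
#' @param n_photons Photons arriving in the bin, \eqn{N_{ph}}.
#' @param geometry A [sampling_geometry()] (or a bare microvillus count).
#'
#' @return Probability (vector over `x`).
#' @seealso [poisson_hit_pmf()] for the large-\eqn{N_u} approximation.
#' @examples
#' binomial_hit_pmf(0, 10, sampling_geometry(300))  # (299/300)^10
#' @export
binomial_hit_pmf <- function(x, n_photons, geometry) {
  geometry <- as_geometry(geometry)
  check_count(n_photons, "n_photons")
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("'x' must be non-negative integer(s)", call. = FALSE)
  }
  if (any(x > n_photons)) {
    stop("'x' cannot exceed 'n_photons'", call. = FALSE)
  }
  stats::dbinom(x, size = n_photons, prob = 1 / geometry$n_microvilli)
}

#' Poisson photon-hit probability
#'
#' Large-population approximation to [binomial_hit_pmf()]: with
#' \eqn{\lambda_M = N_{ph}/N_u} photon hits per microvillus per bin,
#' \deqn{P(x) = \lambda_M^x e^{-\lambda_M} / x!.}
#' Valid when \eqn{x \ll N_{ph}}, \eqn{x \ll N_u} and \eqn{1 \ll N_u};
#' in practice whenever \eqn{N_{ph} \ll N_u^2} (see
#' [poisson_approx_valid()]).
#'
#' @param x Hit count(s), non-negative integer(s).
#' @param lambda Mean photon hits per microvillus per bin,
#'   \eqn{\lambda_M \ge 0}.
#'
#' @return Probability (vector over `x`).
#' @examples
#' poisson_hit_pmf(0, 1 / 30)  # exp(-1/30)
#' @export
poisson_hit_pmf <- function(x, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("'lambda' must be a single non-negative number", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("'x' must be non-negative integer(s)", call. = FALSE)
  }
  stats::dpois(x, lambda)
}

#' Is the Poisson approximation to the hit distribution valid?
#'
#' The Poisson form of the hit pmf holds near \eqn{x = \lambda_M} whenever
#' \eqn{N_{ph} \ll N_u^2}.  The default rule declares the approximation valid
#' when \eqn{N_{ph}/N_u^2 \le} `threshold` (0.01) and \eqn{N_u \ge 100}; both
#' diagnostic ratios are always returned so callers can apply their own
#' cutoff.  For a Drosophila photoreceptor the condition is comfortable even
#' in direct sunlight: fewer than \eqn{5\times10^6} photons per integration
#' window against \eqn{N_u^2 = 9\times10^8}.
#'
#' @param n_photons Photons per bin.
#' @param geometry A [sampling_geometry()].
#' @param threshold Maximum allowed \eqn{N_{ph}/N_u^2} (default 0.01).
#'
#' @return A list: `valid` (logical), `ratio` (\eqn{N_{ph}/N_u^2}),
#'   `lambda` (\eqn{N_{ph}/N_u}), `n_microvilli`.
#' @examples
#' poisson_approx_valid(5000, sampling_geometry(30000))$valid  # TRUE
#' @export
poisson_approx_valid <- function(n_photons, geometry, threshold = 0.01) {
  geometry <- as_geometry(geometry)
  check_count(n_photons, "n_photons")
  nu <- geometry$n_microvilli
  ratio <- n_photons / nu^2
  list(valid = ratio <= threshold && nu >= 100,
       ratio = ratio,
       lambda = n_photons / nu,
       n_microvilli = nu)
}

#' Expected number of microvilli absorbing exactly x photons
#'
#' Under the compound-binomial view the number of microvilli that absorb
#' exactly `x` photons is binomial with mean \eqn{N_u P(x)}.  Uses the exact
#' binomial pmf unless the Poisson approximation is valid for the given
#' geometry, in which case the Poisson form is used.
#'
#' @inheritParams binomial_hit_pmf
#' @return Expected microvillus count(s), \eqn{N_u P(x)}.
#' @examples
#' expected_microvilli_with_hits(1, 1000, sampling_geometry(30000))
#' @export
expected_microvilli_with_hits <- function(x, n_photons, geometry) {
  geometry <- as_geometry(geometry)
  check_count(n_photons, "n_photons")
  if (poisson_approx_valid(n_photons, geometry)$valid) {
    p <- poisson_hit_pmf(x, n_photons / geometry$n_microvilli)
  } else {
    p <- binomial_hit_pmf(pmin(x, n_photons), n_photons, geometry) *
      (x <= n_photons)
  }
  geometry$n_microvilli * p
}

#' Multi-photon-hit percentage
#'
#' Fraction of photon-hit microvilli that receive two or more photons in the
#' same time bin, under Poisson hit statistics:
#' \deqn{P_M = \frac{1 - P(0) - P(1)}{1 - P(0)} = 1 -
#'   \frac{\lambda_M}{e^{\lambda_M} - 1}.}
#' \eqn{P_M} is strictly increasing in \eqn{\lambda_M}, tends to 0 as
#' \eqn{\lambda_M \to 0} (limit value used at exactly 0) and to 1 as
#' \eqn{\lambda_M \to \infty}.  Multi-photon hits are what make quantum-bump
#' summation matter: with 30,000 microvilli \eqn{P_M} stays below 2% even at
#' 1000 photons/ms (bright midday).
#'
#' @param lambda Mean photon hits per microvillus per bin (vectorised).
#' @return Fraction in `[0, 1)`.
#' @examples
#' multi_photon_fraction(1000 / 30000)  # ~0.0166
#' @export
multi_photon_fraction <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("'lambda' must be non-negative", call. = FALSE)
  }
  out <- ifelse(lambda == 0, 0, 1 - lambda / expm1(lambda))
  # expm1 keeps the small-lambda regime (P_M ~ lambda/2) accurate
  as.numeric(out)
}

#' Activated microvilli per photon (normalized sampling gain)
#'
#' Expected number of photon-activated microvilli per incoming photon,
#' \deqn{N_A / N_{ph} = \frac{1 - e^{-\lambda_M}}{\lambda_M},}
#' the normalized gain of pure photon sampling when every multi-photon hit
#' yields a single quantum bump (no summation).  Strictly decreasing in
#' \eqn{\lambda_M}; tends to 1 as \eqn{\lambda_M \to 0} (limit value used at
#' exactly 0).
#'
#' @inheritParams multi_photon_fraction
#' @return Fraction in `(0, 1]`.
#' @examples
#' activated_per_photon(1)  # 1 - exp(-1)
#' @export
activated_per_photon <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("'lambda' must be non-negative", call. = FALSE)
  }
  out <- ifelse(lambda == 0, 1, -expm1(-lambda) / lambda)
  as.numeric(out)
}

#' Multi-photon-hit percentage table
#'
#' Tabulates [multi_photon_fraction()] over a grid of per-bin photon counts
#' (rows) and microvillus counts (columns), as percentages.  The display
#' matrix is rounded to two decimals; the raw fractions are returned
#' alongside.
#'
#' @param photon_levels Per-bin photon counts \eqn{N_{ph}} (rows).
#' @param microvilli_levels Microvillus counts \eqn{N_u} (columns).
#'
#' @return A list with `percent` (matrix rounded to 2 decimals), `raw`
#'   (unrounded fractions in `[0,1)`), and the input levels as dimnames.
#' @examples
#' multi_photon_table(c(10, 100, 1000), c(300, 30000))$percent
#' @export
multi_photon_table <- function(photon_levels, microvilli_levels) {
  if (length(photon_levels) == 0L || length(microvilli_levels) == 0L) {
    stop("photon and microvillus levels must be non-empty", call. = FALSE)
  }
  if (any(photon_levels <= 0) || any(microvilli_levels <= 0)) {
    stop("all levels must be positive", call. = FALSE)
  }
  raw <- outer(photon_levels, microvilli_levels,
               function(p, n) multi_photon_fraction(p / n))
  dimnames(raw) <- list(
    photons_per_bin = format(photon_levels, scientific = FALSE, trim = TRUE),
    n_microvilli = format(microvilli_levels, scientific = FALSE, trim = TRUE))
  list(percent = round(100 * raw, 2), raw = raw)
}
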