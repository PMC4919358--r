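#' Quantum-bump charge model
#'
#' Maps the number `x` of simultaneous photon hits on one microvillus to the
#' charge \eqn{C_x} (fC) of the quantum bump they elicit.  Three regimes
#' bracket all physically sensible models:
#' * `"linear"`: \eqn{C_x = x C_1} — every photon contributes a full bump.
#' * `"no_summation"`: \eqn{C_x = C_1} — multi-photon hits collapse to a
#'   single bump.
#' * sublinear (`"tabulated"` or `"parametric"`): \eqn{C_1 \le C_x < x C_1},
#'   non-decreasing in `x`.
#'
#' The tabulated kind takes a user-supplied `(x, charge)` table, e.g. from a
#' full phototransduction model; beyond the last tabulated `x` the charge is
#' held at the last value (conservative: stays sublinear).  The parametric
#' kind uses \eqn{C_x = C_1 (1 + s (x - 1))} with slope `0 <= s < 1`
#' (`s = 0` is no summation; `s -> 1` approaches linear).
#'
#' @param kind One of `"linear"`, `"no_summation"`, `"tabulated"`,
#'   `"parametric"`.
#' @param c1 Single-photon bump charge \eqn{C_1} in fC (default 1).  All
#'   headline outputs are charge ratios, so its absolute value cancels.
#' @param table For `"tabulated"`: data frame or matrix with columns `x`
#'   and `charge` (fC), containing `x = 1`.
#' @param s For `"parametric"`: summation slope in `[0, 1)`.
#'
#' @return An object of class `"bump_charge_model"` with elements `kind`,
#'   `c1` and `charge_of(x)`.
#' @examples
#' m <- bump_charge_model("parametric", c1 = 8, s = 0.4)
#' charge_of(m, 1:4)
#' @export
bump_charge_model <- function(kind = c("linear", "no_summation",
                                       "tabulated", "parametric"),
                              c1 = 1, table = NULL, s = NULL) {
  kind <- match.arg(kind)
  if (kind == "tabulated") {
    table <- as.data.frame(table)
    if (!all(c("x", "charge") %in% names(table))) {
      stop("'table' needs columns 'x' and 'charge'", call. = FALSE)
    }
    table <- table[order(table$x), , drop = FALSE]
    if (table$x[1] != 1) stop("'table' must contain x = 1", call. = FALSE)
    c1 <- table$charge[1]
  }
  if (!is.finite(c1) || c1 <= 0) stop("'c1' must be positive", call. = FALSE)
  charge_of <- switch(
    kind,
    linear = function(x) x * c1,
    no_summation = function(x) rep_len(c1, length(x)),
    parametric = {
      if (is.null(s) || !is.finite(s) || s < 0 || s >= 1) {
        stop("parametric kind needs slope 's' in [0, 1)", call. = FALSE)
      }
      force(s)
      function(x) c1 * (1 + s * (x - 1))
    },
    tabulated = {
      bad <- which(table$charge < c1 - 1e-12 |
                     table$charge >= table$x * c1 & table$x > 1)
      if (any(diff(table$charge) < -1e-12)) {
        bad <- union(bad, which(diff(table$charge) < -1e-12) + 1L)
      }
      if (length(bad)) {
        stop("bump-charge table violates sublinearity (C_1 <= C_x < x*C_1, ",
             "non-decreasing) at x = ",
             paste(sort(table$x[bad]), collapse = ", "), call. = FALSE)
      }
      xs <- table$x
      ch <- table$charge
      function(x) {
        idx <- findInterval(x, xs)        # hold at last tabulated value
        out <- ifelse(idx >= 1, ch[pmax(idx, 1)], NA_real_)
        if (anyNA(out)) stop("charge requested for x < 1", call. = FALSE)
        out
      }
    }
  )
  structure(list(kind = kind, c1 = c1, charge_of = charge_of,
                 s = if (kind == "parametric") s else NULL,
                 table = if (kind == "tabulated") table else NULL),
            class = "bump_charge_model")
}

#' @rdname bump_charge_model
#' @param model A `bump_charge_model`.
#' @param x Simultaneous photon-hit count(s), `x >= 1`.
#' @export
charge_of <- function(model, x) {
  stopifnot(inherits(model, "bump_charge_model"))
  if (any(x < 1) || any(x != floor(x))) {
    stop("'x' must be integer(s) >= 1", call. = FALSE)
  }
  model$charge_of(x)
}

#' @export
print.bump_charge_model <- function(x, ...) {
  cat("Quantum-bump charge model: ", x$kind,
      " (C_1 = ", format(x$c1), " fC", sep = "")
  if (!is.null(x$s)) cat(", slope s = ", x$s, sep = "")
  cat(")\n")
  invisible(x)
}

# Truncation point for Poisson sums: smallest x beyond which the remaining
# tail mass is numerically irrelevant.
default_x_max <- function(lambda) {
  max(50L, as.integer(stats::qpois(1 - 1e-15, lambda)) + 10L)
}

#' Normalized input-output gain
#'
#' Expected bump charge delivered per photon, relative to the linear-gain
#' reference \eqn{C_1} per photon:
#' \deqn{G(\lambda_M) = \frac{1}{\lambda_M} \sum_{x \ge 1} P(x)
#'   \frac{C_x}{C_1},}
#' with \eqn{P(x)} the Poisson hit pmf at rate \eqn{\lambda_M}.  Linear
#' summation gives exactly 1 (upper bound); no summation gives
#' \eqn{(1 - e^{-\lambda_M})/\lambda_M} (lower bound); every valid sublinear
#' model lies between the two.
#'
#' @param lambda Mean photon hits per microvillus per bin, > 0 (vectorised).
#' @param model A [bump_charge_model()].
#' @param x_max Truncation of the sum over hit multiplicities; defaults to a
#'   point where the Poisson tail mass is below 1e-15.
#'
#' @return Normalized gain(s) in `(0, 1]`.
#' @examples
#' normalized_gain(1, bump_charge_model("no_summation"))  # 1 - exp(-1)
#' @export
normalized_gain <- function(lambda, model, x_max = NULL) {
  stopifnot(inherits(model, "bump_charge_model"))
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("'lambda' must be positive", call. = FALSE)
  }
  vapply(lambda, function(l) {
    xm <- if (is.null(x_max)) default_x_max(l) else x_max
    if (xm < 1) stop("'x_max' must be >= 1", call. = FALSE)
    x <- seq_len(xm)
    sum(stats::dpois(x, l) * model$charge_of(x) / model$c1) / l
  }, numeric(1))
}

#' Quantum-gain factor
#'
#' The fractional charge lost to sublinear bump summation, relative to
#' linear summation of single-photon bumps:
#' \deqn{Q_g = 1 - G(\lambda_M) = 1 - P(0) - \frac{1}{\lambda_M}
#'   \sum_{x \ge 2} P(x) \frac{C_x}{C_1},}
#' using the identity \eqn{P(1)/\lambda_M = P(0)} to absorb the `x = 1`
#' term.  Zero for linear summation; maximal,
#' \eqn{1 - (1 - e^{-\lambda_M})/\lambda_M}, for no summation.
#'
#' @inheritParams normalized_gain
#' @return Quantum-gain factor(s) in `[0, 1)`.
#' @examples
#' quantum_gain_factor(1, bump_charge_model("no_summation"))
#' @export
quantum_gain_factor <- function(lambda, model, x_max = NULL) {
  1 - normalized_gain(lambda, model, x_max)
}

#' Gain summary over a grid of hit rates
#'
#' Evaluates the normalized gain, its analytic bounds and the quantum-gain
#' factor over a grid of \eqn{\lambda_M} values for one bump-charge model.
#'
#' @param lambda_grid Positive hit rates \eqn{\lambda_M}.
#' @param model A [bump_charge_model()].
#' @param x_max Optional truncation (see [normalized_gain()]).
#'
#' @return A data frame with columns `lambda`, `normalized_gain`,
#'   `lower_bound` (\eqn{(1-e^{-\lambda})/\lambda}), `upper_bound` (1),
#'   `quantum_gain_factor`, `multi_photon_fraction`.
#' @examples
#' gain_sweep(c(0.01, 0.1, 1), bump_charge_model("no_summation"))
#' @export
gain_sweep <- function(lambda_grid, model, x_max = NULL) {
  if (!length(lambda_grid)) stop("empty lambda grid", call. = FALSE)
  g <- normalized_gain(lambda_grid, model, x_max)
  data.frame(
    lambda = lambda_grid,
    normalized_gain = g,
    lower_bound = activated_per_photon(lambda_grid),
    upper_bound = 1,
    quantum_gain_factor = 1 - g,
    multi_photon_fraction = multi_photon_fraction(lambda_grid)
  )
}

#' Empirical gain from a simulated allocation
#'
#' Computes the realised input-output gain of a photon allocation: the
#' total bump charge \eqn{C_{out} = \sum_x N_x C_x} over the charge a
#' linear system would deliver, \eqn{C_1 L_{in}}, where \eqn{N_x} counts
#' the realised `x`-photon hit events and \eqn{L_{in}} is the total photon
#' input.  Under the no-summation model this is exactly the activated
#' microvilli per photon, \eqn{N_A / N_{ph}}.
#'
#' @param allocation A [simulate_photons()] result with at least one photon.
#' @param model A [bump_charge_model()].
#'
#' @return A list: `normalized_gain`, `quantum_gain_factor`, `lambda`
#'   (realised mean hits per microvillus per bin), `n_photons`,
#'   `n_activated` (hit microvilli, = bump count), `multi_photon_fraction`
#'   (realised), `x_max_observed`.
#' @examples
#' alloc <- simulate_photons(constant_stimulus(1e6, 0.02),
#'                           sampling_geometry(30000), seed = 5)
#' empirical_gain(alloc, bump_charge_model("no_summation"))$normalized_gain
#' @export
empirical_gain <- function(allocation, model) {
  stopifnot(inherits(allocation, "photon_allocation"),
            inherits(model, "bump_charge_model"))
  n_photons <- sum(allocation$stimulus)
  if (n_photons == 0) {
    stop("allocation carries no photons; gain undefined", call. = FALSE)
  }
  hits <- allocation$events$hits
  c_out <- sum(model$charge_of(hits))
  list(
    normalized_gain = c_out / (model$c1 * n_photons),
    quantum_gain_factor = 1 - c_out / (model$c1 * n_photons),
    lambda = n_photons /
      (allocation$n_bins * allocation$geometry$n_microvilli),
    n_photons = n_photons,
    n_activated = length(hits),
    multi_photon_fraction = mean(hits > 1L),
    x_max_observed = max(hits)
  )
}
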