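#' Photoreceptor sampling geometry
#'
#' Bundles the structural parameters of the photon-sampling stage of a
#' microvillar photoreceptor: the number of microvilli \eqn{N_u} in the
#' rhabdomere (each microvillus is an independent sampling unit) and the
#' duration of one time bin.  A Drosophila R1-R6 photoreceptor has about
#' 30,000 microvilli; a blowfly outer photoreceptor about 90,000.
#'
#' @param n_microvilli Number of microvilli \eqn{N_u}; positive integer.
#' @param bin_duration_ms Duration of one time bin in milliseconds
#'   (default 1 ms, i.e. 1 kHz sampling).
#'
#' @return An object of class `"sampling_geometry"`: a list with elements
#'   `n_microvilli` and `bin_duration_ms`.
#'
#' @examples
#' geom <- sampling_geometry(30000)
#' geom
#' @export
sampling_geometry <- function(n_microvilli, bin_duration_ms = 1) {
  if (length(n_microvilli) != 1L || !is.finite(n_microvilli) ||
      n_microvilli < 1 || n_microvilli != floor(n_microvilli)) {
    stop("'n_microvilli' must be a single integer >= 1", call. = FALSE)
  }
  if (length(bin_duration_ms) != 1L || !is.finite(bin_duration_ms) ||
      bin_duration_ms <= 0) {
    stop("'bin_duration_ms' must be a single positive number", call. = FALSE)
  }
  structure(
    list(n_microvilli = as.integer(n_microvilli),
         bin_duration_ms = as.numeric(bin_duration_ms)),
    class = "sampling_geometry"
  )
}

#' @export
print.sampling_geometry <- function(x, ...) {
  cat("Photoreceptor sampling geometry\n")
  cat("  microvilli (N_u): ", format(x$n_microvilli, big.mark = ","), "\n",
      sep = "")
  cat("  time bin:         ", x$bin_duration_ms, " ms\n", sep = "")
  invisible(x)
}

as_geometry <- function(geometry) {
  if (inherits(geometry, "sampling_geometry")) return(geometry)
  if (is.numeric(geometry) && length(geometry) == 1L) {
    return(sampling_geometry(geometry))
  }
  stop("'geometry' must be a sampling_geometry object or a microvillus count",
       call. = FALSE)
}

check_count <- function(x, name, allow_zero = TRUE) {
  if (length(x) != 1L || !is.finite(x) || x != floor(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  x
}
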