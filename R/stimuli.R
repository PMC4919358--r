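#' Construct a light stimulus
#'
#' A light stimulus is the model's input: a sequence of per-bin absorbed
#' photon counts at a stated sampling rate.  The counts are taken as fixed
#' ground truth — the model adds no external shot noise on top of them.
#'
#' @param counts Non-negative integer photon counts, one per time bin.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000, i.e. 1 ms
#'   bins).  Rates below 200 Hz trigger a warning because they undersample
#'   fly photoreceptor response dynamics.
#' @param mean_rate Optional nominal mean rate in photons/s, kept as
#'   metadata.
#'
#' @return An object of class `"light_stimulus"`: an integer vector with
#'   attributes `sampling_rate_hz` and `mean_rate`.
#' @examples
#' light_stimulus(c(2, 0, 5))
#' @export
light_stimulus <- function(counts, sampling_rate_hz = 1000,
                           mean_rate = NULL) {
  if (length(counts) < 1L) stop("stimulus must have at least one bin",
                                call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("stimulus counts must be non-negative integers", call. = FALSE)
  }
  if (sampling_rate_hz <= 0) stop("'sampling_rate_hz' must be positive",
                                  call. = FALSE)
  if (sampling_rate_hz < 200) {
    warning("sampling below 200 Hz undersamples fly photoreceptor dynamics")
  }
  structure(as.integer(round(counts)),
            sampling_rate_hz = as.numeric(sampling_rate_hz),
            mean_rate = if (is.null(mean_rate)) NULL else as.numeric(mean_rate),
            class = "light_stimulus")
}

#' @export
print.light_stimulus <- function(x, ...) {
  sr <- attr(x, "sampling_rate_hz")
  cat("Light stimulus: ", length(x), " bins at ", sr, " Hz (",
      format(length(x) / sr, digits = 4), " s)\n", sep = "")
  cat("  photons/bin: mean ", format(mean(x), digits = 4),
      ", range [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

#' Constant-intensity stimulus
#'
#' Every bin receives `round(rate / sampling_rate)` photons (round half to
#' even).  The residual between the requested and the realised mean rate is
#' recorded in the `rounding_residual` attribute (photons/s).
#'
#' @param rate_photons_per_s Target intensity in photons/s.
#' @param duration_s Duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#'
#' @return A [light_stimulus()].
#' @examples
#' constant_stimulus(1e6, 0.01)  # 10 bins of 1000 photons
#' @export
constant_stimulus <- function(rate_photons_per_s, duration_s,
                              sampling_rate_hz = 1000) {
  if (rate_photons_per_s < 0) stop("rate must be non-negative", call. = FALSE)
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  n_bins <- max(1L, round(duration_s * sampling_rate_hz))
  per_bin <- round(rate_photons_per_s / sampling_rate_hz)
  stim <- light_stimulus(rep.int(per_bin, n_bins), sampling_rate_hz,
                         mean_rate = rate_photons_per_s)
  attr(stim, "rounding_residual") <-
    per_bin * sampling_rate_hz - rate_photons_per_s
  stim
}

#' Band-limited Gaussian white-noise stimulus
#'
#' Spectral synthesis: Fourier amplitudes are i.i.d. Gaussian below the
#' cutoff frequency and zero above it, giving a flat in-band spectrum.  The
#' series is scaled to the target mean and standard deviation
#' `contrast * mean`, clipped at zero and rounded half-to-even to integer
#' counts.  Deterministic for a given seed.
#'
#' @param mean_rate Target mean intensity in photons/s.
#' @param contrast Standard deviation over mean of the intensity (>= 0).
#' @param cutoff_hz Band limit in Hz; must be below the Nyquist frequency.
#' @param duration_s Duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @param seed Integer RNG seed.
#'
#' @return A [light_stimulus()].
#' @examples
#' s <- white_noise_stimulus(1e5, 0.3, 20, 1, seed = 1)
#' mean(s)  # about 100 photons/ms
#' @export
white_noise_stimulus <- function(mean_rate, contrast, cutoff_hz, duration_s,
                                 sampling_rate_hz = 1000, seed = 1L) {
  if (mean_rate < 0) stop("mean_rate must be non-negative", call. = FALSE)
  if (contrast < 0) stop("contrast must be non-negative", call. = FALSE)
  if (cutoff_hz >= sampling_rate_hz / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  n <- max(1L, round(duration_s * sampling_rate_hz))
  mean_per_bin <- mean_rate / sampling_rate_hz
  if (contrast == 0 || n == 1L) {
    return(constant_stimulus(mean_rate, duration_s, sampling_rate_hz))
  }
  set.seed(seed)
  z <- band_limited_gaussian(n, cutoff_hz, sampling_rate_hz)
  if (stats::sd(z) == 0) {
    return(constant_stimulus(mean_rate, duration_s, sampling_rate_hz))
  }
  z <- z / stats::sd(z)
  counts <- round(pmax(mean_per_bin + contrast * mean_per_bin * z, 0))
  light_stimulus(counts, sampling_rate_hz, mean_rate = mean_rate)
}

#' Naturalistic 1/f stimulus
#'
#' Emulates the second-order statistics of natural light time series: the
#' intensity power spectrum falls off as \eqn{1/f}.  Synthesis is done in
#' log-intensity (a 1/f-amplitude Gaussian series is exponentiated) so the
#' result is positively skewed with occasional bright events and is strictly
#' non-negative before rounding; it is then scaled to the target mean and
#' rounded to integer counts.  Deterministic for a given seed.
#'
#' @param mean_rate Target mean intensity in photons/s.
#' @param duration_s Duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @param seed Integer RNG seed.
#' @param log_sd Standard deviation of the log-intensity fluctuation
#'   (default 0.5; larger values give heavier-tailed intensities).
#'
#' @return A [light_stimulus()].
#' @examples
#' s <- naturalistic_stimulus(1e5, 2, seed = 7)
#' @export
naturalistic_stimulus <- function(mean_rate, duration_s,
                                  sampling_rate_hz = 1000, seed = 1L,
                                  log_sd = 0.5) {
  if (mean_rate <= 0) stop("mean_rate must be positive", call. = FALSE)
  n <- max(2L, round(duration_s * sampling_rate_hz))
  set.seed(seed)
  freq <- seq_len(n %/% 2) * sampling_rate_hz / n
  # Fourier amplitudes ~ 1/sqrt(f) give a 1/f power spectrum
  amp <- 1 / sqrt(freq)
  z <- spectral_synthesis(n, amp)
  z <- log_sd * z / stats::sd(z)
  intensity <- exp(z)
  mean_per_bin <- mean_rate / sampling_rate_hz
  counts <- round(intensity * mean_per_bin / mean(intensity))
  light_stimulus(counts, sampling_rate_hz, mean_rate = mean_rate)
}

# Real Gaussian series with the given one-sided Fourier amplitude profile
# (length n %/% 2, covering frequencies 1..nh cycles; DC is zero so the
# output is pure fluctuation).
spectral_synthesis <- function(n, amp) {
  nh <- n %/% 2
  re <- stats::rnorm(nh) * amp
  im <- stats::rnorm(nh) * amp
  if (n %% 2 == 0) im[nh] <- 0          # Nyquist bin must be real
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[seq_len(nh) + 1L] <- spec
  mirror <- if (n %% 2 == 0) seq_len(nh - 1L) else seq_len(nh)
  full[n + 1L - mirror] <- Conj(spec[mirror])
  Re(stats::fft(full, inverse = TRUE)) / n
}

band_limited_gaussian <- function(n, cutoff_hz, sampling_rate_hz) {
  freq <- seq_len(n %/% 2) * sampling_rate_hz / n
  spectral_synthesis(n, as.numeric(freq <= cutoff_hz))
}

#' Read / write a stimulus as CSV
#'
#' Plain-text round-trippable storage: one `photons_per_bin` column, with
#' metadata (`sampling_rate_hz`, optional `mean_rate`) in `#`-prefixed
#' comment lines before the header.
#'
#' @param path File path.
#' @param stimulus A [light_stimulus()].
#'
#' @return `read_stimulus()` returns a [light_stimulus()];
#'   `write_stimulus()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_stimulus(light_stimulus(c(2, 0, 5)), f)
#' read_stimulus(f)
#' @export
read_stimulus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list(sampling_rate_hz = 1000, mean_rate = NULL)
  for (ln in lines[meta_lines]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) && identical(trimws(body[1]), "photons_per_bin")) {
    body <- body[-1]
  }
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals) | vals < 0 | vals != floor(vals))
  if (length(bad)) {
    stop(sprintf("invalid photon count %s at data line %d of %s",
                 body[bad[1]], bad[1], path), call. = FALSE)
  }
  light_stimulus(vals, meta$sampling_rate_hz, mean_rate = meta$mean_rate)
}

#' @rdname read_stimulus
#' @export
write_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "light_stimulus"))
  hdr <- sprintf("# sampling_rate_hz=%s",
                 format(attr(stimulus, "sampling_rate_hz"), digits = 15))
  mr <- attr(stimulus, "mean_rate")
  if (!is.null(mr)) hdr <- c(hdr, sprintf("# mean_rate=%s",
                                          format(mr, digits = 15)))
  writeLines(c(hdr, "photons_per_bin", as.character(as.integer(stimulus))),
             path)
  invisible(path)
}
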