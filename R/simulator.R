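#' Allocate one bin's photons to microvilli (multinomial scheme)
#'
#' Each of the `n_photons` photons in a time bin independently lands on one
#' of the \eqn{N_u} microvilli, chosen uniformly — a multinomial draw with
#' size \eqn{N_{ph}} and equal cell probabilities \eqn{1/N_u}.  The per-bin
#' photon total is conserved exactly by construction, and the marginal hit
#' count of any one microvillus is Binomial(\eqn{N_{ph}}, \eqn{1/N_u}).
#'
#' Draws from R's global RNG stream; seed control lives in
#' [simulate_photons()].
#'
#' @param n_photons Photons in the bin.
#' @param geometry A [sampling_geometry()].
#'
#' @return A data frame of events with columns `microvillus` (1-based id)
#'   and `hits` (photons absorbed, >= 1); microvilli with no hits are
#'   omitted.
#' @examples
#' set.seed(1)
#' allocate_multinomial(5, sampling_geometry(10))
#' @export
allocate_multinomial <- function(n_photons, geometry) {
  geometry <- as_geometry(geometry)
  check_count(n_photons, "n_photons")
  if (n_photons == 0L) {
    return(data.frame(microvillus = integer(), hits = integer()))
  }
  ids <- sample.int(geometry$n_microvilli, n_photons, replace = TRUE)
  r <- rle(sort(ids))
  data.frame(microvillus = r$values, hits = r$lengths)
}

#' Allocate one bin's photons to microvilli (compound-binomial scheme)
#'
#' Realises the compound-binomial description of photon absorption: the
#' number of microvilli absorbing exactly `x` photons has expectation
#' \eqn{N_u P(x)}, so for each multiplicity `x` from `x_n` down to 1 the
#' scheme draws `round(N_u P(x))` distinct microvilli (at least one for
#' `x <= x_n`) to absorb `x` photons each.  `x_n` is the largest `x` with
#' \eqn{N_u P(x) > 1} — the digitisation limit of drawing whole microvilli.
#'
#' Because expectations need not sum to the photon count, a residual
#' correction then enforces exact conservation: surplus photons are placed
#' as single hits on unoccupied microvilli, and a deficit is settled by
#' removing single-photon events (or, when those run out, by decrementing
#' multi-photon events).  The correction is the smallest perturbation of the
#' drawn configuration compatible with the hard constraint that all bin
#' totals equal the input.
#'
#' @inheritParams allocate_multinomial
#'
#' @return A data frame of events (`microvillus`, `hits`) with attribute
#'   `x_n` (the truncation used; 0 for an empty bin).
#' @examples
#' set.seed(1)
#' a <- allocate_compound_binomial(1000, sampling_geometry(30000))
#' attr(a, "x_n")   # 2 at lambda = 1/30
#' sum(a$hits)      # exactly 1000
#' @export
allocate_compound_binomial <- function(n_photons, geometry) {
  geometry <- as_geometry(geometry)
  check_count(n_photons, "n_photons")
  nu <- geometry$n_microvilli
  if (n_photons == 0L) {
    out <- data.frame(microvillus = integer(), hits = integer())
    attr(out, "x_n") <- 0L
    return(out)
  }
  pmf <- function(x) binomial_hit_pmf(pmin(x, n_photons), n_photons,
                                      geometry) * (x <= n_photons)
  # digitisation limit: largest x with N_u P(x) > 1
  x_n <- 0L
  while (nu * pmf(x_n + 1L) > 1) x_n <- x_n + 1L
  if (x_n == 0L) x_n <- 1L   # always place at least single-photon events

  n_events <- integer(x_n)
  for (x in seq_len(x_n)) {
    expected <- nu * pmf(x)
    n_events[x] <- max(1L, as.integer(floor(expected + 0.5)))
  }
  if (sum(n_events) > nu) {
    stop(sprintf(
      "infeasible allocation: %d photons need %d event slots but only %d microvilli",
      n_photons, sum(n_events), nu), call. = FALSE)
  }
  ids <- sample.int(nu, sum(n_events))   # without replacement across classes
  hits <- rep.int(seq_len(x_n), n_events)

  residual <- n_photons - sum(hits)
  if (residual > 0) {
    # surplus photons become single hits on unoccupied microvilli
    free <- setdiff(seq_len(nu), ids)
    if (length(free) < residual) {
      stop(sprintf(
        "infeasible allocation: %d surplus photons but only %d free microvilli",
        residual, length(free)), call. = FALSE)
    }
    extra <- if (length(free) == 1L) free else sample(free, residual)
    ids <- c(ids, extra)
    hits <- c(hits, rep.int(1L, residual))
  } else if (residual < 0) {
    deficit <- -residual
    singles <- which(hits == 1L)
    drop <- singles[seq_len(min(deficit, length(singles)))]
    if (length(drop)) {
      ids <- ids[-drop]
      hits <- hits[-drop]
      deficit <- deficit - length(drop)
    }
    while (deficit > 0) {
      multi <- which(hits >= 2L)
      if (!length(multi)) {
        stop("infeasible allocation: cannot settle photon deficit",
             call. = FALSE)
      }
      k <- multi[1L]
      dec <- min(deficit, hits[k] - 1L)
      hits[k] <- hits[k] - dec
      deficit <- deficit - dec
    }
  }
  ord <- order(ids)
  out <- data.frame(microvillus = ids[ord], hits = as.integer(hits[ord]))
  attr(out, "x_n") <- x_n
  out
}

#' Simulate photon allocation over a stimulus
#'
#' Runs one allocation per time bin, independently across bins (photon hits
#' to a microvillus carry no memory between bins), and collects the sparse
#' event table.  Deterministic given `(stimulus, geometry, seed, method)`.
#'
#' @param stimulus A [light_stimulus()] (or a plain non-negative integer
#'   vector of per-bin counts).
#' @param geometry A [sampling_geometry()].
#' @param seed Integer RNG seed for the run.
#' @param method `"multinomial"` (default; conserves totals by construction)
#'   or `"compound_binomial"` (expected-count drawing plus residual
#'   correction).
#'
#' @return An object of class `"photon_allocation"`: a list with `events`
#'   (data frame `bin`, `microvillus`, `hits`; 1-based indices), `n_bins`,
#'   `geometry`, `seed`, `method`, and `stimulus` (the input counts).
#' @examples
#' stim <- constant_stimulus(1e5, 0.05)
#' alloc <- simulate_photons(stim, sampling_geometry(30000), seed = 42)
#' alloc
#' @export
simulate_photons <- function(stimulus, geometry, seed = 1L,
                             method = c("multinomial", "compound_binomial")) {
  method <- match.arg(method)
  geometry <- as_geometry(geometry)
  if (!inherits(stimulus, "light_stimulus")) stimulus <- light_stimulus(stimulus)
  allocate <- switch(method,
                     multinomial = allocate_multinomial,
                     compound_binomial = allocate_compound_binomial)
  set.seed(seed)
  n_bins <- length(stimulus)
  ids_l <- vector("list", n_bins)
  hits_l <- vector("list", n_bins)
  n_ev <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    ev <- tryCatch(allocate(stimulus[b], geometry), error = function(e) {
      stop(sprintf("bin %d: %s", b, conditionMessage(e)), call. = FALSE)
    })
    ids_l[[b]] <- ev$microvillus
    hits_l[[b]] <- ev$hits
    n_ev[b] <- nrow(ev)
  }
  events <- data.frame(
    bin = rep.int(seq_len(n_bins), n_ev),
    microvillus = as.integer(unlist(ids_l, use.names = FALSE)),
    hits = as.integer(unlist(hits_l, use.names = FALSE))
  )
  structure(
    list(events = events, n_bins = n_bins, geometry = geometry,
         seed = as.integer(seed), method = method,
         stimulus = as.integer(stimulus),
         sampling_rate_hz = attr(stimulus, "sampling_rate_hz")),
    class = "photon_allocation"
  )
}

#' @export
print.photon_allocation <- function(x, ...) {
  cat("Photon allocation (", x$method, ", seed ", x$seed, ")\n", sep = "")
  cat("  ", x$n_bins, " bins over ", format(x$geometry$n_microvilli,
                                            big.mark = ","),
      " microvilli\n", sep = "")
  cat("  photons: ", sum(x$stimulus), " total, ",
      nrow(x$events), " hit events (",
      sum(x$events$hits > 1L), " multi-photon)\n", sep = "")
  invisible(x)
}

#' Reconstruct the stimulus from an allocation
#'
#' Sums the absorbed photons per bin.  Because allocation conserves photons
#' exactly, the reconstruction equals the input stimulus bin for bin — the
#' model redistributes the light pattern over microvilli without altering
#' it.
#'
#' @param allocation A [simulate_photons()] result.
#' @return A [light_stimulus()] of per-bin totals.
#' @examples
#' stim <- constant_stimulus(5e4, 0.02)
#' alloc <- simulate_photons(stim, sampling_geometry(1000), seed = 3)
#' identical(as.integer(reconstruct_stimulus(alloc)), as.integer(stim))
#' @export
reconstruct_stimulus <- function(allocation) {
  stopifnot(inherits(allocation, "photon_allocation"))
  counts <- integer(allocation$n_bins)
  if (nrow(allocation$events)) {
    sums <- tapply(allocation$events$hits, allocation$events$bin, sum)
    counts[as.integer(names(sums))] <- as.integer(sums)
  }
  sr <- allocation$sampling_rate_hz
  light_stimulus(counts, if (is.null(sr)) 1000 else sr)
}

#' Per-bin hit series of one microvillus
#'
#' Dense per-bin photon-hit counts experienced by a single microvillus over
#' the simulation — the single-unit view of the sampling process.  For a
#' constant stimulus this is (marginally) a Binomial(\eqn{N_{ph}},
#' \eqn{1/N_u}) count per bin, Poisson-like at large \eqn{N_u}.
#'
#' @param allocation A [simulate_photons()] result.
#' @param microvillus_id Microvillus index in `1..n_microvilli`.
#' @return Integer vector of length `n_bins`.
#' @examples
#' stim <- constant_stimulus(1e5, 0.1)
#' alloc <- simulate_photons(stim, sampling_geometry(1000), seed = 9)
#' mean(hit_series(alloc, 1))  # about 0.1 hits/bin
#' @export
hit_series <- function(allocation, microvillus_id) {
  stopifnot(inherits(allocation, "photon_allocation"))
  check_count(microvillus_id, "microvillus_id", allow_zero = FALSE)
  if (microvillus_id > allocation$geometry$n_microvilli) {
    stop("'microvillus_id' out of range", call. = FALSE)
  }
  series <- integer(allocation$n_bins)
  sel <- allocation$events$microvillus == microvillus_id
  if (any(sel)) {
    series[allocation$events$bin[sel]] <- allocation$events$hits[sel]
  }
  series
}
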