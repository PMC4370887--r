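#' Simulate a single-particle fluorescence burst trace
#'
#' Renders a time-binned photon-count trace of liposomes transiting a
#' scanned confocal detection volume. Burst arrivals form a Poisson process
#' with rate `detection_rate_constant * total_concentration`; each burst is
#' a particle drawn from the population, its amplitude scaled by brightness
#' and by a Gaussian-beam factor `exp(-2 b^2 / w0^2)` at a uniformly random
#' impact parameter `b` in `[0, 1.5 w0]`. Counts are spread over the transit
#' time with a Gaussian temporal profile (sd = transit/5, truncated to the
#' transit window) and drawn per bin as Poisson on top of Poisson
#' background. Overlapping arrivals sum in the trace (physical coincidence);
#' the attached ground truth keeps them separate so coincidence error is
#' measurable.
#'
#' @param pop A `bas_population`. Species-only populations are sampled
#'   internally (10^4 particles). A zero-concentration population yields a
#'   background-only trace.
#' @param acq A `bas_acquisition` (scan mode).
#' @param seed Integer seed (or NULL; falls back to `acq$seed`).
#' @return A `bas_trace`: list with integer `counts`, `bin_width`,
#'   `duration`, `acq` and a `ground_truth` data.frame (arrival `time`,
#'   `diameter`, `brightness`, `beam_factor`, noiseless `amplitude` in
#'   counts).
#' @examples
#' pop <- sample_population(liposome_species(200, 0.35, 50), 2000, seed = 1)
#' tr <- simulate_trace(pop, acquisition_params(duration = 2), seed = 1)
#' @export
simulate_trace <- function(pop, acq, seed = NULL) {
  stopifnot(inherits(pop, "bas_population"), inherits(acq, "bas_acquisition"))
  seed <- seed %||% acq$seed
  conc <- total_concentration(pop)
  if (conc > 500)
    warning("concentration ", format(conc, digits = 4),
            " pM exceeds the single-particle limit (< 500 pM); ",
            "expect coincidence losses")
  if (acq$duration < 10 * acq$transit_time)
    warning("duration shorter than 10 transit times; poor burst statistics")
  n_bins <- as.integer(round(acq$duration / acq$bin_width))
  lam_bg <- acq$background_rate * acq$bin_width

  with_seed(seed, {
    if (conc > 0 && is.null(pop$particles))
      pop <- sample_population(split_species(pop$species), 10000L)
    n_bursts <- if (conc > 0)
      stats::rpois(1, acq$detection_rate_constant * conc * acq$duration)
    else 0L
    if (n_bursts > 0) {
      arr <- sort(stats::runif(n_bursts, 0, acq$duration))
      idx <- sample.int(nrow(pop$particles), n_bursts, replace = TRUE)
      g <- sample_beam_factor(n_bursts, acq)
      amp <- pop$particles$brightness[idx] * acq$brightness_scale *
        acq$transit_time * g
      lam <- lam_bg + burst_profile_rates(arr, amp, acq, n_bins)
      gt <- data.frame(time = arr,
                       diameter = pop$particles$diameter[idx],
                       brightness = pop$particles$brightness[idx],
                       beam_factor = g, amplitude = amp)
    } else {
      lam <- rep(lam_bg, n_bins)
      gt <- data.frame(time = numeric(0), diameter = numeric(0),
                       brightness = numeric(0), beam_factor = numeric(0),
                       amplitude = numeric(0))
    }
    counts <- stats::rpois(n_bins, lam)
    new_trace(counts, acq, ground_truth = gt)
  })
}

# Distribute burst amplitudes over bins: truncated-Gaussian temporal profile
# with sd = transit/5 on support +/- transit/2 around the arrival time.
burst_profile_rates <- function(arrival, amplitude, acq, n_bins) {
  bw <- acq$bin_width
  sdt <- acq$transit_time / 5
  half <- acq$transit_time / 2
  m <- ceiling(acq$transit_time / bw) + 1L
  offs <- seq(-ceiling(m / 2), ceiling(m / 2))  # bin offsets around arrival
  ctr <- floor(arrival / bw)                    # 0-based bin of arrival
  lam <- numeric(n_bins)
  norm <- stats::pnorm(half, 0, sdt) - stats::pnorm(-half, 0, sdt)
  for (j in offs) {
    lo <- pmax((ctr + j) * bw - arrival, -half)
    hi <- pmin((ctr + j + 1) * bw - arrival, half)
    w <- ifelse(hi > lo,
                (stats::pnorm(hi, 0, sdt) - stats::pnorm(lo, 0, sdt)) / norm,
                0)
    val <- amplitude * w
    bin <- ctr + j + 1L # 1-based
    ok <- which(bin >= 1L & bin <= n_bins & val > 0)
    if (length(ok)) {
      add <- rowsum(val[ok], bin[ok])
      at <- as.integer(rownames(add))
      lam[at] <- lam[at] + add[, 1]
    }
  }
  lam
}

split_species <- function(sp) {
  lapply(seq_len(nrow(sp)), function(i)
    liposome_species(sp$mean_diameter[i], sp$cv[i], sp$concentration[i],
                     sp$label_density[i]))
}

new_trace <- function(counts, acq, ground_truth = NULL) {
  structure(list(counts = as.integer(counts), bin_width = acq$bin_width,
                 duration = length(counts) * acq$bin_width, acq = acq,
                 ground_truth = ground_truth),
            class = "bas_trace")
}

#' Bin start times of a trace
#' @param trace A `bas_trace`.
#' @return Numeric vector of bin start times, s.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "bas_trace"))
  (seq_along(trace$counts) - 1) * trace$bin_width
}

#' @export
print.bas_trace <- function(x, ...) {
  cat("<bas_trace>", length(x$counts), "bins of", x$bin_width, "s;",
      "mean", format(mean(x$counts), digits = 4), "counts/bin")
  if (!is.null(x$ground_truth) && nrow(x$ground_truth))
    cat(";", nrow(x$ground_truth), "ground-truth bursts")
  cat("\n")
  invisible(x)
}
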