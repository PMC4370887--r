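#' Build a BAS histogram from detected bursts
#'
#' Bins burst amplitudes into log-spaced intensity bins and converts event
#' counts to concentrations via the burst flux calibration:
#' `C_i = n_i / (detection_rate_constant * duration)`, in pM. Each bin also
#' carries the mean amplitude of its events (`mean_intensity`, the `I_i` of
#' the fractional-intensity heat maps) and a validity flag: a bin is valid
#' when it holds at least 5 events, its measured concentration is below the
#' 500 pM single-particle limit, and the whole measurement's total measured
#' concentration is below that limit. Invalid bins are masked (flagged),
#' never zeroed.
#'
#' @param bursts A `bas_bursts` table, or a bare numeric vector of burst
#'   amplitudes.
#' @param acq The `bas_acquisition` of the measurement (provides duration
#'   and flux calibration).
#' @param edges Optional increasing vector of bin edges (burst-intensity
#'   units). Defaults to log-spaced edges covering the data at
#'   `n_per_decade` bins per decade.
#' @param n_per_decade Bins per decade for automatic edges.
#' @param dilution_factor Fold-dilution of the measured sample relative to
#'   the undiluted reaction (1 = undiluted). Stored for
#'   [merge_dilution_series()]; concentrations reported here are measured,
#'   in-cuvette values.
#' @return A `bas_histogram`: data.frame with `bin_lo`, `bin_hi`,
#'   `mean_intensity`, `concentration` (pM), `n_events`, `valid`, plus
#'   attributes `acq` and `dilution_factor`.
#' @export
build_histogram <- function(bursts, acq, edges = NULL, n_per_decade = 24,
                            dilution_factor = 1) {
  stopifnot(inherits(acq, "bas_acquisition"), dilution_factor >= 1)
  amp <- if (is.numeric(bursts)) bursts else bursts$amplitude
  amp <- amp[amp > 0]
  if (length(amp) == 0) {
    warning("no burst events; returning an all-zero histogram")
    if (is.null(edges)) edges <- log_edges(1, 10, n_per_decade)
  }
  if (is.null(edges)) edges <- log_edges(min(amp), max(amp), n_per_decade)
  stopifnot(all(diff(edges) > 0), length(edges) >= 2)
  nb <- length(edges) - 1L
  bin <- findInterval(amp, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= nb
  n_i <- tabulate(bin[inside], nbins = nb)
  mi <- rep(NA_real_, nb)
  if (any(inside)) {
    s <- rowsum(amp[inside], bin[inside])
    mi[as.integer(rownames(s))] <- s[, 1] / n_i[as.integer(rownames(s))]
  }
  conc <- n_i / (acq$detection_rate_constant * acq$duration)
  h <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                  mean_intensity = mi, concentration = conc,
                  n_events = n_i,
                  valid = n_i >= 5 & conc < 500 & sum(conc) < 500)
  structure(h, class = c("bas_histogram", "data.frame"),
            acq = acq, dilution_factor = dilution_factor)
}

#' Fraction of total events per bin
#'
#' The concentration of each bin divided by the total concentration; sums
#' to 1.
#'
#' @param h A `bas_histogram`.
#' @return Numeric vector of per-bin fractions.
#' @export
fraction_of_total <- function(h) {
  stopifnot(inherits(h, "bas_histogram"))
  tot <- sum(h$concentration)
  if (tot <= 0) stop("histogram has zero total concentration")
  h$concentration / tot
}

#' Concentrations rescaled to the undiluted sample
#'
#' @param h A `bas_histogram`.
#' @return Per-bin concentration (pM) multiplied by the dilution factor.
#' @export
undiluted_concentration <- function(h) {
  stopifnot(inherits(h, "bas_histogram"))
  h$concentration * attr(h, "dilution_factor")
}

#' Ratio of concentration-weighted mean burst intensities
#'
#' The fold difference in mean burst size between two samples, and the
#' implied diameter ratio under surface-area brightness scaling
#' (`sqrt(fold)`). A 200 nm vs 100 nm pair gives fold ~ 4; 200 nm vs a
#' 20 nm fission product gives fold ~ 100.
#'
#' @param h1,h2 `bas_histogram`s (numerator, denominator).
#' @return List with `fold` and `implied_diameter_ratio`.
#' @export
mean_intensity_ratio <- function(h1, h2) {
  m1 <- weighted_mean_intensity(h1)
  m2 <- weighted_mean_intensity(h2)
  fold <- m1 / m2
  list(fold = fold, implied_diameter_ratio = sqrt(fold))
}

weighted_mean_intensity <- function(h) {
  stopifnot(inherits(h, "bas_histogram"))
  w <- h$concentration
  ok <- w > 0 & !is.na(h$mean_intensity)
  if (!any(ok)) stop("histogram has no occupied bins")
  sum(h$mean_intensity[ok] * w[ok]) / sum(w[ok])
}

#' @export
print.bas_histogram <- function(x, ...) {
  occ <- sum(x$n_events > 0)
  cat("<bas_histogram>", nrow(x), "bins (", occ, "occupied),",
      sum(x$n_events), "events, total",
      format(sum(x$concentration), digits = 4), "pM (measured)")
  if (attr(x, "dilution_factor") != 1)
    cat(",", attr(x, "dilution_factor"), "fold diluted")
  cat("\n")
  invisible(x)
}
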