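#' Assemble a fission time course
#'
#' @param times Measurement times (minutes), strictly increasing.
#' @param histograms List of `bas_histogram`s, one per time, sharing bin
#'   edges.
#' @param temperature Optional condition label, K or degrees C.
#' @param protein_conc Optional condition label (e.g. uM fission protein).
#' @return A `bas_time_course`.
#' @export
fission_time_course <- function(times, histograms, temperature = NULL,
                                protein_conc = NULL) {
  stopifnot(length(times) == length(histograms), length(times) >= 1,
            all(diff(times) > 0),
            all(vapply(histograms, inherits, logical(1), "bas_histogram")))
  e0 <- c(histograms[[1]]$bin_lo, histograms[[1]]$bin_hi[nrow(histograms[[1]])])
  for (h in histograms[-1])
    if (!isTRUE(all.equal(c(h$bin_lo, h$bin_hi[nrow(h)]), e0)))
      stop("all histograms in a time course must share bin edges")
  structure(list(times = times, histograms = histograms,
                 temperature = temperature, protein_conc = protein_conc),
            class = "bas_time_course")
}

#' Fractional fluorescence intensity per bin
#'
#' One heat-map row: `I_i * C_i / sum_n(I_n * C_n)`, where `I_i` is the
#' mean burst intensity of bin i and `C_i` its concentration; the
#' denominator is the total fluorescence of the sample. Rows sum to 1.
#'
#' @param h A `bas_histogram`.
#' @return Numeric vector of per-bin fractional intensities.
#' @export
fractional_intensity_row <- function(h) {
  stopifnot(inherits(h, "bas_histogram"))
  ic <- ifelse(is.na(h$mean_intensity), 0, h$mean_intensity) * h$concentration
  tot <- sum(ic)
  if (tot <= 0) stop("zero total fluorescence; cannot normalize")
  ic / tot
}

#' Heat-map matrix of a time course
#'
#' Stacks [fractional_intensity_row()]s, one experiment per row, over the
#' shared log-intensity bins; suitable for rendering with a linear
#' brightness map.
#'
#' @param tc A `bas_time_course`.
#' @return Matrix (rows = times, columns = intensity bins) with row labels
#'   from the time points; each row sums to 1.
#' @export
heat_map <- function(tc) {
  stopifnot(inherits(tc, "bas_time_course"))
  m <- t(vapply(tc$histograms, fractional_intensity_row,
                numeric(nrow(tc$histograms[[1]]))))
  rownames(m) <- paste0("t=", tc$times)
  colnames(m) <- format(sqrt(tc$histograms[[1]]$bin_lo *
                               tc$histograms[[1]]$bin_hi), digits = 3)
  m
}

#' Normalized total fluorescence signal over a time course
#'
#' Per-time total `sum(I_i * C_i)` divided by the series maximum. Fission
#' redistributes membrane between objects without consuming it, so for a
#' lossless reaction this stays near 1 throughout.
#'
#' @param tc A `bas_time_course`.
#' @return Numeric vector in (0, 1], one value per time; max is exactly 1.
#' @export
total_signal_series <- function(tc) {
  stopifnot(inherits(tc, "bas_time_course"))
  tot <- vapply(tc$histograms, function(h)
    sum(ifelse(is.na(h$mean_intensity), 0, h$mean_intensity) *
          h$concentration), numeric(1))
  tot / max(tot)
}

#' Window of the smallest product bins
#'
#' Bins whose mean intensity is at most twice the modal product-bin
#' intensity, where the modal bin is the concentration-maximal bin of the
#' final histogram (products dominate by number once fission has run).
#'
#' @param tc A `bas_time_course`.
#' @return Logical vector over bins.
#' @export
product_window <- function(tc) {
  stopifnot(inherits(tc, "bas_time_course"))
  hf <- tc$histograms[[length(tc$histograms)]]
  modal <- which.max(hf$concentration)
  ctr <- sqrt(hf$bin_lo * hf$bin_hi)
  ctr <= 2 * ctr[modal]
}

#' Product-region window below a diameter-equivalent intensity cut
#'
#' Logical mask of bins whose center intensity lies below the beam-center
#' burst amplitude of an object of `max_diameter`. Unlike the modal-bin
#' window of [product_window()], this cut is fixed by instrument
#' calibration rather than by the measured distribution, and it is wide
#' enough to retain coincidence-merged product pairs; kinetic series summed
#' over it are therefore not distorted when the event rate changes over a
#' time course.
#'
#' @param tc A `bas_time_course` (or a single `bas_histogram`).
#' @param max_diameter Diameter cut, nm (default 40: twice a 20 nm product,
#'   four times its brightness, still 25-fold below a 200 nm parent).
#' @return Logical vector over bins.
#' @export
product_region <- function(tc, max_diameter = 40) {
  h <- if (inherits(tc, "bas_time_course")) tc$histograms[[1]] else tc
  stopifnot(inherits(h, "bas_histogram"))
  acq <- attr(h, "acq")
  cut <- brightness_of(max_diameter) * acq$brightness_scale *
    acq$transit_time
  sqrt(h$bin_lo * h$bin_hi) < cut
}

#' Time for the product concentration to reach its plateau
#'
#' Sums the concentration inside the product window at each time and
#' returns the first time at which it reaches `frac` of its final plateau
#' value, by linear interpolation between samples. Errors when the series
#' has not plateaued (last two values differ by more than 10%).
#'
#' @param tc A `bas_time_course`, or a data.frame with columns `time` and
#'   `value` (an already-extracted concentration series).
#' @param window Logical bin mask (see [product_window()]); defaults to
#'   `product_window(tc)`. Ignored for data.frame input.
#' @param frac Plateau fraction in (0, 1); default 0.95.
#' @return Time (same unit as `tc$times`) at which the product
#'   concentration first reaches `frac` of its plateau.
#' @export
time_to_plateau <- function(tc, window = NULL, frac = 0.95) {
  stopifnot(frac > 0, frac < 1)
  if (inherits(tc, "bas_time_course")) {
    window <- window %||% product_window(tc)
    y <- vapply(tc$histograms, function(h)
      sum(h$concentration[window]), numeric(1))
    times <- tc$times
  } else {
    stopifnot(is.data.frame(tc), all(c("time", "value") %in% names(tc)))
    times <- tc$time; y <- tc$value
  }
  n <- length(y)
  stopifnot(n >= 2)
  plateau <- y[n]
  if (plateau <= 0) stop("plateau concentration is zero")
  if (abs(y[n] - y[n - 1]) / plateau > 0.10)
    stop("product concentration has not plateaued ",
         "(last two points differ by more than 10%)")
  target <- frac * plateau
  if (y[1] >= target) return(times[1])
  k <- which(y >= target)[1]
  if (is.na(k)) stop("product concentration never reaches the target fraction")
  times[k - 1] + (times[k] - times[k - 1]) *
    (target - y[k - 1]) / (y[k] - y[k - 1])
}

#' Dose response: starting-size intensity remaining per protein dose
#'
#' For each protein concentration, the fraction of total fractional
#' intensity (heat-map row) remaining in the starting-liposome bin window,
#' defined from the reference (untreated) histogram as the bins with
#' intensity at least one twentieth of its fractional-intensity modal bin
#' (wide enough to hold the beam-factor spread of parent bursts, still an
#' order of magnitude above the ~100-fold dimmer fission products).
#'
#' @param histos List of `list(protein_conc, histogram)` pairs (histograms
#'   share bin edges with the reference).
#' @param reference The untreated starting-sample `bas_histogram`.
#' @return data.frame with `protein_conc` and `remaining` (fraction of
#'   fluorescence still in starting-size bins), ordered by dose.
#' @export
dose_response <- function(histos, reference) {
  stopifnot(inherits(reference, "bas_histogram"), is.list(histos),
            length(histos) >= 1)
  e0 <- c(reference$bin_lo, reference$bin_hi[nrow(reference)])
  row_ref <- fractional_intensity_row(reference)
  ctr <- sqrt(reference$bin_lo * reference$bin_hi)
  window <- ctr >= ctr[which.max(row_ref)] / 20
  res <- lapply(histos, function(p) {
    h <- p[[2]]
    if (!isTRUE(all.equal(c(h$bin_lo, h$bin_hi[nrow(h)]), e0)))
      stop("dose histograms must share bin edges with the reference")
    data.frame(protein_conc = p[[1]],
               remaining = sum(fractional_intensity_row(h)[window]))
  })
  out <- do.call(rbind, res)
  out[order(out$protein_conc), , drop = FALSE]
}
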