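#' Merge a dilution series of BAS histograms
#'
#' A single BAS measurement only quantifies an ~100-fold intensity window
#' inside the single-particle concentration limit; a reaction that converts
#' a few bright parents into thousands of dim products spans more than
#' that. Measuring systematic dilutions and reconciling them reconstructs
#' the full population: each histogram's concentrations are rescaled by its
#' dilution factor, per-histogram validity windows are taken from
#' [build_histogram()] flags, and the overlap between consecutive windows
#' is reconciled by a least-squares fit of complementary cumulative
#' concentration curves with one free scale per histogram, anchored to the
#' least-dilute histogram that has valid bins.
#'
#' @param series A list of `bas_histogram`s (dilution factors are read from
#'   each histogram), or a list of `list(histogram, dilution_factor)` pairs.
#'   All histograms must share bin edges.
#' @return A merged `bas_histogram` at `dilution_factor = 1` covering the
#'   union of the validity windows; per-bin concentrations are undiluted,
#'   event-weighted means of the rescaled valid contributions. The fitted
#'   per-histogram scales are attached as attribute `scales`.
#' @export
merge_dilution_series <- function(series) {
  stopifnot(is.list(series), length(series) >= 2)
  hl <- lapply(series, function(s) {
    if (inherits(s, "bas_histogram")) return(s)
    h <- s[[1]]; attr(h, "dilution_factor") <- s[[2]]; h
  })
  stopifnot(all(vapply(hl, inherits, logical(1), "bas_histogram")))
  edges0 <- c(hl[[1]]$bin_lo, hl[[1]]$bin_hi[nrow(hl[[1]])])
  for (h in hl[-1])
    if (!isTRUE(all.equal(c(h$bin_lo, h$bin_hi[nrow(h)]), edges0)))
      stop("histograms must share bin edges to be merged")
  dil <- vapply(hl, attr, numeric(1), "dilution_factor")
  ord <- order(dil)
  hl <- hl[ord]; dil <- dil[ord]
  nb <- nrow(hl[[1]])
  u <- sapply(hl, function(h) h$concentration) * rep(dil, each = nb)
  v <- sapply(hl, function(h) h$valid)
  ne <- sapply(hl, function(h) h$n_events)
  if (!any(v)) stop("no histogram in the series has valid bins")

  anchor <- which(colSums(v) > 0)[1]
  scale <- rep(NA_real_, length(hl))
  scale[anchor] <- 1
  m_conc <- ifelse(v[, anchor], u[, anchor], 0)
  m_ne <- ifelse(v[, anchor], ne[, anchor], 0)
  m_valid <- v[, anchor]
  for (j in setdiff(seq_along(hl), anchor)) {
    overlap <- m_valid & v[, j]
    if (!any(overlap)) {
      stop("no valid-bin overlap between the histogram at dilution ", dil[j],
           " and the rest of the series; gap between intensities ",
           format(hl[[1]]$bin_hi[max(which(m_valid))], digits = 3), " and ",
           format(hl[[1]]$bin_lo[which(v[, j])[1]], digits = 3))
    }
    # complementary cumulative concentration over the overlapping bins
    Fa <- rev(cumsum(rev(m_conc * overlap)))
    Fj <- rev(cumsum(rev(u[, j] * overlap)))
    scale[j] <- sum(Fa * Fj) / sum(Fj^2)
    add <- v[, j]
    num <- m_conc * m_ne + ifelse(add, scale[j] * u[, j] * ne[, j], 0)
    den <- m_ne + ifelse(add, ne[, j], 0)
    m_conc <- ifelse(den > 0, num / pmax(den, 1), 0)
    m_ne <- den
    m_valid <- m_valid | add
  }
  # bins valid nowhere are masked, not zeroed: fall back to the
  # event-weighted mean of all (rescaled) contributions there
  su <- sweep(u, 2, scale, `*`)
  fallback <- rowSums(su * ne) / pmax(rowSums(ne), 1)
  m_conc <- ifelse(m_valid, m_conc, fallback)
  n_tot <- rowSums(ne)
  mi <- rowSums(sapply(hl, function(h)
    ifelse(is.na(h$mean_intensity), 0, h$mean_intensity) * h$n_events)) /
    pmax(n_tot, 1)
  mi[n_tot == 0] <- NA_real_
  out <- data.frame(bin_lo = hl[[1]]$bin_lo, bin_hi = hl[[1]]$bin_hi,
                    mean_intensity = mi, concentration = m_conc,
                    n_events = n_tot, valid = m_valid)
  structure(out, class = c("bas_histogram", "data.frame"),
            acq = attr(hl[[anchor]], "acq"), dilution_factor = 1,
            scales = scale, dilutions = dil)
}
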