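#' Multi-tau intensity autocorrelation
#'
#' Computes `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on a quasi-log lag grid:
#' the first `2 m` lags at the native bin width, then `m` lags per octave
#' on successively pair-coarsened copies of the trace (the standard
#' multi-tau scheme, default 16 lags per octave). Per-lag uncertainties are
#' estimated by splitting the trace into contiguous segments and taking the
#' standard error of the per-segment estimates (block bootstrap).
#'
#' @param trace A `bas_trace`.
#' @param max_lag Largest lag, s. The trace must be at least 10x longer.
#' @param m Lags per octave.
#' @param n_segments Segments for the uncertainty estimate.
#' @return An `fcs_curve` data.frame with `lag` (s), `G`, `sigma` and
#'   `n_pairs`.
#' @export
autocorrelate <- function(trace, max_lag = NULL, m = 16, n_segments = 10) {
  stopifnot(inherits(trace, "bas_trace"))
  x <- as.numeric(trace$counts)
  bw <- trace$bin_width
  max_lag <- max_lag %||% (trace$duration / 20)
  if (trace$duration < 10 * max_lag)
    stop("trace must be at least 10x longer than max_lag")
  if (stats::var(x) == 0) stop("constant trace has no fluctuations to correlate")
  lags <- multitau_lags(max_lag / bw, m)
  G <- correlate_at(x, lags)
  seg <- split(x, cut(seq_along(x), n_segments, labels = FALSE))
  ns <- sum(lags < min(lengths(seg)) / 4)
  sigma <- rep(NA_real_, length(lags))
  if (ns > 0) {
    gseg <- vapply(seg, function(s) correlate_at(s, lags[seq_len(ns)])$G,
                   numeric(ns))
    sigma[seq_len(ns)] <- apply(matrix(gseg, nrow = ns), 1, stats::sd) /
      sqrt(n_segments)
  }
  structure(data.frame(lag = lags * bw, G = G$G, sigma = sigma,
                       n_pairs = G$n_pairs),
            class = c("fcs_curve", "data.frame"))
}

multitau_lags <- function(max_lag_bins, m) {
  lags <- 1:(2 * m)
  k <- 2L
  while (max(lags) < max_lag_bins) {
    lags <- c(lags, (m + 1):(2 * m) * k)
    k <- k * 2L
  }
  unique(lags[lags <= max_lag_bins])
}

# Direct correlation estimator at integer lags (in bins).
correlate_at <- function(x, lags) {
  n <- length(x)
  res <- vapply(lags, function(k) {
    a <- x[1:(n - k)]; b <- x[(k + 1):n]
    c(mean(a * b) / (mean(a) * mean(b)) - 1, n - k)
  }, numeric(2))
  list(G = res[1, ], n_pairs = res[2, ])
}

#' Fit a single-component 3D diffusion model to an FCS curve
#'
#' Least-squares fit of
#' `G(tau) = G0 / ((1 + tau/tau_D) * sqrt(1 + tau/(kappa^2 tau_D)))`,
#' the free 3D diffusion model for a Gaussian observation volume with
#' structure parameter kappa (fixed, not fitted: single curves constrain it
#' poorly). Points are weighted by `1/sigma^2` where available. Polydisperse
#' samples yield an average diffusion time.
#'
#' @param curve An `fcs_curve`.
#' @param kappa Structure parameter (axial/lateral), fixed.
#' @return An `fcs_fit`: list with `G0`, `tau_D` (s), `kappa`,
#'   `residual_norm` and the `nls` fit object.
#' @export
fit_diffusion <- function(curve, kappa = 5) {
  stopifnot(inherits(curve, "fcs_curve"), kappa >= 1)
  df <- curve[is.finite(curve$G), , drop = FALSE]
  stopifnot(nrow(df) >= 5)
  g0_init <- max(mean(df$G[1:3]), 1e-6)
  below <- which(df$G < g0_init / 2)
  tau_init <- if (length(below)) df$lag[below[1]] else stats::median(df$lag)
  s <- df$sigma
  if (any(is.finite(s) & s > 0)) {
    s[!is.finite(s) | s <= 0] <- max(s[is.finite(s) & s > 0])
    w <- 1 / s^2
  } else w <- rep(1, nrow(df))
  fit <- try(minpack.lm::nlsLM(
    G ~ G0 / ((1 + lag / tauD) * sqrt(1 + lag / (kappa^2 * tauD))),
    data = df, start = list(G0 = g0_init, tauD = tau_init),
    weights = w, lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("diffusion fit did not converge: ", attr(fit, "condition")$message)
  p <- stats::coef(fit)
  if (p[["tauD"]] <= min(df$lag) || p[["tauD"]] >= max(df$lag))
    warning("fitted tau_D lies at the lag-grid boundary")
  structure(list(G0 = unname(p[["G0"]]), tau_D = unname(p[["tauD"]]),
                 kappa = kappa,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fit = fit),
            class = "fcs_fit")
}

#' Expected diffusion time from Stokes-Einstein
#'
#' `tau_D = w0^2 / (4 D)` with `D = kB T / (6 pi eta r_h)`.
#'
#' @param radius_nm Hydrodynamic radius, nm.
#' @param acq A `bas_acquisition` (beam waist, temperature, viscosity).
#' @return Diffusion time, s.
#' @export
expected_tau_d <- function(radius_nm, acq) {
  D <- .kB * acq$temperature / (6 * pi * acq$viscosity * radius_nm * 1e-9)
  (acq$beam_waist * 1e-9)^2 / (4 * D)
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit> G0 =", format(x$G0, digits = 4),
      " tau_D =", format(x$tau_D * 1e3, digits = 4), "ms",
      " kappa =", x$kappa, "\n")
  invisible(x)
}
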