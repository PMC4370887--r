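#' Simulate an FCS intensity trace of freely diffusing liposomes
#'
#' Particles perform 3D Brownian motion through a Gaussian observation
#' volume (lateral waist `w0`, axial extent `kappa * w0`), with per-particle
#' diffusion coefficients from Stokes-Einstein,
#' `D = kB T / (6 pi eta r_h)` with hydrodynamic radius `r_h = d/2`. The
#' detected rate is the brightness-weighted sum of the Gaussian volume
#' factor over particles; counts per bin are Poisson. The resulting
#' autocorrelation decays on the diffusion time `tau_D = w0^2 / (4 D)` and
#' has amplitude `G(0) ~= 1/N` for `N` particles in the effective volume
#' `pi^(3/2) w0^2 z0`.
#'
#' Particles move in a periodic box of 8 w0 x 8 w0 x 8 z0 centered on the
#' beam, large enough that the volume factor is negligible at the faces and
#' that the discrete fluctuation modes of the periodic box approximate free
#' diffusion over the fitted lag range. The particle count in the box is
#' fixed at its mean, which suppresses `G0` by about `V_eff/V_box` (~1%);
#' concentrations should be in the nM range for order-unity occupancies.
#'
#' @param pop A `bas_population` (species-only populations are sampled as
#'   needed to populate the box).
#' @param acq A `bas_acquisition` with `transit_mode = "diffusion"`; finite
#'   `temperature` and `viscosity` are required (`viscosity = Inf` gives
#'   immobile particles).
#' @param seed Integer seed (or NULL).
#' @return A `bas_trace` (no burst ground truth); the attached attribute
#'   `n_expected` is the mean particle number in the effective volume.
#' @export
simulate_fcs_trace <- function(pop, acq, seed = NULL) {
  stopifnot(inherits(pop, "bas_population"), inherits(acq, "bas_acquisition"))
  if (acq$transit_mode != "diffusion")
    stop("simulate_fcs_trace requires transit_mode = 'diffusion'")
  if (is.null(acq$temperature) || is.null(acq$viscosity) ||
      is.na(acq$temperature) || is.na(acq$viscosity))
    stop("temperature and viscosity are required for diffusion simulation")
  conc <- total_concentration(pop)
  stopifnot(conc > 0)
  w0 <- acq$beam_waist * 1e-9          # m
  z0 <- acq$psf_aspect * w0
  Lxy <- 8 * w0
  Lz <- 8 * z0
  box_m3 <- Lxy^2 * Lz
  n_box <- max(2L, round(conc * 1e-12 * 6.02214076e23 * box_m3 * 1e3))
  n_bins <- as.integer(round(acq$duration / acq$bin_width))

  with_seed(seed, {
    src <- if (!is.null(pop$particles)) pop$particles
           else sample_population(split_species(pop$species),
                                  max(n_box, 1000L))$particles
    pick <- sample.int(nrow(src), n_box, replace = TRUE)
    diam <- src$diameter[pick]
    bright <- src$brightness[pick]
    D <- if (is.infinite(acq$viscosity)) rep(0, n_box)
         else .kB * acq$temperature /
           (6 * pi * acq$viscosity * (diam / 2) * 1e-9) # m^2/s
    sd_step <- sqrt(2 * D * acq$bin_width)
    rate <- numeric(n_bins)
    for (i in seq_len(n_box)) {
      x <- wrap_walk(n_bins, Lxy, sd_step[i])
      y <- wrap_walk(n_bins, Lxy, sd_step[i])
      z <- wrap_walk(n_bins, Lz, sd_step[i])
      rate <- rate + bright[i] *
        exp(-2 * (x^2 + y^2) / w0^2 - 2 * z^2 / z0^2)
    }
    counts <- stats::rpois(n_bins, rate * acq$brightness_scale * acq$bin_width)
    tr <- new_trace(counts, acq)
    attr(tr, "n_expected") <- conc * 1e-12 * 6.02214076e23 *
      pi^1.5 * w0^2 * z0 * 1e3
    tr
  })
}

# One periodic-box coordinate trajectory, centered on 0.
wrap_walk <- function(n, L, sd_step) {
  x0 <- stats::runif(1, 0, L)
  if (sd_step == 0) return(rep(x0 - L / 2, n))
  ((x0 + cumsum(c(0, stats::rnorm(n - 1, 0, sd_step)))) %% L) - L / 2
}
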