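#' Acquisition parameters for a BAS or FCS measurement
#'
#' Bundles the instrument model: time binning, burst flux calibration,
#' background, beam geometry and (for FCS) solution conditions. Defaults
#' describe a stage-scanned confocal instrument whose single-particle
#' envelope matches the < 500 pM concentration limit: at the default
#' detection rate constant a 500 pM sample produces a ~5% burst duty cycle,
#' so coincidence losses stay small below the limit and grow above it.
#'
#' @param bin_width Time bin of the photon-count trace, s.
#' @param duration Trace length, s.
#' @param detection_rate_constant Burst flux calibration, bursts s^-1 pM^-1
#'   (instrument-specific; converts burst rate to concentration).
#' @param background_rate Background count rate, counts/s.
#' @param brightness_scale Peak count rate at beam center per unit
#'   brightness, counts s^-1 per [brightness_of()] unit.
#' @param transit_time Scan-dominated transit time through the beam, s.
#' @param transit_mode `"scan"` (stage-scanned, fixed transit) or
#'   `"diffusion"` (free Brownian motion, for FCS).
#' @param psf_aspect Structure parameter kappa = axial/lateral extent of the
#'   observation volume (>= 1).
#' @param beam_waist Lateral 1/e^2 beam waist, nm.
#' @param temperature Solution temperature, K (used by FCS).
#' @param viscosity Solvent viscosity, Pa s (used by FCS; `Inf` freezes
#'   diffusion).
#' @param seed Default integer seed attached to the acquisition (may be
#'   overridden per call).
#' @return An object of class `bas_acquisition`.
#' @examples
#' acquisition_params(duration = 10)
#' @export
acquisition_params <- function(bin_width = 1e-4,
                               duration = 60,
                               detection_rate_constant = 0.25,
                               background_rate = 5000,
                               brightness_scale = 3500,
                               transit_time = 2.5e-4,
                               transit_mode = c("scan", "diffusion"),
                               psf_aspect = 5,
                               beam_waist = 300,
                               temperature = 296,
                               viscosity = 0.93e-3,
                               seed = NULL) {
  transit_mode <- match.arg(transit_mode)
  stopifnot(bin_width > 0, duration > 0, detection_rate_constant > 0,
            background_rate > 0, brightness_scale > 0, transit_time > 0,
            psf_aspect >= 1, beam_waist > 0)
  structure(list(bin_width = bin_width, duration = duration,
                 detection_rate_constant = detection_rate_constant,
                 background_rate = background_rate,
                 brightness_scale = brightness_scale,
                 transit_time = transit_time, transit_mode = transit_mode,
                 psf_aspect = psf_aspect, beam_waist = beam_waist,
                 temperature = temperature, viscosity = viscosity,
                 seed = seed),
            class = "bas_acquisition")
}

#' First-order fission parameters
#'
#' Parent liposomes convert with first-order rate constant `rate_constant`
#' into smaller products. In `direct` mode a converted parent of diameter D
#' is replaced by products drawn at `product_mean_diameter` (+/- cv), with
#' the product count chosen so total membrane surface area is conserved to
#' within half a product's area. In `cascade` mode each completed step
#' halves membrane area (D -> D/sqrt(2) per daughter) and steps repeat until
#' daughters are at or below `product_mean_diameter`, so intermediate sizes
#' populate at intermediate times.
#'
#' @param rate_constant First-order conversion rate k, per unit time (the
#'   same time unit used in [evolve_fission()]'s `t`).
#' @param product_mean_diameter Product mean diameter, nm.
#' @param product_cv Product diameter coefficient of variation.
#' @param mode `"direct"` or `"cascade"`.
#' @param label_bias Multiplier on product label density; 1 means unbiased
#'   partitioning of the fluorescent label at fission (values != 1 break
#'   brightness conservation and exist only as a sensitivity knob).
#' @return An object of class `bas_fission_params`.
#' @export
fission_params <- function(rate_constant, product_mean_diameter = 20,
                           product_cv = 0.3, mode = c("direct", "cascade"),
                           label_bias = 1) {
  mode <- match.arg(mode)
  stopifnot(rate_constant >= 0, product_mean_diameter > 0, product_cv >= 0,
            label_bias > 0)
  structure(list(rate_constant = rate_constant,
                 product_mean_diameter = product_mean_diameter,
                 product_cv = product_cv, mode = mode,
                 label_bias = label_bias),
            class = "bas_fission_params")
}

# Gaussian-beam amplitude factor exp(-2 b^2 / w0^2) at a uniformly random
# impact parameter b in [0, 1.5 w0]. Particles passing the beam off-axis
# yield proportionally dimmer bursts.
sample_beam_factor <- function(n, acq) {
  b <- stats::runif(n, 0, 1.5 * acq$beam_waist)
  exp(-2 * (b / acq$beam_waist)^2)
}
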