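---
title: "Burst analysis spectroscopy of liposome fission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst analysis spectroscopy of liposome fission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basr)
```

## The measurement problem

Membrane fission converts a small number of large, bright vesicles into a
large number of small, dim ones. Bulk fluorescence is nearly blind to this:
the total amount of labeled membrane is unchanged, so the integrated signal
moves by only a few percent even when the particle count grows 100-fold.
Burst analysis spectroscopy (BAS) resolves the change at the single-particle
level: labeled liposomes in free solution transit a confocal detection
volume one at a time, each producing a photon burst whose amplitude reports
the particle's brightness and whose arrival rate reports the particle
concentration.

Two scaling laws carry all the information. For membrane-labeled vesicles
of diameter $d$, brightness is proportional to surface area,

$$ B(d) = \rho \,\pi d^2 , $$

so 200, 100 and 50 nm liposomes sit 1 : 1/4 : 1/16 in mean burst intensity,
and a 20 nm fission product is ~100-fold dimmer than its 200 nm parent.
Conversely, fission of one 200 nm liposome into 20 nm vesicles conserves
area, so it produces $ (200/20)^2 = 100 $ products: a 100-fold concentration
increase paired with a 100-fold amplitude decrease. The package's
simulators, detectors and reconstruction steps exist to recover exactly
these signatures, with known ground truth.

## Synthetic populations and ground truth

Liposome species are parameterized by mean diameter, coefficient of
variation (CV), concentration (pM) and label density. Diameters are drawn
from a normal distribution truncated at zero (the extrusion literature
quotes only means and CVs, not a family; the truncated normal is the
conventional minimal choice). `sample_population()` allocates particles to
mixture components in proportion to concentration and attaches per-particle
brightness.

`evolve_fission()` implements first-order conversion: after time $t$ a
fraction $1 - e^{-kt}$ of parents has reacted. Two product-generation modes
bracket the unknown mechanism:

* **direct** — a converted parent of diameter $D$ is replaced by products
  drawn at the product mean $\pm$ CV; products are accepted greedily until
  the parent's area budget $D^2$ is spent, with a final product kept when
  the remainder covers at least half of it. The discarded remainder is
  therefore below half a product's area, which keeps total brightness
  conserved to well within 0.5% at the population level. With zero product
  CV the count is exactly $\lfloor D^2/D_p^2 \rfloor$ (100 for 200 to
  20 nm).
* **cascade** — repeated area-halving: each completed step replaces a
  vesicle by two daughters of diameter $D/\sqrt 2$. The number of completed
  steps per lineage by time $t$ is drawn as $\min(\mathrm{Poisson}(kt),
  g_{\max})$, where $g_{\max}$ is the generation at which daughters reach
  the product size. The fraction with at least one split is again
  $1-e^{-kt}$, and intermediate sizes populate at intermediate times. This
  lineage-level approximation (all daughters of a lineage share a split
  count) conserves area exactly and is documented here because a fully
  daughter-resolved branching process would only approximately share its
  marginal distribution.

Label partitioning at fission is unbiased by default; a `label_bias`
multiplier exists as a sensitivity knob and intentionally breaks
conservation when moved.

## The instrument model

`simulate_trace()` renders time-binned photon counts. Burst arrivals are a
Poisson process with rate $rC$ ($r$ the detection rate constant in bursts
s$^{-1}$ pM$^{-1}$, $C$ the total concentration). Each burst takes a
particle from the population, an impact parameter $b$ uniform on $[0,\,
1.5\,w_0]$, and contributes counts with amplitude $B \cdot s \cdot \tau_t
\cdot e^{-2b^2/w_0^2}$ spread over the transit time with a truncated
Gaussian temporal profile. Background and signal counts are Poisson per
bin. Coincident arrivals sum in the trace while the attached ground truth
keeps them separate, so the detector's coincidence error is measurable.

The defaults describe a stage-scanned instrument whose numbers were chosen
once, as a self-consistent design, around the single-particle limit:

| parameter | default | why |
|---|---|---|
| bin width | 0.1 ms | resolves the transit with 2–3 bins |
| transit time | 0.25 ms | scan-speed dominated; sets the coincidence window |
| detection rate constant | 0.25 bursts s$^{-1}$ pM$^{-1}$ | at 500 pM the burst duty cycle is ~5%, so counting is linear below the limit and visibly sub-linear above it |
| background rate | 5000 cps | 0.5 counts/bin, enough that a $5\sigma$ threshold is meaningful on discrete Poisson counts (false positives $\ll$ 1/min) |
| brightness scale | 3500 cps per unit | keeps even 20 nm products detectable at the beam edge, so detected amplitude means are not truncation-biased |
| beam waist / aspect | 300 nm, $\kappa = 5$ | typical confocal geometry |

The choices interlock: a longer transit or higher rate constant would make
bursts pile up at a few hundred pM and break the linearity the method
relies on; a dimmer brightness scale would censor the dim tail of product
bursts and inflate their mean amplitude.

## Burst detection and histograms

`estimate_background()` rebins the trace so the expected background per
interval is about 10 counts (using a burst-resistant trimmed mean to choose
the factor), then sigma-clips at $3\sigma$ with Poisson $\sigma=\sqrt\mu$
until stable. Traces in which the clip discards most bins are rejected with
advice to dilute. `detect_bursts()` thresholds at background $+\,k_\sigma
\sigma$ per bin (default $k_\sigma = 5$, standard burst-search practice),
merges runs separated by at most one bin, discards runs shorter than two
bins, and integrates background-subtracted counts as the amplitude; a bin
exactly at threshold is excluded.

`build_histogram()` maps burst counts to concentrations through the flux
calibration, $C_i = n_i/(r\,T)$, on log-spaced bins (24 per decade by
default; the binning is not prescribed by the method and only needs to
resolve the CV-driven width of each population). A bin is flagged valid
when it holds at least 5 events, its measured concentration is below
500 pM, and the whole measurement's total measured concentration is below
500 pM. The last clause is the single-particle limit as an instrument
envelope: it applies to the cuvette contents at measurement time, which is
why a dilution series can make every part of a wide distribution valid
somewhere even though no single measurement can.

## Dilution-series merging

A reaction that turns ~100 pM of parents into ~10,000 pM of products cannot
be measured at one dilution. `merge_dilution_series()` rescales each
histogram by its dilution factor, anchors on the least-dilute histogram
with valid bins, fits one free scale per additional histogram by least
squares on complementary cumulative concentrations over the shared valid
bins, and averages valid contributions weighted by event count. Bins valid
nowhere keep the event-weighted average of all contributions but stay
flagged invalid (masked, not zeroed). The authors' own simultaneous-fitting
procedure is unpublished; this stitching is one defensible realization and
is validated against simulator ground truth only.

## Polydispersity inference

`estimate_cv()` matches the measured burst-intensity CDF against Monte
Carlo templates drawn from the same generative model the simulator uses:
truncated-normal diameters, $B \propto d^2$, and the beam-factor
distribution taken from the histogram's acquisition metadata. Omitting the
beam factor would be wrong here: the measured amplitudes are convolved with
it, and a template lacking it has a visibly narrower shape at every CV. The
distance is the Kolmogorov–Smirnov statistic evaluated at the bin edges
(binning-insensitive at 24 bins/decade), and all grid points share one
random stream, so scores vary smoothly across the grid and the argmin is
stable. Self-consistency (recovering the generating CV on-grid) holds
reliably from $10^4$ events; the package uses $3\times10^4$ data draws and
$10^5$ template draws in its acceptance runs.

## Kinetics, heat maps and dose response

A fission time course is a list of histograms on shared bin edges.
Heat-map rows are fractional intensities
$I_i C_i / \sum_n I_n C_n$ — each row sums to 1 by construction, and the
total $\sum_n I_n C_n$, normalized to its series maximum, tracks
conservation of fluorescent material through the reaction.

`time_to_plateau()` sums the concentration in a product window, takes the
final value as the plateau, and reports the first time the series reaches
95% of it by linear interpolation. On a noiseless first-order curve this
reproduces $\ln(20)/k$ to better than 1%. Two windows are provided.
`product_window()` (bins within twice the modal product-bin intensity of
the final histogram) describes the smallest products, but its cut lands in
the middle of the measured amplitude distribution, and coincidence-merged
product pairs migrate across it as the event rate changes — which bends
each course's normalized curve by a percent or two, more than the flat 95%
crossing tolerates. Kinetic series are therefore summed over
`product_region()`: every bin dimmer than a beam-center 40 nm object, a
calibration-anchored cut that retains merged pairs.

The 95% crossing sits where the curve is flat, so its variance is
dominated by two stochastic terms that were sized by explicit variance
decomposition: counting noise (set by trace length) and the membrane-area
fluctuation of the randomly converted parent subset (set by the number of
sampled parents). The kinetics scenarios use 1200 s measurements (~10^5
product bursts per time point) and 30000 sampled parents. The time grid —
0, 7.5, 15, 26, 34, 52, 68, 180 min — is chosen so that (i) each course's
95% crossing falls mid-segment rather than on a grid point, (ii) the two
crossing segments are self-similar (the fast course's [26, 34] maps onto
the slow course's [52, 68] under the 2-fold rate change), which makes the
convexity bias of linear interpolation cancel exactly in the plateau-time
ratio, and (iii) the final point lies deep in both plateaus so the target
level has converged. The scenario rate constants, $k_{23} = \ln(20)/60
\approx 0.05\,\mathrm{min}^{-1}$ and $k_{37} = 2k_{23}$, are design
choices that place the product plateaus at ~60 and ~30 min.

`dose_response()` reports, per protein concentration, the fraction of
total fractional intensity remaining in the starting-liposome window,
defined from the untreated reference as bins within a factor 20 of its
fractional-intensity mode. The window is deliberately wide: the
impact-parameter factor smears parent bursts over more than a decade, and
a narrow window would count that smear as apparent fission; a factor 20
still sits an order of magnitude above the ~100-fold dimmer products.

## FCS

`simulate_fcs_trace()` propagates particles by Brownian motion through a
3D Gaussian observation volume with Stokes–Einstein diffusion coefficients,
in a periodic box of $8w_0 \times 8w_0 \times 8\kappa w_0$. The box size
matters: smaller boxes truncate long-wavelength concentration modes and fix
the particle number too tightly, which measurably depresses $G(0)$ and
accelerates the apparent decay (about 10% in a $4\times$ box, a few percent
at $8\times$). The particle count is fixed at the box mean, which
suppresses $G(0)$ by about $V_{\mathrm{eff}}/V_{\mathrm{box}} \approx 1\%$.
Simulated FCS samples sit in the nM range so the observation volume holds
order-unity particle numbers.

`autocorrelate()` is a standard multi-tau estimator (16 lags per octave),
with per-lag uncertainties from contiguous-segment block bootstrap.
`fit_diffusion()` fits the single-component 3D model

$$ G(\tau) = \frac{G_0}{(1+\tau/\tau_D)\sqrt{1+\tau/(\kappa^2\tau_D)}} $$

with $\kappa$ fixed from acquisition metadata (single curves constrain it
poorly) and weights $1/\sigma^2$. Polydisperse samples yield an average
$\tau_D$, used as a population-level size indicator only — the method's own
argument for BAS is precisely that intensity scales with $d^2$ while
diffusion is only linear in $d$.

## What the synthetic data do and do not show

The generator reproduces the features the analysis depends on: Poisson
burst statistics, surface-area brightness, beam-geometry amplitude spread,
shot noise, coincidence, and area-conserving fission. It omits
photophysics (bleaching, blinking, triplets), multilamellarity (beyond a
brightness multiplier), instrument drift, and any point-spread-function
structure beyond the Gaussian factor. Passing tests therefore demonstrate
that the analysis chain is internally correct and sensitive at the claimed
scales — not that a specific real instrument is calibrated; on real data
the detection rate constant and brightness scale must come from standards.

## Numerical choices and degenerate inputs

* Seeds: every simulator takes an explicit seed and restores the caller's
  RNG state; equal seeds give byte-identical outputs.
* Thresholding uses strict inequality; a bin exactly at threshold never
  extends a burst.
* `estimate_background()` returns (0, 0) for all-zero traces; empty burst
  lists give all-zero histograms with a warning; zero-concentration
  populations give background-only traces.
* Histogram merging requires shared bin edges and at least one valid-bin
  overlap between dilutions; gaps are reported with the offending
  intensity range.
* `time_to_plateau()` refuses series whose last two points differ by more
  than 10% (no plateau) and series whose plateau is zero.
* The direct-mode product count uses floor semantics for zero product CV,
  so the 100-fold count claim is exact, not approximate.

## Problem sizes

The shipped tests and analysis scripts use 60 s traces at ~100 pM (~1500
bursts) for scaling checks, 10–30 s traces for unit tests, 1200 s per time point
for the kinetics ratio, and 25–50 s FCS traces at 2–8 nM. These sizes
were chosen so that every stochastic check has a comfortable margin between
its expected statistical spread and its tolerance.
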