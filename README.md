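# basr — burst analysis spectroscopy of liposome populations

`basr` implements burst analysis spectroscopy (BAS), a single-particle,
free-solution fluorescence method for following membrane fission, together
with the synthetic data needed to validate it end to end. Membrane-labeled
liposomes transiting a confocal detection volume produce photon bursts;
burst **amplitude** reports particle surface area (brightness
`B = rho * pi * d^2`), burst **rate** reports particle concentration. When
a fission-active protein converts ~200 nm liposomes into ~20 nm vesicles,
area conservation predicts a ~100-fold rise in object count paired with a
~100-fold drop in mean burst size — signatures that bulk fluorescence
cannot see (total signal moves by only 10–20%).

The package is aimed at single-molecule/membrane-biophysics users who want
to prototype, test or teach the analysis chain:

* **Simulation with ground truth** — polydisperse liposome populations
  (truncated-normal diameters), first-order fission (`direct` and
  area-halving `cascade` modes, both conserving membrane area),
  photon-count traces with Poisson shot noise, Gaussian-beam amplitude
  factors and coincidence, and Brownian-dynamics FCS traces.
* **Burst analysis** — robust background estimation, threshold burst
  search, BAS histograms (`C_i = n_i / (r T)` in pM per log intensity
  bin), dilution-series merging for distributions wider than one
  measurement's window, and Monte Carlo template matching for population
  CV.
* **Kinetics** — time courses, fractional-intensity heat maps
  (`I_i C_i / sum I_n C_n`), total-signal conservation, plateau times and
  dose response.
* **FCS** — multi-tau autocorrelation and single-component 3D diffusion
  fits, `G(tau) = G0 / ((1 + tau/tau_D) sqrt(1 + tau/(kappa^2 tau_D)))`,
  with Stokes–Einstein expectations for cross-checks.

## Worked example

Simulate 200 nm and 100 nm standards, detect bursts, and compare mean
burst intensities:

```r
library(basr)
acq <- acquisition_params(duration = 60)      # 60 s trace, 0.1 ms bins
edges <- basr:::default_edges(acq, 15, 400)

hist_of <- function(d, seed) {
  pop <- sample_population(liposome_species(d, cv = 0.35,
                                            concentration = 100),
                           20000, seed = seed)
  tr <- simulate_trace(pop, acq, seed = seed + 1)
  build_histogram(detect_bursts(tr), acq, edges = edges)
}
h200 <- hist_of(200, 1); h100 <- hist_of(100, 2)
sum(h200$concentration)                  # ~100 pM recovered
mean_intensity_ratio(h200, h100)$fold    # ~4 (surface-area scaling)
```

Printed output from this session:

```
> sum(h200$concentration)
[1] 96.13333
> mean_intensity_ratio(h200, h100)$fold
[1] 3.81213
```

96.1 pM against a simulated 100 pM (burst counting is linear below the
~500 pM single-particle limit) and a 3.8-fold intensity ratio against the
ideal 4: the 200 nm standard is four times brighter because it carries four
times the membrane area.

The end-to-end scenarios live in `analysis/01_size_standards.R` …
`analysis/05_fcs.R`; each is a thin driver over the package that prints
what it found and writes tables under `results/`.

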