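# Shared fixtures: short acquisitions keep single tests fast; longer traces
# are reserved for the acceptance suite.

acq_short <- function(duration = 10, ...) {
  acquisition_params(duration = duration, ...)
}

acq_fcs <- function(duration = 10, ...) {
  acquisition_params(bin_width = 5e-5, duration = duration,
                     transit_mode = "diffusion", ...)
}

# A monodisperse-ish sampled population at a given size and concentration.
pop_of <- function(diameter, cv = 0.35, conc = 100, n = 5000, seed = 1) {
  sample_population(liposome_species(diameter, cv, conc), n, seed = seed)
}

# Background-only trace: effectively zero concentration.
background_trace <- function(acq = acq_short(), seed = 1) {
  simulate_trace(pop_of(100, conc = 1e-9, n = 10, seed = seed), acq,
                 seed = seed)
}

# A noiseless trace with hand-placed square pulses on a flat background,
# for exact amplitude checks.
pulse_trace <- function(base, pulses, acq = acq_short(duration = 1)) {
  n <- round(acq$duration / acq$bin_width)
  counts <- rep(base, n)
  for (p in pulses) counts[p$at + seq_len(p$width) - 1L] <-
      base + p$height
  basr_trace <- basr:::new_trace(counts, acq)
  basr_trace
}
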