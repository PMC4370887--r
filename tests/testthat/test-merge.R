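test_that("merging an identical pair at dilution 1 is idempotent", {
  acq <- acq_short(duration = 30)
  amps <- sample_burst_amplitudes(liposome_species(100, 0.3, 100), 2000,
                                  acq, seed = 1)
  h <- build_histogram(amps, acq)
  m <- merge_dilution_series(list(h, h))
  expect_equal(m$concentration, h$concentration)
  expect_equal(m$valid, h$valid)
})

test_that("dilution factors rescale measured concentrations linearly", {
  acq <- acq_short(duration = 30)
  amps <- sample_burst_amplitudes(liposome_species(100, 0.3, 8), 2000,
                                  acq, seed = 2)
  h <- build_histogram(amps, acq, dilution_factor = 10)
  expect_equal(sum(undiluted_concentration(h)), 10 * sum(h$concentration))
  # a measured 8 pM histogram at 10x dilution implies 80 pM undiluted
  h8 <- build_histogram(rep(50, 120), acq_short(duration = 120 / 0.25 / 8),
                        edges = c(10, 100), dilution_factor = 10)
  expect_equal(h8$concentration, 8)
  expect_equal(undiluted_concentration(h8), 80)
})

test_that("a partially fissioned mixture is recovered within 15% from a
           1x/10x dilution pair", {
  acq <- acq_short(duration = 60)
  edges <- basr:::default_edges(acq)
  pop <- sample_population(liposome_species(200, 0.35, 100), 2000, seed = 3)
  fp <- fission_params(0.1, 20, 0.3, "direct")
  # ~4% conversion keeps the undiluted measurement inside the
  # single-particle envelope while the 10x refines the products
  mix <- evolve_fission(pop, fp, t = 0.35, seed = 4)
  truth_parent <- sum(mix$particles$diameter > 100) * mix$particle_conc
  truth_prod <- sum(mix$particles$diameter < 100) * mix$particle_conc
  series <- lapply(c(1, 10), function(dl)
    basr:::measure_sample(mix, acq, edges, dilution = dl,
                          seed = 40 + dl)$histogram)
  m <- merge_dilution_series(series)
  ctr <- sqrt(m$bin_lo * m$bin_hi)
  # product bursts stay below ~ the amplitude of a beam-center 40 nm object
  cut <- brightness_of(40) * acq$brightness_scale * acq$transit_time
  expect_equal(sum(m$concentration), truth_parent + truth_prod,
               tolerance = 0.15)
  expect_equal(sum(m$concentration[ctr < cut]), truth_prod,
               tolerance = 0.15)
})

test_that("series without overlapping valid windows are rejected", {
  acq <- acq_short(duration = 30)
  edges <- c(1, 10, 100, 1000, 10000)
  h_lo <- build_histogram(runif(500, 1, 9), acq, edges = edges,
                          dilution_factor = 1)
  h_hi <- build_histogram(runif(500, 1001, 9000), acq, edges = edges,
                          dilution_factor = 10)
  expect_error(merge_dilution_series(list(h_lo, h_hi)), "overlap")
})

test_that("mismatched bin edges cannot be merged", {
  acq <- acq_short()
  h1 <- build_histogram(runif(100, 1, 9), acq, edges = c(1, 3, 10))
  h2 <- build_histogram(runif(100, 1, 9), acq, edges = c(1, 5, 10))
  expect_error(merge_dilution_series(list(h1, h2)), "share bin edges")
})
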