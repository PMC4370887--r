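test_that("histogram concentrations recover the simulated concentration", {
  acq <- acq_short(duration = 30)
  tr <- simulate_trace(pop_of(100, conc = 100, n = 10000, seed = 2), acq,
                       seed = 41)
  h <- build_histogram(detect_bursts(tr), acq)
  expect_equal(sum(h$concentration), 100, tolerance = 0.08)
})

test_that("an empty burst list yields an all-zero histogram with a warning", {
  acq <- acq_short()
  expect_warning(h <- build_histogram(numeric(0), acq), "no burst")
  expect_equal(sum(h$concentration), 0)
  expect_error(fraction_of_total(h), "zero")
})

test_that("modal intensities of 200 and 50 nm samples sit ~16-fold apart", {
  acq <- acq_short(duration = 30)
  edges <- basr:::default_edges(acq, 15, 400)
  modal <- vapply(c(200, 50), function(d) {
    tr <- simulate_trace(pop_of(d, n = 10000, seed = d), acq, seed = d + 1)
    h <- build_histogram(detect_bursts(tr), acq, edges = edges)
    ctr <- sqrt(h$bin_lo * h$bin_hi)
    sum(h$concentration * ctr) / sum(h$concentration) # weighted mean intensity
  }, numeric(1))
  expect_equal(modal[1] / modal[2], 16, tolerance = 0.15)
})

test_that("fraction_of_total normalizes exactly", {
  acq <- acq_short()
  h <- build_histogram(c(10, 10.5, 95, 100, 110), acq,
                       edges = c(1, 50, 200))
  f <- fraction_of_total(h)
  expect_equal(sum(f), 1)
  expect_equal(f, c(2, 3) / 5)
  h1 <- build_histogram(rep(20, 7), acq, edges = c(1, 50, 200))
  expect_equal(fraction_of_total(h1), c(1, 0))
})

test_that("mean intensity ratios report fold and implied diameter ratio", {
  acq <- acq_short()
  a200 <- sample_burst_amplitudes(liposome_species(200, 0.35, 100), 2e4,
                                  acq, seed = 1)
  a100 <- sample_burst_amplitudes(liposome_species(100, 0.35, 100), 2e4,
                                  acq, seed = 2)
  h1 <- build_histogram(a200, acq)
  h2 <- build_histogram(a100, acq)
  r <- mean_intensity_ratio(h1, h2)
  expect_equal(r$fold, 4, tolerance = 0.08)
  expect_equal(r$implied_diameter_ratio, sqrt(r$fold))
  same <- mean_intensity_ratio(h1, h1)
  expect_equal(same$fold, 1)
  expect_error(
    mean_intensity_ratio(h1, suppressWarnings(
      build_histogram(numeric(0), acq))),
    "occupied")
})

test_that("validity flags require 5 events and the concentration limit", {
  acq <- acq_short(duration = 30)
  # few events per bin -> invalid
  h <- build_histogram(c(10, 11, 12), acq, edges = c(1, 50, 200))
  expect_false(any(h$valid))
  # abundant events at modest concentration -> valid
  amps <- sample_burst_amplitudes(liposome_species(100, 0.2, 100), 1000,
                                  acq, seed = 3)
  h2 <- build_histogram(amps, acq)
  expect_true(any(h2$valid))
  expect_true(all(h2$n_events[h2$valid] >= 5))
})

test_that("concentration estimates are linear below and sub-linear above 500 pM", {
  acq <- acq_short(duration = 20)
  conc <- c(50, 150, 300, 500)
  est <- vapply(conc, function(C) {
    pop <- pop_of(100, conc = C, n = 5000, seed = 17)
    tr <- suppressWarnings(simulate_trace(pop, acq, seed = round(C)))
    sum(build_histogram(detect_bursts(tr), acq)$concentration)
  }, numeric(1))
  slope <- sum(conc * est) / sum(conc^2)
  expect_lt(abs(slope - 1), 0.05)
  pop_hi <- pop_of(100, conc = 2000, n = 5000, seed = 18)
  tr_hi <- suppressWarnings(simulate_trace(pop_hi, acq, seed = 19))
  est_hi <- sum(build_histogram(detect_bursts(tr_hi), acq)$concentration)
  expect_lt(est_hi, 2000 * 0.95) # coincidence losses above the limit
})
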