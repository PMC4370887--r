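make_hist <- function(conc, intensity, acq = acq_short()) {
  nb <- length(conc)
  edges <- 10^seq(0, nb, length.out = nb + 1)
  h <- data.frame(bin_lo = edges[-(nb + 1)], bin_hi = edges[-1],
                  mean_intensity = intensity, concentration = conc,
                  n_events = round(conc * 10),
                  valid = conc > 0)
  structure(h, class = c("bas_histogram", "data.frame"),
            acq = acq, dilution_factor = 1)
}

test_that("fractional intensity implements the heat-map normalization", {
  # two bins with (I=1, C=100) and (I=100, C=1) share the fluorescence
  h <- make_hist(c(100, 1), c(1, 100))
  expect_equal(fractional_intensity_row(h), c(0.5, 0.5))
  h1 <- make_hist(c(0, 5, 0), c(NA, 10, NA))
  expect_equal(fractional_intensity_row(h1), c(0, 1, 0))
  expect_error(fractional_intensity_row(make_hist(c(0, 0), c(NA, NA))),
               "zero")
})

test_that("heat-map rows always sum to one", {
  acq <- acq_short(duration = 20)
  tc <- basr:::kinetics_course(0.15, c(0, 5, 15, 40), acq,
                               fission_params(0.15, 20, 0.3),
                               n_parents = 300, seed = 2)
  hm <- heat_map(tc)
  expect_equal(unname(rowSums(hm)), rep(1, nrow(hm)), tolerance = 1e-12)
  expect_true(all(hm >= 0))
})

test_that("total signal series is normalized to its maximum", {
  acq <- acq_short(duration = 20)
  tc <- basr:::kinetics_course(0.15, c(0, 5, 15, 40), acq,
                               fission_params(0.15, 20, 0.3),
                               n_parents = 300, seed = 4)
  ts <- total_signal_series(tc)
  expect_equal(max(ts), 1)
  expect_true(all(ts > 0 & ts <= 1))
})

test_that("plateau time matches the first-order closed form", {
  k <- 0.07
  t_grid <- seq(0, 120, 0.25)
  series <- data.frame(time = t_grid, value = 1 - exp(-k * t_grid))
  expect_equal(time_to_plateau(series, frac = 0.95), log(20) / k,
               tolerance = 0.01)
  # monotone in the plateau fraction
  expect_gte(time_to_plateau(series, frac = 0.95),
             time_to_plateau(series, frac = 0.5))
})

test_that("unplateaued series are rejected", {
  t_grid <- seq(0, 6, 1)
  series <- data.frame(time = t_grid, value = 1 - exp(-0.15 * t_grid))
  expect_error(time_to_plateau(series), "not plateaued")
})

test_that("rate constants differing 2-fold give 2-fold plateau times", {
  t_grid <- c(0, 7.5, 15, 30, 45, 60, 90, 120)
  tp <- vapply(c(0.05, 0.10), function(k)
    time_to_plateau(data.frame(time = t_grid,
                               value = 1 - exp(-k * t_grid))),
    numeric(1))
  expect_equal(tp[1] / tp[2], 2, tolerance = 0.05)
})

test_that("dose response decreases monotonically with effective rate", {
  acq <- acq_short(duration = 20)
  edges <- basr:::default_edges(acq)
  pop <- sample_population(liposome_species(200, 0.35, 100), 600, seed = 5)
  ref <- basr:::measure_sample(pop, acq, edges, seed = 6)$histogram
  ks <- c(0, 0.02, 0.08, 0.3)
  histos <- lapply(seq_along(ks), function(i) {
    fp <- fission_params(max(ks[i], 1e-9), 20, 0.3)
    pt <- if (ks[i] == 0) pop else evolve_fission(pop, fp, 20, seed = 10 + i)
    list(i, basr:::measure_sample(pt, acq, edges, dilution = 25,
                                  seed = 20 + i)$histogram)
  })
  dr <- dose_response(histos, ref)
  expect_equal(dr$remaining[1], 1, tolerance = 0.05)  # k = 0 control
  expect_true(all(diff(dr$remaining) < 0))
  # complete conversion wipes out the starting-size window
  fp <- fission_params(1, 20, 0.3)
  done <- evolve_fission(pop, fp, 100, seed = 30)
  h_done <- basr:::measure_sample(done, acq, edges, dilution = 25,
                                  seed = 31)$histogram
  expect_lt(dose_response(list(list(1, h_done)), ref)$remaining, 0.05)
})
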