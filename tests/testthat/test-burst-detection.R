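test_that("background rate is recovered within 3% on pure Poisson traces", {
  acq <- acq_short(duration = 20)
  tr <- background_trace(acq, seed = 2)
  bg <- estimate_background(tr)
  expect_equal(bg$rate, acq$background_rate, tolerance = 0.03)
  expect_equal(bg$sigma, sqrt(bg$rate * acq$bin_width))
})

test_that("an all-zero trace has zero background", {
  acq <- acq_short(duration = 1)
  tr <- basr:::new_trace(rep(0L, 10000), acq)
  expect_equal(estimate_background(tr), list(rate = 0, sigma = 0))
})

test_that("sparse bursts leave the background estimate within 5%", {
  acq <- acq_short(duration = 20)
  clean <- background_trace(acq, seed = 6)
  bursty <- clean
  n <- length(bursty$counts)
  at <- seq(50, n - 50, length.out = round(0.01 * n / 3)) # ~1% of bins
  for (a in round(at)) bursty$counts[a + 0:2] <- bursty$counts[a + 0:2] + 40L
  expect_equal(estimate_background(bursty)$rate,
               estimate_background(clean)$rate, tolerance = 0.05)
})

test_that("a trace dominated by signal is rejected with advice to dilute", {
  acq <- acq_short(duration = 1)
  tr <- basr:::new_trace(rpois(10000, 50), acq) # far above 0.5/bin background
  tr$counts[1:3000] <- rpois(3000, 1)           # minority at background
  expect_error(estimate_background(tr), "dilute")
})

test_that("background-only traces yield no bursts at the default threshold", {
  tr <- background_trace(acq_short(duration = 20), seed = 8)
  expect_equal(nrow(detect_bursts(tr)), 0)
})

test_that("false positives stay below one burst per minute", {
  tr <- background_trace(acq_short(duration = 120), seed = 13)
  expect_lt(nrow(detect_bursts(tr)) / 2, 1)
})

test_that("a square pulse is recovered with exact integrated amplitude", {
  base <- 1L
  acq <- acq_short(duration = 1)
  tr <- pulse_trace(base, list(list(at = 2000, width = 5, height = 40)), acq)
  b <- detect_bursts(tr, background = list(rate = base / acq$bin_width,
                                           sigma = sqrt(base)))
  expect_equal(nrow(b), 1)
  expect_equal(b$amplitude, 40 * 5)
  expect_equal(b$n_bins, 5)
  expect_equal(b$peak, base + 40)
  # amplitude additivity: doubling the height doubles the amplitude
  tr2 <- pulse_trace(base, list(list(at = 2000, width = 5, height = 80)), acq)
  b2 <- detect_bursts(tr2, background = list(rate = base / acq$bin_width,
                                             sigma = sqrt(base)))
  expect_equal(b2$amplitude, 2 * b$amplitude)
})

test_that("detected counts and amplitudes track ground truth within 10%", {
  acq <- acq_short(duration = 30)
  tr <- simulate_trace(pop_of(200, n = 10000, seed = 3), acq, seed = 21)
  b <- detect_bursts(tr)
  expect_equal(nrow(b), nrow(tr$ground_truth), tolerance = 0.10)
  expect_equal(mean(b$amplitude), mean(tr$ground_truth$amplitude),
               tolerance = 0.10)
})

test_that("raising the threshold never increases the burst count", {
  acq <- acq_short(duration = 10)
  tr <- simulate_trace(pop_of(50, n = 5000, seed = 4), acq, seed = 31)
  n <- vapply(c(3, 5, 8, 12, 20), function(k)
    nrow(detect_bursts(tr, k_sigma = k)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("runs split by a one-bin dip are merged into one burst", {
  base <- 1L
  acq <- acq_short(duration = 1)
  tr <- pulse_trace(base, list(list(at = 3000, width = 3, height = 30),
                               list(at = 3004, width = 3, height = 30)), acq)
  bg <- list(rate = base / acq$bin_width, sigma = sqrt(base))
  expect_equal(nrow(detect_bursts(tr, background = bg, gap_bins = 1)), 1)
  expect_equal(nrow(detect_bursts(tr, background = bg, gap_bins = 0)), 2)
})
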