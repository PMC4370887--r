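test_that("uncorrelated Poisson traces have no structure beyond noise", {
  acq <- acq_short(duration = 5)
  tr <- basr:::new_trace(rpois(50000, 5), acq)
  cc <- autocorrelate(tr, max_lag = 0.2)
  expect_true(all(abs(cc$G) < 3 / sqrt(cc$n_pairs) / 5)) # mean ~5/bin
})

test_that("a periodic trace correlates at its period", {
  acq <- acq_short(duration = 5)
  period <- 100L # bins
  counts <- rep(c(rep(0L, 50), rep(20L, 50)), length.out = 50000)
  cc <- autocorrelate(basr:::new_trace(counts, acq), max_lag = 0.05)
  at_period <- which.min(abs(cc$lag - period * acq$bin_width))
  at_half <- which.min(abs(cc$lag - period / 2 * acq$bin_width))
  expect_gt(cc$G[at_period], 0.8)
  expect_lt(cc$G[at_half], -0.8)
})

test_that("constant traces are rejected", {
  tr <- basr:::new_trace(rep(7L, 20000), acq_short(duration = 2))
  expect_error(autocorrelate(tr, max_lag = 0.01), "constant")
})

test_that("correlation amplitude reports the particle number in the volume", {
  acq <- acq_fcs(duration = 10)
  pop <- sample_population(liposome_species(100, 0, 8000), 500, seed = 1)
  tr <- simulate_fcs_trace(pop, acq, seed = 1)
  cc <- autocorrelate(tr, max_lag = 0.05)
  expect_equal(cc$G[1], 1 / attr(tr, "n_expected"), tolerance = 0.20)
})

test_that("immobile particles show no diffusion decay", {
  # frozen field: the particle contribution is constant, so the
  # correlation is flat (zero beyond shot noise) with no decay structure
  acq <- acq_fcs(duration = 2, viscosity = Inf)
  pop <- sample_population(liposome_species(100, 0, 5000), 100, seed = 2)
  tr <- simulate_fcs_trace(pop, acq, seed = 2)
  cc <- autocorrelate(tr, max_lag = 0.02)
  expect_lt(max(abs(cc$G)), 1e-3)
  short <- mean(cc$G[1:5]); long <- mean(cc$G[(nrow(cc) - 4):nrow(cc)])
  expect_lt(abs(short - long), 1e-3)
  # contrast: the same sample with finite viscosity decays measurably
  acq2 <- acq_fcs(duration = 2)
  tr2 <- simulate_fcs_trace(pop, acq2, seed = 2)
  cc2 <- autocorrelate(tr2, max_lag = 0.02)
  expect_gt(cc2$G[1] - cc2$G[nrow(cc2)], 0.05)
})

test_that("diffusion-mode preconditions are enforced", {
  pop <- sample_population(liposome_species(100, 0, 5000), 50, seed = 1)
  expect_error(simulate_fcs_trace(pop, acq_short()), "diffusion")
  bad <- acq_fcs(); bad$viscosity <- NA
  expect_error(simulate_fcs_trace(pop, bad), "viscosity")
})

test_that("the diffusion model fit recovers its own parameters exactly", {
  lags <- 10^seq(-4.3, -0.5, length.out = 60)
  G <- 0.1 / ((1 + lags / 1e-3) * sqrt(1 + lags / (25 * 1e-3)))
  curve <- structure(data.frame(lag = lags, G = G, sigma = NA_real_,
                                n_pairs = NA_real_),
                     class = c("fcs_curve", "data.frame"))
  fit <- fit_diffusion(curve, kappa = 5)
  expect_equal(fit$G0, 0.1, tolerance = 1e-3)
  expect_equal(fit$tau_D, 1e-3, tolerance = 1e-3)
})

test_that("fits are unbiased across noisy model-generated curves", {
  lags <- 10^seq(-4.3, -0.7, length.out = 50)
  model <- 0.08 / ((1 + lags / 2e-3) * sqrt(1 + lags / (25 * 2e-3)))
  taus <- vapply(1:50, function(s) {
    set.seed(s)
    curve <- structure(data.frame(lag = lags,
                                  G = model + rnorm(50, 0, 0.0008),
                                  sigma = 0.0008, n_pairs = NA_real_),
                       class = c("fcs_curve", "data.frame"))
    fit_diffusion(curve, kappa = 5)$tau_D
  }, numeric(1))
  expect_lt(abs(mean(taus) / 2e-3 - 1), 0.02)
})

test_that("doubling the radius doubles the fitted diffusion time", {
  acq <- acq_fcs(duration = 25)
  one <- function(d, s) {
    pop <- sample_population(liposome_species(d, 0, 2000), 500, seed = s)
    tr <- simulate_fcs_trace(pop, acq, seed = s + 1)
    fit_diffusion(autocorrelate(tr, max_lag = 0.04))$tau_D
  }
  t100 <- mean(c(one(100, 301), one(100, 302)))
  t50 <- one(50, 303)
  expect_equal(t100 / t50, 2, tolerance = 0.15)
})

test_that("post-fission products diffuse faster than 50 nm liposomes", {
  acq <- acq_fcs(duration = 15)
  tau <- vapply(c(50, 22), function(d) {
    pop <- sample_population(liposome_species(d, 0.1, 3000), 500, seed = d)
    tr <- simulate_fcs_trace(pop, acq, seed = d + 5)
    fit_diffusion(autocorrelate(tr, max_lag = 0.03))$tau_D
  }, numeric(1))
  expect_lt(tau[2], tau[1] * 0.7)
})
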