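test_that("surface-area brightness scaling gives 4x and 16x folds", {
  expect_equal(brightness_of(200) / brightness_of(100), 4)
  expect_equal(brightness_of(200) / brightness_of(50), 16)
  expect_equal(brightness_of(137.5) / brightness_of(137.5), 1)
  expect_equal(brightness_of(100, label_density = 2), 2 * pi * 100^2)
  expect_error(brightness_of(0), "positive")
  expect_error(brightness_of(-10), "positive")
})

test_that("zero-variance species sample exactly at the mean", {
  pop <- sample_population(liposome_species(200, 0, 100), 1000, seed = 1)
  expect_true(all(pop$particles$diameter == 200))
  expect_equal(total_concentration(pop), 100)
})

test_that("sampled diameters reproduce the species mean and CV", {
  pop <- sample_population(liposome_species(200, 0.35, 100), 1e5, seed = 7)
  d <- pop$particles$diameter
  expect_true(all(d > 0))
  expect_lt(abs(sd(d) / mean(d) - 0.35), 0.01 * 0.35 + 0.005)
  expect_lt(abs(mean(d) / 200 - 1), 0.01)
})

test_that("species are sampled in proportion to concentration", {
  pop <- sample_population(list(liposome_species(200, 0.1, 75),
                                liposome_species(50, 0.1, 25)),
                           2e4, seed = 3)
  frac <- mean(pop$particles$species == 1)
  expect_lt(abs(frac - 0.75), 0.02)
  expect_equal(total_concentration(pop), 100)
})

test_that("empty species lists and zero totals are rejected", {
  expect_error(sample_population(list(), 10), "non-empty")
  expect_error(sample_population(liposome_species(200, 0.3, 0), 10),
               "positive")
})

test_that("increasing CV strictly widens the brightness IQR", {
  iqrs <- vapply(c(0.1, 0.2, 0.35, 0.5), function(cv) {
    pop <- sample_population(liposome_species(100, cv, 100), 5e4, seed = 11)
    unname(diff(quantile(pop$particles$brightness, c(0.25, 0.75))))
  }, numeric(1))
  expect_true(all(diff(iqrs) > 0))
})

test_that("intensity distributions widen from 35% to 50% CV", {
  q <- lapply(c(0.35, 0.5), function(cv) {
    pop <- sample_population(liposome_species(200, cv, 100), 5e4, seed = 5)
    quantile(log(pop$particles$brightness), c(0.05, 0.95))
  })
  # wider tails at 50% CV on both sides
  expect_lt(q[[2]][1], q[[1]][1])
  expect_gt(q[[2]][2], q[[1]][2])
})

test_that("population sampling is reproducible under a fixed seed", {
  p1 <- sample_population(liposome_species(200, 0.35, 100), 1000, seed = 42)
  p2 <- sample_population(liposome_species(200, 0.35, 100), 1000, seed = 42)
  expect_identical(p1, p2)
})
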