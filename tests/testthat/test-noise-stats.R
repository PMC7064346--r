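# Dual-reporter noise decomposition: hand-computed cases, the Poisson
# oracle, additivity and scale laws, binning, smoothing and correction.

test_that("intrinsic noise and Fano match hand-computed values", {
  expect_equal(intrinsic_noise(c(8, 12), c(12, 8)), 0.08)
  expect_equal(fano_factor(c(8, 12), c(12, 8)), 1.6)
  x <- c(3, 17, 40, 2.5)
  expect_equal(intrinsic_noise(x, x), 0)
  expect_equal(fano_factor(x, x), 0)
  expect_error(intrinsic_noise(c(0, 0), c(1, 2)), "non-positive")
  expect_error(intrinsic_noise(1:3, 1:4), "equal length")
})

test_that("independent Poisson reporters give eta2 = 1/lambda, Fano = 2", {
  set.seed(101)
  lambda <- 50
  x <- stats::rpois(1e5, lambda)
  y <- stats::rpois(1e5, lambda)
  # eta2 estimator SE ~ eta2 * sqrt(2/n) at Poisson scale
  expect_lt(abs(intrinsic_noise(x, y) - 1 / lambda),
            3 * (1 / lambda) * sqrt(2 / 1e5) * 2)
  expect_equal(fano_factor(x, y), 2, tolerance = 0.05)
})

test_that("the cumulative statistic doubles the per-allele Fano (additivity)", {
  d <- simulate_pairs(p_const(), p_const(), n_pairs = 2000, t_end = 300,
                      seed = 21)
  per_allele <- stats::var(c(d$protein_a, d$protein_b)) /
    mean(c(d$protein_a, d$protein_b))
  cumulative <- fano_factor(d$protein_a, d$protein_b)
  expect_equal(cumulative, 2 * per_allele, tolerance = 0.15)
})

test_that("scaling both channels scales Fano but leaves eta2 unchanged", {
  set.seed(5)
  x <- stats::rgamma(500, 4, 0.1)
  y <- stats::rgamma(500, 4, 0.1)
  expect_equal(intrinsic_noise(3.7 * x, 3.7 * y), intrinsic_noise(x, y))
  expect_equal(fano_factor(3.7 * x, 3.7 * y), 3.7 * fano_factor(x, y))
})

test_that("log binning partitions cells as hand-computed", {
  b <- bin_by_output(c(10, 10.4, 100), bin_width = 0.02, min_cells = 1)
  # log10(10.4) - log10(10) = 0.017 < 0.02: same bin; 100 far away
  expect_equal(b$assignment[1], b$assignment[2])
  expect_false(b$assignment[1] == b$assignment[3])
  # every positive cell in exactly one bin
  totals <- exp(stats::runif(500, 0, 5))
  b2 <- bin_by_output(totals, min_cells = 10)
  expect_equal(length(b2$assignment), 500)
  expect_equal(sum(b2$bins$n_cells), 500)
  # two decades at width 0.02 occupy ~100 bins
  b3 <- bin_by_output(10^seq(1, 3, length.out = 5000), bin_width = 0.02,
                      min_cells = 1)
  expect_gte(nrow(b3$bins), 99)
  expect_lte(nrow(b3$bins), 101)
  # equal totals collapse to one bin
  expect_equal(nrow(bin_by_output(rep(7, 50), min_cells = 1)$bins), 1)
  expect_error(bin_by_output(c(1, 0, 2)), "positive")
})

test_that("noise profiles are zero for identical reporters and contain
          their point estimate in the bootstrap CI", {
  set.seed(9)
  x <- exp(stats::runif(400, 1, 3))
  pr0 <- noise_profile(x, x, n_bins = 5, min_cells = 20, n_boot = 200,
                       seed = 1)
  expect_true(all(pr0$fano == 0))
  expect_true(all(pr0$ci_low == 0 & pr0$ci_high == 0))

  y <- x * mult_noise(400, 0.2)
  pr <- noise_profile(x, y, n_bins = 5, min_cells = 20, n_boot = 500,
                      seed = 2)
  expect_true(all(pr$ci_low <= pr$fano & pr$fano <= pr$ci_high))
  expect_true(all(diff(pr$bin_low) > 0))
  # seed-reproducible bootstrap
  pr2 <- noise_profile(x, y, n_bins = 5, min_cells = 20, n_boot = 500,
                       seed = 2)
  expect_identical(pr$ci_low, pr2$ci_low)
})

test_that("lowess models reproduce constant and smooth quadratic trends", {
  prof <- data.frame(mu = seq(10, 100, length.out = 20),
                     fano = rep(6, 20))
  m <- lowess_model(prof, span = 0.3)
  expect_equal(predict(m, c(15, 55, 200)), rep(6, 3), tolerance = 1e-8)

  set.seed(31)
  mu <- seq(1, 50, length.out = 40)
  f_true <- 5 + 0.02 * (mu - 25)^2
  prof2 <- data.frame(mu = mu, fano = f_true * (1 + stats::rnorm(40, 0, 0.02)))
  m2 <- lowess_model(prof2, span = 0.3)
  interior <- mu[mu > 5 & mu < 45]
  expect_true(all(abs(predict(m2, interior) /
                        (5 + 0.02 * (interior - 25)^2) - 1) < 0.1))
  # span = 1 degenerates toward one global smooth trend
  m3 <- lowess_model(prof2, span = 1)
  expect_true(all(diff(predict(m3, mu)[1:20]) < 0)) # left branch decreasing
  expect_error(lowess_model(prof2[1:3, ]), "5")
})

test_that("measurement-noise subtraction is identity for a zero model and
          near-zero for self-subtraction", {
  set.seed(41)
  x <- exp(stats::runif(2000, 1, 3))
  y <- x * mult_noise(2000, 0.15)
  pr <- noise_profile(x, y, n_bins = 8, min_cells = 50, n_boot = 300,
                      seed = 3)
  zero_model <- structure(list(support = c(0, 1e6),
                               predicted_fano = c(0, 0), span = 0.3),
                          class = "measurement_noise_model")
  same <- subtract_measurement_noise(pr, zero_model)
  expect_equal(same$corrected_fano, same$fano)

  self <- subtract_measurement_noise(pr, lowess_model(pr, span = 0.4))
  # zero up to the smoother's residual, which concentrates at the edges
  expect_lt(stats::median(abs(self$corrected_fano) / self$fano), 0.05)
  expect_true(all(abs(self$corrected_fano) <= 0.35 * self$fano))
  # non-overlapping support is an error
  far <- pr; far$mu <- far$mu * 1e9
  expect_error(subtract_measurement_noise(
    far, lowess_model(pr, span = 0.4)), "overlap")
})
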