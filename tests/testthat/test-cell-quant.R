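# Background fitting, classification, channel scaling and absolute
# conversion on generator-known truth.

test_that("background fit recovers a pure normal and its 84th-percentile
          threshold", {
  set.seed(51)
  f <- fit_background(stats::rnorm(1e4, 100, 10))
  expect_equal(f$bg_mean, 100, tolerance = 0.02)
  expect_equal(f$threshold, 100 + stats::qnorm(0.84) * 10, tolerance = 0.02)
  expect_error(fit_background(rep(5, 200)), "constant")
  expect_error(fit_background(stats::rnorm(50, 0, 1)), "100")
})

test_that("background fit resists a bright expressing tail", {
  set.seed(52)
  v <- c(stats::rnorm(7000, 100, 10),
         stats::rnorm(3000, 320, 90)) # well-separated positives
  f <- fit_background(v)
  expect_equal(f$bg_mean, 100, tolerance = 0.03)
})

test_that("positivity requires exceeding the threshold in both channels", {
  fg <- structure(list(bg_mean = 10, bg_sd = 1, threshold = 11, n_used = 100),
                  class = "background_fit")
  fr <- structure(list(bg_mean = 20, bg_sd = 2, threshold = 22, n_used = 100),
                  class = "background_fit")
  disc <- data.frame(green_rfu = c(10, 15, 15, 10),
                     red_rfu = c(20, 30, 20, 30))
  out <- classify_and_subtract(disc, fg, fr)
  expect_identical(out$positive, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$green_sub, disc$green_rfu - 11)
  expect_equal(out$red_sub, disc$red_rfu - 22)
  expect_error(classify_and_subtract(disc, fg, list()), "background fits")
})

test_that("raising the percentile cutoff never gains positive cells", {
  set.seed(53)
  cfg <- disc_sim_config(n_cells = 800)
  tab <- make_disc_tables(cfg, seed = 54)
  fg <- fit_background(tab$cells$green_rfu)
  fr <- fit_background(tab$cells$red_rfu)
  counts <- vapply(c(0.5, 0.84, 0.95, 0.99), function(q) {
    z <- stats::qnorm(q)
    sum(tab$cells$green_rfu > fg$bg_mean + z * fg$bg_sd &
          tab$cells$red_rfu > fr$bg_mean + z * fr$bg_sd)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("channel scaling recovers exact and noisy generating lines", {
  red <- seq(1, 30, length.out = 40)
  sc <- fit_channel_scaling(2 * red + 5, red)
  expect_equal(sc$slope, 2, tolerance = 1e-10)
  expect_equal(sc$intercept, 5, tolerance = 1e-10)
  expect_equal(sc$r, 1, tolerance = 1e-10)
  expect_false(sc$flagged)

  set.seed(55)
  red2 <- stats::runif(500, 5, 100)
  green2 <- (1.5 * red2 + 3) * mult_noise(500, 0.1)
  sc2 <- fit_channel_scaling(green2, red2)
  expect_gt(sc2$slope, 1.4); expect_lt(sc2$slope, 1.6)

  # independent channels: r near zero, flagged
  sc3 <- fit_channel_scaling(stats::rnorm(200, 50, 10),
                             stats::rnorm(200, 50, 10))
  expect_lt(abs(sc3$r), 0.3)
  expect_true(sc3$flagged)
  expect_error(fit_channel_scaling(rep(1, 30), rep(2, 30)), "degenerate")
  expect_error(fit_channel_scaling(1:10, 1:10), "20")
})

test_that("scaling is near-idempotent on matched channels and totals add up", {
  set.seed(56)
  g <- stats::runif(300, 10, 200)
  r <- g * mult_noise(300, 0.02)
  sc <- fit_channel_scaling(g, r)
  expect_equal(sc$slope, 1, tolerance = 0.05)
  expect_lt(abs(sc$intercept), 0.05 * mean(g))

  unit <- structure(list(slope = 1, intercept = 0, r = 1, n_cells = 10,
                         flagged = FALSE), class = "channel_scaling")
  st <- scale_and_total(g, r, unit)
  expect_equal(st$total_rfu, g + r)
  two <- structure(list(slope = 2, intercept = 5, r = 1, n_cells = 10,
                        flagged = FALSE), class = "channel_scaling")
  expect_equal(scale_and_total(0, 10, two)$scaled_red, 25)
  # regression through the means: mean scaled red equals mean green
  st2 <- scale_and_total(g, r, sc)
  expect_equal(mean(st2$scaled_red), mean(g), tolerance = 1e-6)
})

test_that("RFU conversion reproduces the calibration arithmetic", {
  cal <- conversion_calibration()
  # 10 nM/RFU * 23 fL * Avogadro ~ 138 molecules/RFU, self-consistent
  expect_equal(cal$molecules_per_rfu,
               cal$nM_per_rfu * 1e-9 * cal$nuclear_volume * cal$avogadro,
               tolerance = 1e-10)
  expect_equal(cal$molecules_per_rfu, 138.5, tolerance = 0.005)
  one <- rfu_to_molecules(1)
  expect_equal(one$nM, 10)
  expect_equal(one$molecules, 138.5, tolerance = 0.005)
  expect_equal(rfu_to_molecules(0)$molecules, 0)
  expect_equal(rfu_to_molecules(25)$nM, 250)
  expect_error(rfu_to_molecules(-1), ">= 0")
})

test_that("positive cells classified from synthetic discs carry positive
          totals and roughly the injected fraction", {
  cfg <- disc_sim_config(n_cells = 3000, kon_range = c(2, 10))
  tab <- make_disc_tables(cfg, seed = 7)
  q <- quantify_disc(tab$cells, calib = conversion_calibration())
  frac <- mean(q$cells$positive)
  # injected 30% plus the ~2.6% of background cells that clear the 84th
  # percentile in both channels by chance
  expect_gt(frac, 0.28); expect_lt(frac, 0.35)
  expect_true(all(q$cells$total_rfu[q$cells$positive] > 0))
  expect_false(q$scaling$flagged ||
                 is.na(q$cells$total_molecules[which(q$cells$positive)[1]]))
})

test_that("the slope-ratio repression assay behaves on degenerate input", {
  expect_equal(repression_fold(c(1.1, 1.2, 1.3), c(1.1, 1.2, 1.3))$fold, 1)
  rf <- repression_fold(rep(1.8, 4), rep(1.0, 4))
  expect_equal(rf$fold, 1.8)
  expect_equal(rf$se, 0)
  expect_error(repression_fold(c(1, 2), c(1, 2, 3)), "3 discs")
  expect_error(repression_fold(c(-1, 0, 1), c(1, 1, 1)), "zero mean")
})
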