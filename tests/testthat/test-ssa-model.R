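# The Gillespie core against closed-form oracles of the two-state model.

test_that("parameter construction enforces the model's domain", {
  expect_error(kinetic_params(-1, 1, 1, 1, 1, 1), "finite")
  expect_error(kinetic_params(Inf, 1, 1, 1, 1, 1), "finite")
  expect_error(kinetic_params(1, 1, 1, 1, 1, 1, nG_total = 0), "nG_total")
  # koff = 0 with a silent start is absorbing; the constitutive
  # constructor is the sanctioned way in
  expect_error(kinetic_params(1, 0, 1, 1, 1, 1), "constitutive")
  expect_s3_class(constitutive_params(0.5, 0.5, 0.0462, 0.01),
                  "kinetic_params")
})

test_that("an all-zero-rate allele never leaves the initial state", {
  p <- kinetic_params(0, 0, 0, 0, 0, 0, promoter_on = TRUE)
  res <- simulate_allele(p, t_end = 300, seed = 1)
  expect_identical(res$nM, 0)
  expect_identical(res$nP, 0)
  d <- simulate_pairs(p, p, n_pairs = 10, t_end = 300, seed = 1)
  expect_true(all(d$protein_a == 0 & d$protein_b == 0))
})

test_that("fixed seeds give bit-identical trajectories", {
  p <- p_burst4()
  a <- simulate_allele(p, t_end = 100, seed = 42, record_trajectory = TRUE)
  b <- simulate_allele(p, t_end = 100, seed = 42, record_trajectory = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  d1 <- simulate_pairs(p, p, n_pairs = 50, t_end = 50, seed = 7)
  d2 <- simulate_pairs(p, p, n_pairs = 50, t_end = 50, seed = 7)
  expect_identical(d1, d2)
})

test_that("constitutive stationary means match Sm/Dm and Sm*Sp/(Dm*Dp)", {
  p <- p_const()
  ss <- constitutive_steady_state(p)
  expect_equal(unname(ss["mrna"]), 0.5 / 0.0462, tolerance = 1e-12)
  expect_equal(unname(ss["protein"]), 0.5 * 0.5 / (0.0462 * 0.01),
               tolerance = 1e-12)
  # mRNA relaxes within ~5/Dm ~ 110 min; protein needs ~5/Dp ~ 500 min
  d <- simulate_pairs(p, p, n_pairs = 500, t_end = 900, seed = 11)
  m <- c(d$mrna_a, d$mrna_b)
  pp <- c(d$protein_a, d$protein_b)
  se_m <- stats::sd(m) / sqrt(length(m))
  se_p <- stats::sd(pp) / sqrt(length(pp))
  expect_lt(abs(mean(m) - ss["mrna"]), 3 * se_m)
  expect_lt(abs(mean(pp) - ss["protein"]), 3 * se_p)
  # mRNA is a Poisson birth-death: Fano 1
  expect_lt(abs(stats::var(m) / mean(m) - 1), 0.1)
  # protein Fano converges to 1 + Sp/(Dm+Dp)
  expect_lt(abs(stats::var(pp) / mean(pp) - predicted_fano_constitutive(p)),
            1.2)
})

test_that("two-state stationary protein mean matches the telegraph closed form", {
  p <- kinetic_params(kon = 0.5, koff = 0.5, Sm = 0.5, Sp = 0.5,
                      Dm = 0.0462, Dp = 0.01)
  pred <- promoter_on_fraction(p) *
    unname(constitutive_steady_state(p)["protein"])
  d <- simulate_pairs(p, p, n_pairs = 500, t_end = 900, seed = 13)
  pp <- c(d$protein_a, d$protein_b)
  se <- stats::sd(pp) / sqrt(length(pp))
  expect_lt(abs(mean(pp) - pred), 3 * se)
})

test_that("burst size and frequency follow Sm/koff and (1/kon + 1/koff)^-1", {
  expect_equal(burst_size(p_burst4()), 4)
  expect_equal(burst_size(kinetic_params(1, 0.125, 1, 0.5, 0.0462, 0.01)), 8)
  expect_equal(burst_size(kinetic_params(1, 2, 0, 0.5, 0.0462, 0.01)), 0)
  expect_error(burst_size(p_const()), "constitutive")
  expect_equal(burst_frequency(kinetic_params(1, 1, 1, 1, 1, 1)), 0.5)
  expect_equal(burst_frequency(kinetic_params(1e6, 2, 1, 1, 1, 1)), 2,
               tolerance = 1e-5)
  expect_equal(burst_frequency(kinetic_params(0.025, 1, 1, 1, 1, 1)),
               1 / (1 / 0.025 + 1), tolerance = 1e-12)
  expect_error(burst_frequency(p_const()), "undefined")
})

test_that("predicted constitutive Fano is 1 + Sp/(Dm + Dp)", {
  expect_equal(predicted_fano_constitutive(
    constitutive_params(1, 0, 0.0462, 0.01)), 1)
  expect_equal(predicted_fano_constitutive(p_const()),
               1 + 0.5 / 0.0562, tolerance = 1e-12)
})

test_that("trans-inhibition at phi = 0 reduces to independent alleles", {
  p <- p_burst4(kon = 0.25)
  ind <- simulate_pairs(p, p, n_pairs = 800, t_end = 300, seed = 5)
  cpl <- simulate_trans_inhibited_pairs(p, phi = 0, n_pairs = 800,
                                        t_end = 300, seed = 6)
  m1 <- mean(c(ind$protein_a, ind$protein_b))
  m2 <- mean(c(cpl$protein_a, cpl$protein_b))
  se <- sqrt(stats::var(c(ind$protein_a, ind$protein_b)) / 1600 +
               stats::var(c(cpl$protein_a, cpl$protein_b)) / 1600)
  expect_lt(abs(m1 - m2), 3 * se)
})

test_that("trans-inhibited promoter occupancy matches the 4-state chain", {
  kon <- 0.2; koff <- 1
  # expression events silenced so only the promoter pair evolves
  p <- kinetic_params(kon = kon, koff = koff, Sm = 0, Sp = 0, Dm = 0,
                      Dp = 0)
  for (phi in c(0.5, 1)) {
    pi_st <- promoter_pair_stationary(kon, koff, phi)
    d <- simulate_trans_inhibited_pairs(p, phi, n_pairs = 20000,
                                        t_end = 60, seed = 3,
                                        keep_promoter = TRUE)
    both <- mean(d$gon_a == 1 & d$gon_b == 1)
    se <- sqrt(pi_st["11"] * (1 - pi_st["11"]) / 20000) + 1e-4
    expect_lt(abs(both - pi_st["11"]), 4 * se)
    # inhibition depresses double occupancy below independence
    expect_lt(both, (kon / (kon + koff))^2)
  }
  expect_error(simulate_trans_inhibited_pairs(p, phi = 1.2, n_pairs = 10),
               "phi")
})

test_that("sweeps pool pairs_per_value pairs at each swept value", {
  base <- p_burst4()
  sw <- sweep_pairs(base, "kon", 0.1, 1, n_values = 3,
                    pairs_per_value = 20, t_end = 20, seed = 1)
  expect_equal(nrow(sw), 60)
  expect_equal(length(unique(sw$param_value)), 3)
  expect_true(all(table(sw$param_value) == 20))
  expect_identical(attr(sw, "spacing"), "log")
  lin <- sweep_pairs(base, "koff", 0.1, 1, n_values = 4,
                     pairs_per_value = 5, t_end = 10, seed = 1,
                     spacing = "linear")
  expect_equal(attr(lin, "values"), seq(0.1, 1, length.out = 4))
  expect_error(sweep_pairs(base, "Dp", 0.1, 1), "arg")
  expect_error(sweep_pairs(base, "kon", 0, 1, spacing = "log"), "log")
})

test_that("the steady-state diagnostic tracks the closed form", {
  p <- p_const()
  chk <- steady_state_check(p, t_end = 2000, seed = 2)
  expect_equal(chk$observed[chk$quantity == "mrna"],
               chk$predicted[chk$quantity == "mrna"], tolerance = 0.25)
  expect_equal(chk$observed[chk$quantity == "protein"],
               chk$predicted[chk$quantity == "protein"], tolerance = 0.25)
})
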