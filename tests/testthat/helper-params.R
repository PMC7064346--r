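# Shared fixtures: the measured rate constants used throughout the suite.
# Dm = 0.0462/min (mRNA decay), Dp = 0.01/min (protein decay as used in
# simulations), Sp = 0.5 protein/mRNA/min, Sm = 0.5 mRNA/min, and a
# two-state promoter with burst size Sm/koff = 4.

p_const <- function() {
  constitutive_params(Sm = 0.5, Sp = 0.5, Dm = 0.0462, Dp = 0.01)
}

p_burst4 <- function(kon = 1) {
  kinetic_params(kon = kon, koff = 0.125, Sm = 0.5, Sp = 0.5,
                 Dm = 0.0462, Dp = 0.01)
}

# log-normal multiplicative noise with unit mean and given CV
mult_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# stationary distribution of the mutually inhibiting two-promoter chain
# (states 00, 10, 01, 11), solved exactly from the generator matrix
promoter_pair_stationary <- function(kon, koff, phi) {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- kon; Q[1, 3] <- kon
  Q[2, 4] <- kon * (1 - phi); Q[2, 1] <- koff
  Q[3, 4] <- kon * (1 - phi); Q[3, 1] <- koff
  Q[4, 2] <- koff; Q[4, 3] <- koff
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 4))
  stats::setNames(qr.solve(A, c(0, 0, 0, 0, 1)),
                  c("00", "10", "01", "11"))
}
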