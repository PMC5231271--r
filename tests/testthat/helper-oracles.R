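# Independent oracles and small generators used across the test files.

# brute-force Kendall tau-a: enumerate all pairs; ties count for neither side
tau_bruteforce <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (n * (n - 1) / 2)
}

# bivariate normal sample with correlation rho
rbvn <- function(n, rho) {
  u <- rnorm(n)
  cbind(u, rho * u + sqrt(1 - rho^2) * rnorm(n))
}

# standard-normal quintile cuts used by the ordinal observation scheme
quintiles <- qnorm(c(0.2, 0.4, 0.6, 0.8))

# a small mixed-scale phenotype trio (continuous, binary, ordinal) sharing a
# latent equicorrelation, plus an independent or associated genotype
make_mixed_trio <- function(n, rho, effect = 0, maf = 0.3) {
  z <- rbinom(n, 2L, maf)
  Sigma <- matrix(rho, 3, 3); diag(Sigma) <- 1
  V <- outer(z - 1, rep(effect, 3)) + matrix(rnorm(n * 3), n, 3) %*% chol(Sigma)
  ph <- cbind(V[, 1],
              as.integer(V[, 2] > 0),
              findInterval(V[, 3], quintiles) + 1L)
  list(phenotypes = ph, scales = c("continuous", "binary", "ordinal"), z = z)
}
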