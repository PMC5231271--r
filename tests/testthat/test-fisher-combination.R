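# Fisher statistic, covariance polynomial, gamma moment matching, combined
# p-values, and the permutation oracle on a small dataset.

test_that("Fisher statistic matches direct evaluation and rejects bad input", {
  expect_equal(fisher_statistic(c(1, 1, 1)), 0)
  expect_equal(fisher_statistic(c(exp(-1), exp(-2))), 6)
  expect_equal(fisher_statistic(rep(0.05, 6)), -12 * log(0.05), tolerance = 1e-12)
  # order invariance and block additivity
  p <- c(0.2, 0.01, 0.7)
  expect_equal(fisher_statistic(p), fisher_statistic(rev(p)))
  expect_equal(fisher_statistic(p), fisher_statistic(p[1:2]) + fisher_statistic(p[3]))
  # log-space input agrees and survives underflow-scale values
  expect_equal(fisher_statistic(log(p), log = TRUE), fisher_statistic(p))
  expect_equal(fisher_statistic(c(-800, -900), log = TRUE), 3400)
  expect_error(fisher_statistic(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_statistic(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("covariance polynomial reproduces derived values and its shape", {
  expect_equal(pair_covariance(0, 1000), -0.0039081, tolerance = 1e-10)
  expect_equal(pair_covariance(1, 1000), 3.9979, tolerance = 1e-10)
  expect_equal(pair_covariance(0.5, 1000), 0.9779334, tolerance = 1e-6)
  # even in rho; increasing in |rho|; finite-sample term vanishes at |rho|=1
  r <- seq(0, 1, by = 0.05)
  expect_equal(pair_covariance(-r, 500), pair_covariance(r, 500))
  expect_true(all(diff(pair_covariance(r, 500)) > 0))
  expect_equal(pair_covariance(-1, 17), 3.9979, tolerance = 1e-10)
  expect_error(pair_covariance(1.01, 100), "\\[-1, 1\\]")
  expect_error(pair_covariance(0.5, 1), ">= 2")
})

test_that("gamma null moment identities hold exactly by construction", {
  # independence, infinite n: chi-squared with 2M df
  g <- gamma_null(diag(2), n = Inf)
  expect_equal(g$kappa, 2)
  expect_equal(g$nu, 2)
  # derived M=2, rho=0.5, n=1000 parameters
  g2 <- gamma_null(matrix(c(1, .5, .5, 1), 2), n = 1000)
  expect_equal(g2$var_S, 9.9559, tolerance = 1e-4)
  expect_equal(g2$nu, 2.48897, tolerance = 1e-5)
  expect_equal(g2$kappa, 1.60709, tolerance = 1e-5)
  # kappa*nu = 2M and kappa*nu^2 = var_S for arbitrary valid inputs
  set.seed(601)
  for (M in c(2, 4, 6)) {
    L <- matrix(rnorm(M * M), M)
    R <- cov2cor(crossprod(L) + diag(M))
    g <- gamma_null(R, n = 250, M = M)
    expect_equal(g$kappa * g$nu, 2 * M, tolerance = 1e-12)
    expect_equal(g$kappa * g$nu^2, g$var_S, tolerance = 1e-10)
  }
  # M=6 equicorrelated: var = 24 + 30 * pair_covariance(rho)
  rho <- 0.35
  R6 <- matrix(rho, 6, 6); diag(R6) <- 1
  expect_equal(gamma_null(R6, n = 100)$var_S,
               24 + 30 * pair_covariance(rho, 100), tolerance = 1e-12)
  # flagged (NA) correlations refuse combination
  Rna <- diag(2); Rna[1, 2] <- Rna[2, 1] <- NA
  expect_error(gamma_null(Rna, n = 100), "flagged")
})

test_that("combined p-value reduces to the marginal at M=1 and to closed forms", {
  g1 <- gamma_null(M = 1, n = Inf)
  for (p0 in c(0.9, 0.05, 1e-8, 1e-30)) {
    expect_equal(combined_pvalue(-2 * log(p0), g1), p0, tolerance = 1e-10)
  }
  # M=2 independent: (1 + S/2) exp(-S/2)
  g2 <- gamma_null(diag(2), n = Inf)
  S <- -2 * log(0.1) * 2
  expect_equal(combined_pvalue(S, g2), (1 + S / 2) * exp(-S / 2), tolerance = 1e-10)
  expect_equal(combined_pvalue(S, g2), 0.0560517, tolerance = 1e-6)
  expect_equal(combined_pvalue(0, g2), 1)
  # strictly decreasing in S
  ss <- seq(0, 40, by = 2)
  expect_true(all(diff(combined_pvalue(ss, g2)) < 0))
  expect_error(combined_pvalue(-1, g2), "nonnegative")
})

test_that("multivariate scan reuses one null, skips or reduces flagged SNPs", {
  set.seed(602)
  d <- make_mixed_trio(250, 0.35, effect = 0.5)
  genos <- cbind(assoc = d$z, null = rbinom(250, 2, 0.3),
                 sep = as.integer(rbinom(250, 2, 0.3) == 2))
  # make the binary phenotype separate perfectly on the third SNP
  ph <- d$phenotypes
  ph[, 2] <- genos[, "sep"]
  R <- latent_cor(ph, d$scales)
  marg <- marginal_scan(ph, d$scales, genos)
  out <- multivariate_scan(marg, R)
  expect_length(out, 3L)
  sep_rec <- out[[3]]
  expect_true(is.na(sep_rec$p_multi))
  expect_equal(sep_rec$M_used, 0L)
  # reduced-M mode recombines the remaining phenotypes with a recomputed null
  out2 <- multivariate_scan(marg, R, on_flagged = "reduce")
  expect_equal(out2[[3]]$M_used, 2L)
  expect_true(is.finite(out2[[3]]$p_multi))
  # consistency of the non-flagged records across modes
  expect_equal(out[[1]]$p_multi, out2[[1]]$p_multi)
  # the S identity: sum of -2 log marginal p over used phenotypes
  expect_equal(out[[1]]$S, sum(-2 * marg[[1]]$logp), tolerance = 1e-12)
})

test_that("permutation oracle is reproducible and bounded as specified", {
  set.seed(603)
  d <- make_mixed_trio(150, 0.35, effect = 0)
  pr <- permutation_pvalue(d$phenotypes, d$scales, d$z, B = 200, seed = 604)
  expect_gte(pr$p_perm, 1 / 201)
  expect_lte(pr$p_perm, 1)
  # identical seed, identical stream
  pr2 <- permutation_pvalue(d$phenotypes, d$scales, d$z, B = 200, seed = 604)
  expect_equal(pr$p_perm, pr2$p_perm)
  # an overwhelmingly associated SNP attains the lower bound 1/(B+1)
  set.seed(605)
  dd <- make_mixed_trio(300, 0.2, effect = 1.5)
  pr3 <- permutation_pvalue(dd$phenotypes, dd$scales, dd$z, B = 199, seed = 606)
  expect_equal(pr3$p_perm, 1 / 200)
  expect_error(permutation_pvalue(d$phenotypes, d$scales, d$z, B = 50),
               "at least 100")
})
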