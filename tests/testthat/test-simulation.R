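# Generators and experiment drivers: distributional laws, determinism, and
# small-scale behaviour of the three study drivers (full-scale calibration is
# exercised by the acceptance suite).

test_that("genotype generator follows the binomial allele-count law", {
  set.seed(701)
  z <- simulate_genotypes(4e4, 0.5)
  expect_true(all(z %in% 0:2))
  expect_equal(mean(z), 1, tolerance = 0.02)
  expect_equal(unname(tabulate(z + 1L, 3) / 4e4), c(.25, .5, .25), tolerance = 0.03)
  expect_equal(mean(simulate_genotypes(4e4, 0.1)), 0.2, tolerance = 0.02)
  expect_error(simulate_genotypes(10, 0.7), "\\(0, 0.5\\]")
  expect_error(simulate_genotypes(10, 0), "\\(0, 0.5\\]")
  set.seed(5); a <- simulate_genotypes(100, 0.3)
  set.seed(5); b <- simulate_genotypes(100, 0.3)
  expect_identical(a, b)
})

test_that("latent generator hits the requested moments and genotype shifts", {
  set.seed(702)
  V <- simulate_latents(rep(1L, 2e4), rho = 0.75, effects = rep(0, 4))
  cc <- cor(V)
  expect_equal(unname(cc[upper.tri(cc)]), rep(0.75, 6), tolerance = 0.03)
  expect_equal(unname(apply(V, 2, var)), rep(1, 4), tolerance = 0.05)
  # mean separation between homozygote groups is 2 * effect
  z <- c(rep(0L, 8000), rep(2L, 8000))
  V2 <- simulate_latents(z, rho = 0, effects = c(0.9, 0))
  expect_equal(mean(V2[z == 2, 1]) - mean(V2[z == 0, 1]), 1.8, tolerance = 0.06)
  expect_equal(mean(V2[z == 2, 2]) - mean(V2[z == 0, 2]), 0, tolerance = 0.06)
  expect_error(simulate_latents(0:2, rho = -0.9, effects = rep(0, 6)),
               "positive definite")
})

test_that("discretize implements the threshold conventions", {
  expect_identical(discretize(c(-1, 0.5), "binary", 0), c(0L, 1L))
  # boundary value goes below the cut (strict >)
  expect_identical(discretize(c(0, 1e-9), "binary", 0), c(0L, 1L))
  v <- c(-2, -0.5, 0.1, 0.9, 3)
  expect_identical(discretize(v, "ordinal", quintiles),
                   findInterval(v, quintiles) + 1L)
  # explicit quintile cuts give balanced level frequencies
  set.seed(703)
  lv <- tabulate(discretize(rnorm(2e4), "ordinal", quintiles), 5) / 2e4
  expect_equal(lv, rep(0.2, 5), tolerance = 0.05)
  # default ordinal cuts divide the observed range into 5 equal-width bins
  w <- rnorm(5e3)
  dd <- discretize(w, "ordinal")
  expect_identical(dd, findInterval(w, min(w) + (1:4) * (max(w) - min(w)) / 5) + 1L)
  expect_equal(sort(unique(dd)), 1:5)
  # a cut below the data range puts everything in the top category
  expect_identical(discretize(c(0.5, 2), "binary", -10), c(1L, 1L))
  expect_error(discretize(v, "ordinal", c(1, 0)), "increasing")
})

test_that("correlation accuracy driver returns calibrated cells and honors seeds", {
  t1 <- sim_correlation_accuracy(rho_grid = 0.5,
                                 pairs = list(c("continuous", "binary")),
                                 reps = 150, n = 400, seed = 704)
  expect_equal(t1$mean, 0.5, tolerance = 3.5 * t1$se)
  t2 <- sim_correlation_accuracy(rho_grid = 0.5,
                                 pairs = list(c("continuous", "binary")),
                                 reps = 150, n = 400, seed = 704)
  expect_identical(t1, t2)
  t3 <- sim_correlation_accuracy(rho_grid = 0, pairs = list(c("binary", "binary")),
                                 reps = 100, n = 300, seed = 705)
  expect_equal(t3$mean, 0, tolerance = 3.5 * t3$se)
})

test_that("covariance accuracy driver is near zero at rho = 0 and conservative", {
  cv <- sim_covariance_accuracy(rho_grid = c(0, 0.5),
                                pairs = list(c("binary", "binary")),
                                reps = 400, n = 300, seed = 706)
  expect_equal(cv$empirical[cv$rho == 0], 0, tolerance = 3.5 * cv$se[cv$rho == 0])
  # thresholding attenuates dependence: empirical below the plug-in estimate
  expect_lt(cv$empirical[cv$rho == 0.5],
            cv$estimate[cv$rho == 0.5] + 3 * cv$se[cv$rho == 0.5])
  expect_equal(cv$var_S_empirical, 8 + 2 * cv$empirical, tolerance = 1e-12)
})

test_that("power driver rejects near nominal under the null and detects signal", {
  r0 <- sim_power(rho = 0, effects = rep(0, 6), reps = 150, alpha = 0.05,
                  methods = c("Mixed", "Continuous"), seed = 707)
  expect_true(all(r0$power <= 0.05 + 3 * sqrt(0.05 * 0.95 / 150)))
  r1 <- sim_power(rho = 0, effects = rep(0.5, 6), reps = 120, alpha = 1e-4,
                  methods = c("Latent", "Mixed", "Dichotomous"), seed = 708)
  expect_gt(r1$power[r1$method == "Latent"], 0.8)
  expect_gt(r1$power[r1$method == "Mixed"], 0.75)
  # gold standard at least as powerful as the observed-scale tests
  expect_gte(r1$power[r1$method == "Latent"] + 3 * max(r1$se),
             r1$power[r1$method == "Mixed"])
  expect_gte(r1$power[r1$method == "Mixed"] + 3 * max(r1$se),
             r1$power[r1$method == "Dichotomous"])
  # reproducibility under the master seed
  r2 <- sim_power(rho = 0, effects = rep(0.5, 6), reps = 120, alpha = 1e-4,
                  methods = c("Latent", "Mixed", "Dichotomous"), seed = 708)
  expect_identical(r1$power, r2$power)
})
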