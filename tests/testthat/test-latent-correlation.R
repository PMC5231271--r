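# Latent-correlation estimators: hand-computable examples, closed forms,
# estimator agreement, and parameter recovery at moderate n.

test_that("Kendall tau-a matches brute-force pair enumeration", {
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1)
  # K_c = 4, K_d = 2 over the 6 pairs
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3)
  set.seed(402)
  for (i in 1:5) {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_equal(kendall_tau(x, y), tau_bruteforce(x, y), tolerance = 1e-12)
  }
  # tied values count as neither concordant nor discordant, denominator fixed
  xt <- c(1, 1, 2, 3); yt <- c(2, 1, 1, 3)
  expect_equal(kendall_tau(xt, yt), tau_bruteforce(xt, yt), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(kendall_tau(exp(x), y^3 + y), kendall_tau(x, y))
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(kendall_tau(1, 2), "complete pairs")
})

test_that("sine transform maps tau to the normal correlation", {
  expect_equal(kendall_sine(0), 0)
  expect_equal(kendall_sine(1), 1)
  expect_equal(kendall_sine(1 / 3), 0.5)
  expect_equal(kendall_sine(-0.5), -kendall_sine(0.5))  # odd
  tt <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(kendall_sine(tt)) > 0))          # strictly increasing
  expect_error(kendall_sine(1.2), "\\[-1, 1\\]")
  # agrees with the product-moment correlation of the latent sample
  set.seed(403)
  uv <- rbvn(5000, 0.6)
  expect_equal(kendall_sine(kendall_tau(uv[, 1], uv[, 2])),
               cor(uv[, 1], uv[, 2]), tolerance = 0.03)
})

test_that("Brogden/Lord biserial reproduce hand-computed values and bounds", {
  # numerator (3+4) - 4*0.5*2.5 = 2; denominator (4+3) - 5 = 2
  expect_equal(brogden_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(brogden_biserial(c(1, 2, 3, 4), c(1, 0, 0, 1)), 0)
  expect_equal(lord_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))$rho, 1)
  expect_equal(lord_biserial(-c(1, 2, 3, 4), c(0, 0, 1, 1))$rho, -1)
  # sign-equivariance on noisy data
  set.seed(404)
  uv <- rbvn(400, 0.45)
  x <- as.integer(uv[, 1] > 0)
  expect_equal(lord_biserial(-uv[, 2], x)$rho, -lord_biserial(uv[, 2], x)$rho)
  expect_lte(abs(lord_biserial(uv[, 2], x)$rho), 1)
  expect_error(brogden_biserial(c(1, 2, 3), c(1, 1, 1)), "constant")
  # recovery at moderate n
  set.seed(405)
  uv <- rbvn(4000, 0.8)
  expect_equal(lord_biserial(uv[, 2], as.integer(uv[, 1] > 0))$rho, 0.8,
               tolerance = 0.05)
})

test_that("tetrachoric MLE solves the orthant equation", {
  expect_equal(tetrachoric(matrix(c(25, 25, 25, 25), 2))$rho, 0, tolerance = 1e-6)
  # balanced margins give the closed form sin(2*pi*(p11 - 1/4))
  expect_equal(tetrachoric(matrix(c(35, 15, 15, 35), 2))$rho,
               sin(2 * pi * (0.35 - 0.25)), tolerance = 1e-5)
  for (p11 in c(0.05, 0.15, 0.3, 0.45)) {
    n11 <- round(400 * p11)
    tab <- matrix(c(n11, 200 - n11, 200 - n11, n11), 2)
    expect_equal(tetrachoric(tab)$rho, sin(2 * pi * (n11 / 400 - 0.25)),
                 tolerance = 1e-4)
  }
  # monotone in p11 for fixed margins
  rhos <- vapply(c(30, 35, 40, 45), function(n11)
    tetrachoric(matrix(c(n11, 50 - n11, 50 - n11, n11), 2))$rho, 0)
  expect_true(all(diff(rhos) > 0))
  # degenerate margin errors; zero cell clamps to the boundary with a flag
  expect_error(tetrachoric(matrix(c(10, 0, 20, 0), 2)), "margin")
  est <- tetrachoric(matrix(c(30, 10, 10, 0), 2))
  expect_true(est$boundary)
  expect_lte(abs(est$rho), 0.999)
})

test_that("polychoric agrees with tetrachoric on 2x2 and recovers rho on RxC", {
  tab <- matrix(c(35, 15, 15, 35), 2)
  expect_equal(polychoric(tab)$rho, tetrachoric(tab)$rho, tolerance = 1e-4)
  set.seed(406)
  for (rho in c(-0.6, 0.4)) {
    uv <- rbvn(3000, rho)
    x <- findInterval(uv[, 1], quintiles) + 1L
    y <- findInterval(uv[, 2], quintiles) + 1L
    expect_equal(polychoric(x = x, y = y)$rho, rho, tolerance = 0.06)
  }
  # independence table -> 0
  ind <- outer(c(20, 30, 50), c(40, 60)) / 100
  expect_equal(polychoric(ind)$rho, 0, tolerance = 1e-3)
  expect_error(polychoric(matrix(c(5, 0, 7, 0), 2)), "margin")
})

test_that("polyserial recovers the latent correlation and handles edge cases", {
  set.seed(407)
  uv <- rbvn(3000, 0.5)
  x <- findInterval(uv[, 1], quintiles) + 1L
  expect_equal(polyserial(uv[, 2], x)$rho, 0.5, tolerance = 0.06)
  uv <- rbvn(3000, -0.8)
  x <- findInterval(uv[, 1], quintiles) + 1L
  expect_equal(polyserial(uv[, 2], x)$rho, -0.8, tolerance = 0.05)
  # independent inputs -> ~0
  expect_equal(polyserial(rnorm(2000), sample(1:4, 2000, TRUE))$rho, 0,
               tolerance = 0.08)
  expect_error(polyserial(rnorm(20), rep(2L, 20)), "single ordinal level")
  expect_error(polyserial(rep(1, 20), rep(1:2, 10)), "constant")
})

test_that("pairwise dispatch follows the scale table and is symmetric", {
  set.seed(408)
  uv <- rbvn(300, 0.5)
  cont <- uv[, 1]; cont2 <- uv[, 2]
  bin <- as.integer(uv[, 2] > 0)
  ordn <- findInterval(uv[, 2], quintiles) + 1L
  expect_equal(latent_cor_pair(cont, cont2, "continuous", "continuous")$method,
               "kendall_sine")
  expect_equal(latent_cor_pair(cont, bin, "continuous", "binary")$method,
               "lord_biserial")
  expect_equal(latent_cor_pair(cont, ordn, "continuous", "ordinal")$method,
               "polyserial")
  expect_equal(latent_cor_pair(bin, bin, "binary", "binary")$method,
               "tetrachoric")
  expect_equal(latent_cor_pair(bin, ordn, "binary", "ordinal")$method,
               "polychoric")
  expect_equal(latent_cor_pair(ordn, ordn, "ordinal", "ordinal")$method,
               "polychoric")
  # symmetry under argument swap
  expect_equal(latent_cor_pair(cont, bin, "continuous", "binary")$rho,
               latent_cor_pair(bin, cont, "binary", "continuous")$rho)
  # perfect linear relation between continuous pairs
  expect_equal(latent_cor_pair(cont, 2 * cont + 1, "continuous", "continuous")$rho, 1)
  expect_error(latent_cor_pair(cont[1:5], bin[1:5], "continuous", "binary"),
               "complete pairs")
})

test_that("latent_cor assembles a symmetric unit-diagonal matrix and records failures", {
  set.seed(409)
  d <- make_mixed_trio(500, 0.5)
  R <- latent_cor(d$phenotypes, d$scales)
  expect_true(isSymmetric(unclass(R)))
  expect_equal(diag(unclass(R)), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(abs(R[upper.tri(R)] - 0.5) < 0.15))
  expect_equal(attr(R, "methods")[1, 2], "lord_biserial")
  # three mutually independent columns -> near-zero off-diagonals
  ph0 <- cbind(rnorm(800), as.integer(rnorm(800) > 0),
               findInterval(rnorm(800), quintiles) + 1L)
  R0 <- latent_cor(ph0, d$scales)
  expect_true(all(abs(R0[upper.tri(R0)]) < 0.12))
  # a constant column fails its pairs but leaves the rest intact
  ph_bad <- cbind(ph0, 1)
  Rb <- latent_cor(ph_bad, c(d$scales, "binary"))
  expect_true(all(is.na(Rb[4, 1:3])))
  expect_length(attr(Rb, "failures"), 3L)
  expect_false(anyNA(Rb[1:3, 1:3]))
})

test_that("equicorrelated six-column mixed instrument recovers its latent correlation", {
  set.seed(410)
  z <- simulate_genotypes(1500, 0.3)
  V <- simulate_latents(z, rho = 0.5, effects = rep(0, 6))
  ph <- cbind(V[, 1:2],
              discretize(V[, 3], "binary"), discretize(V[, 4], "binary"),
              discretize(V[, 5], "ordinal"), discretize(V[, 6], "ordinal"))
  scales <- c("continuous", "continuous", "binary", "binary", "ordinal", "ordinal")
  R <- latent_cor(ph, scales)
  expect_true(all(abs(R[upper.tri(R)] - 0.5) < 0.1))
})
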