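# Synthetic-data generators and the three simulation studies:
#   1. correlation-estimator accuracy (mean/SD of estimates over a rho grid),
#   2. covariance conservativeness (empirical cov of -2 log p pairs vs the
#      polynomial estimate),
#   3. type-I error and power of four analysis strategies on a pleiotropic
#      six-phenotype design (Latent / Mixed / Dichotomous / Continuous).
#
# Study conditions (the defaults): n = 1000 individuals for the correlation
# and covariance studies; the power design uses n = 100, six phenotypes
# (2 continuous, 2 binary, 2 ordinal with 5 levels), latent equicorrelation
# rho in {0, 0.35, 0.75}, genetic effects in {0, 0.5, 0.7, 0.9}, MAF drawn
# uniformly on [0.1, 0.5] per replicate, and alpha = 1e-4. Binary cuts sit at
# the latent median (0); ordinal cuts divide the observed range into five
# equal-width intervals (see discretize()).
# Seeding: a master seed spawns one child seed per replicate, so any single
# replicate is reproducible in isolation.

# default observation scheme of the six-phenotype power design
.POWER_SCALES <- c("continuous", "continuous", "binary", "binary", "ordinal", "ordinal")

.child_seeds <- function(seed, reps) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max - 1L, reps))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Simulate additive genotype dosages under Hardy-Weinberg equilibrium
#'
#' Allele counts `Z ~ Binomial(2, maf)` per individual, so `E[Z] = 2 * maf`
#' and genotype frequencies follow Hardy-Weinberg proportions.
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Integer vector of 0/1/2 dosages.
#' @export
simulate_genotypes <- function(n, maf) {
  if (!is.finite(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  rbinom(n, 2L, maf)
}

#' Simulate pleiotropic latent phenotypes
#'
#' Latent vector `V_i ~ MVN(mu(Z_i), Sigma)` per individual with unit
#' variances and equicorrelation `rho`; the genotype shifts each latent mean
#' additively: `mu_j = -e_j, 0, +e_j` for `Z = 0, 1, 2`.
#'
#' @param z Genotype dosage vector.
#' @param rho Latent equicorrelation; the implied matrix must be positive
#'   definite (`rho > -1/(M-1)`).
#' @param effects Vector of genetic effect sizes `e_1..e_M`.
#' @return n x M matrix of latent phenotypes.
#' @export
simulate_latents <- function(z, rho, effects) {
  M <- length(effects)
  n <- length(z)
  Sigma <- matrix(rho, M, M); diag(Sigma) <- 1
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("equicorrelation matrix is not positive definite", call. = FALSE))
  E <- matrix(rnorm(n * M), n, M) %*% L
  mu <- outer(z - 1, effects)
  mu + E
}

#' Threshold a continuous vector onto a binary or ordinal scale
#'
#' Binary: 1 iff `v > cuts[1]`. Ordinal: level `k` iff `v` lies in
#' `(cuts[k-1], cuts[k]]`, with open extremes, giving levels `1..length(cuts)+1`.
#'
#' Default cuts reproduce the validation-study conditions: binary splits at 0
#' (the latent median); ordinal divides the *observed range* into five
#' equal-width intervals (`min(v) + k * range/5`, `k = 1..4`). Equal-width
#' division — not equal-probability quintiles — is what the reference
#' sampling distributions of the polyserial/polychoric estimators imply
#' (equal-probability cuts give visibly smaller estimator SDs at high
#' correlation); pass `cuts = qnorm(c(.2, .4, .6, .8))` for quintiles.
#'
#' @param v Continuous vector.
#' @param scale `"binary"` or `"ordinal"`.
#' @param cuts Strictly increasing cut points; defaults as described above.
#' @return Integer vector on the requested scale.
#' @export
discretize <- function(v, scale = c("binary", "ordinal"), cuts = NULL) {
  scale <- match.arg(scale)
  if (is.null(cuts)) {
    cuts <- if (scale == "binary") 0 else
      min(v) + seq_len(4L) * (max(v) - min(v)) / 5
  }
  if (is.unsorted(cuts, strictly = TRUE)) stop("cuts must be strictly increasing", call. = FALSE)
  if (scale == "binary") {
    if (length(cuts) != 1L) stop("binary discretization takes one cut", call. = FALSE)
    as.integer(v > cuts)
  } else {
    out <- rep(1L, length(v))
    for (ct in cuts) out <- out + (v > ct)
    out
  }
}

# Observe the latent matrix under the mixed-scale scheme.
.observe_mixed <- function(V, scales = .POWER_SCALES) {
  U <- V
  for (j in seq_along(scales)) {
    if (scales[j] == "binary")  U[, j] <- discretize(V[, j], "binary")
    if (scales[j] == "ordinal") U[, j] <- discretize(V[, j], "ordinal")
  }
  U
}

# Draw one bivariate-normal sample and observe it under the given scale pair.
.observe_pair <- function(n, rho, pair) {
  z2 <- rnorm(n)
  u <- z2
  v <- rho * z2 + sqrt(1 - rho^2) * rnorm(n)
  obs <- function(x, sc) switch(sc, continuous = x,
                                binary = discretize(x, "binary"),
                                ordinal = discretize(x, "ordinal"))
  list(x = obs(u, pair[1L]), y = obs(v, pair[2L]))
}

.PAIR_GRID <- list(
  c("continuous", "continuous"), c("continuous", "binary"),
  c("continuous", "ordinal"), c("binary", "binary"),
  c("binary", "ordinal"), c("ordinal", "ordinal")
)

#' Correlation-estimator accuracy study
#'
#' For each latent correlation and scale pair, draws `reps` bivariate-normal
#' samples of size `n`, observes them on the pair's scales (median cut for
#' binary, quintile cuts for ordinal), estimates the latent correlation with
#' the scale-matched estimator, and tabulates the mean and SD of the
#' estimates.
#'
#' @param rho_grid Latent correlations to cover.
#' @param pairs List of 2-vectors of scales; defaults to all six combinations.
#' @param reps Replicates per cell.
#' @param n Sample size per replicate.
#' @param seed Master seed.
#' @return Data frame with columns `pair`, `rho`, `mean`, `sd`, `se`, `reps`.
#' @export
sim_correlation_accuracy <- function(rho_grid = seq(-0.9, 0.9, by = 0.1),
                                     pairs = .PAIR_GRID, reps = 1000L,
                                     n = 1000L, seed = NULL) {
  rows <- list()
  for (pair in pairs) {
    pname <- paste(pair, collapse = "-")
    for (rho in rho_grid) {
      seeds <- .child_seeds(seed, reps)
      est <- vapply(seq_len(reps), function(r) {
        set.seed(seeds[r])
        d <- .observe_pair(n, rho, pair)
        latent_cor_pair(d$x, d$y, pair[1L], pair[2L])$rho
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pname, rho = rho, mean = mean(est), sd = sd(est),
        se = sd(est) / sqrt(reps), reps = reps)
    }
  }
  do.call(rbind, rows)
}

#' Covariance conservativeness study
#'
#' For each latent correlation and scale pair, simulates `reps` null
#' replicates (genotype at the given MAF, independent of the phenotypes),
#' records the pair of marginal p-values, and compares the empirical
#' covariance of `(-2 log p_u, -2 log p_v)` with the polynomial estimate
#' [pair_covariance()] evaluated at the true `rho`. The estimate should be
#' conservative (at or above the empirical value) for thresholded scales and
#' tight for continuous-continuous.
#'
#' @param rho_grid Latent correlations to cover.
#' @param pairs List of scale pairs (default all six).
#' @param reps Null replicates per cell.
#' @param n Individuals per replicate.
#' @param maf Genotype minor allele frequency (study condition: 0.5).
#' @param seed Master seed.
#' @return Data frame with `pair`, `rho`, `empirical`, `estimate`, `se`
#'   (Monte-Carlo SE of the empirical covariance), `var_S_empirical`
#'   (`4*2 + 2*empirical`), `reps`.
#' @export
sim_covariance_accuracy <- function(rho_grid = c(-0.75, -0.5, -0.35, 0, 0.35, 0.5, 0.75),
                                    pairs = .PAIR_GRID, reps = 2000L,
                                    n = 1000L, maf = 0.5, seed = NULL) {
  rows <- list()
  for (pair in pairs) {
    pname <- paste(pair, collapse = "-")
    for (rho in rho_grid) {
      seeds <- .child_seeds(seed, reps)
      lp <- vapply(seq_len(reps), function(r) {
        set.seed(seeds[r])
        d <- .observe_pair(n, rho, pair)
        z <- simulate_genotypes(n, maf)
        c(marginal_test(d$x, z, pair[1L])$logp,
          marginal_test(d$y, z, pair[2L])$logp)
      }, numeric(2))
      a <- -2 * lp[1L, ]; b <- -2 * lp[2L, ]
      keep <- is.finite(a) & is.finite(b)
      a <- a[keep]; b <- b[keep]
      emp <- cov(a, b)
      # MC standard error of the sample covariance
      se <- sd((a - mean(a)) * (b - mean(b))) / sqrt(length(a))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pname, rho = rho, empirical = emp,
        estimate = pair_covariance(rho, n), se = se,
        var_S_empirical = 8 + 2 * emp, reps = sum(keep))
    }
  }
  do.call(rbind, rows)
}

# --- power / type-I study -----------------------------------------------------

# One replicate of the four-strategy comparison. Returns the multivariate
# p-value per strategy (NA when any marginal fit or correlation failed; such
# replicates are counted as non-rejections by the caller).
.power_replicate <- function(n, rho, effects, maf_range,
                             methods = c("Latent", "Mixed", "Dichotomous", "Continuous"),
                             true_rho = FALSE) {
  maf <- if (length(maf_range) == 2L) runif(1, maf_range[1L], maf_range[2L]) else maf_range
  z <- simulate_genotypes(n, maf)
  M <- length(effects)
  V <- simulate_latents(z, rho, effects)
  U <- .observe_mixed(V, .POWER_SCALES[seq_len(M)])
  scalesU <- .POWER_SCALES[seq_len(M)]
  # Dichotomous competitor: binary stays; continuous median-split at the
  # latent-scale median 0; ordinal split above its middle level.
  one <- function(ph, scales) {
    lp <- vapply(seq_len(M), function(j) marginal_test(ph[, j], z, scales[j])$logp, 0)
    if (any(!is.finite(lp))) return(NA_real_)
    R <- tryCatch(latent_cor(ph, scales), error = function(e) NULL)
    if (is.null(R) || any(!is.finite(R[upper.tri(R)]))) return(NA_real_)
    if (true_rho) R[upper.tri(R) | lower.tri(R)] <- rho
    null <- gamma_null(R, n = n, M = M)
    combined_pvalue(fisher_statistic(lp, log = TRUE), null)
  }
  out <- setNames(rep(NA_real_, length(methods)), methods)
  if ("Latent" %in% methods) out["Latent"] <- one(V, rep("continuous", M))
  if ("Mixed" %in% methods) out["Mixed"] <- one(U, scalesU)
  if ("Dichotomous" %in% methods) {
    # Dichotomous competitor: binary stays; continuous median-split at the
    # latent-scale median 0; ordinal split above its middle level.
    D <- U
    for (j in seq_len(M)) {
      D[, j] <- switch(scalesU[j],
        continuous = as.integer(U[, j] > 0),
        binary = U[, j],
        ordinal = as.integer(U[, j] > 3))
    }
    out["Dichotomous"] <- one(D, rep("binary", M))
  }
  if ("Continuous" %in% methods) out["Continuous"] <- one(U, rep("continuous", M))
  out
}

#' Type-I error and power study
#'
#' Simulates the pleiotropic six-phenotype design and estimates the rejection
#' proportion at level `alpha` for four analysis strategies sharing each
#' replicate's data (common random numbers): `Latent` (test applied to the
#' latent continuous phenotypes; the gold standard), `Mixed` (the proposed
#' test on the observed mixed-scale phenotypes), `Dichotomous` (everything
#' dichotomized, logistic marginals), and `Continuous` (everything treated as
#' continuous, linear marginals). Correlation matrices are re-estimated from
#' each replicate's phenotypes. Replicates with any flagged fit count as
#' non-rejections (conservative) and are tallied.
#'
#' @param rho Latent equicorrelation (0, 0.35, 0.75 in the study design).
#' @param effects Genetic effect sizes `e_1..e_6` (recycled to length 6).
#' @param reps Number of replicates.
#' @param n Individuals per replicate (study condition: 100).
#' @param maf_range MAF law: length-2 range for a per-replicate uniform draw,
#'   or a single fixed value.
#' @param alpha Significance level (study condition: 1e-4).
#' @param methods Subset of the four strategy names to run.
#' @param seed Master seed.
#' @return Data frame of class `power_table`: `method`, `power`, `se`
#'   (binomial MC error), `n_flagged`, `reps`, plus the design columns.
#' @export
sim_power <- function(rho = 0, effects = rep(0.5, 6), reps = 1000L, n = 100L,
                      maf_range = c(0.1, 0.5), alpha = 1e-4,
                      methods = c("Latent", "Mixed", "Dichotomous", "Continuous"),
                      seed = NULL) {
  effects <- rep_len(effects, 6L)
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- .child_seeds(seed, reps)
  pm <- vapply(seq_len(reps), function(r) {
    set.seed(seeds[r])
    .power_replicate(n, rho, effects, maf_range, methods)
  }, numeric(length(methods)))
  pm <- matrix(pm, nrow = length(methods))
  # flagged replicates (NA p) count as non-rejections
  rej <- rowMeans(!is.na(pm) & pm < alpha)
  out <- data.frame(
    method = methods,
    power = rej,
    se = sqrt(pmax(rej * (1 - rej), 1e-12) / reps),
    n_flagged = rowSums(is.na(pm)),
    reps = reps, rho = rho, alpha = alpha, n = n,
    effects = paste(effects, collapse = ","))
  class(out) <- c("power_table", "data.frame")
  out
}
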