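# Phase-2: combine the M marginal p-values per SNP into the Fisher statistic
# S = sum(-2 log p_j) and evaluate it against a gamma null whose moments are
# matched to the dependence among phenotypes:
#   E[S] = kappa * nu = 2M
#   Var[S] = kappa * nu^2 = 4M + sum_{j != j'} cov(-2 log p_j, -2 log p_j')
# with each pairwise covariance approximated by an even polynomial in the
# latent correlation plus a finite-sample correction (accurate to < 0.001):
#   cov ~ sum_{l=1..5} c_l rho^(2l) - (c_1 / N) (1 - rho^2)^2.
# Thresholded (binary/ordinal) phenotypes carry less dependence than their
# latents, so plugging in the latent correlation over-estimates the covariance
# -- the variance estimate is conservative and the type-I error is controlled.

# fixed polynomial constants of the covariance approximation
.FISHER_COV_C <- c(3.9081, 0.0313, 0.1022, -0.1378, 0.0941)

#' Fisher's combination statistic
#'
#' `S = sum(-2 log p_j)` over the marginal p-values of one SNP. Accepts
#' natural-log p-values directly (`log = TRUE`) so that genome-wide-significant
#' marginals never underflow before the transform.
#'
#' @param p Numeric vector of p-values in (0, 1], or their natural logs.
#' @param log Set to `TRUE` when `p` holds `log(p)`.
#' @return Scalar statistic, `>= 0`.
#' @examples
#' fisher_statistic(c(exp(-1), exp(-2)))  # 6
#' @export
fisher_statistic <- function(p, log = FALSE) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p))) stop("p-values must be finite (non-flagged)", call. = FALSE)
  lp <- if (log) p else {
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
    base::log(p)
  }
  if (log && any(lp > 0)) stop("log p-values must be <= 0", call. = FALSE)
  sum(-2 * lp)
}

#' Covariance of a dependent pair of -2 log p terms
#'
#' Polynomial approximation of `cov(-2 log p_j, -2 log p_j')` as a function of
#' the (latent) correlation `rho` between the two phenotypes:
#' `sum(c_l * rho^(2l)) - (c_1 / n) * (1 - rho^2)^2` with fixed constants
#' `c = (3.9081, 0.0313, 0.1022, -0.1378, 0.0941)`. Even in `rho`, increasing
#' in `|rho|`, equal to `sum(c) = 3.9979` at `|rho| = 1`, and slightly
#' negative (`-c_1/n`) at `rho = 0` -- the finite-sample term is kept exactly
#' as specified, without flooring.
#'
#' @param rho Correlation(s) in `[-1, 1]`.
#' @param n Sample size used for the correlation estimate (`>= 2`).
#' @return Covariance estimate(s).
#' @examples
#' pair_covariance(0.5, 1000)  # 0.97793...
#' @export
pair_covariance <- function(rho, n) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1))
    stop("rho must lie in [-1, 1]", call. = FALSE)
  if (any(n < 2)) stop("n must be >= 2", call. = FALSE)
  r2 <- rho^2
  poly <- .FISHER_COV_C[1] * r2 + .FISHER_COV_C[2] * r2^2 +
    .FISHER_COV_C[3] * r2^3 + .FISHER_COV_C[4] * r2^4 + .FISHER_COV_C[5] * r2^5
  poly - (.FISHER_COV_C[1] / n) * (1 - r2)^2
}

#' Gamma null distribution of the Fisher statistic
#'
#' Moment-matches the gamma null of `S` for `M` dependent phenotypes:
#' `Var[S] = 4M + sum_{j != j'} pair_covariance(rho_jj', n_jj')`, then
#' `nu = Var[S] / (2M)` and `kappa = 4M^2 / Var[S]` so that
#' `kappa * nu = 2M` holds exactly. Under independence (and `n -> Inf`) this
#' reduces to the chi-squared distribution with `2M` degrees of freedom.
#'
#' @param corr MxM latent correlation matrix (e.g. from [latent_cor()]), or
#'   `NULL` for the independence null.
#' @param n Sample size(s) for the finite-sample term: a scalar, or a matrix
#'   of pairwise complete counts (as in the `n_pair` attribute of
#'   [latent_cor()]). Use `Inf` to drop the finite-sample term.
#' @param M Number of phenotypes; defaults to `ncol(corr)`.
#' @return Object of class `gamma_null` with fields `kappa`, `nu`, `M`,
#'   `var_S`.
#' @examples
#' gamma_null(diag(2), n = Inf)  # kappa = 2, nu = 2: chi-squared, 4 df
#' @export
gamma_null <- function(corr = NULL, n = Inf, M = if (is.null(corr)) 1L else ncol(corr)) {
  if (is.null(corr)) corr <- diag(1, M)
  corr <- as.matrix(unclass(corr))
  if (nrow(corr) != M || ncol(corr) != M)
    stop("corr must be an MxM matrix", call. = FALSE)
  off <- upper.tri(corr)
  if (any(!is.finite(corr[off])))
    stop("correlation matrix has failed (flagged) entries; cannot build the null",
         call. = FALSE)
  nmat <- if (is.matrix(n)) n[off] else rep_len(n, sum(off))
  var_S <- 4 * M + 2 * sum(pair_covariance(corr[off], pmin(nmat, .Machine$double.xmax)))
  if (var_S <= 0) stop("non-positive Var[S]; pathological correlation input", call. = FALSE)
  nu <- var_S / (2 * M)
  kappa <- 4 * M^2 / var_S
  structure(list(kappa = kappa, nu = nu, M = M, var_S = var_S),
            class = "gamma_null")
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf("gamma null for Fisher S over M = %d phenotypes\n", x$M))
  cat(sprintf("  shape kappa = %.5f, scale nu = %.5f (E[S] = %.1f, Var[S] = %.4f)\n",
              x$kappa, x$nu, x$kappa * x$nu, x$var_S))
  invisible(x)
}

#' Combined multivariate p-value
#'
#' Upper-tail probability of the Fisher statistic under its gamma null.
#' With a single phenotype this returns the marginal p-value exactly
#' (the gamma reduces to an exponential with scale 2).
#'
#' @param S Fisher statistic(s), `>= 0`.
#' @param null A [gamma_null()] object.
#' @param log.p Return the natural log of the p-value.
#' @return Upper-tail probability in (0, 1].
#' @export
combined_pvalue <- function(S, null, log.p = FALSE) {
  stopifnot(inherits(null, "gamma_null"))
  if (any(S < 0)) stop("S must be nonnegative", call. = FALSE)
  pgamma(S, shape = null$kappa, scale = null$nu, lower.tail = FALSE, log.p = log.p)
}

#' Multivariate combination scan
#'
#' Combines per-SNP marginal p-values (from [marginal_scan()]) into
#' multivariate p-values. The latent correlation matrix and the gamma null are
#' computed once per phenotype set -- they are properties of the phenotypes,
#' not of any SNP -- and reused across all SNPs. SNPs with any flagged
#' marginal fit are skipped by default (reported with `NA` and the flag);
#' `on_flagged = "reduce"` instead re-forms the null from the non-flagged
#' subset of phenotypes for that SNP.
#'
#' @param marginals List of per-SNP marginal records from [marginal_scan()].
#' @param corr Latent correlation matrix of the phenotype set ([latent_cor()]).
#' @param n Sample size(s) for the finite-sample covariance term; defaults to
#'   the pairwise complete counts recorded on `corr`.
#' @param on_flagged `"skip"` (default) or `"reduce"`.
#' @return List of per-SNP records: `snp`, `S`, `p_multi`, `log_p_multi`,
#'   `M_used`, `flags`.
#' @export
multivariate_scan <- function(marginals, corr, n = NULL,
                              on_flagged = c("skip", "reduce")) {
  on_flagged <- match.arg(on_flagged)
  M <- ncol(corr)
  if (length(marginals) && length(marginals[[1L]]$p) != M)
    stop("phenotype set of marginal records does not match the correlation matrix",
         call. = FALSE)
  if (is.null(n)) {
    n <- attr(corr, "n_pair")
    if (is.null(n)) stop("supply n (no pairwise counts recorded on corr)", call. = FALSE)
  }
  null_full <- gamma_null(corr, n = n, M = M)
  lapply(marginals, function(rec) {
    ok <- is.finite(rec$logp)
    if (all(ok)) {
      S <- fisher_statistic(rec$logp, log = TRUE)
      return(list(snp = rec$snp, S = S,
                  p_multi = combined_pvalue(S, null_full),
                  log_p_multi = combined_pvalue(S, null_full, log.p = TRUE),
                  M_used = M, flags = rec$flags))
    }
    if (on_flagged == "skip" || sum(ok) < 1L) {
      return(list(snp = rec$snp, S = NA_real_, p_multi = NA_real_,
                  log_p_multi = NA_real_, M_used = 0L, flags = rec$flags))
    }
    sub <- which(ok)
    null_sub <- gamma_null(unclass(corr)[sub, sub, drop = FALSE],
                           n = if (is.matrix(n)) n[sub, sub, drop = FALSE] else n,
                           M = length(sub))
    S <- fisher_statistic(rec$logp[sub], log = TRUE)
    list(snp = rec$snp, S = S,
         p_multi = combined_pvalue(S, null_sub),
         log_p_multi = combined_pvalue(S, null_sub, log.p = TRUE),
         M_used = length(sub), flags = rec$flags)
  })
}

#' Permutation p-value for one SNP (validation oracle)
#'
#' Recomputes the Fisher statistic under `B` random permutations of the
#' genotype vector (breaking any genotype-phenotype association while keeping
#' the phenotype dependence intact) and returns
#' `(1 + #\{S_perm >= S_obs\}) / (B + 1)`. This is the slow exact-null oracle
#' the gamma approximation replaces; it validates, not powers, the scan.
#'
#' @param phenotypes N x M phenotype matrix.
#' @param scales Length-M scale declarations.
#' @param z Genotype dosage vector.
#' @param covariates Optional covariate matrix (rows permuted with `z`? no --
#'   covariates belong to individuals and stay fixed; only `z` is permuted).
#' @param B Number of permutations (`>= 100`).
#' @param seed Optional integer seed for the permutation stream.
#' @return List with `p_perm`, `S_obs`, `B`, `n_flagged_perms`.
#' @export
permutation_pvalue <- function(phenotypes, scales, z, covariates = NULL,
                               B = 1000L, seed = NULL) {
  if (B < 100L) stop("use at least 100 permutations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  phenotypes <- as.matrix(phenotypes)
  M <- ncol(phenotypes)
  s_of <- function(zz) {
    lp <- vapply(seq_len(M), function(j)
      marginal_test(phenotypes[, j], zz, scales[j], covariates)$logp, 0)
    if (any(!is.finite(lp))) return(NA_real_)
    fisher_statistic(lp, log = TRUE)
  }
  S_obs <- s_of(z)
  if (!is.finite(S_obs)) stop("flagged marginal fit on the observed data", call. = FALSE)
  S_perm <- vapply(seq_len(B), function(b) s_of(sample(z)), 0)
  nbad <- sum(!is.finite(S_perm))
  list(p_perm = (1 + sum(S_perm >= S_obs, na.rm = TRUE)) / (B + 1),
       S_obs = S_obs, B = B, n_flagged_perms = nbad)
}
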