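# Phase-1 marginal association tests: per-(SNP, phenotype) regression p-values
# with the model chosen by measurement scale. All three models report the
# two-sided Wald test on the additive genotype coefficient; p-values are
# carried in log space so downstream -2*log(p) sums never underflow.
#
# Fits operate on design matrices directly (no formula machinery): a genome
# scan makes one fit per SNP x phenotype and the simulation studies make
# hundreds of thousands, so per-call overhead matters.

# A marginal result: two-sided p (and its log), the genotype coefficient and
# SE, and a flag ("ok", or the reason the fit is unusable).
.marginal_result <- function(p, logp, beta = NA_real_, se = NA_real_, flag = "ok") {
  list(p = unname(p), logp = unname(logp), beta = unname(beta),
       se = unname(se), flag = flag)
}

.flagged <- function(flag) .marginal_result(NA_real_, NA_real_, flag = flag)

.design <- function(z, covariates, n) {
  if (is.null(covariates)) {
    cbind(`(Intercept)` = 1, genotype = z)
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    cbind(`(Intercept)` = 1, genotype = z, covariates)
  }
}

# Complete-case rows for one (SNP, phenotype) fit.
.complete_rows <- function(y, z, covariates) {
  keep <- is.finite(y) & is.finite(z)
  if (!is.null(covariates)) keep <- keep & apply(is.finite(as.matrix(covariates)), 1, all)
  keep
}

#' Linear-regression marginal test for a continuous phenotype
#'
#' Ordinary least squares of the phenotype on genotype dosage (0/1/2) plus
#' optional covariates; returns the classical two-sided t-test p-value for the
#' genotype slope.
#'
#' @param y Continuous phenotype vector.
#' @param z Genotype dosage vector (allele counts 0/1/2).
#' @param covariates Optional numeric matrix of covariates (no intercept).
#' @return List with `p`, `logp` (natural log of `p`), `beta`, `se`, `flag`.
#'   Flags: `"monomorphic"`, `"rank_deficient"`, `"boundary"` (numerically
#'   perfect fit).
#' @export
assoc_linear <- function(y, z, covariates = NULL) {
  keep <- .complete_rows(y, z, covariates)
  y <- y[keep]; z <- z[keep]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3L || var(z) == 0) return(.flagged("monomorphic"))
  X <- .design(z, covariates, n)
  fit <- lm.fit(X, y)
  df <- n - fit$rank
  if (fit$rank < ncol(X) || df < 1L) return(.flagged("rank_deficient"))
  rss <- sum(fit$residuals^2)
  if (rss <= 1e-12 * sum((y - mean(y))^2)) return(.flagged("boundary"))
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  i <- 2L  # genotype column
  se <- sqrt(sigma2 * XtXinv[i, i])
  tval <- fit$coefficients[i] / se
  logp <- log(2) + pt(abs(tval), df, lower.tail = FALSE, log.p = TRUE)
  .marginal_result(exp(logp), logp, fit$coefficients[i], se)
}

#' Logistic-regression marginal test for a binary phenotype
#'
#' Maximum-likelihood logistic regression of a 0/1 phenotype on genotype
#' dosage plus optional covariates; returns the two-sided Wald p-value for the
#' genotype coefficient. Complete or quasi-complete separation (detected by a
#' diverging coefficient or exploding standard error) and IRLS non-convergence
#' are flagged rather than reported as p-values.
#'
#' @inheritParams assoc_linear
#' @param y Binary phenotype vector coded 0/1.
#' @return As [assoc_linear()]; extra flags `"separation"`, `"no_variation"`,
#'   `"not_converged"`.
#' @export
assoc_logistic <- function(y, z, covariates = NULL) {
  keep <- .complete_rows(y, z, covariates)
  y <- y[keep]; z <- z[keep]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3L || var(z) == 0) return(.flagged("monomorphic"))
  if (length(unique(y)) < 2L) return(.flagged("no_variation"))
  X <- .design(z, covariates, n)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit)) return(.flagged("not_converged"))
  if (!fit$converged) {
    # distinguish (quasi-)complete separation from plain IRLS failure
    mu <- fit$fitted.values
    flag <- if (any(mu > 1 - 1e-6) || any(mu < 1e-6)) "separation" else "not_converged"
    return(.flagged(flag))
  }
  if (fit$rank < ncol(X)) return(.flagged("rank_deficient"))
  R <- qr.R(fit$qr)              # qr of sqrt(W) X at convergence
  cov <- chol2inv(R)             # (X' W X)^{-1}
  i <- 2L
  beta <- fit$coefficients[i]
  se <- sqrt(cov[i, i])
  if (!is.finite(se) || abs(beta) > 15 || se > 100) return(.flagged("separation"))
  zval <- beta / se
  logp <- log(2) + pnorm(abs(zval), lower.tail = FALSE, log.p = TRUE)
  .marginal_result(exp(logp), logp, beta, se)
}

# --- cumulative logit (proportional odds) ------------------------------------

# Direct Newton-type maximization of the proportional-odds log-likelihood
#   P(Y <= k | x) = plogis(zeta_k - x' beta),
# with analytic gradient, BFGS search, and the observed information at the
# optimum for Wald inference. MASS::polr fits the same model; this fitter
# exists because a scan/simulation makes ~10^5 such fits and the formula
# interface dominates the cost. polr serves as the independent cross-check
# in the test suite.
.cumlogit_fit <- function(y, X) {
  # Newton-Raphson on the proportional-odds negative log-likelihood with
  # analytic gradient and observed information; quadratic convergence in
  # ~4-6 iterations, and the information matrix at the optimum doubles as the
  # Wald covariance. Falls back to BFGS if the Newton step fails.
  K <- max(y)
  n <- length(y)
  p <- ncol(X)
  q <- K - 1L + p
  cnt <- tabulate(y, K)
  zeta0 <- qlogis(cumsum(cnt[-K]) / n)
  th <- c(zeta0, rep(0, p))
  bi <- K:(K + p - 1L)
  upK <- y == K; low0 <- y == 1L
  ui <- pmin(y, K - 1L)
  li <- pmax(y - 1L, 1L)
  agg <- function(w, idx) {           # sum w within threshold index, length K-1
    out <- numeric(K - 1L)
    s <- rowsum(w, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  vgh <- function(th) {
    zeta <- th[seq_len(K - 1L)]
    if (is.unsorted(zeta)) return(NULL)
    eta <- drop(X %*% th[bi])
    Fu <- plogis(zeta[ui] - eta); Fu[upK] <- 1
    Fl <- plogis(zeta[li] - eta); Fl[low0] <- 0
    pi_ <- pmax(Fu - Fl, 1e-300)
    fu <- Fu * (1 - Fu); fu[upK] <- 0
    fl <- Fl * (1 - Fl); fl[low0] <- 0
    au <- fu / pi_; bu <- fl / pi_
    cA <- fu * (1 - 2 * Fu) / pi_; cA[upK] <- 0
    cB <- fl * (1 - 2 * Fl) / pi_; cB[low0] <- 0
    s <- au - bu
    g <- c(-(agg(au, ui) - agg(bu, li)), drop(crossprod(X, s)))
    # observed information blocks
    Hzz <- diag(agg(-cA + au^2, ui) + agg(cB + bu^2, li), K - 1L)
    cross <- -au * bu                 # couples (ui, li) for interior categories
    int <- !upK & !low0
    if (any(int)) {
      cs <- rowsum(cross[int], ui[int])     # li = ui - 1 on interior rows
      for (r in seq_len(nrow(cs))) {
        k <- as.integer(rownames(cs))[r]
        if (k > 1L) {
          Hzz[k, k - 1L] <- Hzz[k, k - 1L] + cs[r]
          Hzz[k - 1L, k] <- Hzz[k, k - 1L]
        }
      }
    }
    wzb_u <- cA - au * s
    wzb_l <- cB - bu * s
    Hzb <- matrix(0, K - 1L, p)
    for (j in seq_len(p)) {
      Hzb[, j] <- agg(wzb_u * X[, j], ui) - agg(wzb_l * X[, j], li)
    }
    Hbb <- crossprod(X * (cB - cA + s^2), X)
    H <- rbind(cbind(Hzz, Hzb), cbind(t(Hzb), Hbb))
    list(v = -sum(log(pi_)), g = g, H = H)
  }
  cur <- vgh(th)
  if (is.null(cur)) return(.cumlogit_fit_bfgs(y, X))
  for (it in 1:30) {
    step_dir <- tryCatch(solve(cur$H, cur$g), error = function(e) NULL)
    if (is.null(step_dir) || any(!is.finite(step_dir)))
      return(.cumlogit_fit_bfgs(y, X))
    step <- 1
    repeat {
      cand <- th - step * step_dir
      nxt <- vgh(cand)
      if (!is.null(nxt) && is.finite(nxt$v) && nxt$v <= cur$v + 1e-12) break
      step <- step / 2
      if (step < 1e-10) return(.cumlogit_fit_bfgs(y, X))
    }
    converged <- max(abs(nxt$g)) < 1e-8 * (1 + abs(nxt$v)) ||
      abs(cur$v - nxt$v) < 1e-12 * (1 + abs(nxt$v))
    th <- cand; cur <- nxt
    if (converged) {
      cov <- tryCatch(chol2inv(chol(cur$H)), error = function(e) NULL)
      if (is.null(cov)) return(.cumlogit_fit_bfgs(y, X))
      return(list(zeta = th[seq_len(K - 1L)], beta = th[bi],
                  vcov_beta = cov[bi, bi, drop = FALSE], logLik = -cur$v))
    }
  }
  .cumlogit_fit_bfgs(y, X)
}

.cumlogit_fit_bfgs <- function(y, X) {
  K <- max(y)
  n <- length(y)
  p <- ncol(X)
  cnt <- tabulate(y, K)
  # start: marginal cumulative logits, slopes 0
  zeta0 <- qlogis(cumsum(cnt[-K]) / n)
  theta0 <- c(zeta0, rep(0, p))
  bi <- K:(K + p - 1L)
  upK <- y == K; low0 <- y == 1L      # open-ended categories
  ui <- pmin(y, K - 1L)               # index of upper threshold
  li <- pmax(y - 1L, 1L)              # index of lower threshold
  # negll and grad share all heavy computation; optim evaluates them at the
  # same point back-to-back, so cache by parameter vector.
  cache <- new.env(parent = emptyenv())
  evalpt <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return()
    zeta <- th[seq_len(K - 1L)]
    if (is.unsorted(zeta)) {
      cache$th <- th; cache$v <- 1e10
      cache$g <- numeric(K - 1L + p)
      return()
    }
    eta <- drop(X %*% th[bi])
    Fu <- plogis(zeta[ui] - eta); Fu[upK] <- 1
    Fl <- plogis(zeta[li] - eta); Fl[low0] <- 0
    pi_ <- pmax(Fu - Fl, 1e-300)
    du <- Fu * (1 - Fu); du[upK] <- 0
    dl <- Fl * (1 - Fl); dl[low0] <- 0
    wu <- du / pi_
    wl <- dl / pi_
    gz <- numeric(K - 1L)
    su <- rowsum(wu, ui); gz[as.integer(rownames(su))] <- su
    sl <- rowsum(wl, li); gz[as.integer(rownames(sl))] <- gz[as.integer(rownames(sl))] - sl
    cache$th <- th
    cache$v <- -sum(log(pi_))
    cache$g <- c(-gz, drop(crossprod(X, wu - wl)))
  }
  negll <- function(th) { evalpt(th); cache$v }
  grad <- function(th) { evalpt(th); cache$g }
  opt <- tryCatch(
    optim(theta0, negll, grad, method = "BFGS",
          control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0) return(NULL)
  H <- tryCatch(optimHess(opt$par, negll, grad), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(zeta = opt$par[seq_len(K - 1L)],
       beta = opt$par[bi],
       vcov_beta = cov[bi, bi, drop = FALSE],
       logLik = -opt$value)
}

#' Cumulative-logit (proportional odds) marginal test for an ordinal phenotype
#'
#' Fits the proportional-odds model with ordered intercepts and a single
#' genotype slope (plus optional covariate slopes) and returns the two-sided
#' Wald p-value for the genotype coefficient. With two observed categories the
#' model reduces to logistic regression and reproduces its p-value. Unobserved
#' intermediate categories are collapsed with a warning.
#'
#' @inheritParams assoc_linear
#' @param y Ordinal phenotype vector (positive integers).
#' @return As [assoc_linear()]; extra flags `"no_variation"`,
#'   `"not_converged"`, `"separation"`.
#' @export
assoc_cumlogit <- function(y, z, covariates = NULL) {
  keep <- .complete_rows(y, z, covariates)
  y <- y[keep]; z <- z[keep]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3L || var(z) == 0) return(.flagged("monomorphic"))
  lev <- sort(unique(y))
  if (length(lev) < 2L) return(.flagged("no_variation"))
  if (length(lev) < length(seq(min(y), max(y))))
    warning("empty ordinal categories collapsed", call. = FALSE)
  yi <- match(y, lev)
  X <- if (is.null(covariates)) cbind(genotype = z) else cbind(genotype = z, covariates)
  fit <- .cumlogit_fit(yi, X)
  if (is.null(fit)) return(.flagged("not_converged"))
  beta <- fit$beta[1L]
  se <- sqrt(fit$vcov_beta[1L, 1L])
  if (!is.finite(se) || abs(beta) > 15 || se > 100) return(.flagged("separation"))
  zval <- beta / se
  logp <- log(2) + pnorm(abs(zval), lower.tail = FALSE, log.p = TRUE)
  .marginal_result(exp(logp), logp, beta, se)
}

#' Scale-dispatched marginal test
#'
#' Routes to [assoc_linear()], [assoc_logistic()], or [assoc_cumlogit()]
#' according to the declared measurement scale.
#'
#' @inheritParams assoc_linear
#' @param scale One of `"continuous"`, `"binary"`, `"ordinal"`.
#' @export
marginal_test <- function(y, z, scale, covariates = NULL) {
  scale <- match.arg(scale, .SCALES)
  switch(scale,
    continuous = assoc_linear(y, z, covariates),
    binary     = assoc_logistic(y, z, covariates),
    ordinal    = assoc_cumlogit(y, z, covariates)
  )
}

#' Marginal p-value scan over SNPs and phenotypes
#'
#' For each SNP passing the missingness and monomorphism filters, fits the
#' scale-matched marginal model against every phenotype column and collects
#' the M two-sided p-values (log scale retained for the Fisher statistic).
#'
#' @param phenotypes N x M numeric matrix (columns may contain NA).
#' @param scales Length-M character vector of measurement scales.
#' @param genotypes N x G matrix of allele counts 0/1/2 (NA allowed).
#' @param covariates Optional N x C covariate matrix.
#' @param min_nonmissing Minimum non-missing genotypes per SNP (default 10).
#' @return List of per-SNP records: `snp`, `p`, `logp`, `flags`, `ok`
#'   (TRUE when every phenotype fit succeeded).
#' @export
marginal_scan <- function(phenotypes, scales, genotypes, covariates = NULL,
                          min_nonmissing = 10L) {
  phenotypes <- as.matrix(phenotypes)
  genotypes <- as.matrix(genotypes)
  if (nrow(phenotypes) != nrow(genotypes))
    stop("phenotypes and genotypes must cover the same individuals", call. = FALSE)
  if (!is.null(covariates) && nrow(as.matrix(covariates)) != nrow(phenotypes))
    stop("covariates must cover the same individuals", call. = FALSE)
  M <- ncol(phenotypes)
  stopifnot(length(scales) == M)
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  lapply(seq_len(ncol(genotypes)), function(g) {
    z <- genotypes[, g]
    nz <- sum(is.finite(z))
    if (nz < min_nonmissing || var(z, na.rm = TRUE) == 0) {
      return(list(snp = snp_ids[g], p = rep(NA_real_, M),
                  logp = rep(NA_real_, M),
                  flags = rep("monomorphic_or_missing", M), ok = FALSE))
    }
    fits <- lapply(seq_len(M), function(j)
      marginal_test(phenotypes[, j], z, scales[j], covariates))
    list(snp = snp_ids[g],
         p = vapply(fits, `[[`, 0, "p"),
         logp = vapply(fits, `[[`, 0, "logp"),
         flags = vapply(fits, `[[`, "", "flag"),
         ok = all(vapply(fits, `[[`, "", "flag") == "ok"))
  })
}
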