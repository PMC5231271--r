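# Latent-correlation estimators for every combination of measurement scales.
# All estimators target the correlation rho of an underlying bivariate normal
# (U, V); binary/ordinal observations are threshold crossings of the latents.
# Estimator choice by scale pair:
#   continuous-continuous -> Kendall tau-a mapped through sin(pi*tau/2)
#   continuous-binary     -> Lord's bounded version of Brogden's biserial
#   continuous-ordinal    -> polyserial MLE (two-step)
#   binary-binary         -> tetrachoric MLE
#   binary-ordinal, ordinal-ordinal -> polychoric MLE (two-step)

.SCALES <- c("continuous", "binary", "ordinal")

# Numerical bounds: the MLE solvers search rho in [-RHO_MAX, RHO_MAX] because
# their likelihoods degenerate at |rho| = 1; solutions at the search boundary
# are flagged. Closed-form estimators (Kendall sine, Lord) may return exactly
# +-1, which the downstream covariance polynomial handles.
.RHO_MAX <- 0.999

.cor_estimate <- function(rho, method, n_used, converged = TRUE, boundary = FALSE) {
  if (is.finite(rho) && abs(rho) >= .RHO_MAX) boundary <- TRUE
  structure(
    list(rho = rho, method = method, n_used = n_used,
         converged = converged, boundary = boundary),
    class = "cor_estimate"
  )
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf("latent correlation estimate: %.4f  (%s, n = %d%s%s)\n",
              x$rho, x$method, x$n_used,
              if (!x$converged) ", NOT converged" else "",
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 2L) stop("fewer than 2 complete pairs", call. = FALSE)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Kendall's tau (tau-a) for two continuous vectors
#'
#' Concordance statistic `tau = (K_c - K_d) / (n(n-1)/2)` over all pairs of
#' observations; tied pairs count as neither concordant nor discordant and the
#' denominator is the total pair count (the tau-a convention). Missing values
#' are removed pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar tau in `[-1, 1]`.
#' @seealso [kendall_sine()] to map tau to the latent-normal correlation.
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 1/3
#' @export
kendall_tau <- function(x, y) {
  d <- .check_pair(x, y)
  if (length(unique(d$x)) < 2L || length(unique(d$y)) < 2L)
    stop("undefined correlation: constant input", call. = FALSE)
  n <- d$n
  n0 <- n * (n - 1) / 2
  # base R's C implementation returns tau-b; recover the concordance count
  # K_c - K_d exactly from its definition and renormalize to tau-a.
  tb <- cor(d$x, d$y, method = "kendall")
  tx <- table(d$x); ty <- table(d$y)
  Tx <- sum(tx * (tx - 1) / 2)
  Ty <- sum(ty * (ty - 1) / 2)
  num <- tb * sqrt((n0 - Tx) * (n0 - Ty))
  num / n0
}

#' Map Kendall's tau to the bivariate-normal correlation
#'
#' Under bivariate normality, `rho = sin(pi * tau / 2)` (Greiner's relation);
#' this is the continuous-continuous latent-correlation estimator.
#'
#' @param tau Kendall's tau in `[-1, 1]`.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' kendall_sine(1 / 3)  # 0.5
#' @export
kendall_sine <- function(tau) {
  if (any(!is.finite(tau)) || any(abs(tau) > 1))
    stop("tau must lie in [-1, 1]", call. = FALSE)
  sin(pi * tau / 2)
}

.cor_kendall_sine <- function(x, y) {
  d <- .check_pair(x, y)
  .cor_estimate(kendall_sine(kendall_tau(d$x, d$y)), "kendall_sine", d$n)
}

#' Brogden's biserial correlation
#'
#' Ratio of the observed covariance-type numerator `sum(y * x) - n * mean(x) *
#' mean(y)` to its maximum attainable value, obtained by packing all `x = 1`
#' cases onto the largest `n1 = sum(x)` order statistics of `y`. Bounded above
#' by 1 but may fall below -1 for negative association; use [lord_biserial()]
#' for the bounded-in-both-directions version.
#'
#' @param y Continuous vector.
#' @param x Binary (0/1) vector.
#' @return Scalar estimate, at most 1.
#' @examples
#' brogden_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1
#' @export
brogden_biserial <- function(y, x) {
  d <- .check_pair(x, y)
  x <- d$x; y <- d$y; n <- d$n
  if (!all(x %in% c(0, 1))) stop("x must be coded 0/1", call. = FALSE)
  n1 <- sum(x)
  if (n1 == 0L || n1 == n) stop("undefined correlation: constant binary input", call. = FALSE)
  base <- n * mean(x) * mean(y)
  num <- sum(y * x) - base
  den <- sum(sort(y, decreasing = TRUE)[seq_len(n1)]) - base
  if (den <= 0) stop("undefined correlation: degenerate continuous input", call. = FALSE)
  num / den
}

#' Lord's bounded biserial correlation
#'
#' Brogden's estimator when it is nonnegative; otherwise `-brogden(x, -y)`,
#' which bounds the estimate into `[-1, 1]` (sign-equivariant in `y`).
#' This is the continuous-binary latent-correlation estimator.
#'
#' @inheritParams brogden_biserial
#' @return A `cor_estimate` with method `"lord_biserial"`.
#' @examples
#' lord_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))$rho   #  1
#' lord_biserial(-c(1, 2, 3, 4), c(0, 0, 1, 1))$rho  # -1
#' @export
lord_biserial <- function(y, x) {
  d <- .check_pair(x, y)
  rb <- brogden_biserial(d$y, d$x)
  r <- if (rb >= 0) rb else -brogden_biserial(-d$y, d$x)
  .cor_estimate(r, "lord_biserial", d$n)
}

# --- contingency tables -------------------------------------------------------

# Cross-tabulate two integer-coded vectors into an R x C count matrix with
# ascending level order; only observed levels form rows/columns.
contingency_table <- function(x, y) {
  d <- .check_pair(x, y)
  ux <- sort(unique(d$x)); uy <- sort(unique(d$y))
  xi <- match(d$x, ux); yi <- match(d$y, uy)
  tab <- matrix(tabulate((yi - 1L) * length(ux) + xi, length(ux) * length(uy)),
                length(ux), length(uy))
  dimnames(tab) <- list(as.character(ux), as.character(uy))
  tab
}

.check_table <- function(tab, square2 = FALSE) {
  if (!is.matrix(tab) || any(tab < 0) || sum(tab) <= 0)
    stop("invalid contingency table", call. = FALSE)
  if (square2 && !all(dim(tab) == c(2L, 2L)))
    stop("tetrachoric correlation requires a 2x2 table", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a zero margin leaves the threshold unidentified",
         call. = FALSE)
  tab
}

# Thresholds from marginal proportions: category k of an ascending-coded
# variable corresponds to the latent value falling in (z_{k-1}, z_k], with
# z_k = qnorm(cumulative proportion at or below category k). The highest
# category therefore sits above the top threshold.
.margin_thresholds <- function(margin_counts) {
  p <- cumsum(margin_counts) / sum(margin_counts)
  qnorm(p[-length(p)])
}

#' Tetrachoric correlation (maximum likelihood)
#'
#' MLE of the latent bivariate-normal correlation from a 2x2 table of two
#' dichotomized variables. Thresholds are fixed at the normal quantiles of the
#' marginal proportions; `rho` then solves the orthant equation
#' `P(U > h, V > k) = p11`, with `p11` the proportion in the top category of
#' both margins. For 50/50 margins the solution has the closed form
#' `sin(2 * pi * (p11 - 1/4))`.
#'
#' @param tab 2x2 count matrix, rows/columns in ascending category order
#'   (low category first), or `NULL` when `x`/`y` are given.
#' @param x,y Optional binary 0/1 vectors tabulated internally.
#' @return A `cor_estimate` with method `"tetrachoric"`. A zero cell with
#'   nonzero margins yields a boundary estimate clamped to `+-0.999` and
#'   flagged via `boundary = TRUE`.
#' @examples
#' tetrachoric(matrix(c(35, 15, 15, 35), 2))$rho  # ~0.588
#' @export
tetrachoric <- function(tab = NULL, x = NULL, y = NULL) {
  if (is.null(tab)) tab <- contingency_table(x, y)
  tab <- .check_table(tab, square2 = TRUE)
  n <- sum(tab)
  h <- .margin_thresholds(rowSums(tab))   # single threshold for X
  k <- .margin_thresholds(colSums(tab))   # single threshold for Y
  p11 <- tab[2L, 2L] / n                  # both in the top category
  f <- function(rho) bvnu(h, k, rho) - p11
  # orthant probability is increasing in rho; check the attainable range
  lo <- f(-.RHO_MAX); hi <- f(.RHO_MAX)
  if (lo >= 0) return(.cor_estimate(-.RHO_MAX, "tetrachoric", n, boundary = TRUE))
  if (hi <= 0) return(.cor_estimate(.RHO_MAX, "tetrachoric", n, boundary = TRUE))
  r <- uniroot(f, c(-.RHO_MAX, .RHO_MAX), tol = 1e-6)$root
  .cor_estimate(r, "tetrachoric", n)
}

# Rectangle probabilities for an R x C table given thresholds and rho:
# pi_ij = P(z_{i-1} < U <= z_i, w_{j-1} < V <= w_j). The joint CDF is
# evaluated once on the (R+1) x (C+1) threshold grid, with the infinite
# boundary rows/columns filled in closed form, and differenced.
.rect_probs <- function(zx, zy, rho) {
  R <- length(zx) + 1L; C <- length(zy) + 1L
  G <- matrix(0, R + 1L, C + 1L)
  G[R + 1L, ] <- c(0, pnorm(zy), 1)
  G[, C + 1L] <- c(0, pnorm(zx), 1)
  if (R > 1L && C > 1L)
    G[2:R, 2:C] <- bvnu(rep(-zx, times = C - 1L), rep(-zy, each = R - 1L), rho)
  p <- G[-1L, -1L, drop = FALSE] - G[-(R + 1L), -1L, drop = FALSE] -
    G[-1L, -(C + 1L), drop = FALSE] + G[-(R + 1L), -(C + 1L), drop = FALSE]
  pmax(p, 0)
}

#' Polychoric correlation (two-step maximum likelihood)
#'
#' MLE of the latent correlation from an RxC contingency table of two
#' ordinal (or binary, as the 2-level special case) variables. Estimation is
#' two-step: thresholds are fixed at the normal quantiles of the cumulative
#' marginal proportions, then the profile likelihood
#' `sum(n_ij * log(pi_ij(rho)))` is maximized over `rho`, where `pi_ij` is the
#' bivariate-normal rectangle probability of cell `(i, j)`.
#'
#' @param tab RxC count matrix (ascending category order), or `NULL` when
#'   `x`/`y` are given.
#' @param x,y Optional integer-coded vectors tabulated internally.
#' @return A `cor_estimate` with method `"polychoric"`.
#' @examples
#' polychoric(matrix(c(35, 15, 15, 35), 2))$rho  # agrees with tetrachoric()
#' @export
polychoric <- function(tab = NULL, x = NULL, y = NULL) {
  if (is.null(tab)) tab <- contingency_table(x, y)
  tab <- .check_table(tab)
  n <- sum(tab)
  zx <- .margin_thresholds(rowSums(tab))
  zy <- .margin_thresholds(colSums(tab))
  nll <- function(rho) {
    p <- .rect_probs(zx, zy, rho)
    -sum(tab[tab > 0] * log(pmax(p[tab > 0], 1e-300)))
  }
  opt <- optimize(nll, c(-.RHO_MAX, .RHO_MAX), tol = 1e-6)
  boundary <- .RHO_MAX - abs(opt$minimum) < 1e-4
  .cor_estimate(opt$minimum, "polychoric", n, boundary = boundary)
}

#' Polyserial correlation (two-step maximum likelihood)
#'
#' MLE of the latent correlation between an observed continuous variable and
#' an ordinal variable. The likelihood factorizes as
#' `prod f(y_i) * P(x_i | y_i)` with
#' `P(x_i = j | y_i) = pnorm(theta_j) - pnorm(theta_{j-1})` and
#' `theta_j = (zeta_j - rho * z_i) / sqrt(1 - rho^2)`,
#' `z_i = (y_i - mu) / sigma`. Two-step: `mu`, `sigma` from the continuous
#' sample, thresholds `zeta` from the ordinal margins, then a 1-D profile
#' maximization over `rho`.
#'
#' @param y Continuous vector.
#' @param x Ordinal vector (positive integers, at least 2 observed levels).
#' @return A `cor_estimate` with method `"polyserial"`.
#' @export
polyserial <- function(y, x) {
  d <- .check_pair(x, y)
  x <- d$x; y <- d$y; n <- d$n
  lev <- sort(unique(x))
  if (length(lev) < 2L)
    stop("undefined correlation: single ordinal level", call. = FALSE)
  if (sd(y) == 0) stop("undefined correlation: constant continuous input", call. = FALSE)
  xi <- match(x, lev)
  zeta <- .margin_thresholds(tabulate(xi, nbins = length(lev)))
  z <- (y - mean(y)) / sd(y)
  bounds <- c(-Inf, zeta, Inf)
  up <- bounds[xi + 1L]   # zeta_j
  lo <- bounds[xi]        # zeta_{j-1}
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- pnorm((up - rho * z) / s) - pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  opt <- optimize(nll, c(-.RHO_MAX, .RHO_MAX), tol = 1e-6)
  boundary <- .RHO_MAX - abs(opt$minimum) < 1e-4
  .cor_estimate(opt$minimum, "polyserial", n, boundary = boundary)
}

# --- dispatch and matrix assembly --------------------------------------------

#' Latent correlation between two phenotype vectors of declared scales
#'
#' Dispatches to the scale-appropriate estimator:
#' continuous-continuous Kendall sine, continuous-binary Lord biserial,
#' continuous-ordinal polyserial, binary-binary tetrachoric, binary-ordinal
#' and ordinal-ordinal polychoric. Symmetric in its arguments.
#'
#' @param a,b Numeric phenotype vectors sharing individual order.
#' @param scale_a,scale_b Each one of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param n_min Minimum pairwise-complete observations (default 10).
#' @return A `cor_estimate`.
#' @export
latent_cor_pair <- function(a, b, scale_a, scale_b, n_min = 10L) {
  scale_a <- match.arg(scale_a, .SCALES)
  scale_b <- match.arg(scale_b, .SCALES)
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < n_min)
    stop(sprintf("only %d complete pairs; %d required", sum(keep), n_min),
         call. = FALSE)
  a <- a[keep]; b <- b[keep]
  key <- paste(sort(c(scale_a, scale_b)), collapse = "-")
  # orient so the continuous (or first-listed) scale comes first
  if (match(scale_a, .SCALES) > match(scale_b, .SCALES)) {
    tmp <- a; a <- b; b <- tmp
  }
  switch(key,
    "continuous-continuous" = .cor_kendall_sine(a, b),
    "binary-continuous"     = lord_biserial(a, b),
    "continuous-ordinal"    = polyserial(a, b),
    "binary-binary"         = tetrachoric(x = a, y = b),
    "binary-ordinal"        = polychoric(x = a, y = b),
    "ordinal-ordinal"       = polychoric(x = a, y = b),
    stop("unsupported scale combination: ", key, call. = FALSE)
  )
}

#' Latent correlation matrix of a mixed-scale phenotype set
#'
#' Applies [latent_cor_pair()] to every column pair of a phenotype matrix and
#' assembles the symmetric MxM latent correlation matrix with unit diagonal.
#' Pairs whose estimation fails are recorded as `NA` with the error message
#' retained; downstream combination refuses such matrices.
#'
#' @param phenotypes Numeric matrix or data frame, one column per phenotype.
#' @param scales Character vector of per-column scales.
#' @param n_min Minimum pairwise-complete observations per pair.
#' @return An object of class `latent_cor`: the correlation matrix with
#'   attributes `methods` (estimator per pair), `n_pair` (complete pairs used),
#'   `boundary` (clamped-estimate flags), and `failures`.
#' @examples
#' set.seed(1)
#' u <- matrix(rnorm(400), 200)
#' ph <- cbind(u[, 1], as.integer(u[, 2] > 0))
#' latent_cor(ph, c("continuous", "binary"))
#' @export
latent_cor <- function(phenotypes, scales, n_min = 10L) {
  phenotypes <- as.matrix(phenotypes)
  M <- ncol(phenotypes)
  if (M < 2L) stop("need at least 2 phenotypes", call. = FALSE)
  if (length(scales) != M) stop("one scale per phenotype column required", call. = FALSE)
  scales <- vapply(unname(scales), match.arg, "", choices = .SCALES, USE.NAMES = FALSE)
  cn <- colnames(phenotypes)
  if (is.null(cn)) cn <- paste0("P", seq_len(M))
  R <- diag(1, M)
  meth <- matrix(NA_character_, M, M)
  npair <- matrix(NA_integer_, M, M)
  bound <- matrix(FALSE, M, M)
  failures <- list()
  for (j in seq_len(M - 1L)) {
    for (k in (j + 1L):M) {
      est <- tryCatch(
        latent_cor_pair(phenotypes[, j], phenotypes[, k],
                        scales[j], scales[k], n_min = n_min),
        error = function(e) e
      )
      if (inherits(est, "error")) {
        R[j, k] <- R[k, j] <- NA_real_
        failures[[paste(cn[j], cn[k], sep = ":")]] <- conditionMessage(est)
      } else {
        R[j, k] <- R[k, j] <- est$rho
        meth[j, k] <- meth[k, j] <- est$method
        npair[j, k] <- npair[k, j] <- est$n_used
        bound[j, k] <- bound[k, j] <- est$boundary
      }
    }
  }
  dimnames(R) <- list(cn, cn)
  structure(R, class = c("latent_cor", "matrix"),
            scales = scales, methods = meth, n_pair = npair,
            boundary = bound, failures = failures)
}

#' @export
print.latent_cor <- function(x, digits = 4, ...) {
  cat("Latent correlation matrix (", ncol(x), " phenotypes)\n", sep = "")
  print(round(unclass(x), digits))
  f <- attr(x, "failures")
  if (length(f))
    cat("failed pairs:", paste(names(f), collapse = ", "), "\n")
  invisible(x)
}
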