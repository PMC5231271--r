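# Top-level user interface: the two-phase multivariate scan as a single
# fitting function returning a classed result with print/summary/plot methods.

#' Two-phase multivariate association scan for mixed-scale phenotypes
#'
#' Runs the full analysis: (phase 1) per SNP, scale-matched marginal
#' regressions of every phenotype on genotype dosage with optional covariate
#' adjustment; (phase 2) the Fisher combination statistic
#' `S = sum(-2 log p_j)` per SNP, referred to a gamma null whose moments are
#' matched using the latent correlation matrix of the phenotype set. The
#' correlation matrix and the gamma null are computed once -- they depend only
#' on the phenotypes -- and reused across all SNPs, which is what makes the
#' scan cheap relative to the marginal fits.
#'
#' @param phenotypes N x M numeric matrix or data frame of phenotypes.
#' @param genotypes N x G matrix of additive allele counts (0/1/2, NA for
#'   missing), e.g. from [read_genotypes()].
#' @param scales Length-M character vector: `"continuous"`, `"binary"`, or
#'   `"ordinal"` per phenotype column.
#' @param covariates Optional N x C numeric covariate matrix.
#' @param correlation Optional precomputed [latent_cor()] matrix (estimated
#'   from `phenotypes` when omitted).
#' @param snp_info Optional data frame with one row per SNP (`snp`, `chr`,
#'   `pos`) carried into the results.
#' @param threshold Genome-wide significance threshold on the multivariate
#'   p-value (default `1e-6`).
#' @param min_nonmissing Per-SNP floor on non-missing genotypes.
#' @param on_flagged Per-SNP policy when a marginal fit is flagged: `"skip"`
#'   the SNP (default) or `"reduce"` to the non-flagged phenotypes with a
#'   recomputed null.
#' @return An object of class `pleioscan`: list with `results` (per-SNP data
#'   frame: marginal p-values, `S`, `p_multi`, flags), `correlation`, `null`
#'   ([gamma_null()]), `scales`, `threshold`, and bookkeeping counts.
#' @examples
#' set.seed(7)
#' z <- replicate(20, simulate_genotypes(300, 0.3))
#' V <- simulate_latents(z[, 1], rho = 0.35, effects = rep(0.6, 3))
#' ph <- cbind(V[, 1], discretize(V[, 2], "binary"), discretize(V[, 3], "ordinal"))
#' fit <- pleioscan(ph, z, c("continuous", "binary", "ordinal"))
#' summary(fit)
#' @export
pleioscan <- function(phenotypes, genotypes, scales, covariates = NULL,
                      correlation = NULL, snp_info = NULL, threshold = 1e-6,
                      min_nonmissing = 10L, on_flagged = c("skip", "reduce")) {
  on_flagged <- match.arg(on_flagged)
  phenotypes <- as.matrix(phenotypes)
  genotypes <- as.matrix(genotypes)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)", call. = FALSE)
  M <- ncol(phenotypes)
  if (length(scales) != M) stop("one scale per phenotype column required", call. = FALSE)
  if (is.null(correlation)) correlation <- latent_cor(phenotypes, scales)
  if (length(attr(correlation, "failures")))
    stop("latent correlation failed for pairs: ",
         paste(names(attr(correlation, "failures")), collapse = ", "), call. = FALSE)
  n_pair <- attr(correlation, "n_pair")
  null <- gamma_null(correlation, n = n_pair, M = M)
  marg <- marginal_scan(phenotypes, scales, genotypes, covariates,
                        min_nonmissing = min_nonmissing)
  comb <- multivariate_scan(marg, correlation, n = n_pair, on_flagged = on_flagged)
  pmat <- do.call(rbind, lapply(marg, `[[`, "p"))
  pn <- colnames(phenotypes)
  if (is.null(pn)) pn <- paste0("P", seq_len(M))
  colnames(pmat) <- paste0("p_", pn)
  res <- data.frame(
    snp = vapply(comb, `[[`, "", "snp"),
    S = vapply(comb, `[[`, 0, "S"),
    p_multi = vapply(comb, `[[`, 0, "p_multi"),
    M_used = vapply(comb, `[[`, 0L, "M_used"),
    flags = vapply(comb, function(r) paste(unique(r$flags[r$flags != "ok"]),
                                           collapse = ";"), ""),
    stringsAsFactors = FALSE)
  res <- cbind(res[, "snp", drop = FALSE], pmat,
               res[, c("S", "p_multi", "M_used", "flags")])
  if (!is.null(snp_info)) {
    stopifnot(nrow(snp_info) == nrow(res))
    res <- cbind(snp_info[setdiff(names(snp_info), "snp")], res)
    ord <- if (all(c("chr", "pos") %in% names(res)))
      order(res$chr, res$pos) else seq_len(nrow(res))
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(list(results = res, correlation = correlation, null = null,
                 scales = scales, threshold = threshold,
                 n_individuals = nrow(phenotypes),
                 n_snps = ncol(genotypes),
                 n_skipped = sum(!vapply(comb, function(r) r$M_used > 0, TRUE))),
            class = "pleioscan")
}

#' @export
print.pleioscan <- function(x, ...) {
  cat("Multivariate mixed-scale association scan\n")
  cat(sprintf("  %d individuals, %d phenotypes (%s), %d SNPs (%d skipped)\n",
              x$n_individuals, length(x$scales),
              paste(substr(x$scales, 1, 4), collapse = "/"),
              x$n_snps, x$n_skipped))
  cat(sprintf("  gamma null: kappa = %.4f, nu = %.4f (Var[S] = %.4f)\n",
              x$null$kappa, x$null$nu, x$null$var_S))
  nsig <- sum(x$results$p_multi < x$threshold, na.rm = TRUE)
  cat(sprintf("  %d SNP(s) below the %.3g significance threshold\n",
              nsig, x$threshold))
  invisible(x)
}

#' @export
summary.pleioscan <- function(object, top = 10L, ...) {
  print(object)
  res <- object$results[!is.na(object$results$p_multi), , drop = FALSE]
  res <- res[order(res$p_multi), , drop = FALSE]
  cat("\nTop SNPs by multivariate p-value:\n")
  print(utils::head(res, top), digits = 4, row.names = FALSE)
  invisible(object)
}

#' Extract the per-SNP results table
#' @param x A `pleioscan` fit.
#' @param ... Unused.
#' @return The per-SNP results data frame.
#' @export
as.data.frame.pleioscan <- function(x, ...) x$results

#' QQ plot of the multivariate p-values
#'
#' Observed `-log10 p_multi` against the expected uniform quantiles; the
#' genome-wide picture of whether the scan is well calibrated (points on the
#' diagonal under the null) or carries signal (departure upward at the tail).
#'
#' @param x A `pleioscan` fit.
#' @param ... Passed to [plot()].
#' @export
plot.pleioscan <- function(x, ...) {
  p <- sort(x$results$p_multi[!is.na(x$results$p_multi)])
  if (!length(p)) stop("no usable SNPs to plot", call. = FALSE)
  expct <- (seq_along(p) - 0.5) / length(p)
  plot(-log10(expct), -log10(p),
       xlab = expression(-log[10] ~ "expected p"),
       ylab = expression(-log[10] ~ "observed p"), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
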