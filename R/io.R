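# File I/O: phenotype/covariate tables (TSV/CSV with an individual-ID column),
# genotypes as VCF (ALT-dosage 0/1/2 from diploid GT fields) or
# additive-coded text, and the scan-results writer (TSV plus QQ data).
# Individuals are aligned between files by ID, never by row order.

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed table: ", path, call. = FALSE)
  df
}

#' Read a phenotype table with per-column scale declarations
#'
#' Expects a TSV (or `.csv`) with a header row, one row per individual, and an
#' individual-ID column (the first column, or named by `id_col`). Each
#' phenotype column is validated against its declared scale: binary columns
#' must be coded 0/1; ordinal columns are coerced to consecutive positive
#' integers `1..t` preserving the observed order; non-numeric tokens are
#' masked as missing.
#'
#' @param path Path to the table.
#' @param scales Named character vector mapping phenotype column names to
#'   scales, or an unnamed vector matching the non-ID columns in order.
#' @param id_col Name of the individual-ID column (default: first column).
#' @return List with `phenotypes` (numeric matrix, rownames = individual IDs)
#'   and `scales`.
#' @export
read_phenotypes <- function(path, scales, id_col = NULL) {
  df <- .read_table(path)
  if (is.null(id_col)) id_col <- names(df)[1L]
  if (!id_col %in% names(df)) stop("no ID column '", id_col, "' in ", path, call. = FALSE)
  ids <- as.character(df[[id_col]])
  ph <- df[setdiff(names(df), id_col)]
  if (!is.null(names(scales)) && all(nzchar(names(scales)))) {
    missing_cols <- setdiff(names(scales), names(ph))
    if (length(missing_cols))
      stop("declared phenotype column(s) not in file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    ph <- ph[names(scales)]
  } else if (length(scales) != ncol(ph)) {
    stop(sprintf("%d scales declared for %d phenotype columns",
                 length(scales), ncol(ph)), call. = FALSE)
  }
  scales <- vapply(unname(scales), match.arg, "", choices = .SCALES, USE.NAMES = FALSE)
  mat <- matrix(NA_real_, nrow(ph), ncol(ph),
                dimnames = list(ids, names(ph)))
  for (j in seq_along(ph)) {
    v <- suppressWarnings(as.numeric(as.character(ph[[j]])))
    col <- names(ph)[j]
    obs <- v[is.finite(v)]
    if (scales[j] == "binary" && length(setdiff(unique(obs), c(0, 1)))) {
      bad <- which(is.finite(v) & !v %in% c(0, 1))[1L]
      stop(sprintf("column '%s' declared binary but row %d has value %s",
                   col, bad, format(v[bad])), call. = FALSE)
    }
    if (scales[j] == "ordinal") {
      if (any(obs != round(obs)))
        stop(sprintf("column '%s' declared ordinal but has non-integer values", col),
             call. = FALSE)
      lev <- sort(unique(obs))
      v <- match(v, lev)               # coerce to 1..t preserving order
    }
    mat[, j] <- v
  }
  list(phenotypes = mat, scales = scales)
}

#' Read a covariate table
#'
#' Same layout as [read_phenotypes()]; all covariate columns must be numeric
#' (code factors before writing the file).
#'
#' @inheritParams read_phenotypes
#' @return Numeric matrix with rownames = individual IDs.
#' @export
read_covariates <- function(path, id_col = NULL) {
  df <- .read_table(path)
  if (is.null(id_col)) id_col <- names(df)[1L]
  ids <- as.character(df[[id_col]])
  cv <- df[setdiff(names(df), id_col)]
  mat <- vapply(cv, function(x) suppressWarnings(as.numeric(as.character(x))),
                numeric(nrow(cv)))
  mat <- matrix(mat, nrow = nrow(cv), dimnames = list(ids, names(cv)))
  mat
}

# GT field -> ALT dosage; half calls and anything non-diploid -> NA.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  out[gt %in% c("1/1", "1|1")] <- 2
  out
}

#' Read genotypes from VCF or additive-coded text
#'
#' VCF: biallelic SNV records with diploid GT fields are converted to ALT
#' allele dosage 0/1/2 (half calls `./.` become missing); multi-allelic
#' records are skipped and counted. Additive text: whitespace-delimited,
#' header of SNP identifiers, first column individual ID, entries 0/1/2 or NA.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"additive"`.
#' @return List with `genotypes` (N x G numeric matrix, rownames = individual
#'   IDs, colnames = SNP ids), `snp_info` (data frame: snp, chr, pos), and
#'   `n_skipped` (multi-allelic / malformed records dropped).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "additive")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "additive"
  if (format == "vcf") .read_vcf(path) else .read_additive(path)
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  G <- t(apply(gt, 1L, .gt_to_dosage))
  G <- matrix(as.numeric(G), nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  rownames(G) <- ids
  list(genotypes = t(G),
       snp_info = data.frame(snp = ids, chr = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             stringsAsFactors = FALSE),
       n_skipped = n_skipped)
}

.read_additive <- function(path) {
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  G <- as.matrix(df[-1L])
  storage.mode(G) <- "double"
  bad <- is.finite(G) & !(G %in% c(0, 1, 2))
  n_skipped <- 0L
  if (any(bad)) {
    G[bad] <- NA_real_
    n_skipped <- sum(bad)
  }
  rownames(G) <- ids
  list(genotypes = G,
       snp_info = data.frame(snp = colnames(G), chr = NA_character_,
                             pos = NA_integer_, stringsAsFactors = FALSE),
       n_skipped = n_skipped)
}

#' Align phenotype, genotype, and covariate matrices by individual ID
#'
#' Intersects rownames (individual IDs) across the inputs and returns all
#' matrices in a common row order.
#'
#' @param phenotypes,genotypes Matrices with individual IDs as rownames.
#' @param covariates Optional matrix with individual IDs as rownames.
#' @param min_n Error if fewer than this many shared individuals remain.
#' @return List of aligned matrices and `ids`.
#' @export
align_individuals <- function(phenotypes, genotypes, covariates = NULL, min_n = 10L) {
  ids <- intersect(rownames(phenotypes), rownames(genotypes))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  if (length(ids) < min_n)
    stop(sprintf("only %d individuals shared across files (need >= %d)",
                 length(ids), min_n), call. = FALSE)
  list(phenotypes = phenotypes[ids, , drop = FALSE],
       genotypes = genotypes[ids, , drop = FALSE],
       covariates = if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE],
       ids = ids)
}

#' Write scan results and QQ data
#'
#' Writes the per-SNP results as a TSV (p-values in scientific notation with
#' 12 significant digits so that re-reading reproduces them) and a companion
#' `<stem>_qq.tsv` with the sorted observed multivariate p-values against
#' expected uniform quantiles, ready for QQ plotting. Output is deterministic:
#' identical fits produce byte-identical files.
#'
#' @param fit A [pleioscan()] fit (or its results data frame).
#' @param path Output TSV path; the QQ file sits next to it.
#' @return Invisibly, a list with both paths and the row count.
#' @export
write_scan_results <- function(fit, path) {
  res <- if (inherits(fit, "pleioscan")) fit$results else as.data.frame(fit)
  out <- res
  for (j in names(out)) {
    if (is.numeric(out[[j]]) && (grepl("^p_", j) || j %in% c("p_multi", "S")))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.12e", out[[j]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("failed writing results to ", path, ": ", conditionMessage(e), call. = FALSE))
  qq_path <- sub("(\\.[^.]+)?$", "_qq.tsv", path)
  p <- sort(res$p_multi[!is.na(res$p_multi)])
  qq <- data.frame(expected = if (length(p)) (seq_along(p) - 0.5) / length(p) else numeric(0),
                   observed = p)
  qq$expected <- sprintf("%.12e", qq$expected)
  qq$observed <- sprintf("%.12e", as.numeric(qq$observed))
  utils::write.table(qq, qq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(results = path, qq = qq_path, n = nrow(res)))
}
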