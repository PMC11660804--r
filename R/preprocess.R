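#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors across samples via
#' edgeR's reference implementation: the reference sample is the one whose
#' upper-quartile count fraction is closest to the mean upper-quartile
#' fraction; per sample, gene-wise log2 ratios against the reference (M) are
#' trimmed at `trim_m` and average log2 abundances (A) at `trim_a`, a
#' precision-weighted mean of the surviving M values is exponentiated, and
#' the factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples, with dimnames.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1. A sample sharing no expressed gene with the reference gets
#'   factor 1 with a warning.
#' @export
#' @examples
#' counts <- matrix(rpois(200, 20), 50, 4,
#'                  dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
#' tmm_normalize(counts)
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  check_count_matrix(counts)
  if (ncol(counts) < 2L) abort("TMM normalization needs at least 2 samples")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort(sprintf("sample %s has zero total count",
                  colnames(counts)[which(libsize == 0)[1L]]))
  }
  # reference column, edgeR's rule: upper-quartile fraction closest to mean
  uq <- apply(counts, 2L, quantile, probs = 0.75) / libsize
  ref <- which.min(abs(uq - mean(uq)))
  # guard samples sharing no co-expressed gene with the reference
  shared <- colSums(counts > 0 & counts[, ref] > 0) > 0
  f <- rep(1, ncol(counts))
  if (!all(shared)) {
    warn(sprintf("sample(s) %s share no expressed gene with the reference; factor set to 1",
                 paste(colnames(counts)[!shared], collapse = ", ")))
  }
  ok <- which(shared)
  if (length(ok) >= 1L) {
    sub <- counts[, ok, drop = FALSE]
    f[ok] <- edgeR::calcNormFactors(sub, method = "TMM",
                                    refColumn = match(ref, ok),
                                    logratioTrim = trim_m, sumTrim = trim_a)
  }
  f[!is.finite(f) | f <= 0] <- 1
  f <- f / geo_mean(f)
  setNames(f, colnames(counts))
}

#' Counts per million with normalization factors
#'
#' `cpm[i, j] = counts[i, j] / (libsize_j * factor_j) * 1e6`, the effective
#' library size being the raw library size times the TMM factor.
#'
#' @inheritParams tmm_normalize
#' @param norm_factors Positive per-sample factors (e.g. [tmm_normalize()]).
#' @return Numeric matrix of CPM values, same dimnames as `counts`.
#' @export
cpm_normalize <- function(counts, norm_factors = tmm_normalize(counts)) {
  check_count_matrix(counts)
  if (length(norm_factors) != ncol(counts) || any(norm_factors <= 0)) {
    abort("`norm_factors` must be positive, one per sample")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) abort("zero library size")
  sweep(counts, 2L, libsize * norm_factors, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene is retained iff it is present (raw count >= `min_count`) in
#' strictly more than `min_frac` of the samples.
#'
#' @inheritParams tmm_normalize
#' @param min_count Presence threshold on the raw count (default 2).
#' @param min_frac Fraction of samples that must exceed it, strict
#'   inequality (default 0.30).
#' @return Named logical vector over genes.
#' @export
filter_expressed <- function(counts, min_count = 2, min_frac = 0.30) {
  check_count_matrix(counts)
  check_scalar(min_count, "min_count", lower = 0)
  check_scalar(min_frac, "min_frac", lower = 0, upper = 1)
  rowSums(counts >= min_count) > min_frac * ncol(counts)
}

#' MAD-based phenotype outlier filter
#'
#' Retains values inside `median(v) - k * MAD` to `median(v) + k * MAD`,
#' where `MAD = median(|v - median(v)|)` is the raw (unscaled) median
#' absolute deviation — no 1.4826 consistency factor. Missing values stay
#' missing in the returned mask. If the MAD is 0 (e.g. a majority-constant
#' vector) every non-missing value is retained.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param k Fence half-width in MAD units (default 3.5).
#' @param scaled If `TRUE`, use the 1.4826-scaled MAD instead.
#' @return Logical vector: `TRUE` retained, `FALSE` removed, `NA` missing.
#' @export
#' @examples
#' mad_filter(c(1:9, 100))  # removes only 100
mad_filter <- function(values, k = 3.5, scaled = FALSE) {
  if (!is.numeric(values)) abort("`values` must be numeric")
  check_scalar(k, "k", lower = 0)
  obs <- !is.na(values)
  if (sum(obs) < 3L) abort("mad_filter needs at least 3 non-missing values")
  med <- median(values[obs])
  m <- mad(values[obs], center = med, constant = if (scaled) 1.4826 else 1)
  mask <- rep(NA, length(values))
  if (m == 0) {
    mask[obs] <- TRUE
  } else {
    mask[obs] <- values[obs] >= med - k * m & values[obs] <= med + k * m
  }
  mask
}

#' Standardize expression per gene
#'
#' Centers and scales each gene to mean 0 and variance 1 across samples,
#' using the population (divide-by-n) variance by default so the mean ORM
#' diagonal is exactly 1. Genes with zero variance are dropped with a
#' warning, never turned into NaN.
#'
#' @param x Numeric matrix, genes x samples (e.g. CPM values).
#' @param var_type `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return List: `standardized` (matrix over retained genes), `gene_means`,
#'   `gene_vars` (named, retained genes), `dropped` (ids of zero-variance
#'   genes).
#' @export
standardize_expression <- function(x, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  n <- ncol(x)
  mu <- rowMeans(x)
  cen <- x - mu
  v <- rowSums(cen^2) / if (var_type == "population") n else (n - 1L)
  zero <- v <= 0
  if (any(zero)) {
    warn(sprintf("dropping %d zero-variance gene(s): %s", sum(zero),
                 paste(head(rownames(x)[zero], 5L), collapse = ", ")))
  }
  keep <- !zero
  list(standardized = cen[keep, , drop = FALSE] / sqrt(v[keep]),
       gene_means = mu[keep], gene_vars = v[keep],
       dropped = rownames(x)[zero])
}

#' Preprocess a count matrix for association analysis
#'
#' Full expression-side preprocessing: TMM factors, CPM, expressed-gene
#' filter, optional log2 transform, per-gene standardization.
#'
#' @inheritParams tmm_normalize
#' @inheritParams filter_expressed
#' @inheritParams standardize_expression
#' @param log_cpm If `TRUE`, standardize `log2(CPM + 1)` instead of CPM.
#' @return Object of class `twas_expr`: list with `cpm` (filtered genes),
#'   `standardized`, `norm_factors`, `gene_means`, `gene_vars`,
#'   `dropped_genes`, `n_genes_in`, and the parameters used.
#' @export
preprocess_counts <- function(counts, min_count = 2, min_frac = 0.30,
                              trim_m = 0.30, trim_a = 0.05,
                              log_cpm = FALSE,
                              var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  check_count_matrix(counts)
  nf <- tmm_normalize(counts, trim_m = trim_m, trim_a = trim_a)
  keep <- filter_expressed(counts, min_count = min_count, min_frac = min_frac)
  if (!any(keep)) abort("no gene passes the expressed-gene filter")
  cpm_mat <- cpm_normalize(counts, nf)[keep, , drop = FALSE]
  basis <- if (log_cpm) log2(cpm_mat + 1) else cpm_mat
  std <- standardize_expression(basis, var_type = var_type)
  structure(
    list(cpm = cpm_mat, standardized = std$standardized,
         norm_factors = nf, gene_means = std$gene_means,
         gene_vars = std$gene_vars, dropped_genes = std$dropped,
         n_genes_in = nrow(counts),
         params = list(min_count = min_count, min_frac = min_frac,
                       trim_m = trim_m, trim_a = trim_a, log_cpm = log_cpm,
                       var_type = var_type)),
    class = "twas_expr"
  )
}

#' @export
print.twas_expr <- function(x, ...) {
  cat(sprintf(
    "<twas_expr> %d/%d genes retained, %d samples%s\n",
    nrow(x$standardized), x$n_genes_in, ncol(x$standardized),
    if (length(x$dropped_genes)) sprintf(" (%d zero-variance dropped)",
                                         length(x$dropped_genes)) else ""))
  invisible(x)
}

#' Per-trait phenotype quality control
#'
#' Applies the MAD outlier rule to one trait and requires complete
#' covariates, returning the retained sample ids and QC bookkeeping.
#'
#' @param phenotypes Data frame with `sample_id`, covariate columns, traits.
#' @param trait Trait column name.
#' @param covariates Covariate columns that must be non-missing.
#' @param mad_k MAD fence half-width (default 3.5).
#' @return List: `sample_ids` retained, `removed_outliers`, `n_missing`.
#' @export
qc_phenotype <- function(phenotypes, trait, covariates = c("sex", "season"),
                         mad_k = 3.5) {
  if (!trait %in% names(phenotypes)) {
    abort(sprintf("trait `%s` not found in phenotype table", trait))
  }
  miss_cov <- setdiff(covariates, names(phenotypes))
  if (length(miss_cov)) {
    abort(sprintf("covariate(s) not found: %s", paste(miss_cov, collapse = ", ")))
  }
  v <- phenotypes[[trait]]
  mask <- mad_filter(v, k = mad_k)
  cov_ok <- stats::complete.cases(phenotypes[covariates])
  keep <- !is.na(mask) & mask & cov_ok
  list(sample_ids = phenotypes$sample_id[keep],
       removed_outliers = phenotypes$sample_id[!is.na(mask) & !mask],
       n_missing = sum(is.na(v)))
}
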