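#' Omics relationship matrix (ORM) from standardized expression
#'
#' The expression-based similarity between samples j and k over m genes is
#' \deqn{O_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij}-\mu_i)(x_{ik}-\mu_i)}{\sigma^2_i}}
#' i.e. `O = Z'Z / m` for the standardized gene-by-sample matrix `Z`. Under
#' population-variance standardization the diagonal averages exactly 1 and
#' every row sums to 0 (each gene vector is centered). The standardized
#' vectors are cached so single genes can be removed exactly with
#' [orm_downdate()].
#'
#' @param z Standardized matrix, genes x samples: each row must have mean 0
#'   (checked to 1e-6) and population variance 1.
#' @param check_psd If `TRUE` (default), verify the minimum eigenvalue is
#'   >= -1e-8 and error otherwise.
#' @return Object of class `twas_orm`: list with `O` (n x n), `m`,
#'   `sample_ids`, and the cached `z`.
#' @export
#' @examples
#' z <- standardize_expression(matrix(rpois(60, 10), 6, 10,
#'      dimnames = list(paste0("g", 1:6), paste0("s", 1:10))))$standardized
#' orm <- compute_orm(z)
#' mean(diag(orm$O))  # 1
compute_orm <- function(z, check_psd = TRUE) {
  if (!is.matrix(z) || !is.numeric(z)) abort("`z` must be a numeric matrix")
  m <- nrow(z)
  if (m < 1L) abort("need at least one gene")
  if (max(abs(rowMeans(z))) > 1e-6) {
    abort("`z` rows are not centered: standardize the expression first")
  }
  O <- crossprod(z) / m
  O <- (O + t(O)) / 2  # enforce exact symmetry against rounding
  if (check_psd) {
    ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      abort(sprintf("ORM is not positive semi-definite (min eigenvalue %.3e)",
                    min(ev)))
    }
  }
  structure(list(O = O, m = m, sample_ids = colnames(z), z = z),
            class = "twas_orm")
}

#' Exact leave-one-gene-out ORM downdate
#'
#' Removes gene `gene` from an ORM without recomputation:
#' `O_(-i) = (m * O - z_i z_i') / (m - 1)`, which equals the ORM rebuilt
#' from scratch without that gene.
#'
#' @param orm A [compute_orm()] object.
#' @param gene Gene id (rowname of the cached standardized matrix).
#' @return A `twas_orm` over the remaining m - 1 genes.
#' @export
orm_downdate <- function(orm, gene) {
  stopifnot(inherits(orm, "twas_orm"))
  if (orm$m <= 1L) abort("cannot downdate an ORM with a single gene")
  if (!gene %in% rownames(orm$z)) {
    abort(sprintf("gene `%s` is not in the ORM", gene))
  }
  zi <- orm$z[gene, ]
  O <- (orm$m * orm$O - tcrossprod(zi)) / (orm$m - 1L)
  z <- orm$z[setdiff(rownames(orm$z), gene), , drop = FALSE]
  structure(list(O = (O + t(O)) / 2, m = orm$m - 1L,
                 sample_ids = orm$sample_ids, z = z),
            class = "twas_orm")
}

#' @export
print.twas_orm <- function(x, ...) {
  cat(sprintf("<twas_orm> %d samples, %d genes; mean diagonal %.4f\n",
              ncol(x$O), x$m, mean(diag(x$O))))
  invisible(x)
}
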