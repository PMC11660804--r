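#' Tidy a REML variance-component fit
#' @param x A [reml_fit()] object.
#' @param ... Unused.
#' @return Tibble with one row per variance component.
#' @export
tidy.twas_reml <- function(x, ...) {
  tibble::tibble(component = c("sigma_o2", "sigma_e2"),
                 estimate = c(x$sigma_o2, x$sigma_e2))
}

#' One-row summary of a REML fit
#' @inheritParams tidy.twas_reml
#' @return One-row tibble: variance components, polygenic fraction,
#'   restricted log-likelihood, convergence.
#' @export
glance.twas_reml <- function(x, ...) {
  tibble::tibble(sigma_o2 = x$sigma_o2, sigma_e2 = x$sigma_e2,
                 var_frac = x$sigma_o2 / (x$sigma_o2 + x$sigma_e2),
                 loglik = x$loglik, converged = x$converged,
                 n_iter = x$n_iter, n = x$n, p = x$p)
}

#' Tidy an association scan
#' @param x A [run_trait()] result.
#' @param ... Unused.
#' @return The per-gene tibble (gene_id, beta, se, chisq, p).
#' @export
tidy.twas_assoc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "beta", "se", "chisq", "p")])
}

#' One-row summary of an association scan
#' @inheritParams tidy.twas_assoc
#' @return One-row tibble: trait, sample and gene counts, variance
#'   components, genomic inflation factor.
#' @export
glance.twas_assoc <- function(x, ...) {
  vc <- attr(x, "vc")
  p <- x$p[!is.na(x$p)]
  lam <- if (length(p) >= 2L) genomic_inflation(p)$lambda else NA_real_
  tibble::tibble(trait = attr(x, "trait"), n = attr(x, "n"), m = attr(x, "m"),
                 sigma_o2 = vc$sigma_o2, sigma_e2 = vc$sigma_e2,
                 var_frac = vc$sigma_o2 / (vc$sigma_o2 + vc$sigma_e2),
                 lambda = lam,
                 fixed_effects = paste(attr(x, "fixed_effects"),
                                       collapse = "+"))
}

#' Tidy an inflation report (QQ coordinates)
#' @param x A [genomic_inflation()] object.
#' @param ... Unused.
#' @return Tibble of expected/observed -log10 p, sorted by expected.
#' @export
tidy.twas_inflation <- function(x, ...) x$qq

#' One-row summary of an inflation report
#' @inheritParams tidy.twas_inflation
#' @return One-row tibble: lambda, CI, number of tests.
#' @export
glance.twas_inflation <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_tests = x$n_tests, ci_level = x$ci_level,
                 ci_method = x$ci_method)
}

#' Tidy a candidate set
#' @param x A [pick_candidates()] object.
#' @param ... Unused.
#' @return The top-k tibble with a `significant` flag.
#' @export
tidy.twas_candidates <- function(x, ...) tibble::as_tibble(x$top)

#' One-row summary of a candidate set
#' @inheritParams tidy.twas_candidates
#' @return One-row tibble: counts of significant and top genes.
#' @export
glance.twas_candidates <- function(x, ...) {
  tibble::tibble(trait = x$trait %||% NA_character_,
                 n_significant = nrow(x$significant),
                 n_top = nrow(x$top), alpha = x$alpha, k = x$k,
                 n_tested = x$n_tested)
}

#' Widen a phenotypic correlation table into a matrix
#' @param x A [phenotype_correlations()] result.
#' @param value Which value to spread: `"r"`, `"p"`, or `"stars"`.
#' @return A symmetric matrix over the traits.
#' @export
cor_matrix <- function(x, value = c("r", "p", "stars")) {
  value <- match.arg(value)
  traits <- attr(x, "traits")
  mat <- matrix(if (value == "stars") NA_character_ else NA_real_,
                length(traits), length(traits),
                dimnames = list(traits, traits))
  for (i in seq_len(nrow(x))) {
    mat[x$trait1[i], x$trait2[i]] <- x[[value]][i]
    mat[x$trait2[i], x$trait1[i]] <- x[[value]][i]
  }
  mat
}
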