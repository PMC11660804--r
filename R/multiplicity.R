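#' Genomic inflation factor with confidence interval
#'
#' Converts raw p-values to 1-df chi-square statistics through the
#' upper-tail inverse CDF and reports
#' \eqn{\hat\lambda = \mathrm{median}(\chi^2) / 0.4549} (the denominator
#' being the median of the chi-square distribution with 1 df). The default
#' 95% CI is the distribution-free binomial order-statistic interval for
#' the median, each endpoint divided by the same constant; a percentile
#' bootstrap is available as an alternative. QQ coordinates use uniform
#' plotting positions (i - 0.5)/n.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param ci_level Confidence level (default 0.95).
#' @param ci_method `"order_stat"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return Object of class `twas_inflation`: `lambda`, `ci_low`, `ci_high`,
#'   `n_tests`, `qq` (tibble of expected/observed -log10 p, sorted by
#'   expected quantile).
#' @export
#' @examples
#' genomic_inflation(runif(1000))
genomic_inflation <- function(pvals, ci_level = 0.95,
                              ci_method = c("order_stat", "bootstrap"),
                              n_boot = 1000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  pvals <- as.numeric(pvals)
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1] with no missing values")
  }
  n <- length(pvals)
  if (n < 20L) warn("fewer than 20 tests: the lambda CI is not meaningful")
  denom <- qchisq(0.5, df = 1)  # 0.4549364
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / denom

  alpha <- 1 - ci_level
  if (ci_method == "order_stat" && n >= 2L) {
    # distribution-free CI for the median from binomial order statistics:
    # P(X_(j) <= med <= X_(k)) = P(j <= B <= k-1), B ~ Binomial(n, 1/2)
    s <- sort(chisq)
    j <- qbinom(alpha / 2, n, 0.5)
    while (j > 0 && pbinom(j - 1, n, 0.5) > alpha / 2) j <- j - 1L
    j <- max(j, 1L)
    k <- n + 1L - j
    ci_low <- s[j] / denom
    ci_high <- s[min(k, n)] / denom
  } else {
    bl <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        median(chisq[sample.int(n, n, replace = TRUE)]) / denom
      }, numeric(1))
    })
    ci_low <- unname(quantile(bl, alpha / 2))
    ci_high <- unname(quantile(bl, 1 - alpha / 2))
  }

  ord <- order(pvals)
  qq <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(pvals[ord])
  )
  qq <- qq[order(qq$expected), ]
  structure(list(lambda = lambda, ci_low = min(ci_low, lambda),
                 ci_high = max(ci_high, lambda), n_tests = n, qq = qq,
                 ci_level = ci_level, ci_method = ci_method),
            class = "twas_inflation")
}

#' @export
print.twas_inflation <- function(x, ...) {
  cat(sprintf("<twas_inflation> lambda = %.3f (%.0f%% CI %.3f-%.3f), %d tests\n",
              x$lambda, 100 * x$ci_level, x$ci_low, x$ci_high, x$n_tests))
  invisible(x)
}

#' FDR adjustment of raw p-values
#'
#' Benjamini-Hochberg step-up adjustment (Benjamini-Yekutieli available via
#' `method`), with significance called at `adjusted p < alpha`. Results are
#' mapped back to the input order.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return Tibble: `p`, `p_adj`, `significant`, in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvals, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  pvals <- as.numeric(pvals)
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1] with no missing values")
  }
  adj <- p.adjust(pvals, method = method)
  tibble::tibble(p = pvals, p_adj = adj, significant = adj < alpha)
}

#' Candidate gene calling
#'
#' From an association table: the genes significant at FDR-adjusted
#' `p < alpha`, and the `k` genes with the lowest raw p-values (ties broken
#' lexicographically by gene id) for downstream functional enrichment.
#'
#' @param assoc An association tibble with `gene_id` and `p` columns (e.g.
#'   from [run_trait()]); rows with missing p are excluded from ranking.
#' @param k Size of the lowest-p candidate list (default 20).
#' @param alpha FDR threshold (default 0.05).
#' @param method FDR method passed to [bh_adjust()].
#' @return Object of class `twas_candidates`: list with `trait`,
#'   `significant` (tibble incl. `p_adj`), `top` (tibble of the k lowest-p
#'   genes, ascending p), `alpha`, `k`.
#' @export
pick_candidates <- function(assoc, k = 20, alpha = 0.05,
                            method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!all(c("gene_id", "p") %in% names(assoc))) {
    abort("`assoc` must have gene_id and p columns")
  }
  tested <- dplyr::filter(assoc, !is.na(.data$p))
  if (nrow(tested) == 0L) abort("no tested genes (all p missing)")
  adj <- bh_adjust(tested$p, alpha = alpha, method = method)
  tested <- dplyr::mutate(tested, p_adj = adj$p_adj,
                          significant = adj$significant)
  ord <- order(tested$p, tested$gene_id)
  top <- tested[ord[seq_len(min(k, nrow(tested)))], ]
  structure(list(trait = attr(assoc, "trait"),
                 significant = dplyr::filter(tested, .data$significant),
                 top = top, alpha = alpha, k = k, n_tested = nrow(tested)),
            class = "twas_candidates")
}

#' @export
print.twas_candidates <- function(x, ...) {
  cat(sprintf("<twas_candidates>%s %d significant at FDR < %g; top %d of %d tested\n",
              if (!is.null(x$trait)) paste0(" trait ", x$trait, ":") else "",
              nrow(x$significant), x$alpha, nrow(x$top), x$n_tested))
  invisible(x)
}

star_code <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Pairwise phenotypic correlations
#'
#' Pearson correlations among trait columns on pairwise-complete
#' observations, with two-sided t-test p-values and significance stars at
#' 0.05 / 0.01 / 0.001. Constant traits yield missing correlations.
#'
#' @param phenotypes Data frame with trait columns.
#' @param traits Trait column names (default: all numeric non-id columns).
#' @return Object of class `twas_cor`: long tibble `trait1`, `trait2`, `r`,
#'   `n`, `p`, `stars` over all unordered pairs (including the diagonal).
#' @export
phenotype_correlations <- function(phenotypes, traits = NULL) {
  df <- as.data.frame(phenotypes)
  if (is.null(traits)) {
    traits <- names(df)[vapply(df, is.numeric, logical(1))]
    traits <- setdiff(traits, "sample_id")
  }
  if (length(traits) < 2L) abort("need at least 2 traits")
  pairs <- expand.grid(i = seq_along(traits), j = seq_along(traits))
  pairs <- pairs[pairs$i <= pairs$j, ]
  rows <- purrr::pmap(pairs, function(i, j) {
    x <- df[[traits[i]]]; y <- df[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) abort(sprintf("fewer than 3 pairwise-complete observations for %s/%s",
                              traits[i], traits[j]))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else if (i == j) {
      r <- 1; p <- 0
    } else {
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "pearson"))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    tibble::tibble(trait1 = traits[i], trait2 = traits[j],
                   r = r, n = n, p = p, stars = star_code(p))
  })
  structure(dplyr::bind_rows(rows),
            class = c("twas_cor", "tbl_df", "tbl", "data.frame"),
            traits = traits)
}
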