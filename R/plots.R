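#' QQ plot of association p-values
#'
#' Observed versus expected -log10 p under the uniform null, annotated with
#' the genomic inflation factor.
#'
#' @param object A [genomic_inflation()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twas_inflation <- function(object, ...) {
  ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$expected,
                                          y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.3f (%.0f%% CI %.3f-%.3f)",
                         object$lambda, 100 * object$ci_level,
                         object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an association scan
#'
#' One point per gene at -log10 p. With an `annotation` table carrying
#' `gene_id`, `chrom`, `pos`, genes are laid out by genomic position and
#' coloured by chromosome; otherwise they are plotted in matrix order.
#'
#' @param object A [run_trait()] result.
#' @param annotation Optional tibble with `gene_id`, `chrom`, `pos`.
#' @param alpha FDR threshold drawn as the significance line (default 0.05);
#'   the line is placed at the largest raw p called significant, if any.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twas_assoc <- function(object, annotation = NULL, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p), ]
  df$neglog10p <- -log10(df$p)
  adj <- bh_adjust(df$p, alpha = alpha)
  sig_p <- if (any(adj$significant)) max(df$p[adj$significant]) else NA_real_
  if (!is.null(annotation)) {
    df <- dplyr::inner_join(df, annotation, by = "gene_id")
    df <- dplyr::arrange(df, .data$chrom, .data$pos)
    df$idx <- seq_len(nrow(df))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx,
                                           y = .data$neglog10p,
                                           colour = factor(.data$chrom))) +
      ggplot2::guides(colour = "none") +
      ggplot2::labs(x = "Gene (by genomic position)")
  } else {
    df$idx <- seq_len(nrow(df))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx,
                                           y = .data$neglog10p)) +
      ggplot2::labs(x = "Gene (matrix order)")
  }
  gg <- gg + ggplot2::geom_point(size = 0.7, alpha = 0.8) +
    ggplot2::labs(y = expression(-log[10](p)),
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
  if (!is.na(sig_p)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(sig_p),
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Heatmap of phenotypic correlations
#'
#' Lower-triangle tile plot of pairwise Pearson correlations with
#' significance stars.
#'
#' @param object A [phenotype_correlations()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twas_cor <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$trait1 != df$trait2, ]
  traits <- attr(object, "traits")
  df$trait1 <- factor(df$trait1, levels = traits)
  df$trait2 <- factor(df$trait2, levels = traits)
  df$label <- sprintf("%.2f%s", df$r, df$stars)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait2, y = .data$trait1,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.twas_inflation
#' @param pvals Raw p-values, as an alternative entry point.
#' @export
plot_qq <- function(pvals, ...) autoplot(genomic_inflation(pvals), ...)
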