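#' Simulation configuration for synthetic TWAS data
#'
#' Bundles and validates every parameter of the synthetic data generator.
#' The defaults emulate the kind of dataset the pipeline targets: ~115
#' samples, ~10k expressed genes with widely varying mean expression,
#' lognormal library sizes, negative-binomial counts, a small set of causal
#' genes, a polygenic background spread over all genes, sex and birth-season
#' fixed effects, and occasional phenotype outliers.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param n_causal Number of causal genes per trait (drawn once, shared
#'   across traits; per-trait effect sizes are drawn independently).
#' @param causal_effect_sd Standard deviation of causal effect sizes, in
#'   phenotype units per SD of standardized expression.
#' @param polygenic_var_frac Target \eqn{\sigma^2_o/(\sigma^2_o+\sigma^2_e)}:
#'   the fraction of (non-fixed, non-causal) phenotypic variance explained by
#'   the polygenic background over all genes. Must lie in `[0, 1)`.
#' @param residual_var Residual variance \eqn{\sigma^2_e}.
#' @param libsize_log_sd SD of log library-size factors (lognormal).
#' @param mean_libsize Expected library size (total reads per sample).
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi}
#'   (variance \eqn{\mu + \phi\mu^2}). `0` is the Poisson-limit sentinel.
#' @param mean_log_expr_sd SD of per-gene log mean relative expression.
#' @param sex_effect Additive fixed effect of the second sex level, in
#'   phenotype units.
#' @param season_effects Numeric vector of 3 additive birth-season effects.
#' @param outlier_rate Probability that a sample's phenotype is shifted into
#'   the outlier range (per trait).
#' @param outlier_scale Outlier shift magnitude in trait-SD units. The
#'   default (6) places outliers well beyond the median ± 3.5 MAD fence so
#'   that phenotype QC must catch them.
#' @param traits Character vector of trait names to simulate.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 40, n_genes = 500, seed = 1)
sim_config <- function(n_samples = 115,
                       n_genes = 10288,
                       n_causal = 2,
                       causal_effect_sd = 1,
                       polygenic_var_frac = 0.3,
                       residual_var = 1,
                       libsize_log_sd = 0.5,
                       mean_libsize = 2e6,
                       nb_dispersion = 0.1,
                       mean_log_expr_sd = 1.8,
                       sex_effect = 0.5,
                       season_effects = c(-0.3, 0, 0.3),
                       outlier_rate = 0.02,
                       outlier_scale = 6,
                       traits = c("CW", "DP", "LW", "RLW", "WF", "DL", "CL"),
                       seed = 1L) {
  check_scalar(n_samples, "n_samples", lower = 2, integer = TRUE)
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(n_causal, "n_causal", lower = 0, integer = TRUE)
  if (n_causal > n_genes) stop_config("n_causal", "must be <= n_genes")
  check_scalar(causal_effect_sd, "causal_effect_sd", lower = 0)
  check_scalar(polygenic_var_frac, "polygenic_var_frac", lower = 0, upper = 1)
  if (polygenic_var_frac >= 1) {
    stop_config("polygenic_var_frac", "must be < 1 (residual variance is positive)")
  }
  check_scalar(residual_var, "residual_var", lower = 0, strict_lower = TRUE)
  check_scalar(libsize_log_sd, "libsize_log_sd", lower = 0)
  check_scalar(mean_libsize, "mean_libsize", lower = 0, strict_lower = TRUE)
  check_scalar(nb_dispersion, "nb_dispersion", lower = 0)
  check_scalar(mean_log_expr_sd, "mean_log_expr_sd", lower = 0, strict_lower = TRUE)
  check_scalar(sex_effect, "sex_effect")
  if (!is.numeric(season_effects) || length(season_effects) != 3L ||
      !all(is.finite(season_effects))) {
    stop_config("season_effects", "must be 3 finite numbers")
  }
  check_scalar(outlier_rate, "outlier_rate", lower = 0, upper = 1)
  check_scalar(outlier_scale, "outlier_scale", lower = 0, strict_lower = TRUE)
  if (!is.character(traits) || length(traits) < 1L || anyDuplicated(traits)) {
    stop_config("traits", "must be distinct trait names")
  }
  check_scalar(seed, "seed", integer = TRUE)

  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_causal = as.integer(n_causal), causal_effect_sd = causal_effect_sd,
         polygenic_var_frac = polygenic_var_frac, residual_var = residual_var,
         libsize_log_sd = libsize_log_sd, mean_libsize = mean_libsize,
         nb_dispersion = nb_dispersion, mean_log_expr_sd = mean_log_expr_sd,
         sex_effect = sex_effect, season_effects = season_effects,
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         traits = traits, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a gene-by-sample read-count matrix
#'
#' Counts are drawn negative-binomially around gene-specific lognormal mean
#' relative expression levels scaled by per-sample lognormal library sizes.
#' The same seed and configuration always reproduce the same matrix.
#'
#' @param config A [sim_config()] object.
#' @return Integer matrix, genes x samples, with gene/sample id dimnames.
#' @export
#' @examples
#' counts <- simulate_counts(sim_config(n_samples = 10, n_genes = 50, seed = 1))
#' dim(counts)
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  m <- config$n_genes
  n <- config$n_samples
  with_seed(config$seed, {
    # relative expression per gene, normalized to proportions of the library
    rel <- exp(rnorm(m, mean = 0, sd = config$mean_log_expr_sd))
    prop <- rel / sum(rel)
    # library sizes: lognormal around mean_libsize (mean-corrected)
    ls_sd <- config$libsize_log_sd
    libsize <- config$mean_libsize * exp(rnorm(n, -ls_sd^2 / 2, ls_sd))
    mu <- outer(prop, libsize)  # expected counts, genes x samples
    counts <- if (config$nb_dispersion == 0) {
      rpois(m * n, lambda = mu)
    } else {
      rnbinom(m * n, mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = m, ncol = n)
    dimnames(counts) <- list(
      sprintf("g%0*d", nchar(m), seq_len(m)),
      sprintf("s%0*d", nchar(n), seq_len(n))
    )
    counts
  })
}

#' Simulate phenotypes with a known causal and polygenic architecture
#'
#' Builds, for each configured trait,
#' \deqn{y = C\beta + \sum_{i \in causal} w_i b_i + W u + e}
#' where `C` holds sex (2 levels) and birth season (3 levels), `W` is the
#' matrix of standardized expression levels of all filtered genes (the same
#' TMM/CPM standardization convention the analysis uses, so the analysis
#' model is exactly well specified by default), `u ~ N(0, sigma_o^2/m)` per
#' gene, and `e ~ N(0, sigma_e^2)`. A fraction of samples gets an additive
#' outlier shift of `outlier_scale` trait SDs. Everything drawn is recorded
#' in the returned truth table.
#'
#' @param counts Count matrix from [simulate_counts()] (or compatible).
#' @param config A [sim_config()] object.
#' @param causal_genes Optional character vector of causal gene ids
#'   (overrides random choice; recycled across traits).
#' @param causal_effects Optional numeric vector of causal effect sizes used
#'   for every trait (overrides `causal_effect_sd` draws).
#' @param latent_polygenic If `TRUE`, the polygenic term is generated from a
#'   latent Gaussian gene matrix instead of the standardized observed
#'   expression — a model-misspecification toggle for robustness studies.
#'
#' @return A list with elements `phenotypes` (tibble: sample_id, sex,
#'   season, one column per trait) and `truth` (list: causal effects per
#'   trait, polygenic draws, variance components, outlier ids).
#' @export
simulate_phenotypes <- function(counts, config,
                                causal_genes = NULL,
                                causal_effects = NULL,
                                latent_polygenic = FALSE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  check_count_matrix(counts)
  n <- ncol(counts)

  # standardized expression under the analysis convention (TMM + CPM +
  # expressed-gene filter + per-gene population-variance standardization)
  nf <- tmm_normalize(counts)
  keep <- filter_expressed(counts)
  cpm_mat <- cpm_normalize(counts, nf)
  std <- standardize_expression(cpm_mat[keep, , drop = FALSE])
  Z <- std$standardized
  m <- nrow(Z)
  if (config$n_causal > m) {
    abort(sprintf(
      "n_causal (%d) exceeds the number of expressed genes after filtering (%d)",
      config$n_causal, m))
  }

  sigma_e2 <- config$residual_var
  f <- config$polygenic_var_frac
  sigma_o2 <- if (f > 0) f / (1 - f) * sigma_e2 else 0

  with_seed(config$seed + 1L, {
    sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
    season <- factor(sample(c("S1", "S2", "S3"), n, replace = TRUE),
                     levels = c("S1", "S2", "S3"))
    fixed_part <- config$sex_effect * (sex == "M") +
      config$season_effects[as.integer(season)]

    if (is.null(causal_genes)) {
      causal_genes <- if (config$n_causal > 0) {
        sample(rownames(Z), config$n_causal)
      } else character()
    } else {
      if (!all(causal_genes %in% rownames(Z))) {
        abort("causal_genes must be expressed (filter-passing) gene ids")
      }
    }
    n_causal <- length(causal_genes)

    if (latent_polygenic) {
      W <- matrix(rnorm(m * n), nrow = m)
    } else {
      W <- Z
    }

    traits <- config$traits
    pheno <- matrix(NA_real_, nrow = n, ncol = length(traits),
                    dimnames = list(colnames(counts), traits))
    causal_tbl <- vector("list", length(traits))
    poly_tbl <- vector("list", length(traits))
    outlier_tbl <- vector("list", length(traits))

    for (t in seq_along(traits)) {
      b <- if (n_causal == 0) numeric() else if (!is.null(causal_effects)) {
        rep_len(causal_effects, n_causal)
      } else {
        rnorm(n_causal, 0, config$causal_effect_sd)
      }
      u <- if (sigma_o2 > 0) rnorm(m, 0, sqrt(sigma_o2 / m)) else numeric(m)
      e <- rnorm(n, 0, sqrt(sigma_e2))
      y <- as.numeric(fixed_part) + crossprod(W, u)[, 1L] + e
      if (n_causal > 0) {
        y <- y + crossprod(Z[causal_genes, , drop = FALSE], b)[, 1L]
      }
      out_ids <- character()
      if (config$outlier_rate > 0) {
        hit <- which(runif(n) < config$outlier_rate)
        if (length(hit)) {
          shift <- sample(c(-1, 1), length(hit), replace = TRUE) *
            config$outlier_scale * sd(y)
          y[hit] <- y[hit] + shift
          out_ids <- colnames(counts)[hit]
        }
      }
      pheno[, t] <- y
      causal_tbl[[t]] <- tibble::tibble(trait = traits[t],
                                        gene_id = causal_genes, effect = b)
      poly_tbl[[t]] <- tibble::tibble(trait = traits[t],
                                      gene_id = rownames(Z), effect = u)
      outlier_tbl[[t]] <- tibble::tibble(trait = traits[t], sample_id = out_ids)
    }

    phenotypes <- tibble::tibble(
      sample_id = colnames(counts), sex = sex, season = season,
      tibble::as_tibble(pheno)
    )
    truth <- list(
      causal = dplyr::bind_rows(causal_tbl),
      polygenic = dplyr::bind_rows(poly_tbl),
      outliers = dplyr::bind_rows(outlier_tbl),
      sigma_o2 = sigma_o2,
      sigma_e2 = sigma_e2,
      expressed_genes = rownames(Z)
    )
    list(phenotypes = phenotypes, truth = truth)
  })
}

#' Simulate a complete synthetic TWAS dataset
#'
#' Convenience wrapper: [simulate_counts()] then [simulate_phenotypes()].
#'
#' @inheritParams simulate_phenotypes
#' @param config A [sim_config()] object.
#' @return List with `counts`, `phenotypes`, `truth`, and the echoed `config`.
#' @export
simulate_twas <- function(config, causal_genes = NULL, causal_effects = NULL,
                          latent_polygenic = FALSE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  counts <- simulate_counts(config)
  ph <- simulate_phenotypes(counts, config, causal_genes = causal_genes,
                            causal_effects = causal_effects,
                            latent_polygenic = latent_polygenic)
  list(counts = counts, phenotypes = ph$phenotypes, truth = ph$truth,
       config = config)
}
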