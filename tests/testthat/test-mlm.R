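# helper: phenotype frame with sex/season covariates
make_pheno <- function(n, y) {
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    sex = factor(rep_len(c("F", "M"), n)),
    season = factor(rep_len(c("S1", "S2", "S3"), n)),
    y = y)
}

test_that("backward elimination keeps overwhelming effects and drops absent ones", {
  n <- 200
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    season <- factor(sample(c("S1", "S2", "S3"), n, replace = TRUE))
    y <- 5 * (sex == "M") + rnorm(n)
    sel <- select_fixed_effects(
      tibble::tibble(y = y, sex = sex, season = season), "y")$selected
    ("sex" %in% sel) && !("season" %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("under the null each factor is retained at about its type-I level", {
  n <- 200
  kept_sex <- vapply(1:400, function(s) {
    set.seed(1000 + s)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    season <- factor(sample(c("S1", "S2", "S3"), n, replace = TRUE))
    sel <- select_fixed_effects(
      tibble::tibble(y = rnorm(n), sex = sex, season = season), "y")$selected
    "sex" %in% sel
  }, logical(1))
  expect_gte(mean(kept_sex), 0.01)
  expect_lte(mean(kept_sex), 0.10)
})

test_that("the retention threshold is a sharp boundary at p = 0.05", {
  set.seed(31)
  n <- 40
  sex <- factor(rep(c("F", "M"), each = n / 2))
  e <- stats::residuals(lm(rnorm(n) ~ sex))  # noise orthogonal to sex
  p_of <- function(delta) {
    fit <- lm(y ~ sex, data = data.frame(y = delta * (sex == "M") + e, sex))
    drop1(fit, test = "F")[["Pr(>F)"]][2]
  }
  d49 <- stats::uniroot(function(d) p_of(d) - 0.049, c(0.01, 5))$root
  d51 <- stats::uniroot(function(d) p_of(d) - 0.051, c(0.01, 5))$root
  sel49 <- select_fixed_effects(
    tibble::tibble(y = d49 * (sex == "M") + e, sex = sex), "y",
    candidates = "sex")$selected
  sel51 <- select_fixed_effects(
    tibble::tibble(y = d51 * (sex == "M") + e, sex = sex), "y",
    candidates = "sex")$selected
  expect_identical(sel49, "sex")
  expect_identical(sel51, character(0))
})

test_that("a near-identity ORM is flagged as unidentifiable", {
  set.seed(40)
  n <- 30
  y <- rnorm(n)
  expect_warning(vc <- reml_fit(y, NULL, diag(n)), "unidentifiable")
  expect_equal(vc$sigma_o2, 0)
  expect_gt(vc$sigma_e2, 0)
  expect_true(vc$converged)
})

test_that("permuting the phenotype against the ORM drives sigma_o2 to 0", {
  cfg <- sim_config(n_samples = 100, n_genes = 400, n_causal = 0,
                    polygenic_var_frac = 0.5, outlier_rate = 0,
                    sex_effect = 0, season_effects = c(0, 0, 0),
                    traits = "y", seed = 50)
  sim <- simulate_twas(cfg)
  expr <- preprocess_counts(sim$counts)
  orm <- compute_orm(expr$standardized)
  eig <- eigen(orm$O, symmetric = TRUE)
  y <- sim$phenotypes$y
  set.seed(51)
  ratios <- vapply(1:20, function(i) {
    vc <- reml_fit(sample(y), NULL, orm$O, eig = eig)
    vc$sigma_o2 / (vc$sigma_o2 + vc$sigma_e2)
  }, numeric(1))
  expect_lt(median(ratios), 0.1)
})

test_that("with sigma_o2 = 0 the gene test reduces to the OLS partial test", {
  set.seed(60)
  n <- 24
  z <- make_std(10, n, seed = 60)
  orm <- compute_orm(z)
  ph <- make_pheno(n, rnorm(n))
  X <- cbind("(Intercept)" = 1, sexM = as.numeric(ph$sex == "M"))
  g <- rownames(z)[3]
  fit <- lm(ph$y ~ 0 + X + z[g, ])
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  fake_vc <- structure(
    list(sigma_o2 = 0, sigma_e2 = mse, ratio = 0, loglik = NA,
         converged = TRUE, n_iter = 0L, n = n, p = 2L,
         eig = eigen(orm$O, symmetric = TRUE)),
    class = "twas_reml")
  res <- test_gene(ph$y, X, orm, g, vc = fake_vc)
  sm <- summary(fit)$coefficients
  expect_equal(res$beta, unname(sm[3, 1]), tolerance = 1e-8)
  expect_equal(res$se, unname(sm[3, 2]), tolerance = 1e-8)
  expect_equal(res$chisq, unname(sm[3, 3])^2, tolerance = 1e-8)
  expect_equal(res$p, pchisq(unname(sm[3, 3])^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("the Woodbury-downdated GLS matches the explicit dense oracle", {
  set.seed(70)
  n <- 8; m <- 6
  z <- make_std(m, n, seed = 70)
  orm <- compute_orm(z)
  y <- rnorm(n)
  X <- cbind("(Intercept)" = rep(1, n))
  vc <- reml_fit(y, X, orm$O)
  for (i in seq_len(m)) {
    g <- rownames(z)[i]
    res <- test_gene(y, X, orm, g, vc = vc)
    ora <- oracle_gls(y, X, z, i, vc$sigma_o2, vc$sigma_e2, exclude = TRUE)
    expect_equal(res$beta, unname(ora["beta"]), tolerance = 1e-8)
    expect_equal(res$se, unname(ora["se"]), tolerance = 1e-8)
    expect_equal(res$p, unname(ora["p"]), tolerance = 1e-8)
  }
})

test_that("target exclusion changes the test and matches its own oracle", {
  set.seed(71)
  n <- 10; m <- 8
  z <- make_std(m, n, seed = 71)
  orm <- compute_orm(z)
  y <- as.numeric(2 * z[1, ] + rnorm(n))
  X <- cbind("(Intercept)" = rep(1, n))
  vc <- reml_fit(y, X, orm$O)
  g <- rownames(z)[1]
  excl <- test_gene(y, X, orm, g, vc = vc, exclude_target = TRUE)
  incl <- test_gene(y, X, orm, g, vc = vc, exclude_target = FALSE)
  expect_false(isTRUE(all.equal(excl$p, incl$p)))
  expect_equal(excl$p,
               unname(oracle_gls(y, X, z, 1, vc$sigma_o2, vc$sigma_e2,
                                 exclude = TRUE)["p"]), tolerance = 1e-8)
  expect_equal(incl$p,
               unname(oracle_gls(y, X, z, 1, vc$sigma_o2, vc$sigma_e2,
                                 exclude = FALSE)["p"]), tolerance = 1e-8)
})

test_that("per-gene REML and global REML with downdates nearly agree", {
  cfg <- sim_config(n_samples = 50, n_genes = 250, n_causal = 1,
                    causal_effect_sd = 1, polygenic_var_frac = 0.3,
                    outlier_rate = 0, traits = "y", seed = 80)
  sim <- simulate_twas(cfg)
  glob <- run_trait(sim$phenotypes, sim$counts, "y", vc_mode = "global",
                    min_samples = 20)
  perg <- run_trait(sim$phenotypes, sim$counts, "y", vc_mode = "per_gene",
                    min_samples = 20)
  ok <- !is.na(glob$p) & !is.na(perg$p)
  expect_gt(cor(glob$chisq[ok], perg$chisq[ok]), 0.95)
  expect_lt(median(abs(glob$chisq[ok] - perg$chisq[ok]) /
                     pmax(glob$chisq[ok], 1)), 0.1)
})

test_that("a strongly causal gene ranks at the top of the scan", {
  ranks <- vapply(1:5, function(s) {
    cfg <- sim_config(n_samples = 120, n_genes = 500, n_causal = 1,
                      polygenic_var_frac = 0.3, outlier_rate = 0,
                      traits = "y", seed = 200 + s)
    sd_y <- sqrt(cfg$residual_var / (1 - cfg$polygenic_var_frac))
    sim <- simulate_twas(cfg, causal_effects = 1.0 * sd_y)
    res <- run_trait(sim$phenotypes, sim$counts, "y")
    tab <- tidy(res)[order(tidy(res)$p, tidy(res)$gene_id), ]
    which(tab$gene_id == sim$truth$causal$gene_id[1])
  }, numeric(1))
  expect_lte(median(ranks), 5)
})

test_that("run_trait is deterministic and applies the per-trait mask", {
  cfg <- sim_config(n_samples = 45, n_genes = 150, n_causal = 0,
                    polygenic_var_frac = 0.2, outlier_rate = 0,
                    traits = "y", seed = 90)
  sim <- simulate_twas(cfg)
  ph <- sim$phenotypes
  ph$y[3] <- NA                           # missing phenotype
  ph$y[10] <- max(ph$y, na.rm = TRUE) + 50 * sd(ph$y, na.rm = TRUE)  # outlier
  a <- run_trait(ph, sim$counts, "y", min_samples = 20)
  b <- run_trait(ph, sim$counts, "y", min_samples = 20)
  expect_identical(tidy(a), tidy(b))
  expect_equal(attr(a, "n"), 43L)
  expect_false(ph$sample_id[3] %in% attr(a, "sample_ids"))
  expect_false(ph$sample_id[10] %in% attr(a, "sample_ids"))
})

test_that("run_trait refuses hopeless sample sizes", {
  cfg <- sim_config(n_samples = 20, n_genes = 80, n_causal = 0,
                    traits = "y", seed = 91)
  sim <- simulate_twas(cfg)
  expect_error(run_trait(sim$phenotypes, sim$counts, "y"), "refusing")
})
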