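#' Backward elimination of fixed effects
#'
#' Ordinary-least-squares backward elimination on the phenotype alone:
#' starting from all candidate factors, repeatedly drop the factor with the
#' largest partial-F p-value above `alpha` (factors are tested as whole
#' blocks, so a 3-level season is one joint test) until every remaining
#' factor is significant. The intercept is never dropped.
#'
#' @param phenotypes Data frame holding the trait and candidate columns.
#' @param trait Trait column name (response).
#' @param candidates Character vector of candidate fixed-effect columns.
#' @param alpha Retention threshold on the partial-F p-value (default 0.05).
#' @return List of class `twas_fixsel`: `selected` (character), `steps`
#'   (tibble of drop decisions), `trait`.
#' @export
select_fixed_effects <- function(phenotypes, trait,
                                 candidates = c("sex", "season"),
                                 alpha = 0.05) {
  dat <- as.data.frame(phenotypes)[c(trait, candidates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (cc in candidates) {
    if (is.character(dat[[cc]])) dat[[cc]] <- factor(dat[[cc]])
    if (is.factor(dat[[cc]])) dat[[cc]] <- droplevels(dat[[cc]])
    if (is.factor(dat[[cc]]) && nlevels(dat[[cc]]) < 2L) {
      abort(sprintf("candidate `%s` has fewer than 2 observed levels", cc))
    }
  }
  remaining <- candidates
  steps <- list()
  repeat {
    fml <- stats::reformulate(if (length(remaining)) remaining else "1",
                              response = trait)
    fit <- lm(fml, data = dat)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      abort(sprintf("collinear fixed-effect design; aliased term(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (!length(remaining)) break
    dr <- drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1L]
    names(pv) <- rownames(dr)[-1L]
    worst <- which.max(pv)
    if (pv[worst] >= alpha) {
      steps[[length(steps) + 1L]] <- tibble::tibble(
        factor = names(pv)[worst], p_value = unname(pv[worst]),
        action = "dropped")
      remaining <- setdiff(remaining, names(pv)[worst])
    } else {
      steps[[length(steps) + 1L]] <- tibble::tibble(
        factor = names(pv), p_value = unname(pv), action = "retained")
      break
    }
  }
  structure(list(selected = remaining,
                 steps = if (length(steps)) dplyr::bind_rows(steps)
                         else tibble::tibble(factor = character(),
                                             p_value = numeric(),
                                             action = character()),
                 trait = trait),
            class = "twas_fixsel")
}

# fixed-effect design matrix (intercept + treatment-coded factors)
build_design <- function(phenotypes, selected) {
  dat <- as.data.frame(phenotypes)
  for (cc in selected) {
    if (is.character(dat[[cc]])) dat[[cc]] <- factor(dat[[cc]])
    if (is.factor(dat[[cc]])) dat[[cc]] <- droplevels(dat[[cc]])
  }
  fml <- stats::reformulate(if (length(selected)) selected else "1")
  model.matrix(fml, data = dat)
}

# -2 * restricted log-likelihood profile in the rotated basis, up to an
# additive constant; d are ORM eigenvalues, yt/Xt eigenrotated y and X
neg2_reml <- function(log_gamma, d, yt, Xt) {
  h <- exp(log_gamma) * d + 1
  Xh <- Xt / h
  XtHX <- crossprod(Xt, Xh)
  beta <- solve(XtHX, crossprod(Xh, yt))
  r <- yt - Xt %*% beta
  q <- sum(r^2 / h)
  np <- length(yt) - ncol(Xt)
  sum(log(h)) + determinant(XtHX, logarithm = TRUE)$modulus + np * log(q)
}

#' REML variance components on an ORM
#'
#' Fits \eqn{y \sim N(X\beta,\; \sigma^2_o O + \sigma^2_e I)} by restricted
#' maximum likelihood. The ORM is eigendecomposed once; the restricted
#' likelihood is then a one-dimensional profile in the variance ratio
#' \eqn{\gamma = \sigma^2_o/\sigma^2_e}, maximized by bounded scalar search
#' over log-gamma in `[log 1e-6, log 1e6]` (tolerance 1e-8), with the total
#' variance profiled out in closed form. A boundary optimum clamps
#' \eqn{\sigma^2_o} to 0. A near-identity ORM (all eigenvalues equal within
#' 1e-8) makes the ratio unidentifiable; the fit then reports
#' \eqn{\sigma^2_o = 0} with a warning.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (with intercept), or `NULL` for an
#'   intercept-only design.
#' @param O ORM matrix (n x n, PSD) or a `twas_orm` object.
#' @param eig Optional precomputed `eigen(O, symmetric = TRUE)`.
#' @return Object of class `twas_reml`: `sigma_o2`, `sigma_e2`, `ratio`,
#'   `loglik` (restricted), `converged`, `n_iter`, `n`, `p`, and the
#'   eigendecomposition (for reuse by the association scan).
#' @export
reml_fit <- function(y, X = NULL, O, eig = NULL) {
  if (inherits(O, "twas_orm")) O <- O$O
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n || n != nrow(O)) abort("dimension mismatch in reml_fit")
  p <- ncol(X)
  if (n < p + 2L) abort("too few samples for the fixed-effect design")
  if (is.null(eig)) eig <- eigen(O, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-8) {
    abort(sprintf("ORM is not positive semi-definite (min eigenvalue %.3e)",
                  min(eig$values)))
  }
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  np <- n - p

  ols_q <- function() {
    beta <- stats::lm.fit(Xt, yt)$residuals
    sum(beta^2)
  }

  if (max(d) - min(d) < 1e-8) {
    warn("ORM is (near) identity: variance components are unidentifiable; reporting sigma_o2 = 0")
    s2 <- ols_q() / np
    return(structure(list(sigma_o2 = 0, sigma_e2 = s2, ratio = 0,
                          loglik = NA_real_, converged = TRUE, n_iter = 0L,
                          n = n, p = p, eig = eig),
                     class = "twas_reml"))
  }

  n_eval <- 0L
  f <- function(lg) {
    n_eval <<- n_eval + 1L
    neg2_reml(lg, d, yt, Xt)
  }
  lo <- log(1e-6); hi <- log(1e6)
  opt <- optimize(f, interval = c(lo, hi), tol = 1e-8)
  lg <- opt$minimum
  # boundary handling: if the low boundary is at least as good, clamp to 0
  converged <- TRUE
  if (f(lo) <= opt$objective + 1e-10 || lg - lo < 1e-6) {
    gamma <- 0
  } else if (hi - lg < 1e-6) {
    gamma <- exp(lg)
    converged <- FALSE
    warn("REML ratio search hit the upper bound; estimates may be unreliable")
  } else {
    gamma <- exp(lg)
  }

  h <- gamma * d + 1
  Xh <- Xt / h
  XtHX <- crossprod(Xt, Xh)
  beta <- solve(XtHX, crossprod(Xh, yt))
  r <- yt - Xt %*% beta
  q <- sum(r^2 / h)
  sigma_e2 <- q / np
  sigma_o2 <- gamma * sigma_e2
  loglik <- -0.5 * (np * log(2 * pi * sigma_e2) + sum(log(h)) +
                    as.numeric(determinant(XtHX, logarithm = TRUE)$modulus) + np)
  structure(list(sigma_o2 = sigma_o2, sigma_e2 = sigma_e2, ratio = gamma,
                 loglik = loglik, converged = converged, n_iter = n_eval,
                 n = n, p = p, eig = eig),
            class = "twas_reml")
}

#' @export
print.twas_reml <- function(x, ...) {
  cat(sprintf(
    "<twas_reml> sigma_o2 = %.4g, sigma_e2 = %.4g (ratio %.3g), n = %d%s\n",
    x$sigma_o2, x$sigma_e2,
    x$sigma_o2 / (x$sigma_o2 + x$sigma_e2), x$n,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# GLS Wald test of one gene in the rotated basis with a rank-one Woodbury
# downdate of the covariance. All inputs rotated by the ORM eigenvectors:
# yt = U'y, Xt = U'X, zt = U'z_i. V_(-i) = A - c z z' with
# A = (m sigma_o2/(m-1)) O + sigma_e2 I (so a = diag in rotated basis) and
# c = sigma_o2/(m-1); exclude = FALSE tests against the full-O covariance.
gls_gene_rotated <- function(yt, Xt, zt, d, sigma_o2, sigma_e2, m,
                             exclude = TRUE) {
  if (exclude && m > 1L) {
    a <- (m * sigma_o2 / (m - 1L)) * d + sigma_e2
    cc <- sigma_o2 / (m - 1L)
  } else {
    a <- sigma_o2 * d + sigma_e2
    cc <- 0
  }
  G <- cbind(Xt, gene = zt)
  Ga <- G / a
  M <- crossprod(G, Ga)
  v <- crossprod(Ga, yt)
  if (cc > 0) {
    za <- zt / a
    denom <- 1 - cc * sum(zt * za)
    Gz <- crossprod(G, za)     # G' A^-1 z
    yz <- sum(za * yt)         # z' A^-1 y
    M <- M + (cc / denom) * tcrossprod(Gz)
    v <- v + (cc / denom) * Gz * yz
  }
  k <- ncol(G)
  cov <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(cov) || !all(is.finite(cov)) || cov[k, k] <= 0) {
    return(c(beta = NA_real_, se = NA_real_, chisq = NA_real_, p = NA_real_))
  }
  beta <- cov %*% v
  b <- unname(beta[k, 1L])
  se <- unname(sqrt(cov[k, k]))
  chisq <- (b / se)^2
  c(beta = b, se = se, chisq = chisq,
    p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Mixed-model association test of a single gene
#'
#' Generalized least squares estimate and 1-df Wald chi-square test of the
#' effect of one gene's standardized expression on the phenotype, under
#' \eqn{V_{(-i)} = \sigma^2_o O_{(-i)} + \sigma^2_e I} where \eqn{O_{(-i)}}
#' excludes the tested gene from the polygenic term (so it is never fitted
#' as fixed and random effect simultaneously).
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (with intercept).
#' @param orm A [compute_orm()] object built *including* gene `gene`.
#' @param gene Gene id to test.
#' @param vc Either a [reml_fit()] object (variance components reused across
#'   genes, `vc_mode = "global"`) or `NULL` to re-estimate them for this
#'   gene's leave-one-out ORM (`vc_mode = "per_gene"`).
#' @param exclude_target If `FALSE`, test against the full-ORM covariance
#'   (no exclusion) — for comparison only.
#' @return One-row tibble: `gene_id`, `beta`, `se`, `chisq`, `p`.
#' @export
test_gene <- function(y, X, orm, gene, vc = NULL, exclude_target = TRUE) {
  stopifnot(inherits(orm, "twas_orm"))
  if (!gene %in% rownames(orm$z)) abort(sprintf("gene `%s` not in ORM", gene))
  zi <- orm$z[gene, ]
  if (is.null(vc)) {
    # per-gene REML on the explicitly downdated ORM, with the gene as a
    # fixed covariate in the variance-component model
    Oi <- if (exclude_target) orm_downdate(orm, gene)$O else orm$O
    vc <- reml_fit(y, cbind(X, gene = zi), Oi)
    eig <- vc$eig
    yt <- crossprod(eig$vectors, y)
    Xt <- crossprod(eig$vectors, X)
    zt <- crossprod(eig$vectors, zi)[, 1L]
    res <- gls_gene_rotated(yt, Xt, zt, pmax(eig$values, 0),
                            vc$sigma_o2, vc$sigma_e2, m = orm$m,
                            exclude = FALSE)  # Oi already excludes the gene
  } else {
    stopifnot(inherits(vc, "twas_reml"))
    eig <- vc$eig
    yt <- crossprod(eig$vectors, y)
    Xt <- crossprod(eig$vectors, X)
    zt <- crossprod(eig$vectors, zi)[, 1L]
    res <- gls_gene_rotated(yt, Xt, zt, pmax(eig$values, 0),
                            vc$sigma_o2, vc$sigma_e2, m = orm$m,
                            exclude = exclude_target)
  }
  tibble::tibble(gene_id = gene, beta = res[["beta"]], se = res[["se"]],
                 chisq = res[["chisq"]], p = res[["p"]])
}

#' Run the full association scan for one trait
#'
#' Orchestrates the per-trait analysis: apply the trait's QC mask (MAD
#' outlier rule, complete covariates), backward-eliminate fixed effects,
#' preprocess the counts on the retained samples (TMM, CPM, expressed-gene
#' filter, standardization), build the ORM, estimate variance components
#' once by REML on the full ORM, and Wald-test every gene with its exact
#' leave-one-out ORM downdate (Woodbury rank-one update of the covariance
#' inverse). Everything is deterministic: two runs on the same inputs give
#' identical tables.
#'
#' @param phenotypes Data frame: `sample_id`, covariates, trait columns.
#' @param counts Gene x sample count matrix (columns matched by sample id).
#' @param trait Trait column to analyze.
#' @param candidates Candidate fixed-effect columns for backward elimination.
#' @param mad_k Phenotype outlier fence in MAD units (default 3.5).
#' @param min_count,min_frac Expressed-gene filter parameters.
#' @param trim_m,trim_a TMM trim fractions.
#' @param log_cpm Standardize log2(CPM+1) instead of CPM.
#' @param vc_mode `"global"` (one REML per trait, exact rank-one downdates
#'   per gene; default) or `"per_gene"` (variance components re-estimated on
#'   every leave-one-out ORM; slow, for verification).
#' @param exclude_target Exclude the tested gene from the polygenic term
#'   (default `TRUE`).
#' @param min_samples Minimum retained samples to attempt the model.
#' @return Object of class `twas_assoc`: a tibble (`gene_id`, `beta`, `se`,
#'   `chisq`, `p`) with attributes `trait`, `n`, `m`, `fixed_effects`, `vc`,
#'   `params`.
#' @export
run_trait <- function(phenotypes, counts, trait,
                      candidates = c("sex", "season"),
                      mad_k = 3.5, min_count = 2, min_frac = 0.30,
                      trim_m = 0.30, trim_a = 0.05, log_cpm = FALSE,
                      vc_mode = c("global", "per_gene"),
                      exclude_target = TRUE, min_samples = 30) {
  vc_mode <- match.arg(vc_mode)
  check_count_matrix(counts)
  if (!"sample_id" %in% names(phenotypes)) {
    abort("`phenotypes` must have a sample_id column")
  }

  qc <- qc_phenotype(phenotypes, trait, covariates = candidates, mad_k = mad_k)
  ids <- intersect(qc$sample_ids, colnames(counts))
  if (length(ids) < min_samples) {
    abort(sprintf(
      "only %d samples retained for trait %s (need >= %d); refusing to fit",
      length(ids), trait, min_samples))
  }
  ph <- as.data.frame(phenotypes)[match(ids, phenotypes$sample_id), ,
                                  drop = FALSE]

  sel <- select_fixed_effects(ph, trait, candidates = candidates)
  X <- build_design(ph, sel$selected)
  y <- ph[[trait]]

  expr <- preprocess_counts(counts[, ids, drop = FALSE],
                            min_count = min_count, min_frac = min_frac,
                            trim_m = trim_m, trim_a = trim_a,
                            log_cpm = log_cpm)
  orm <- compute_orm(expr$standardized)
  genes <- rownames(orm$z)

  if (vc_mode == "global") {
    vc <- reml_fit(y, X, orm$O)
    eig <- vc$eig
    yt <- crossprod(eig$vectors, y)
    Xt <- crossprod(eig$vectors, X)
    Zt <- orm$z %*% eig$vectors  # gene rows rotated
    d <- pmax(eig$values, 0)
    out <- matrix(NA_real_, nrow = length(genes), ncol = 4L)
    for (i in seq_along(genes)) {
      out[i, ] <- gls_gene_rotated(yt, Xt, Zt[i, ], d,
                                   vc$sigma_o2, vc$sigma_e2, m = orm$m,
                                   exclude = exclude_target)
    }
    res <- tibble::tibble(gene_id = genes, beta = out[, 1L], se = out[, 2L],
                          chisq = out[, 3L], p = out[, 4L])
  } else {
    vc <- reml_fit(y, X, orm$O)  # reported summary; tests refit per gene
    res <- dplyr::bind_rows(lapply(genes, function(g) {
      test_gene(y, X, orm, g, vc = NULL, exclude_target = exclude_target)
    }))
  }

  vc_slim <- vc
  vc_slim$eig <- NULL
  structure(res,
            class = c("twas_assoc", class(res)),
            trait = trait, n = length(ids), m = orm$m,
            fixed_effects = sel$selected, vc = vc_slim,
            params = list(mad_k = mad_k, min_count = min_count,
                          min_frac = min_frac, trim_m = trim_m,
                          trim_a = trim_a, log_cpm = log_cpm,
                          vc_mode = vc_mode, exclude_target = exclude_target),
            sample_ids = ids)
}

#' @export
print.twas_assoc <- function(x, ...) {
  vc <- attr(x, "vc")
  cat(sprintf("<twas_assoc> trait %s: %d genes, %d samples; sigma_o2/(sigma_o2+sigma_e2) = %.3f\n",
              attr(x, "trait"), attr(x, "m"), attr(x, "n"),
              vc$sigma_o2 / (vc$sigma_o2 + vc$sigma_e2)))
  NextMethod()
}
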