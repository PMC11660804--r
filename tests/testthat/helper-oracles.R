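# Independent brute-force oracles, coded from the definitions, never from
# the package implementation.

# Trimmed-mean-of-M-values factors: per sample against the reference (the
# sample whose upper-quartile count fraction is closest to the mean), trim
# gene-wise log2 ratios (M) and average abundances (A), precision-weighted
# mean of surviving M values, exponentiated, geometric-mean-1 rescaled.
oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rc / nR))
    A <- (log2(obs / nO) + log2(rc / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - rc) / (nR * rc)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Element-by-element double loop over the similarity definition
# O_jk = (1/m) sum_i (x_ij - mu_i)(x_ik - mu_i) / sigma2_i,
# with population mean/variance across samples.
oracle_orm <- function(x) {
  m <- nrow(x); n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / n
  O <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      O[j, k] <- sum((x[, j] - mu) * (x[, k] - mu) / v) / m
    }
  }
  O
}

# From-scratch dense GLS Wald test of gene `gene_idx`: rebuild the
# leave-one-out ORM explicitly, form V = sigma_o2 * O_(-i) + sigma_e2 * I,
# invert it explicitly, and test the gene's standardized vector appended to
# the fixed design.
oracle_gls <- function(y, X, Z, gene_idx, sigma_o2, sigma_e2,
                       exclude = TRUE) {
  zi <- Z[gene_idx, ]
  Zm <- if (exclude) Z[-gene_idx, , drop = FALSE] else Z
  O <- crossprod(Zm) / nrow(Zm)
  V <- sigma_o2 * O + sigma_e2 * diag(ncol(Zm))
  Vi <- solve(V)
  G <- cbind(X, zi)
  cov <- solve(t(G) %*% Vi %*% G)
  beta <- cov %*% t(G) %*% Vi %*% y
  k <- ncol(G)
  b <- beta[k]; se <- sqrt(cov[k, k]); chisq <- (b / se)^2
  c(beta = b, se = se, chisq = chisq,
    p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up from the definition: sort ascending, take
# cumulative minima of p_(j) * m / j from the largest rank down, cap at 1,
# map back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  stepup <- p[o] * m / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(stepup))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# small random count fixture with dimnames
make_counts <- function(m, n, seed = 1, lambda = 30) {
  set.seed(seed)
  matrix(rpois(m * n, lambda), m, n,
         dimnames = list(sprintf("g%03d", seq_len(m)),
                         sprintf("s%03d", seq_len(n))))
}

# standardized gene x sample matrix (population variance) from Poisson data
make_std <- function(m, n, seed = 1) {
  standardize_expression(make_counts(m, n, seed) + 0)$standardized
}
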