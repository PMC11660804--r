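test_that("TMM factors are 1 for identical samples and for pure depth shifts", {
  counts <- make_counts(100, 2, seed = 1)
  counts[, 2] <- counts[, 1]
  expect_equal(unname(tmm_normalize(counts)), c(1, 1))
  # sample B = 2 x sample A: every M value is 0, no composition bias
  doubled <- cbind(counts[, 1, drop = FALSE], counts[, 1, drop = FALSE] * 2L)
  colnames(doubled) <- c("sA", "sB")
  expect_equal(unname(tmm_normalize(doubled)), c(1, 1))
})

test_that("TMM matches a brute-force trimmed-weighted-mean oracle", {
  set.seed(42)
  counts <- make_counts(200, 4, seed = 42, lambda = 40)
  # inflate 20 genes 8-fold in sample 1: composition bias pushes its factor
  # below 1
  counts[1:20, 1] <- counts[1:20, 1] * 8L
  f <- tmm_normalize(counts)
  expect_lt(f[1], 1)
  expect_equal(unname(f), unname(oracle_tmm(counts)), tolerance = 1e-8)
  expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-10)
  # and on several random matrices without planted bias
  for (s in 2:4) {
    cm <- make_counts(150, 5, seed = s, lambda = 15)
    expect_equal(unname(tmm_normalize(cm)), unname(oracle_tmm(cm)),
                 tolerance = 1e-8)
  }
})

test_that("TMM factors are invariant to global depth scaling of one sample", {
  # M and A values and the trimming are exactly depth-invariant; the
  # precision weights depend on depth, so the invariance is approximate
  counts <- make_counts(120, 4, seed = 7)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  expect_equal(unname(tmm_normalize(counts)), unname(tmm_normalize(scaled)),
               tolerance = 0.01)
})

test_that("CPM columns sum to 1e6 with unit factors and honor the factor", {
  counts <- make_counts(80, 3, seed = 2)
  cpm1 <- cpm_normalize(counts, rep(1, 3))
  expect_equal(unname(colSums(cpm1)), rep(1e6, 3))
  # count 50 in a 1e6-read sample: CPM 50 at factor 1, 40 at factor 1.25
  counts2 <- matrix(c(50L, 999950L), 2, 1,
                    dimnames = list(c("g1", "g2"), "s1"))
  counts2 <- cbind(counts2, s2 = c(50L, 999950L))
  expect_equal(cpm_normalize(counts2, c(1, 1))["g1", "s1"], 50)
  expect_equal(cpm_normalize(counts2, c(1.25, 1))["g1", "s1"], 40)
})

test_that("expressed-gene filter applies the strict >30% rule", {
  counts <- matrix(0L, 3, 10,
                   dimnames = list(c("zero", "three", "four"),
                                   sprintf("s%02d", 1:10)))
  counts["three", 1:3] <- 5L
  counts["four", 1:4] <- 5L
  counts[1, ] <- counts[1, ]  # all-zero gene stays zero
  keep <- filter_expressed(counts, min_count = 2, min_frac = 0.30)
  expect_false(keep[["zero"]])   # never present
  expect_false(keep[["three"]])  # 3 > 3.0 is false: excluded
  expect_true(keep[["four"]])    # 4 > 3.0: included
})

test_that("expressed-gene filter is monotone in both thresholds", {
  counts <- make_counts(100, 20, seed = 9, lambda = 2)
  base <- filter_expressed(counts, 2, 0.30)
  expect_true(all(filter_expressed(counts, 3, 0.30) <= base))
  expect_true(all(filter_expressed(counts, 2, 0.50) <= base))
})

test_that("MAD filter reproduces hand-computed bounds and degenerate cases", {
  v <- c(1:9, 100)
  # median 5.5, unscaled MAD 2.5, fence [-3.25, 14.25]: only 100 removed
  mask <- mad_filter(v, k = 3.5)
  expect_identical(mask, c(rep(TRUE, 9), FALSE))
  expect_true(all(mad_filter(c(5, 5, 5, 5))))  # MAD 0: everything retained
  withNA <- mad_filter(c(1:9, 100, NA))
  expect_true(is.na(withNA[11]))
  expect_error(mad_filter(c(1, NA, NA)), "3 non-missing")
})

test_that("MAD filter is location/scale equivariant", {
  set.seed(4)
  v <- c(rnorm(30), 8, -9, NA)
  base <- mad_filter(v)
  for (ab in list(c(2.5, 3), c(-1.7, 10), c(0.01, -5))) {
    expect_identical(mad_filter(ab[1] * v + ab[2]), base)
  }
})

test_that("standardization matches hand arithmetic and drops constant genes", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  std <- standardize_expression(x)
  # mean 2, population variance 2/3: (1-2)/sqrt(2/3) = -1.224745
  expect_equal(unname(std$standardized[1, ]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(std$gene_means), 2)
  expect_equal(unname(std$gene_vars), 2 / 3)

  y <- rbind(x, g2 = c(7, 7, 7))
  expect_warning(std2 <- standardize_expression(y), "zero-variance")
  expect_identical(std2$dropped, "g2")
  expect_equal(nrow(std2$standardized), 1L)

  # any standardized row: mean 0, population variance 1
  z <- make_std(20, 12, seed = 3)
  expect_equal(unname(rowMeans(z)), rep(0, 20), tolerance = 1e-10)
  expect_equal(unname(rowSums(z^2) / ncol(z)), rep(1, 20), tolerance = 1e-10)
})

test_that("standardized output is invariant to scaling one sample's counts", {
  counts <- make_counts(60, 8, seed = 6, lambda = 25)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 4L
  a <- preprocess_counts(counts)
  b <- preprocess_counts(scaled)
  # exact up to the depth dependence of the TMM precision weights
  expect_equal(a$standardized, b$standardized, tolerance = 0.01)
})

test_that("per-trait phenotype QC removes outliers and incomplete covariates", {
  ph <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    sex = factor(c(rep(c("F", "M"), 5), "M", NA)),
    season = factor(rep(c("S1", "S2", "S3"), 4)),
    y = c(seq(-1, 1, length.out = 10), 50, 0.2))
  qc <- qc_phenotype(ph, "y")
  expect_false("s11" %in% qc$sample_ids)  # gross outlier
  expect_true("s11" %in% qc$removed_outliers)
  # a sample with a missing covariate is dropped even if its value is fine
  expect_false("s12" %in% qc$sample_ids)
  expect_false("s12" %in% qc$removed_outliers)
  expect_setequal(qc$sample_ids, sprintf("s%02d", 1:10))
})
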