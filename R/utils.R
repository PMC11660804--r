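# internal validators and small helpers

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "twasmlm_config_error")
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (integer && x != round(x)) stop_config(field, "must be an integer")
  if (strict_lower && x <= lower) {
    stop_config(field, sprintf("must be > %g", lower))
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%g, %g]", lower, upper))
  }
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(sprintf("duplicated gene id: %s",
                  rownames(counts)[anyDuplicated(rownames(counts))]))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(sprintf("duplicated sample id: %s",
                  colnames(counts)[anyDuplicated(colnames(counts))]))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must contain non-negative integers")
  }
  invisible(counts)
}

# geometric mean of a positive vector
geo_mean <- function(x) exp(mean(log(x)))
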