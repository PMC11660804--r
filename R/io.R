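#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds gene ids.
#' Duplicated gene ids and non-integer cells are errors naming the
#' offending row/column.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, genes x samples, with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("counts file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("counts file %s is empty or has no sample columns", path))
  }
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    abort(sprintf("duplicated gene id in %s: %s", path, dup[1L]))
  }
  mat <- as.matrix(df[-1L])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-integer count in %s at gene %s, sample %s (value '%s')",
      path, gene_ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
      mat[bad[1L, 1L], bad[1L, 2L]]))
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(gene_ids, colnames(mat))
  check_count_matrix(num)
  num
}

#' Write a count matrix to TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param counts Integer matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  check_count_matrix(counts)
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table from TSV
#'
#' Expects columns `sample_id`, covariates (e.g. `sex`, `season`) and one
#' numeric column per trait. Non-numeric trait cells are errors naming the
#' row and column.
#'
#' @param path Path to a TSV file.
#' @param covariates Columns treated as categorical covariates.
#' @return Tibble with `sample_id`, factor covariates, numeric traits.
#' @export
read_phenotypes <- function(path, covariates = c("sex", "season")) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"sample_id" %in% names(df)) {
    abort(sprintf("phenotype file %s lacks a sample_id column", path))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicated sample id in %s: %s", path,
                  df$sample_id[duplicated(df$sample_id)][1L]))
  }
  covariates <- intersect(covariates, names(df))
  traits <- setdiff(names(df), c("sample_id", covariates))
  for (tr in traits) {
    raw <- df[[tr]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "NA" & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric phenotype value in %s at row %d, column %s (value '%s')",
                    path, bad[1L], tr, raw[bad[1L]]))
    }
    df[[tr]] <- num
  }
  for (cc in covariates) df[[cc]] <- factor(df[[cc]])
  df
}

#' Write a phenotype table to TSV
#' @param phenotypes Data frame with `sample_id` first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(tibble::as_tibble(phenotypes), path, progress = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Can also be loaded from a YAML file with [read_run_config()].
#'
#' @param counts Path to a counts TSV, or `NULL` to simulate.
#' @param phenotypes Path to a phenotype TSV, or `NULL` to simulate.
#' @param outdir Output directory.
#' @param traits Traits to analyze (`NULL`: every numeric trait column).
#' @param candidates Candidate fixed effects for backward elimination.
#' @param min_count,min_frac Expressed-gene filter parameters.
#' @param mad_k Phenotype MAD fence.
#' @param trim_m,trim_a TMM trim fractions.
#' @param log_cpm Standardize log2(CPM+1).
#' @param vc_mode Variance-component mode (see [run_trait()]).
#' @param exclude_target Exclude tested gene from the polygenic term.
#' @param alpha FDR threshold.
#' @param top_k Size of the lowest-p candidate list.
#' @param sim A [sim_config()] or parameter list for simulation when no
#'   input paths are given.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts = NULL, phenotypes = NULL, outdir,
                       traits = NULL, candidates = c("sex", "season"),
                       min_count = 2, min_frac = 0.30, mad_k = 3.5,
                       trim_m = 0.30, trim_a = 0.05, log_cpm = FALSE,
                       vc_mode = "global", exclude_target = TRUE,
                       alpha = 0.05, top_k = 20, sim = NULL) {
  if (is.null(counts) != is.null(phenotypes)) {
    abort("provide both `counts` and `phenotypes` paths, or neither (simulate)")
  }
  if (is.null(counts) && is.null(sim)) sim <- sim_config()
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  structure(list(counts = counts, phenotypes = phenotypes, outdir = outdir,
                 traits = traits, candidates = candidates,
                 min_count = min_count, min_frac = min_frac, mad_k = mad_k,
                 trim_m = trim_m, trim_a = trim_a, log_cpm = log_cpm,
                 vc_mode = vc_mode, exclude_target = exclude_target,
                 alpha = alpha, top_k = top_k, sim = sim,
                 version = as.character(utils::packageVersion("twasmlm"))),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  do.call(run_config, cfg)
}

#' Run the end-to-end TWAS pipeline
#'
#' Simulate (when no input paths are configured) or load counts and
#' phenotypes, preprocess, run the per-trait mixed-model association scan,
#' compute inflation diagnostics, FDR-adjust, call candidates, and write
#' every artifact (TSV results, QC report JSON, candidate lists, QQ data,
#' correlation table) plus a manifest with input hashes and parameters into
#' `outdir`. Reruns on identical inputs reproduce identical outputs.
#'
#' @param config A [run_config()] object or path to its YAML form.
#' @return Invisibly, a list with per-trait `twas_assoc` objects,
#'   inflation reports, candidate sets, the correlation table, and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$counts)) {
    sim <- simulate_twas(config$sim)
    counts <- sim$counts
    phenotypes <- sim$phenotypes
    counts_path <- file.path(outdir, "counts.tsv")
    pheno_path <- file.path(outdir, "phenotypes.tsv")
    write_counts(counts, counts_path)
    write_phenotypes(phenotypes, pheno_path)
    # ground truth goes to its own file, never read by the analysis below
    readr::write_tsv(sim$truth$causal, file.path(outdir, "truth_causal.tsv"),
                     progress = FALSE)
    yaml::write_yaml(unclass(config$sim), file.path(outdir, "sim_config.yaml"))
  } else {
    counts_path <- config$counts
    pheno_path <- config$phenotypes
    counts <- withCallingHandlers(
      read_counts(counts_path),
      error = function(e) abort(paste0("[stage counts] ", conditionMessage(e))))
    phenotypes <- tryCatch(
      read_phenotypes(pheno_path, covariates = config$candidates),
      error = function(e) abort(paste0("[stage phenotypes] ", conditionMessage(e))))
  }

  traits <- config$traits
  if (is.null(traits)) {
    traits <- setdiff(
      names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
      "sample_id")
  }

  # QC report on the full count matrix
  keep <- filter_expressed(counts, config$min_count, config$min_frac)
  qc_report <- list(
    n_genes_in = nrow(counts), n_genes_expressed = sum(keep),
    n_samples = ncol(counts),
    per_trait = lapply(setNames(traits, traits), function(tr) {
      qc <- qc_phenotype(phenotypes, tr, covariates = config$candidates,
                         mad_k = config$mad_k)
      list(n_retained = length(qc$sample_ids),
           removed_outliers = as.list(qc$removed_outliers),
           n_missing = qc$n_missing)
    }))
  jsonlite::write_json(qc_report, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  assoc <- list(); inflation <- list(); candidates <- list()
  for (tr in traits) {
    res <- tryCatch(
      run_trait(phenotypes, counts, tr, candidates = config$candidates,
                mad_k = config$mad_k, min_count = config$min_count,
                min_frac = config$min_frac, trim_m = config$trim_m,
                trim_a = config$trim_a, log_cpm = config$log_cpm,
                vc_mode = config$vc_mode,
                exclude_target = config$exclude_target),
      error = function(e) abort(paste0("[stage assoc:", tr, "] ",
                                       conditionMessage(e))))
    infl <- genomic_inflation(res$p[!is.na(res$p)])
    cand <- pick_candidates(res, k = config$top_k, alpha = config$alpha)
    out_tbl <- dplyr::left_join(
      tibble::as_tibble(res),
      dplyr::select(dplyr::bind_rows(cand$significant, cand$top) |>
                      dplyr::distinct(.data$gene_id, .keep_all = TRUE),
                    "gene_id", "p_adj"),
      by = "gene_id")
    adj_all <- bh_adjust(res$p[!is.na(res$p)], alpha = config$alpha)
    out_tbl$p_adj[!is.na(out_tbl$p)] <- adj_all$p_adj
    readr::write_tsv(out_tbl, file.path(outdir, paste0("assoc_", tr, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(infl$qq, file.path(outdir, paste0("qq_", tr, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(cand$top["gene_id"],
                     file.path(outdir, paste0("top", config$top_k, "_", tr, ".txt")),
                     col_names = FALSE, progress = FALSE)
    jsonlite::write_json(
      list(trait = tr, lambda = infl$lambda, ci_low = infl$ci_low,
           ci_high = infl$ci_high, n_tests = infl$n_tests,
           sigma_o2 = attr(res, "vc")$sigma_o2,
           sigma_e2 = attr(res, "vc")$sigma_e2,
           fixed_effects = attr(res, "fixed_effects"),
           n_samples = attr(res, "n"), n_genes = attr(res, "m")),
      file.path(outdir, paste0("model_", tr, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    assoc[[tr]] <- res; inflation[[tr]] <- infl; candidates[[tr]] <- cand
  }

  cors <- if (length(traits) >= 2L) {
    pc <- phenotype_correlations(phenotypes, traits = traits)
    readr::write_tsv(tibble::as_tibble(pc),
                     file.path(outdir, "phenotype_correlations.tsv"),
                     progress = FALSE)
    pc
  } else NULL

  manifest <- list(
    package = "twasmlm", version = config$version,
    inputs = list(counts = unname(tools::md5sum(counts_path)),
                  phenotypes = unname(tools::md5sum(pheno_path))),
    parameters = config[setdiff(names(config),
                                c("counts", "phenotypes", "outdir", "sim"))],
    sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    traits = traits,
    artifacts = sort(setdiff(list.files(outdir), "manifest.json")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(assoc = assoc, inflation = inflation,
                 candidates = candidates, correlations = cors,
                 manifest = manifest_path, outdir = outdir))
}
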