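# Interchange formats: TSV with a header row throughout (the conventional
# tabular shape for 450K manifests and methylation matrices), BED6 for
# regions. Coordinates are 1-based inclusive everywhere except BED export.

#' Read / write a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`, `gene_annot`, `cgi_relation`,
#' `context`, `snp_flag`, `crossreactive_flag`. Rows are sorted by
#' (chrom, pos) on read; write-then-read restores the table exactly.
#'
#' @param path File path.
#' @return `read_manifest()`: the manifest tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      gene_annot = readr::col_character(),
      cgi_relation = readr::col_character(),
      context = readr::col_character(),
      snp_flag = readr::col_logical(),
      crossreactive_flag = readr::col_logical()
    ),
    progress = FALSE
  )
  man$gene_annot[is.na(man$gene_annot)] <- ""
  dup <- which(duplicated(man$probe_id))
  if (length(dup)) {
    abort_bad_arg(sprintf("duplicate probe id '%s' at line %d",
                          man$probe_id[dup[1]], dup[1] + 1L))
  }
  if (anyNA(man$pos)) {
    abort_bad_arg(sprintf("non-numeric position at line %d", which(is.na(man$pos))[1] + 1L))
  }
  parse_gene_annot(man$probe_id, man$gene_annot)  # validates tokens
  bad_cgi <- setdiff(unique(man$cgi_relation), CGI_CATEGORIES)
  if (length(bad_cgi)) {
    abort_bad_arg(paste0("unknown CGI categories: ", paste(bad_cgi, collapse = ", ")))
  }
  man[order(man$chrom, man$pos), ]
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read / write a probe-major numeric matrix
#'
#' TSV whose first column holds row ids (`probe_id` by default) and whose
#' header row holds sample ids.
#'
#' @param path File path.
#' @param id_col Name of the id column (`"probe_id"` or `"gene_id"`).
#' @param sheet Optional sample sheet; if given, the matrix columns must
#'   cover its `sample_id`s.
#' @return `read_matrix()`: a wide tibble.
#' @export
read_matrix <- function(path, id_col = "probe_id", sheet = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    abort_bad_arg(sprintf("matrix file '%s' is empty or has no sample columns", path))
  }
  names(tbl)[1] <- id_col
  num_cols <- setdiff(names(tbl), id_col)
  if (!all(vapply(tbl[num_cols], is.numeric, TRUE))) {
    abort_bad_arg(sprintf("non-numeric values in matrix file '%s'", path))
  }
  if (!is.null(sheet)) {
    missing <- setdiff(sheet$sample_id, num_cols)
    if (length(missing)) {
      abort_bad_arg(paste0("matrix lacks sample column(s): ",
                           paste(missing, collapse = ", ")))
    }
  }
  tbl
}

#' @rdname read_matrix
#' @param tbl Wide tibble to write.
#' @export
write_matrix <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read / write the paired sample sheet (CSV)
#'
#' @param path File path.
#' @return `read_sample_sheet()`: a tibble `sample_id`, `subject_id`,
#'   `phase`, `age`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      subject_id = readr::col_character(),
      phase = readr::col_character(),
      age = readr::col_double()
    ),
    progress = FALSE
  )
  check_paired_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet tibble to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated study bundle to a directory
#'
#' Emits manifest TSV, methylated/unmethylated intensity TSVs, sample sheet
#' CSV, expression counts TSV, and the ground-truth TSV.
#'
#' @param study A [simulate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  write_matrix(study$m, file.path(dir, "intensity_methylated.tsv"))
  write_matrix(study$u, file.path(dir, "intensity_unmethylated.tsv"))
  write_matrix(study$detection_fail, file.path(dir, "detection_fail.tsv"))
  write_sample_sheet(study$sheet, file.path(dir, "samples.csv"))
  write_matrix(study$counts, file.path(dir, "expression_counts.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Run the full paired methylation pipeline
#'
#' Orchestrates the stages end to end on a study bundle: scaling
#' normalization, beta/M computation, staged probe filtering, descriptive
#' profiling (methylation states, sample clustering on the consensus set),
#' the three-method site-level consensus, DMR calling, and cis
#' methylation-expression correlation. All result tables are written as TSV
#' (plus BED6 for DMRs) into `out_dir` together with a plain-text run
#' manifest recording parameters, seed, and per-stage row counts. Identical
#' inputs and seed give byte-identical outputs.
#'
#' @param study A [simulate_study()] bundle, or a list with the same
#'   elements loaded from files.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param alpha FDR threshold for site- and region-level calls.
#' @param max_gap DMR / segment window (bp).
#' @param min_cpgs Minimum CpGs per DMR.
#' @param delta_beta_threshold |delta-beta| filter for correlation pairs.
#' @param n_permutations Permutations per correlation pair.
#' @param detect_frac Detection-failure fraction for the unreliable-probe rule.
#' @param seed Seed for the correlation permutations.
#' @return A list of class `meth_pipeline` with elements `filter_report`,
#'   `states`, `clustering`, `sites`, `dmrs`, `correlations`,
#'   `region_summary`, plus the intermediate `beta`, `m_values`, `diffs`.
#' @export
run_pipeline <- function(study, out_dir = NULL, alpha = 0.05, max_gap = 500,
                         min_cpgs = 3, delta_beta_threshold = 0.1,
                         n_permutations = 1000, detect_frac = 0.05,
                         seed = 1L) {
  norm <- scale_normalize(study$m, study$u)
  beta <- compute_beta(norm$m, norm$u)
  m_values <- compute_m(norm$m, norm$u)
  flt <- filter_probes(beta, m_values, study$manifest,
                       detection_fail = study$detection_fail,
                       detect_frac = detect_frac)
  beta <- flt$beta
  m_values <- flt$m_values

  states <- classify_states(beta, study$sheet)
  diffs <- paired_differences(m_values, beta, study$sheet)
  sites <- test_differential_methylation(diffs, study$manifest, alpha = alpha,
                                         max_gap = max_gap)
  consensus_ids <- sites$probe_id[sites$consensus]
  clustering <- if (length(consensus_ids) >= 2) {
    cluster_samples(beta, consensus_ids, study$sheet)
  } else {
    NULL
  }
  dmrs <- call_dmrs(sites, study$manifest, diffs = diffs, min_cpgs = min_cpgs,
                    max_gap = max_gap, alpha = alpha)

  expr_cpm <- cpm(study$counts)
  pairs <- select_pairs(sites, study$manifest, expr_cpm,
                        delta_beta_threshold = delta_beta_threshold)
  correlations <- if (nrow(pairs) > 0) {
    correlate_pairs(pairs, beta, expr_cpm, study$sheet, alpha = alpha,
                    n_permutations = n_permutations, seed = seed)
  } else {
    NULL
  }
  region_summary <- if (!is.null(correlations)) summarize_regions(correlations) else NULL

  res <- structure(
    list(
      filter_report = flt$report, states = states, clustering = clustering,
      sites = sites, dmrs = dmrs, correlations = correlations,
      region_summary = region_summary, beta = beta, m_values = m_values,
      diffs = diffs,
      params = list(alpha = alpha, max_gap = max_gap, min_cpgs = min_cpgs,
                    delta_beta_threshold = delta_beta_threshold,
                    n_permutations = n_permutations,
                    detect_frac = detect_frac, seed = seed)
    ),
    class = "meth_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  w(tibble::as_tibble(res$filter_report), "filter_report.tsv")
  w(tibble::as_tibble(res$states), "methylation_states.tsv")
  w(tibble::as_tibble(res$sites), "site_results.tsv")
  w(dplyr::mutate(tibble::as_tibble(res$dmrs),
                  probes = purrr::map_chr(.data$probes, paste, collapse = ";")),
    "dmrs.tsv")
  dmrs_to_bed(res$dmrs, file.path(out_dir, "dmrs.bed"))
  if (!is.null(res$correlations)) {
    w(tibble::as_tibble(res$correlations), "correlations.tsv")
    w(res$region_summary, "region_summary.tsv")
  }
  if (!is.null(res$clustering)) w(res$clustering$clusters, "sample_clusters.tsv")
  manifest_lines <- c(
    "methcycle run manifest",
    paste0("package_version: ", as.character(utils::packageVersion("methcycle"))),
    paste0("params: ", paste(names(res$params), unlist(res$params),
                             sep = "=", collapse = " ")),
    paste0("n_probes_tested: ", nrow(res$sites)),
    paste0("n_consensus: ", sum(res$sites$consensus)),
    paste0("n_dmrs: ", nrow(res$dmrs)),
    paste0("n_correlation_pairs: ",
           if (is.null(res$correlations)) 0L else nrow(res$correlations))
  )
  writeLines(manifest_lines, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}

#' @export
print.meth_pipeline <- function(x, ...) {
  cat("<meth_pipeline>\n")
  print(x$filter_report)
  g <- glance(x$sites)
  cat(sprintf("  consensus DMCs: %d / %d probes (%.1f%%); %d up, %d down\n",
              g$n_consensus, g$n_probes, 100 * g$frac_consensus,
              g$n_increased, g$n_decreased))
  cat(sprintf("  DMRs: %d\n", nrow(x$dmrs)))
  if (!is.null(x$correlations)) {
    gc <- glance(x$correlations)
    cat(sprintf("  correlation: %d / %d pairs significant (%.1f%%)\n",
                gc$n_significant, gc$n_pairs, 100 * gc$frac_significant))
  }
  invisible(x)
}
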