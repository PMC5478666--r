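#' Counts per million
#'
#' Library-size-normalised expression: `CPM = count / library size * 1e6`,
#' with the library size taken as each sample's total count.
#'
#' @param counts Wide gene-major tibble (`gene_id` + one column per sample)
#'   of non-negative counts.
#' @return A wide tibble of CPM values, same shape.
#' @export
cpm <- function(counts) {
  m <- tbl_to_mat(counts, id_col = "gene_id")
  if (any(m < 0, na.rm = TRUE)) abort_bad_arg("counts must be non-negative")
  lib <- colSums(m)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    abort_bad_arg(paste0("sample(s) with zero total counts: ",
                         paste(zero, collapse = ", ")))
  }
  mat_to_tbl(sweep(m, 2, lib, `/`) * 1e6, id_col = "gene_id")
}

#' Select cis CpG-gene candidate pairs for correlation
#'
#' Applies the pair-selection filters: the CpG must be consensus-significant
#' with |delta-beta| above the threshold, must carry at least one gene
#' annotation (which excludes open-sea CpGs), and the annotated gene must be
#' present in the expression matrix. A CpG annotated to k genes yields k
#' pairs; for each (CpG, gene) pair the first listed subregion is the
#' record's region.
#'
#' @param sites A `dm_sites` tibble.
#' @param manifest Probe manifest.
#' @param expression Wide gene-major expression tibble (counts or CPM).
#' @param delta_beta_threshold Minimum |delta-beta| (default 0.1).
#' @return A tibble: `probe_id`, `gene_id`, `region`, `region_group`,
#'   `delta_beta`.
#' @export
select_pairs <- function(sites, manifest, expression, delta_beta_threshold = 0.1) {
  if (delta_beta_threshold <= 0) abort_bad_arg("`delta_beta_threshold` must be > 0")
  cand <- sites[sites$consensus & abs(sites$delta_beta) > delta_beta_threshold,
                c("probe_id", "delta_beta")]
  man <- manifest[match(cand$probe_id, manifest$probe_id), ]
  ann <- parse_gene_annot(man$probe_id, man$gene_annot)
  ann <- ann[!duplicated(ann[c("probe_id", "gene_id")]), ]   # first region per gene
  out <- dplyr::inner_join(cand, ann, by = "probe_id")
  out <- out[out$gene_id %in% expression$gene_id, ]
  out$region_group <- region_group(out$region)
  tibble::as_tibble(out[c("probe_id", "gene_id", "region", "region_group", "delta_beta")])
}

# All permutations of 1..n (n small), as an n! x n index matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman correlation with a permutation p-value
#'
#' Spearman's rho between a CpG's beta-values and a gene's CPM values over
#' the same samples, with significance from the permutation null: the
#' expression vector is permuted `B` times and
#' `p = (1 + #(|rho_b| >= |rho_obs|)) / (B + 1)` (two-sided, add-one so p is
#' never 0). When `n! <= B` the full permutation distribution is enumerated
#' instead and `p = #(|rho_b| >= |rho_obs|) / n!`. A constant input vector
#' leaves rho undefined: the record is flagged with `rho = NA`, `p = 1`.
#'
#' @param beta_vector,expr_vector Aligned numeric vectors over the samples.
#' @param n_permutations Number of random permutations B (default 10000).
#' @param seed Optional seed scoped to this call.
#' @return A one-row tibble: `rho`, `p_value`, `exhaustive`.
#' @export
spearman_permutation <- function(beta_vector, expr_vector,
                                 n_permutations = 10000, seed = NULL) {
  if (length(beta_vector) != length(expr_vector)) {
    abort_bad_arg("vectors must have the same length")
  }
  if (n_permutations < 99) abort_bad_arg("`n_permutations` must be >= 99")
  n <- length(beta_vector)
  if (stats::sd(beta_vector) == 0 || stats::sd(expr_vector) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = 1, exhaustive = FALSE))
  }
  rx <- rank(beta_vector)
  ry <- rank(expr_vector)
  rho_obs <- stats::cor(rx, ry)
  exhaustive <- factorial(n) <= n_permutations

  rx_c <- rx - mean(rx)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_perm <- function(perm_mat) as.vector((perm_mat %*% rx_c) / denom)

  if (exhaustive) {
    P <- all_permutations(n)
    R <- matrix(ry[P], nrow(P), n)
    rho_b <- rho_perm(R)
    p <- sum(abs(rho_b) >= abs(rho_obs) - 1e-12) / factorial(n)
  } else {
    p <- with_seed(seed, {
      B <- n_permutations
      P <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
      R <- matrix(ry[t(P)], B, n, byrow = FALSE)
      rho_b <- rho_perm(R)
      (1 + sum(abs(rho_b) >= abs(rho_obs) - 1e-12)) / (B + 1)
    })
  }
  tibble::tibble(rho = rho_obs, p_value = p, exhaustive = exhaustive)
}

#' Correlate candidate CpG-gene pairs
#'
#' Runs [spearman_permutation()] for every selected pair over the samples
#' shared by the methylation and expression matrices (both phases pooled).
#'
#' @param pairs Output of [select_pairs()].
#' @param beta Wide probe-major beta tibble.
#' @param expression_cpm Wide gene-major CPM tibble (see [cpm()]).
#' @param sheet Sample sheet; only its samples present in both matrices are
#'   used.
#' @param alpha Significance level on the permutation p (default 0.05).
#' @param n_permutations,seed Passed to [spearman_permutation()]; pair i uses
#'   `seed + i` so records are independent and reproducible.
#' @return A tibble of class `meth_expr_cor`: the pair columns plus `rho`,
#'   `p_value`, `significant`, `sign`; attribute `"n_samples"`.
#' @export
correlate_pairs <- function(pairs, beta, expression_cpm, sheet, alpha = 0.05,
                            n_permutations = 10000, seed = NULL) {
  b <- tbl_to_mat(beta)
  e <- tbl_to_mat(expression_cpm, id_col = "gene_id")
  samples <- intersect(intersect(colnames(b), colnames(e)), sheet$sample_id)
  if (length(samples) < 3) abort_bad_arg("need at least 3 shared samples")
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    spearman_permutation(
      b[pairs$probe_id[i], samples],
      e[pairs$gene_id[i], samples],
      n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else seed + i
    )
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(pairs, res)
  out$significant <- !is.na(out$rho) & out$p_value < alpha
  out$sign <- dplyr::case_when(
    is.na(out$rho) ~ NA_character_,
    out$rho >= 0 ~ "positive",
    TRUE ~ "negative"
  )
  attr(out, "n_samples") <- length(samples)
  attr(out, "alpha") <- alpha
  class(out) <- c("meth_expr_cor", class(out))
  out
}

#' @method glance meth_expr_cor
#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$significant),
    frac_significant = mean(x$significant),
    n_positive = sum(x$significant & x$sign == "positive"),
    n_negative = sum(x$significant & x$sign == "negative"),
    n_samples = attr(x, "n_samples")
  )
}

#' Region-median aggregation of significant correlations
#'
#' For each gene region containing more than one significantly correlated
#' CpG, the median rho across those CpGs; regions with a single significant
#' CpG pass its rho through.
#'
#' @param records A `meth_expr_cor` tibble.
#' @return A tibble: `gene_id`, `region`, `n_cpgs`, `median_rho`.
#' @export
aggregate_region_median <- function(records) {
  records |>
    dplyr::filter(.data$significant) |>
    dplyr::summarise(
      n_cpgs = dplyr::n(),
      median_rho = stats::median(.data$rho),
      .by = c("gene_id", "region")
    )
}

#' Regional summary of methylation-expression correlations
#'
#' The Table-1-style breakdown: per gene subregion and per super-group
#' (5' region = TSS1500 + TSS200 + 5'UTR + 1stExon; gene body = Body +
#' 3'UTR), the number of tested CpG-gene records, how many correlated
#' significantly (% of tested), and how many of the significant ones were
#' positive / negative (% of significant). Percentages are rounded to one
#' decimal; regions with zero tested records report NA percentages.
#'
#' @param records A `meth_expr_cor` tibble.
#' @return A tibble with `region` (super-group rows first), `n_tested`,
#'   `n_correlated`, `pct_correlated`, `n_positive`, `pct_positive`,
#'   `n_negative`, `pct_negative`, and `level` (`"group"`/`"region"`).
#' @export
summarize_regions <- function(records) {
  one_row <- function(df, label, level) {
    n_tested <- nrow(df)
    n_cor <- sum(df$significant)
    n_pos <- sum(df$significant & df$sign == "positive")
    n_neg <- sum(df$significant & df$sign == "negative")
    tibble::tibble(
      region = label, level = level,
      n_tested = n_tested,
      n_correlated = n_cor,
      pct_correlated = if (n_tested > 0) round(100 * n_cor / n_tested, 1) else NA_real_,
      n_positive = n_pos,
      pct_positive = if (n_cor > 0) round(100 * n_pos / n_cor, 1) else NA_real_,
      n_negative = n_neg,
      pct_negative = if (n_cor > 0) round(100 * n_neg / n_cor, 1) else NA_real_
    )
  }
  groups <- list(
    list(label = "5' region", members = FIVE_PRIME_REGIONS),
    list(label = "Body", members = GENE_BODY_REGIONS)
  )
  purrr::map(groups, function(g) {
    dplyr::bind_rows(
      one_row(records[records$region %in% g$members, ], g$label, "group"),
      purrr::map(g$members, function(r) {
        one_row(records[records$region == r, ], r, "region")
      }) |> purrr::list_rbind()
    )
  }) |> purrr::list_rbind()
}
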