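# Phase means per probe: mean beta over subjects within each phase.
phase_means <- function(beta, sheet) {
  check_paired_sheet(sheet)
  b <- tbl_to_mat(beta)
  missing <- setdiff(sheet$sample_id, colnames(b))
  if (length(missing)) {
    abort_bad_arg(paste0("samples missing from beta matrix: ",
                         paste(missing, collapse = ", ")))
  }
  pre <- rowMeans(b[, sheet$sample_id[sheet$phase == "LH+2"], drop = FALSE])
  rec <- rowMeans(b[, sheet$sample_id[sheet$phase == "LH+8"], drop = FALSE])
  tibble::tibble(probe_id = beta$probe_id, mean_beta_pre = pre, mean_beta_rec = rec)
}

#' Classify probes as hyper-, hypo- or intermediately methylated
#'
#' A probe is consistently hypermethylated when its phase-mean beta exceeds
#' 0.8 in both the pre-receptive and receptive phase, consistently
#' hypomethylated when below 0.2 in both, and intermediate otherwise.
#'
#' @param beta Wide probe-major tibble of beta-values.
#' @param sheet Paired sample sheet.
#' @param hyper,hypo Beta thresholds for the two consistent states.
#' @return A tibble (`probe_id`, `mean_beta_pre`, `mean_beta_rec`, `state`)
#'   of class `meth_states`; [glance()] returns the state fractions.
#' @export
classify_states <- function(beta, sheet, hyper = 0.8, hypo = 0.2) {
  pm <- phase_means(beta, sheet)
  pm$state <- dplyr::case_when(
    pm$mean_beta_pre > hyper & pm$mean_beta_rec > hyper ~ "hypermethylated",
    pm$mean_beta_pre < hypo & pm$mean_beta_rec < hypo ~ "hypomethylated",
    TRUE ~ "intermediate"
  )
  class(pm) <- c("meth_states", class(pm))
  pm
}

#' @method glance meth_states
#' @export
glance.meth_states <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    n_probes = n,
    frac_hyper = mean(x$state == "hypermethylated"),
    frac_hypo = mean(x$state == "hypomethylated"),
    frac_intermediate = mean(x$state == "intermediate")
  )
}

# Collapse each probe's gene annotation to one category on the chosen axis.
# Subregion axis: multiple *distinct* subregions -> "Others"; none -> "Unknown".
probe_categories <- function(manifest, category_axis = c("cgi", "subregion")) {
  category_axis <- match.arg(category_axis)
  if (category_axis == "cgi") {
    return(tibble::tibble(probe_id = manifest$probe_id,
                          category = manifest$cgi_relation))
  }
  ann <- parse_gene_annot(manifest$probe_id, manifest$gene_annot)
  per_probe <- ann |>
    dplyr::distinct(.data$probe_id, .data$region) |>
    dplyr::summarise(
      category = if (dplyr::n() == 1) .data$region[1] else "Others",
      .by = "probe_id"
    )
  tibble::tibble(probe_id = manifest$probe_id) |>
    dplyr::left_join(per_probe, by = "probe_id") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "Unknown"))
}

#' Per-category methylation distributions
#'
#' Groups probes by CpG-island relation or by gene subregion (probes with
#' multiple distinct subregion annotations are pooled into `"Others"`,
#' unannotated probes into `"Unknown"`) and collects per-probe phase-mean
#' beta-values for each category and phase.
#'
#' @inheritParams classify_states
#' @param manifest Probe manifest.
#' @param category_axis `"cgi"` or `"subregion"`.
#' @return A long tibble (`probe_id`, `category`, `phase`, `mean_beta`);
#'   the `"quantiles"` attribute holds a per-category, per-phase summary
#'   (quartiles and mean).
#' @export
distribution_by_category <- function(beta, manifest, sheet,
                                     category_axis = c("cgi", "subregion")) {
  category_axis <- match.arg(category_axis)
  pm <- phase_means(beta, sheet)
  cats <- probe_categories(manifest, category_axis)
  long <- pm |>
    dplyr::inner_join(cats, by = "probe_id") |>
    tidyr::pivot_longer(
      c("mean_beta_pre", "mean_beta_rec"),
      names_to = "phase", values_to = "mean_beta"
    ) |>
    dplyr::mutate(phase = ifelse(.data$phase == "mean_beta_pre", "LH+2", "LH+8"))
  qs <- long |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = stats::quantile(.data$mean_beta, 0.25),
      median = stats::median(.data$mean_beta),
      q75 = stats::quantile(.data$mean_beta, 0.75),
      mean = mean(.data$mean_beta),
      .by = c("category", "phase")
    )
  attr(long, "quantiles") <- qs
  long
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two collections of beta-values (e.g. two genomic categories) by
#' the maximum ECDF gap D and its asymptotic p-value.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A one-row tibble: `statistic` (D), `p_value`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    abort_bad_arg("both samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Chi-square enrichment of significant probes across genomic categories
#'
#' Tests whether the category distribution of a significant probe set differs
#' from the distribution over all analysed probes: a goodness-of-fit
#' chi-square of observed significant-set counts against expected proportions
#' taken from the all-probe set.
#'
#' @param significant_probes,all_probes Character vectors of probe ids
#'   (`significant_probes` must be a subset of `all_probes`).
#' @param manifest Probe manifest.
#' @param category_axis `"cgi"` or `"subregion"`.
#' @return A list with `test` (one-row tibble: `statistic`, `df`, `p_value`)
#'   and `table` (per-category `n_significant`, `frac_significant`, `n_all`,
#'   `frac_all`).
#' @export
chisq_category_enrichment <- function(significant_probes, all_probes, manifest,
                                      category_axis = c("cgi", "subregion")) {
  category_axis <- match.arg(category_axis)
  if (!all(significant_probes %in% all_probes)) {
    abort_bad_arg("significant probes must be a subset of all probes")
  }
  cats <- probe_categories(manifest, category_axis)
  cat_all <- cats$category[match(all_probes, cats$probe_id)]
  cat_sig <- cats$category[match(significant_probes, cats$probe_id)]
  levels <- sort(unique(cat_all))
  if (length(levels) < 2) abort_bad_arg("need at least 2 categories")
  n_all <- table(factor(cat_all, levels))
  n_sig <- table(factor(cat_sig, levels))
  if (any(n_all == 0 & n_sig > 0)) {
    abort_bad_arg("category with zero expected but non-zero observed count; collapse categories")
  }
  props <- as.numeric(n_all) / length(cat_all)
  ct <- suppressWarnings(stats::chisq.test(as.numeric(n_sig), p = props))
  list(
    test = tibble::tibble(
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = ct$p.value
    ),
    table = tibble::tibble(
      category = levels,
      n_significant = as.integer(n_sig),
      frac_significant = as.numeric(n_sig) / max(1L, length(cat_sig)),
      n_all = as.integer(n_all),
      frac_all = props
    )
  )
}

#' Hierarchical clustering of samples on a probe subset
#'
#' Clusters samples by their beta-values over a chosen probe subset
#' (typically the consensus differentially methylated CpGs), reports the
#' two-branch cut, and how well it agrees with the phase labels.
#'
#' @inheritParams classify_states
#' @param probe_subset Character vector of probe ids (length >= 2).
#' @param dist_method,linkage Distance and agglomeration method (defaults:
#'   Euclidean, average linkage).
#' @return A list with `hclust` (the tree), `clusters` (tibble `sample_id`,
#'   `phase`, `branch`), and `agreement`: the fraction of samples correctly
#'   separated under the best branch-to-phase assignment.
#' @export
cluster_samples <- function(beta, probe_subset, sheet,
                            dist_method = "euclidean", linkage = "average") {
  if (length(probe_subset) < 2) abort_bad_arg("need at least 2 probes to cluster on")
  b <- tbl_to_mat(beta)
  missing <- setdiff(probe_subset, rownames(b))
  if (length(missing)) {
    abort_bad_arg(paste0("probes not in beta matrix: ",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (ncol(b) < 3) abort_bad_arg("need at least 3 samples to cluster")
  x <- t(b[probe_subset, , drop = FALSE])
  hc <- stats::hclust(stats::dist(x, method = dist_method), method = linkage)
  branch <- stats::cutree(hc, k = 2)
  cl <- tibble::tibble(
    sample_id = names(branch),
    phase = sheet$phase[match(names(branch), sheet$sample_id)],
    branch = unname(branch)
  )
  n_pre_b1 <- sum(cl$phase == "LH+2" & cl$branch == 1)
  n_pre_b2 <- sum(cl$phase == "LH+2" & cl$branch == 2)
  n_rec_b1 <- sum(cl$phase == "LH+8" & cl$branch == 1)
  n_rec_b2 <- sum(cl$phase == "LH+8" & cl$branch == 2)
  agreement <- max(n_pre_b1 + n_rec_b2, n_pre_b2 + n_rec_b1) / nrow(cl)
  list(hclust = hc, clusters = cl, agreement = agreement)
}
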