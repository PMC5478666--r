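#' Compute beta-values from probe intensities
#'
#' Uses Illumina's offset formula `beta = m / (m + u + 100)`, where `m` is the
#' methylated and `u` the unmethylated probe intensity. The +100 offset keeps
#' beta defined at zero total intensity and shrinks it slightly toward zero
#' for dim probes; beta always lies in `[0, 1)`.
#'
#' @param m,u Wide probe-major tibbles (`probe_id` + one column per sample)
#'   of methylated / unmethylated intensities, aligned on probes and samples.
#' @return A wide tibble of beta-values with the same shape.
#' @export
compute_beta <- function(m, u) {
  check_same_probes(m, u, "methylated", "unmethylated")
  mm <- tbl_to_mat(m)
  uu <- tbl_to_mat(u)
  if (any(mm < 0, na.rm = TRUE) || any(uu < 0, na.rm = TRUE)) {
    abort_bad_arg("intensities must be non-negative")
  }
  mat_to_tbl(mm / (mm + uu + 100))
}

#' Compute M-values from probe intensities
#'
#' `M = log2((m + offset) / (u + offset))`, the log2 ratio of methylated to
#' unmethylated intensity. M-values are the variance-stabilised scale used
#' for differential testing. The small offset (default 1, not the beta
#' formula's 100) keeps M finite at zero intensities without materially
#' biasing it for well-measured probes.
#'
#' @inheritParams compute_beta
#' @param offset Positive intensity offset added to both channels.
#' @return A wide tibble of M-values.
#' @export
compute_m <- function(m, u, offset = 1) {
  check_same_probes(m, u, "methylated", "unmethylated")
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0) {
    abort_bad_arg("`offset` must be a single positive number")
  }
  mm <- tbl_to_mat(m)
  uu <- tbl_to_mat(u)
  if (any(mm < 0, na.rm = TRUE) || any(uu < 0, na.rm = TRUE)) {
    abort_bad_arg("intensities must be non-negative")
  }
  mat_to_tbl(log2((mm + offset) / (uu + offset)))
}

#' Staged probe filtering with per-rule accounting
#'
#' Applies the two-stage probe-exclusion protocol used for 450K data:
#' stage 1 removes SNP-overlapping probes, cross-reactive probes, and probes
#' with unreliable detection (failure in more than `detect_frac` of samples);
#' stage 2 removes sex-chromosome (chrX/chrY) and non-CpG-context probes.
#' Rules are applied in that order and each probe is counted once, at the
#' first rule that removes it, so the report always balances:
#' `initial - sum(removed) = remaining`.
#'
#' @param beta,m_values Wide probe-major tibbles to filter (aligned).
#' @param manifest Probe manifest covering every probe in the matrices.
#' @param detection_fail Optional wide logical tibble of per-probe-per-sample
#'   detection failures; `NULL` skips the unreliability rule.
#' @param detect_frac Failure fraction above which a probe is unreliable.
#' @return A list with the filtered `beta` and `m_values` tibbles and
#'   `report`, a tibble of `rule`, `n_removed`, `n_remaining` rows (in
#'   application order) whose class `filter_report` pretty-prints the
#'   accounting.
#' @export
filter_probes <- function(beta, m_values, manifest, detection_fail = NULL,
                          detect_frac = 0.05) {
  check_same_probes(beta, m_values, "beta", "M-value")
  missing <- setdiff(beta$probe_id, manifest$probe_id)
  if (length(missing)) {
    abort_bad_arg(paste0(
      "probes absent from manifest: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5)
    ))
  }
  man <- manifest[match(beta$probe_id, manifest$probe_id), ]

  unreliable <- rep(FALSE, nrow(beta))
  if (!is.null(detection_fail)) {
    check_same_probes(beta, detection_fail, "beta", "detection flag")
    fl <- tbl_to_mat(detection_fail)
    unreliable <- rowMeans(fl) > detect_frac
  }

  rules <- list(
    snp_overlap = man$snp_flag,
    cross_reactive = man$crossreactive_flag,
    unreliable = unreliable,
    sex_chromosome = man$chrom %in% c("chrX", "chrY"),
    non_cpg_context = !is.null(man$context) & man$context != "CG"
  )

  removed_by <- rep(NA_character_, nrow(beta))
  for (rule in names(rules)) {
    hit <- rules[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  keep <- is.na(removed_by)

  n_removed <- vapply(names(rules), function(r) sum(removed_by == r, na.rm = TRUE), 0L)
  report <- tibble::tibble(
    rule = names(rules),
    n_removed = unname(n_removed),
    n_remaining = nrow(beta) - cumsum(unname(n_removed))
  )
  class(report) <- c("filter_report", class(report))
  attr(report, "n_initial") <- nrow(beta)

  list(beta = beta[keep, ], m_values = m_values[keep, ], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Probe filtering: %d probes in\n", attr(x, "n_initial")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  - %-16s removed %6d -> %d remain\n",
                x$rule[i], x$n_removed[i], x$n_remaining[i]))
  }
  invisible(x)
}

#' Per-sample scaling normalization of intensities
#'
#' Rescales each sample's methylated and unmethylated intensities by a single
#' scalar so that its mean total intensity (m + u over the retained probes)
#' equals the across-sample grand mean. Within-sample m:u ratios are
#' unchanged, so M-values are essentially untouched and beta-values shift
#' only through the +100 offset.
#'
#' @inheritParams compute_beta
#' @return A list with rescaled `m` and `u` tibbles and `scalars`, a named
#'   numeric vector of per-sample factors.
#' @export
scale_normalize <- function(m, u) {
  check_same_probes(m, u, "methylated", "unmethylated")
  mm <- tbl_to_mat(m)
  uu <- tbl_to_mat(u)
  if (ncol(mm) < 2) abort_bad_arg("scaling normalization needs at least 2 samples")
  tot <- colMeans(mm + uu)
  zero <- names(tot)[tot == 0]
  if (length(zero)) {
    abort_bad_arg(paste0("sample(s) with all-zero intensities: ",
                         paste(zero, collapse = ", ")))
  }
  scalars <- mean(tot) / tot
  list(
    m = mat_to_tbl(sweep(mm, 2, scalars, `*`)),
    u = mat_to_tbl(sweep(uu, 2, scalars, `*`)),
    scalars = scalars
  )
}
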