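#' Per-subject paired differences
#'
#' Realises the paired design: for every probe and subject, the receptive
#' minus pre-receptive difference on the M scale (`d`) and on the beta scale
#' (`dbeta`). Subject ages are attached (with a mean-centred copy) for the
#' age-adjusted tests.
#'
#' @param m_values,beta Wide probe-major tibbles of M- and beta-values over
#'   the same probes and samples.
#' @param sheet Paired sample sheet (every subject one sample per phase).
#' @return An object of class `paired_diffs`: a list with matrices `d` and
#'   `dbeta` (probes x subjects), `probe_id`, `subjects`, `age`, `age_c`.
#' @export
paired_differences <- function(m_values, beta, sheet) {
  check_same_probes(m_values, beta, "M-value", "beta")
  check_paired_sheet(sheet)
  mm <- tbl_to_mat(m_values)
  bb <- tbl_to_mat(beta)
  subjects <- unique(sheet$subject_id)
  pre_id <- sheet$sample_id[match(paste(subjects, "LH+2"),
                                  paste(sheet$subject_id, sheet$phase))]
  rec_id <- sheet$sample_id[match(paste(subjects, "LH+8"),
                                  paste(sheet$subject_id, sheet$phase))]
  missing <- setdiff(c(pre_id, rec_id), colnames(mm))
  if (length(missing)) {
    abort_bad_arg(paste0("samples missing from matrices: ",
                         paste(missing, collapse = ", ")))
  }
  d <- mm[, rec_id, drop = FALSE] - mm[, pre_id, drop = FALSE]
  dbeta <- bb[, rec_id, drop = FALSE] - bb[, pre_id, drop = FALSE]
  colnames(d) <- colnames(dbeta) <- subjects
  age <- sheet$age[match(subjects, sheet$subject_id)]
  structure(
    list(
      d = d, dbeta = dbeta, probe_id = m_values$probe_id,
      subjects = subjects, age = age, age_c = age - mean(age)
    ),
    class = "paired_diffs"
  )
}

#' @export
print.paired_diffs <- function(x, ...) {
  cat(sprintf("<paired_diffs> %d probes x %d subjects (receptive - pre-receptive)\n",
              nrow(x$d), length(x$subjects)))
  invisible(x)
}

#' @method tidy paired_diffs
#' @export
tidy.paired_diffs <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(x$probe_id, length(x$subjects)),
    subject_id = rep(x$subjects, each = nrow(x$d)),
    d_m = as.vector(x$d),
    d_beta = as.vector(x$dbeta)
  )
}

# Newton solve of trigamma(x) = y, vectorised (used by the variance
# moment-matching below).
trigamma_inverse <- function(y) {
  out <- numeric(length(y))
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  mid <- which(y <= 1e7 & y >= 1e-6)
  if (length(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# Moment-matching of the scaled inverse-chi-square variance prior (d0, s0^2)
# from per-probe residual variances s2 on d residual df: the log of
# s2 ~ s0^2 F(d, d0) has moments involving di/trigamma functions; solve them.
estimate_moderation <- function(s2, df_resid) {
  z <- log(s2)
  z <- z[is.finite(z)]
  if (length(z) < 2) abort_bad_arg("need >= 2 finite residual variances to moderate")
  e_bias <- digamma(df_resid / 2) - log(df_resid / 2)
  evar <- stats::var(z)
  excess <- evar - trigamma(df_resid / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) - e_bias)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(mean(z) - e_bias + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Closed-form per-probe regression of the difference vectors on centred age:
# returns intercepts, residual variances and the unscaled variance of the
# intercept estimate. X is shared across probes so one solve suffices.
fit_diff_model <- function(d, age_c, adjust_age = TRUE) {
  n <- ncol(d)
  X <- if (adjust_age && stats::sd(age_c) > 0) cbind(1, age_c) else cbind(rep(1, n))
  p <- ncol(X)
  if (n - p < 1) abort_bad_arg("zero residual degrees of freedom")
  XtXi <- solve(crossprod(X))
  B <- d %*% X %*% XtXi                  # probes x p coefficients
  R <- d - B %*% t(X)
  s2 <- unname(rowSums(R^2)) / (n - p)
  list(b0 = unname(B[, 1]), s2 = s2, v0 = XtXi[1, 1], df_resid = n - p)
}

#' Empirical-Bayes moderated paired test
#'
#' For each probe, regresses the per-subject paired differences on centred
#' age and tests the intercept (the age-adjusted mean difference). Residual
#' variances are shrunk toward a pooled prior: the prior degrees of freedom
#' `d0` and prior variance `s0sq` are estimated by moment-matching on the log
#' residual variances (a scaled inverse-chi-square prior, as in
#' empirical-Bayes moderated t testing), giving
#' `s_tilde^2 = (d0 * s0sq + df * s2) / (d0 + df)` and a t statistic on
#' `d0 + df` degrees of freedom. With `d0 = 0` the ordinary t statistic is
#' recovered; as `d0 -> Inf` all probes share the prior variance.
#'
#' @param diffs A [paired_differences()] object.
#' @param adjust_age Regress out centred age before testing? (default TRUE)
#' @param moderation Optional list `(d0, s0sq)` to override the estimated
#'   prior (useful for the limiting cases).
#' @return A tibble (`probe_id`, `estimate`, `statistic`, `p_value`) of class
#'   `moderated_test`; [glance()] reports `d0`, `s0sq`, and the total df.
#' @export
moderated_paired_test <- function(diffs, adjust_age = TRUE, moderation = NULL) {
  n <- ncol(diffs$d)
  if (n < 3) abort_bad_arg("need at least 3 subjects")
  fit <- fit_diff_model(diffs$d, diffs$age_c, adjust_age)
  mod <- if (is.null(moderation)) estimate_moderation(fit$s2, fit$df_resid) else moderation
  d0 <- mod$d0
  if (is.infinite(d0)) {
    s2_tilde <- rep(mod$s0sq, length(fit$s2))
    df_total <- Inf
  } else {
    s2_tilde <- (d0 * mod$s0sq + fit$df_resid * fit$s2) / (d0 + fit$df_resid)
    df_total <- d0 + fit$df_resid
  }
  tstat <- fit$b0 / sqrt(s2_tilde * fit$v0)
  p <- 2 * stats::pt(-abs(tstat), df_total)
  out <- tibble::tibble(
    probe_id = diffs$probe_id,
    estimate = fit$b0,
    statistic = tstat,
    p_value = p
  )
  attr(out, "moderation") <- list(d0 = d0, s0sq = mod$s0sq, df_total = df_total)
  class(out) <- c("moderated_test", class(out))
  out
}

#' @method glance moderated_test
#' @export
glance.moderated_test <- function(x, ...) {
  m <- attr(x, "moderation")
  tibble::tibble(d0 = m$d0, s0sq = m$s0sq, df_total = m$df_total,
                 n_probes = nrow(x))
}

# Exact or approximate two-sided signed-rank p for one difference vector.
# Zeros dropped (Wilcoxon's convention); midranks for tied |d|.
signed_rank_one <- function(d, exact_max_n = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(c(W = NA_real_, p = 1, n_used = 0, exact = NA))
  }
  a <- abs(d)
  r <- rank(a)
  W <- sum(r[d > 0])
  ties <- anyDuplicated(a) > 0
  if (!ties && n <= exact_max_n) {
    p_low <- stats::psignrank(W, n)
    p_high <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  c(W = W, p = p, n_used = n, exact = exact)
}

#' Paired Wilcoxon signed-rank test per probe
#'
#' A distribution-free companion to the moderated test for data whose paired
#' differences deviate from normality. Zero differences are dropped; the
#' statistic is the sum of positive-difference ranks of |d|. The two-sided
#' p-value is exact (from the signed-rank null distribution) when the number
#' of non-zero differences is at most `exact_max_n` and |d| has no ties,
#' otherwise a normal approximation with tie and continuity corrections is
#' used. All differences zero gives p = 1 by convention, flagged via
#' `n_used = 0`. This arm is unadjusted for age: a rank test admits no
#' covariate.
#'
#' @param diffs A [paired_differences()] object.
#' @param exact_max_n Largest n for which the exact null is used.
#' @return A tibble: `probe_id`, `statistic` (W), `p_value`, `n_used`,
#'   `exact`.
#' @export
wilcoxon_paired_test <- function(diffs, exact_max_n = 25L) {
  if (ncol(diffs$d) < 1) abort_bad_arg("need at least 1 subject")
  res <- t(apply(diffs$d, 1, signed_rank_one, exact_max_n = exact_max_n))
  tibble::tibble(
    probe_id = diffs$probe_id,
    statistic = unname(res[, "W"]),
    p_value = unname(res[, "p"]),
    n_used = as.integer(unname(res[, "n_used"])),
    exact = as.logical(unname(res[, "exact"]))
  )
}

# Conditional null distribution of the segment t statistic for a k-CpG
# segment, given the same-sign selection event of the greedy segmentation.
# Sign-flip symmetry: conditioning k iid mean-zero probe vectors on all
# row-means sharing a sign is equivalent to flipping each row to a positive
# mean (then the overall sign is a fair coin, irrelevant for |t|), so the
# null is sampled exactly with no rejection step.
segment_null_abs_t <- function(k, age_c, adjust_age, n_null, seed) {
  n <- length(age_c)
  with_seed(seed, {
    d <- matrix(stats::rnorm(n_null * k * n), n_null * k, n)
    flip <- sign(rowMeans(d))
    d <- d * flip
    grp <- rep(seq_len(n_null), each = k)
    x <- rowsum(d, grp) / k
    fit <- fit_diff_model(x, age_c, adjust_age)
    abs(fit$b0 / sqrt(fit$s2 * fit$v0))
  })
}

#' Spatial segment test
#'
#' Exploits the spatial correlation of nearby CpGs: consecutive probes are
#' greedily grouped into segments while the inter-CpG gap stays within
#' `max_gap` and the per-probe mean difference keeps the same sign; each
#' segment's per-subject mean difference is then tested with the
#' (unmoderated) age-adjusted paired model, and the segment p-value is
#' assigned to every member probe. Singletons are their own segments.
#'
#' Because multi-CpG segments are selected for having same-signed member
#' effects, the plain t reference distribution is anti-conservative for
#' them. Their p-values are therefore computed against the conditional null
#' of the t statistic given that selection event, sampled exactly via
#' per-probe sign-flip symmetry (`n_null` draws per segment size, fixed
#' internal seeds, so results are deterministic). Singleton segments use the
#' analytic t distribution. The unconditional t p-value is kept in
#' `p_unadjusted`.
#'
#' @param diffs A [paired_differences()] object.
#' @param manifest Probe manifest sorted by (chrom, pos) and covering all
#'   probes in `diffs`.
#' @param max_gap Maximum inter-CpG gap (bp) within a segment.
#' @param adjust_age Regress out centred age? (default TRUE)
#' @param n_null Conditional-null draws per distinct segment size.
#' @return A tibble (`probe_id`, `segment_id`, `statistic`, `p_value`,
#'   `p_unadjusted`); the `"segments"` attribute tabulates each segment
#'   (chrom, start, end, n_cpgs, statistic, p_value, p_unadjusted).
#' @export
segment_test <- function(diffs, manifest, max_gap = 500, adjust_age = TRUE,
                         n_null = 20000) {
  man <- manifest[manifest$probe_id %in% diffs$probe_id, ]
  if (!identical(order(man$chrom, man$pos), seq_len(nrow(man)))) {
    abort_bad_arg("manifest must be sorted by (chrom, pos)")
  }
  if (!setequal(man$probe_id, diffs$probe_id)) {
    abort_bad_arg("manifest must cover exactly the probes in `diffs`")
  }
  ord <- match(man$probe_id, diffs$probe_id)
  d <- diffs$d[ord, , drop = FALSE]
  mean_d <- rowMeans(d)
  sgn <- sign(mean_d)
  new_chrom <- man$chrom != dplyr::lag(man$chrom, default = "")
  gap_break <- c(TRUE, diff(man$pos) > max_gap)
  sign_break <- c(TRUE, sgn[-1] != sgn[-length(sgn)])
  seg_id <- cumsum(new_chrom | gap_break | sign_break)

  seg_d <- rowsum(d, seg_id, reorder = TRUE) / as.vector(table(seg_id))
  fit <- fit_diff_model(seg_d, diffs$age_c, adjust_age)
  tstat <- fit$b0 / sqrt(fit$s2 * fit$v0)
  p_unadj <- 2 * stats::pt(-abs(tstat), fit$df_resid)

  n_cpgs <- as.integer(table(seg_id))
  p <- p_unadj
  for (k in sort(unique(n_cpgs[n_cpgs > 1]))) {
    null_t <- segment_null_abs_t(k, diffs$age_c, adjust_age, n_null,
                                 seed = 86420L + k)
    idx <- which(n_cpgs == k)
    # one-pass empirical p: (1 + #null >= |t|) / (n_null + 1)
    rk <- findInterval(abs(tstat[idx]) - 1e-12, sort(null_t))
    p[idx] <- (1 + n_null - rk) / (n_null + 1)
  }

  seg_tab <- tibble::tibble(
    segment_id = as.integer(rownames(seg_d)),
    chrom = man$chrom[!duplicated(seg_id)],
    start = as.integer(tapply(man$pos, seg_id, min)),
    end = as.integer(tapply(man$pos, seg_id, max)),
    n_cpgs = n_cpgs,
    statistic = tstat,
    p_value = p,
    p_unadjusted = p_unadj
  )
  out <- tibble::tibble(
    probe_id = man$probe_id,
    segment_id = seg_id,
    statistic = tstat[match(seg_id, seg_tab$segment_id)],
    p_value = p[match(seg_id, seg_tab$segment_id)],
    p_unadjusted = p_unadj[match(seg_id, seg_tab$segment_id)]
  )
  # restore the input probe order
  out <- out[match(diffs$probe_id, out$probe_id), ]
  attr(out, "segments") <- seg_tab
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone and capped at 1, in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort_bad_arg("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Three-method consensus of differentially methylated CpGs
#'
#' Intersects the probes called significant (q < alpha) by the moderated
#' paired test, the Wilcoxon signed-rank test, and the segment test. The
#' effect size is the mean paired beta-difference (delta-beta, receptive
#' minus pre-receptive) and the direction its sign.
#'
#' @param moderated,wilcoxon,segment Result tibbles from the three tests,
#'   each with `probe_id`, `statistic`, `p_value` and a `q_value` column
#'   (add one with [bh_fdr()]; for the segment test apply BH across unique
#'   segments and propagate — [test_differential_methylation()] does this).
#' @param diffs The [paired_differences()] object (for delta-beta).
#' @param alpha FDR threshold (default 0.05).
#' @return A tibble of class `dm_sites` with per-probe `delta_beta`,
#'   per-method statistic/p/q and significance flags, `consensus`, and
#'   `direction` (`"increased"`/`"decreased"`); [glance()] summarises counts.
#' @export
consensus_sites <- function(moderated, wilcoxon, segment, diffs, alpha = 0.05) {
  ids <- diffs$probe_id
  for (tab in list(moderated, wilcoxon, segment)) {
    if (!identical(tab$probe_id, ids)) {
      abort_bad_arg("probe ids of the three method tables must align with `diffs`")
    }
    if (!"q_value" %in% names(tab)) {
      abort_bad_arg("each method table needs a `q_value` column (see bh_fdr())")
    }
  }
  delta_beta <- rowMeans(diffs$dbeta)
  out <- tibble::tibble(
    probe_id = ids,
    delta_beta = delta_beta,
    stat_moderated = moderated$statistic,
    p_moderated = moderated$p_value,
    q_moderated = moderated$q_value,
    stat_wilcoxon = wilcoxon$statistic,
    p_wilcoxon = wilcoxon$p_value,
    q_wilcoxon = wilcoxon$q_value,
    stat_segment = segment$statistic,
    p_segment = segment$p_value,
    q_segment = segment$q_value
  )
  out$sig_moderated <- !is.na(out$q_moderated) & out$q_moderated < alpha
  out$sig_wilcoxon <- !is.na(out$q_wilcoxon) & out$q_wilcoxon < alpha
  out$sig_segment <- !is.na(out$q_segment) & out$q_segment < alpha
  out$consensus <- out$sig_moderated & out$sig_wilcoxon & out$sig_segment
  out$direction <- ifelse(out$delta_beta >= 0, "increased", "decreased")
  attr(out, "alpha") <- alpha
  class(out) <- c("dm_sites", class(out))
  out
}

#' @method glance dm_sites
#' @export
glance.dm_sites <- function(x, ...) {
  cons <- x[x$consensus, ]
  tibble::tibble(
    n_probes = nrow(x),
    n_sig_moderated = sum(x$sig_moderated),
    n_sig_wilcoxon = sum(x$sig_wilcoxon),
    n_sig_segment = sum(x$sig_segment),
    n_consensus = nrow(cons),
    frac_consensus = nrow(cons) / max(1L, nrow(x)),
    n_increased = sum(cons$direction == "increased"),
    n_decreased = sum(cons$direction == "decreased"),
    mean_delta_beta_increased = mean(cons$delta_beta[cons$direction == "increased"]),
    mean_delta_beta_decreased = mean(cons$delta_beta[cons$direction == "decreased"])
  )
}

#' Run the full three-method site-level analysis
#'
#' Convenience wrapper: runs the moderated, Wilcoxon and segment tests,
#' applies BH per method (across probes for the first two; across unique
#' segments, then propagated to members, for the segment test), and
#' intersects at `alpha`.
#'
#' @inheritParams segment_test
#' @param alpha FDR threshold for each method and the consensus.
#' @return A `dm_sites` tibble (see [consensus_sites()]).
#' @export
test_differential_methylation <- function(diffs, manifest, alpha = 0.05,
                                          max_gap = 500, adjust_age = TRUE) {
  mod <- moderated_paired_test(diffs, adjust_age = adjust_age)
  mod$q_value <- bh_fdr(mod$p_value)
  wil <- wilcoxon_paired_test(diffs)
  wil$q_value <- bh_fdr(wil$p_value)
  seg <- segment_test(diffs, manifest, max_gap = max_gap, adjust_age = adjust_age)
  seg_tab <- attr(seg, "segments")
  seg_tab$q_value <- bh_fdr(seg_tab$p_value)
  seg$q_value <- seg_tab$q_value[match(seg$segment_id, seg_tab$segment_id)]
  consensus_sites(mod, wil, seg, diffs, alpha = alpha)
}
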