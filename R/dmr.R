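#' Call differentially methylated regions (DMRs)
#'
#' Scans each chromosome's position-ordered significant CpGs (q < alpha; by
#' default the three-method consensus flag) and forms maximal runs in which
#' every adjacent pair of significant CpGs lies within `max_gap` bp and
#' shares the direction of methylation change. Runs with at least `min_cpgs`
#' members are emitted as DMRs. The default rule (`window_rule = "gap"`)
#' bounds the gap between consecutive CpGs; `window_rule = "span"` instead
#' bounds the total span of the run. The region p-value retests each region's
#' per-subject mean difference with the age-adjusted paired model; region
#' q-values are BH-adjusted across the emitted DMRs.
#'
#' @param sites A `dm_sites` tibble from [test_differential_methylation()]
#'   or [consensus_sites()].
#' @param manifest Probe manifest (chrom, pos, gene annotations).
#' @param diffs The [paired_differences()] object (for region-level testing);
#'   `NULL` skips region p-values.
#' @param min_cpgs Minimum CpGs per DMR (default 3).
#' @param max_gap Window size in bp (default 500).
#' @param alpha Site FDR threshold (default 0.05).
#' @param use Which significance call defines "differentially methylated":
#'   `"consensus"` (default) or one of `"moderated"`, `"wilcoxon"`,
#'   `"segment"` (that method's q < alpha).
#' @param window_rule `"gap"` (adjacent gap <= max_gap) or `"span"` (total
#'   span <= max_gap).
#' @return A tibble of class `dmr_set`: `dmr_id`, `chrom`, `start`, `end`
#'   (1-based inclusive CpG span), `n_cpgs`, `direction`, `probes`
#'   (list-column), `genes` (semicolon-delimited), `p_value`, `q_value`.
#' @export
call_dmrs <- function(sites, manifest, diffs = NULL, min_cpgs = 3,
                      max_gap = 500, alpha = 0.05,
                      use = c("consensus", "moderated", "wilcoxon", "segment"),
                      window_rule = c("gap", "span")) {
  use <- match.arg(use)
  window_rule <- match.arg(window_rule)
  if (min_cpgs < 2) abort_bad_arg("`min_cpgs` must be >= 2")
  if (max_gap <= 0) abort_bad_arg("`max_gap` must be positive")
  missing <- setdiff(sites$probe_id, manifest$probe_id)
  if (length(missing)) {
    abort_bad_arg(paste0("probes absent from manifest: ",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }

  sig_flag <- switch(use,
    consensus = sites$consensus,
    moderated = sites$q_moderated < alpha,
    wilcoxon = sites$q_wilcoxon < alpha,
    segment = sites$q_segment < alpha
  )
  sig <- sites[sig_flag, c("probe_id", "direction")]
  man <- manifest[match(sig$probe_id, manifest$probe_id), c("chrom", "pos", "gene_annot")]
  sig <- dplyr::bind_cols(sig, man)
  sig <- sig[order(sig$chrom, sig$pos), ]

  empty <- tibble::tibble(
    dmr_id = character(), chrom = character(), start = integer(),
    end = integer(), n_cpgs = integer(), direction = character(),
    probes = list(), genes = character(), p_value = double(), q_value = double()
  )
  if (nrow(sig) == 0) {
    class(empty) <- c("dmr_set", class(empty))
    return(empty)
  }

  # run construction among significant CpGs only
  if (window_rule == "gap") {
    brk <- c(TRUE,
             sig$chrom[-1] != sig$chrom[-nrow(sig)] |
               diff(sig$pos) > max_gap |
               sig$direction[-1] != sig$direction[-nrow(sig)])
    run_id <- cumsum(brk)
  } else {
    # span rule: greedy left-anchored runs with total span <= max_gap
    run_id <- integer(nrow(sig))
    cur <- 1L
    anchor <- 1L
    run_id[1] <- 1L
    for (i in seq_len(nrow(sig))[-1]) {
      same <- sig$chrom[i] == sig$chrom[anchor] &&
        sig$direction[i] == sig$direction[anchor] &&
        (sig$pos[i] - sig$pos[anchor]) <= max_gap
      if (!same) {
        cur <- cur + 1L
        anchor <- i
      }
      run_id[i] <- cur
    }
  }

  regions <- sig |>
    dplyr::mutate(run_id = run_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      n_cpgs = dplyr::n(),
      direction = .data$direction[1],
      probes = list(.data$probe_id),
      genes = paste(
        sort(unique(parse_gene_annot(.data$probe_id, .data$gene_annot)$gene_id)),
        collapse = ";"
      ),
      .by = "run_id"
    ) |>
    dplyr::filter(.data$n_cpgs >= min_cpgs) |>
    dplyr::select(-"run_id")

  if (nrow(regions) == 0) {
    class(empty) <- c("dmr_set", class(empty))
    return(empty)
  }

  regions$dmr_id <- sprintf("DMR%04d", seq_len(nrow(regions)))
  regions$p_value <- NA_real_
  regions$q_value <- NA_real_
  if (!is.null(diffs)) {
    reg_d <- do.call(rbind, lapply(regions$probes, function(pr) {
      colMeans(diffs$d[match(pr, diffs$probe_id), , drop = FALSE])
    }))
    fit <- fit_diff_model(reg_d, diffs$age_c, adjust_age = TRUE)
    tstat <- fit$b0 / sqrt(fit$s2 * fit$v0)
    regions$p_value <- 2 * stats::pt(-abs(tstat), fit$df_resid)
    regions$q_value <- bh_fdr(regions$p_value)
  }
  out <- regions[c("dmr_id", "chrom", "start", "end", "n_cpgs", "direction",
                   "probes", "genes", "p_value", "q_value")]
  class(out) <- c("dmr_set", class(out))
  out
}

#' @method glance dmr_set
#' @export
glance.dmr_set <- function(x, ...) {
  tibble::tibble(
    n_dmrs = nrow(x),
    n_increased = sum(x$direction == "increased"),
    n_decreased = sum(x$direction == "decreased"),
    n_cpgs_in_dmrs = sum(x$n_cpgs),
    n_genes = length(unique(unlist(strsplit(x$genes[x$genes != ""], ";"))))
  )
}

#' Export DMRs as BED6 records
#'
#' Converts the 1-based inclusive CpG spans to BED's 0-based half-open
#' convention. The score is `-10 * log10(region q)` capped at 1000.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param path Optional file to write (a `#` header comment plus one line per
#'   DMR); `NULL` returns the records only.
#' @return A tibble of BED6 columns (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`), invisibly if written to `path`.
#' @export
dmrs_to_bed <- function(dmrs, path = NULL) {
  score <- ifelse(
    is.na(dmrs$q_value), 0,
    pmin(1000, round(-10 * log10(pmax(dmrs$q_value, 1e-100))))
  )
  bed <- tibble::tibble(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end = dmrs$end,
    name = dmrs$dmr_id,
    score = as.integer(score),
    strand = "."
  )
  if (!is.null(path)) {
    header <- "# BED6: differentially methylated regions (score = -10*log10(q), capped at 1000)"
    lines <- c(header, do.call(paste, c(bed, sep = "\t")))
    writeLines(lines, path)
    return(invisible(bed))
  }
  bed
}
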