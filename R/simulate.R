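#' Configuration for the synthetic paired methylation study
#'
#' Bundles every tunable of the synthetic-data generator emulating a paired
#' pre-receptive (LH+2) / receptive (LH+8) endometrial methylation study on a
#' 450K-style array: a cohort of subjects sampled at both time-points,
#' clustered CpG positions, a tri-modal baseline methylation landscape, a
#' small minority of truly differential CpGs with mostly-increasing small
#' effects, spatially contiguous planted differentially methylated blocks, and
#' gene expression coupled (in both directions, depending on gene region) to
#' methylation at designated CpG-gene pairs.
#'
#' @param n_subjects Number of subjects; each contributes one sample per phase.
#' @param age_range Numeric length-2, subject age range in years.
#' @param n_probes Total number of CpG probes on the simulated array.
#' @param n_chromosomes Number of autosomes probes are spread over (sex
#'   chromosomes are added on top via `frac_sexchr`).
#' @param cluster_size_mean Mean number of CpGs per positional cluster.
#' @param cluster_gap Length-2 range (bp) of within-cluster inter-CpG spacing.
#' @param between_gap Length-2 range (bp) of gaps between clusters.
#' @param landscape_weights Named proportions for the (hypo, intermediate,
#'   hyper) baseline methylation modes; must sum to 1.
#' @param frac_dmc Proportion of probes that are truly differentially
#'   methylated between phases.
#' @param frac_increase Proportion of true DMCs whose methylation increases in
#'   the receptive phase.
#' @param effect_delta_beta Length-2 range of |delta-beta| for planted effects.
#' @param sigma_m Within-subject (residual) noise SD on the M scale.
#' @param subject_sd Between-subject random-effect SD on the M scale.
#' @param n_dmr_blocks Number of planted contiguous differential blocks (>= 3
#'   consecutive CpGs spanning <= 500 bp, same effect sign).
#' @param frac_corr_pairs Proportion of eligible CpG-gene pairs given a
#'   planted expression coupling.
#' @param coupling_strength Target Spearman correlation magnitude for coupled
#'   pairs, in (0, 1].
#' @param corr_sign_by_region Named probabilities of a *positive* coupling for
#'   probes in the `"gene body"` vs `"5' region"` groups.
#' @param libsize_range Length-2 range of expression library sizes (total
#'   counts per sample).
#' @param expr_noise_sd SD of log-scale expression noise for uncoupled genes
#'   and for the residual part of coupled genes.
#' @param frac_snp,frac_crossreactive Proportions of probes flagged as
#'   SNP-overlapping / cross-reactive in the manifest.
#' @param frac_sexchr Proportion of probes placed on chrX/chrY.
#' @param frac_noncpg Proportion of probes in non-CpG (CH) context.
#' @param frac_detect_fail Proportion of probes with frequent detection
#'   failures across samples.
#' @param mean_total_intensity Median of the log-normal total intensity
#'   (m + u) distribution, in arbitrary scanner units.
#' @param seed Integer RNG seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 17,
                       age_range = c(24, 35),
                       n_probes = 20000,
                       n_chromosomes = 5,
                       cluster_size_mean = 6,
                       cluster_gap = c(20, 180),
                       between_gap = c(2000, 50000),
                       landscape_weights = c(hypo = 0.33, intermediate = 0.48, hyper = 0.19),
                       frac_dmc = 0.05,
                       frac_increase = 0.845,
                       effect_delta_beta = c(0.05, 0.25),
                       sigma_m = 0.3,
                       subject_sd = 0.3,
                       n_dmr_blocks = 30,
                       frac_corr_pairs = 0.3,
                       coupling_strength = 0.8,
                       corr_sign_by_region = c("gene body" = 0.56, "5' region" = 0.44),
                       libsize_range = c(1e6, 2e6),
                       expr_noise_sd = 0.5,
                       frac_snp = 0.01,
                       frac_crossreactive = 0.06,
                       frac_sexchr = 0.02,
                       frac_noncpg = 0.005,
                       frac_detect_fail = 0.003,
                       mean_total_intensity = 3000,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
      abort_bad_arg(sprintf("`%s` must be a single integer >= %d", name, min))
    }
  }
  chk_count(cfg$n_subjects, "n_subjects", 2)
  chk_count(cfg$n_probes, "n_probes", 0)
  chk_count(cfg$n_chromosomes, "n_chromosomes", 1)
  chk_count(cfg$n_dmr_blocks, "n_dmr_blocks", 0)
  props <- c(
    frac_dmc = cfg$frac_dmc, frac_increase = cfg$frac_increase,
    frac_corr_pairs = cfg$frac_corr_pairs, frac_snp = cfg$frac_snp,
    frac_crossreactive = cfg$frac_crossreactive, frac_sexchr = cfg$frac_sexchr,
    frac_noncpg = cfg$frac_noncpg, frac_detect_fail = cfg$frac_detect_fail
  )
  bad <- names(props)[!is.finite(props) | props < 0 | props > 1]
  if (length(bad)) {
    abort_bad_arg(paste0("proportions outside [0,1]: ", paste(bad, collapse = ", ")))
  }
  if (length(cfg$landscape_weights) != 3 || any(cfg$landscape_weights < 0) ||
      abs(sum(cfg$landscape_weights) - 1) > 1e-8) {
    abort_bad_arg("`landscape_weights` must be 3 non-negative proportions summing to 1")
  }
  if (cfg$coupling_strength <= 0 || cfg$coupling_strength > 1) {
    abort_bad_arg("`coupling_strength` must be in (0, 1]")
  }
  if (cfg$n_probes > 0 && cfg$n_probes < 3 * cfg$n_dmr_blocks) {
    abort_bad_arg("`n_probes` must be at least 3 * `n_dmr_blocks`")
  }
  if (cfg$sigma_m < 0 || cfg$subject_sd < 0 || cfg$expr_noise_sd < 0) {
    abort_bad_arg("noise standard deviations must be non-negative")
  }
  if (diff(cfg$age_range) < 0 || diff(cfg$libsize_range) < 0) {
    abort_bad_arg("`age_range` and `libsize_range` must be non-decreasing")
  }
  invisible(cfg)
}

#' Generate a synthetic probe manifest
#'
#' Lays CpG probes along chromosomes in positional clusters (mimicking the
#' clustering of array probes around CpG islands and gene regions), assigns
#' each probe one CpG-island-relation category, zero or more `gene:subregion`
#' annotations, and SNP-overlap / cross-reactivity flags. Open-sea clusters
#' are mostly unannotated, so the open-sea exclusion downstream coincides with
#' the absence of gene annotation.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `probe_id`, `chrom`, `pos` (1-based bp),
#'   `gene_annot` (semicolon-delimited `gene:subregion` tokens, `""` if none),
#'   `cgi_relation`, `context` (`"CG"`/`"CH"`), `snp_flag`,
#'   `crossreactive_flag`; sorted by (chrom, pos), positions strictly
#'   increasing within chromosome.
#' @export
generate_manifest <- function(config) {
  validate_sim_config(config)
  n <- config$n_probes
  empty <- tibble::tibble(
    probe_id = character(), chrom = character(), pos = integer(),
    gene_annot = character(), cgi_relation = character(), context = character(),
    snp_flag = logical(), crossreactive_flag = logical()
  )
  if (n == 0) return(empty)

  with_seed(config$seed + 101L, {
    n_sex <- round(config$frac_sexchr * n)
    chroms <- c(paste0("chr", seq_len(config$n_chromosomes)),
                if (n_sex > 0) c("chrX", "chrY"))
    # spread probes over chromosomes; sex chromosomes get the sex fraction
    n_auto <- n - n_sex
    alloc <- c(
      table(factor(sample.int(config$n_chromosomes, n_auto, replace = TRUE),
                   levels = seq_len(config$n_chromosomes))),
      if (n_sex > 0) {
        nx <- ceiling(n_sex / 2)
        c(nx, n_sex - nx)
      }
    )
    names(alloc) <- chroms
    alloc <- alloc[alloc > 0]

    gene_counter <- 0L
    per_chrom <- purrr::imap(alloc, function(n_c, chrom) {
      # carve the chromosome's probes into clusters
      sizes <- integer()
      while (sum(sizes) < n_c) {
        sizes <- c(sizes, 1L + stats::rpois(1, config$cluster_size_mean - 1))
      }
      if (sum(sizes) > n_c) sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_c)
      sizes <- sizes[sizes > 0]
      n_clusters <- length(sizes)
      cluster_id <- rep(seq_len(n_clusters), sizes)

      gaps_within <- round(stats::runif(n_c, config$cluster_gap[1], config$cluster_gap[2]))
      gaps_between <- round(stats::runif(n_clusters, config$between_gap[1], config$between_gap[2]))
      # first probe of a cluster jumps by the between-cluster gap
      first_of_cluster <- !duplicated(cluster_id)
      step <- ifelse(first_of_cluster, gaps_between[cluster_id], gaps_within)
      pos <- 10000L + cumsum(step)

      cgi <- sample(CGI_CATEGORIES, n_clusters, replace = TRUE,
                    prob = c(0.30, 0.12, 0.12, 0.06, 0.06, 0.34))
      zone <- ifelse(stats::runif(n_clusters) < 0.5, "promoter", "body")
      gene <- sprintf("GENE%05d", gene_counter + seq_len(n_clusters))
      gene_counter <<- gene_counter + n_clusters

      annot <- purrr::map_chr(seq_len(n_c), function(i) {
        cl <- cluster_id[i]
        if (cgi[cl] == "OpenSea" && stats::runif(1) < 0.8) return("")
        region <- if (zone[cl] == "promoter") {
          sample(FIVE_PRIME_REGIONS, 1, prob = c(0.35, 0.25, 0.25, 0.15))
        } else {
          sample(GENE_BODY_REGIONS, 1, prob = c(0.8, 0.2))
        }
        tok <- paste0(gene[cl], ":", region)
        # a minority of probes carry a second annotation (neighbouring gene)
        if (stats::runif(1) < 0.05) {
          other <- if (cl < n_clusters) cl + 1L else max(cl - 1L, 1L)
          region2 <- sample(SUBREGIONS, 1)
          tok <- paste0(tok, ";", gene[other], ":", region2)
        }
        tok
      })

      tibble::tibble(
        chrom = chrom, pos = as.integer(pos), gene_annot = annot,
        cgi_relation = cgi[cluster_id]
      )
    })

    out <- dplyr::bind_rows(per_chrom)
    out$probe_id <- sprintf("cg%08d", seq_len(nrow(out)))
    out$context <- ifelse(stats::runif(nrow(out)) < config$frac_noncpg, "CH", "CG")
    out$snp_flag <- stats::runif(nrow(out)) < config$frac_snp
    out$crossreactive_flag <- stats::runif(nrow(out)) < config$frac_crossreactive
    out <- out[order(out$chrom, out$pos), ]
    if (anyDuplicated(paste(out$chrom, out$pos))) {
      abort_bad_arg("duplicate (chrom, pos) generated; this is a bug")
    }
    tibble::as_tibble(out[c("probe_id", "chrom", "pos", "gene_annot",
                            "cgi_relation", "context", "snp_flag",
                            "crossreactive_flag")])
  })
}

#' Generate the paired sample sheet
#'
#' Each subject contributes exactly two samples: one pre-receptive (LH+2) and
#' one receptive (LH+8), with a single age drawn per subject.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sample_id`, `subject_id`, `phase`
#'   (`"LH+2"`/`"LH+8"`) and `age` (years).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed + 202L, {
    subjects <- sprintf("S%02d", seq_len(config$n_subjects))
    ages <- round(stats::runif(config$n_subjects, config$age_range[1], config$age_range[2]))
    tibble::tibble(
      sample_id = paste0(rep(subjects, each = 2), "_", rep(c("LH2", "LH8"), config$n_subjects)),
      subject_id = rep(subjects, each = 2),
      phase = rep(c("LH+2", "LH+8"), config$n_subjects),
      age = rep(ages, each = 2)
    )
  })
}

# Choose planted DMR blocks: runs of >= 3 consecutive probes on one chromosome
# spanning <= 500 bp, non-overlapping. Returns a list of integer index vectors
# into the manifest rows.
place_dmr_blocks <- function(manifest, n_blocks, max_span = 500L) {
  if (n_blocks == 0) return(list())
  taken <- rep(FALSE, nrow(manifest))
  blocks <- vector("list", n_blocks)
  # candidate starts: position i such that probes i..i+2 are same-chrom,
  # within max_span, and free
  for (b in seq_len(n_blocks)) {
    ok <- which(
      seq_len(nrow(manifest)) <= nrow(manifest) - 2 &
        manifest$chrom == dplyr::lead(manifest$chrom, 2) &
        (dplyr::lead(manifest$pos, 2) - manifest$pos) <= max_span &
        !taken & !dplyr::lead(taken, 2) & !dplyr::lead(taken, 1)
    )
    if (!length(ok)) {
      abort_bad_arg(sprintf(
        "cannot place planted DMR block %d: too few clustered probes remain", b
      ))
    }
    start <- sample(ok, 1)
    idx <- start:(start + 2)
    # greedily extend while staying within max_span of the block start
    j <- start + 3
    while (j <= nrow(manifest) && manifest$chrom[j] == manifest$chrom[start] &&
           manifest$pos[j] - manifest$pos[start] <= max_span && !taken[j] &&
           length(idx) < 6) {
      idx <- c(idx, j)
      j <- j + 1
    }
    taken[idx] <- TRUE
    blocks[[b]] <- idx
  }
  blocks
}

#' Simulate paired methylation intensities and the ground-truth table
#'
#' Baseline probe levels are drawn on the M (log2-odds) scale from a tri-modal
#' landscape (hypo / intermediate / hypermethylated). For each sample,
#' `M = mu + subject effect + phase * delta + noise`, where `delta` is chosen
#' on the M scale so that the induced beta-scale difference matches the
#' planted `true_delta_beta`. Planted DMR blocks give the same-signed effect
#' to >= 3 consecutive probes spanning <= 500 bp. Methylated/unmethylated
#' intensities are emitted by drawing a log-normal total intensity `T` and
#' splitting `m = expit(M) * T`, `u = T - m`, so that downstream beta
#' (computed with the +100 offset) and M values approximate the generative
#' values, offset bias included.
#'
#' @param manifest Output of [generate_manifest()].
#' @param sheet Output of [generate_cohort()].
#' @param config A [sim_config()].
#' @return A list with wide tibbles `m` and `u` (probes x samples),
#'   `detection_fail` (logical, same shape), and `truth` (per-probe
#'   `is_dmc`, `true_delta_beta`, `dmr_block_id`, `coupled_gene`,
#'   `coupling_sign`, `coupling_strength`).
#' @export
simulate_methylation <- function(manifest, sheet, config) {
  validate_sim_config(config)
  check_paired_sheet(sheet)
  n_p <- nrow(manifest)
  n_s <- nrow(sheet)

  with_seed(config$seed + 303L, {
    w <- config$landscape_weights
    mode <- sample(c("hypo", "intermediate", "hyper"), n_p, replace = TRUE, prob = w)
    mu <- numeric(n_p)
    mu[mode == "hypo"] <- rnorm_trunc(sum(mode == "hypo"), -3.3, 0.35, hi = -2.3)
    mu[mode == "hyper"] <- rnorm_trunc(sum(mode == "hyper"), 3.3, 0.35, lo = 2.3)
    mu[mode == "intermediate"] <- stats::runif(sum(mode == "intermediate"), -1.7, 1.7)

    # plant effects: DMR blocks first, then scattered single DMCs
    blocks <- place_dmr_blocks(manifest, config$n_dmr_blocks)
    block_id <- rep(NA_integer_, n_p)
    for (b in seq_along(blocks)) block_id[blocks[[b]]] <- b
    n_dmc_total <- round(config$frac_dmc * n_p)
    in_block <- which(!is.na(block_id))
    n_single <- max(0L, n_dmc_total - length(in_block))
    singles <- sample(setdiff(seq_len(n_p), in_block), n_single)
    is_dmc <- rep(FALSE, n_p)
    is_dmc[c(in_block, singles)] <- TRUE

    # signs: one per block (shared), one per scattered DMC
    sign_of_block <- ifelse(stats::runif(length(blocks)) < config$frac_increase, 1, -1)
    eff_sign <- rep(0, n_p)
    eff_sign[in_block] <- sign_of_block[block_id[in_block]]
    eff_sign[singles] <- ifelse(stats::runif(n_single) < config$frac_increase, 1, -1)

    target <- rep(0, n_p)
    idx <- which(is_dmc)
    target[idx] <- eff_sign[idx] *
      stats::runif(length(idx), config$effect_delta_beta[1], config$effect_delta_beta[2])

    # convert the beta-scale target into an M-scale shift; clamp so the
    # receptive-phase beta stays inside (0.02, 0.98)
    beta0 <- expit2(mu)
    beta1 <- pmin(pmax(beta0 + target, 0.02), 0.98)
    target <- beta1 - beta0
    target[!is_dmc] <- 0
    beta1[!is_dmc] <- beta0[!is_dmc]
    delta_m <- ifelse(is_dmc, logit2(beta1) - mu, 0)

    subjects <- unique(sheet$subject_id)
    b_subj <- matrix(stats::rnorm(n_p * length(subjects), 0, config$subject_sd),
                     n_p, length(subjects), dimnames = list(NULL, subjects))
    is_rec <- as.numeric(sheet$phase == "LH+8")
    eps <- matrix(stats::rnorm(n_p * n_s, 0, config$sigma_m), n_p, n_s)
    m_val <- mu + b_subj[, sheet$subject_id, drop = FALSE] +
      outer(delta_m, is_rec) + eps

    total <- matrix(stats::rlnorm(n_p * n_s, log(config$mean_total_intensity), 0.25), n_p, n_s)
    meth <- expit2(m_val) * total
    unmeth <- total - meth
    dimnames(meth) <- dimnames(unmeth) <- list(manifest$probe_id, sheet$sample_id)

    fail <- matrix(FALSE, n_p, n_s, dimnames = dimnames(meth))
    bad_probes <- which(stats::runif(n_p) < config$frac_detect_fail)
    if (length(bad_probes)) {
      fail[bad_probes, ] <- matrix(
        stats::runif(length(bad_probes) * n_s) < 0.5, length(bad_probes), n_s
      )
    }

    truth <- tibble::tibble(
      probe_id = manifest$probe_id,
      is_dmc = is_dmc,
      true_delta_beta = target,
      dmr_block_id = block_id,
      coupled_gene = NA_character_,
      coupling_sign = NA_real_,
      coupling_strength = NA_real_
    )

    # plant expression couplings among gene-annotated DMCs (one probe per gene)
    ann <- parse_gene_annot(manifest$probe_id, manifest$gene_annot)
    eligible <- ann[ann$probe_id %in% manifest$probe_id[is_dmc], ]
    eligible <- eligible[!duplicated(eligible$gene_id), ]
    eligible <- eligible[!duplicated(eligible$probe_id), ]
    pick <- stats::runif(nrow(eligible)) < config$frac_corr_pairs
    chosen <- eligible[pick, ]
    if (nrow(chosen)) {
      grp <- region_group(chosen$region)
      p_pos <- unname(config$corr_sign_by_region[grp])
      p_pos[is.na(p_pos)] <- 0.5
      sgn <- ifelse(stats::runif(nrow(chosen)) < p_pos, 1, -1)
      i <- match(chosen$probe_id, truth$probe_id)
      truth$coupled_gene[i] <- chosen$gene_id
      truth$coupling_sign[i] <- sgn
      truth$coupling_strength[i] <- config$coupling_strength
    }

    list(
      m = mat_to_tbl(meth), u = mat_to_tbl(unmeth),
      detection_fail = mat_to_tbl(fail * 1) |>
        dplyr::mutate(dplyr::across(-probe_id, as.logical)),
      truth = truth
    )
  })
}

#' Simulate an expression count matrix coupled to methylation
#'
#' For coupled CpG-gene pairs, log relative expression follows
#' `a + k * (sign * r * z(M) + sqrt(1 - r^2) * e)`, a Gaussian-copula
#' construction whose latent Pearson correlation `r = 2 sin(pi * strength / 6)`
#' yields a Spearman correlation of approximately `strength` against the
#' probe's M-values. Uncoupled genes vary independently of methylation.
#' Counts are the library-size-scaled relative expression rounded to integers
#' (so with all noise at zero, a coupled gene's CPM is strictly monotone in
#' the probe's methylation and the sample Spearman correlation is exactly
#' `sign * 1` when `coupling_strength = 1`).
#'
#' @param manifest,sheet,config As in [simulate_methylation()].
#' @param truth The `truth` tibble from [simulate_methylation()] (carries the
#'   planted couplings).
#' @param intensities The list returned by [simulate_methylation()]; used to
#'   derive per-sample M-values for the coupled probes.
#' @return A wide tibble of integer counts, genes x samples.
#' @export
simulate_expression <- function(manifest, sheet, truth, config, intensities) {
  validate_sim_config(config)
  if (config$coupling_strength <= 0 || config$coupling_strength > 1) {
    abort_bad_arg("`coupling_strength` must be in (0, 1]")
  }
  ann <- parse_gene_annot(manifest$probe_id, manifest$gene_annot)
  genes <- sort(unique(ann$gene_id))
  coupled <- truth[!is.na(truth$coupled_gene), ]
  if (nrow(coupled) && !all(coupled$coupled_gene %in% genes)) {
    abort_bad_arg("coupled genes in `truth` must be annotated in the manifest")
  }
  n_g <- length(genes)
  n_s <- nrow(sheet)

  m_mat <- log2((tbl_to_mat(intensities$m) + 1) / (tbl_to_mat(intensities$u) + 1))

  with_seed(config$seed + 404L, {
    a <- stats::rnorm(n_g, 0, 1.5)                      # log relative abundance
    log_r <- matrix(rep(a, n_s), n_g, n_s)
    noise <- matrix(stats::rnorm(n_g * n_s, 0, config$expr_noise_sd), n_g, n_s)
    log_r <- log_r + noise

    if (nrow(coupled)) {
      r_lat <- 2 * sin(pi * coupled$coupling_strength / 6)
      for (k in seq_len(nrow(coupled))) {
        g <- match(coupled$coupled_gene[k], genes)
        mv <- m_mat[coupled$probe_id[k], sheet$sample_id]
        z <- as.numeric(scale(mv))
        resid <- stats::rnorm(n_s)
        lat <- coupled$coupling_sign[k] * r_lat[k] * z + sqrt(1 - r_lat[k]^2) * resid
        log_r[g, ] <- a[g] + lat                        # coupling replaces the free noise
      }
    }

    rel <- exp(log_r)
    lib <- stats::runif(n_s, config$libsize_range[1], config$libsize_range[2])
    counts <- round(sweep(rel, 2, lib / colSums(rel), `*`))
    dimnames(counts) <- list(genes, sheet$sample_id)
    mat_to_tbl(counts, id_col = "gene_id")
  })
}

#' Simulate a complete paired methylation study
#'
#' Runs all four generators under one seed and returns the bundle the
#' pipeline consumes: manifest, sample sheet, intensity matrices, detection
#' flags, ground truth, and an expression count matrix.
#'
#' @param config A [sim_config()].
#' @return A list of class `meth_study` with elements `config`, `manifest`,
#'   `sheet`, `m`, `u`, `detection_fail`, `truth`, `counts`.
#' @export
simulate_study <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  sheet <- generate_cohort(config)
  sim <- simulate_methylation(manifest, sheet, config)
  counts <- simulate_expression(manifest, sheet, sim$truth, config, sim)
  structure(
    list(
      config = config, manifest = manifest, sheet = sheet,
      m = sim$m, u = sim$u, detection_fail = sim$detection_fail,
      truth = sim$truth, counts = counts
    ),
    class = "meth_study"
  )
}

#' @export
print.meth_study <- function(x, ...) {
  cat("<meth_study>\n")
  cat(sprintf("  %d probes x %d samples (%d subjects, 2 phases)\n",
              nrow(x$manifest), nrow(x$sheet), nrow(x$sheet) / 2))
  cat(sprintf("  %d true DMCs (%d in %d planted blocks), %d coupled genes\n",
              sum(x$truth$is_dmc), sum(!is.na(x$truth$dmr_block_id)),
              length(unique(stats::na.omit(x$truth$dmr_block_id))),
              sum(!is.na(x$truth$coupled_gene))))
  cat(sprintf("  %d genes in expression matrix\n", nrow(x$counts)))
  invisible(x)
}
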