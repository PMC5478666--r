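# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no data files.

# Wide probe-major tibble from a plain matrix.
make_tbl <- function(mat, ids = sprintf("cg%03d", seq_len(nrow(mat))),
                     samples = sprintf("smp%02d", seq_len(ncol(mat))),
                     id_col = "probe_id") {
  dimnames(mat) <- list(ids, samples)
  tibble::as_tibble(mat, rownames = id_col)
}

# Minimal paired sheet for n subjects; sample ids "S01_LH2", "S01_LH8", ...
make_sheet <- function(n_subjects, ages = seq(24, length.out = n_subjects)) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  tibble::tibble(
    sample_id = paste0(rep(subjects, each = 2), "_", rep(c("LH2", "LH8"), n_subjects)),
    subject_id = rep(subjects, each = 2),
    phase = rep(c("LH+2", "LH+8"), n_subjects),
    age = rep(ages, each = 2)
  )
}

# Hand-rolled manifest: one row per probe.
make_manifest <- function(probe_id, chrom, pos, gene_annot = "",
                          cgi_relation = "OpenSea", context = "CG",
                          snp_flag = FALSE, crossreactive_flag = FALSE) {
  tibble::tibble(
    probe_id = probe_id, chrom = chrom, pos = as.integer(pos),
    gene_annot = rep_len(gene_annot, length(probe_id)),
    cgi_relation = rep_len(cgi_relation, length(probe_id)),
    context = rep_len(context, length(probe_id)),
    snp_flag = rep_len(snp_flag, length(probe_id)),
    crossreactive_flag = rep_len(crossreactive_flag, length(probe_id))
  )
}

# A paired_diffs object straight from a difference matrix (probes x subjects),
# bypassing the intensity layer, for unit tests of the test statistics.
make_diffs <- function(d, ages = seq(24, length.out = ncol(d)),
                       dbeta = d / 10) {
  d <- as.matrix(d)
  probe_id <- sprintf("cg%03d", seq_len(nrow(d)))
  subjects <- sprintf("S%02d", seq_len(ncol(d)))
  dimnames(d) <- list(NULL, subjects)
  dbeta <- as.matrix(dbeta)
  dimnames(dbeta) <- dimnames(d)
  structure(
    list(d = d, dbeta = dbeta, probe_id = probe_id, subjects = subjects,
         age = ages, age_c = ages - mean(ages)),
    class = "paired_diffs"
  )
}

# ---- independent oracles -------------------------------------------------

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(W_all - mu) >= abs(W_obs - mu))
  list(W = W_obs, p = p)
}

# Brute-force two-sample KS D: maximum ECDF gap over all pooled points.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Brute-force DMR enumeration: all maximal runs of significant CpGs with
# adjacent gaps <= max_gap and a shared direction, length >= min_cpgs.
# `df` has columns chrom, pos, direction (significant CpGs only), sorted.
oracle_dmrs <- function(df, min_cpgs = 3, max_gap = 500) {
  df <- df[order(df$chrom, df$pos), ]
  out <- list()
  n <- nrow(df)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n &&
           df$chrom[j + 1] == df$chrom[j] &&
           df$pos[j + 1] - df$pos[j] <= max_gap &&
           df$direction[j + 1] == df$direction[i]) {
      j <- j + 1
    }
    if (j - i + 1 >= min_cpgs) {
      out[[length(out) + 1]] <- data.frame(
        chrom = df$chrom[i], start = df$pos[i], end = df$pos[j],
        n_cpgs = j - i + 1, direction = df$direction[i]
      )
    }
    i <- j + 1
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character()))
  }
  do.call(rbind, out)
}

# Hand BH step-up: q_i = min_{j >= i} p_(j) * n / j, in input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}
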