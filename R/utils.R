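# Internal helpers shared across modules.

# Wide probe-major tibble (probe_id + one column per sample) <-> numeric matrix.
tbl_to_mat <- function(tbl, id_col = "probe_id") {
  stopifnot(is.data.frame(tbl), id_col %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[id_col]]
  m
}

mat_to_tbl <- function(m, id_col = "probe_id") {
  tibble::as_tibble(m, rownames = id_col)
}

# logit/expit on the log2 scale used for M-values: M = log2(beta/(1-beta)).
logit2 <- function(beta) log2(beta / (1 - beta))
expit2 <- function(m) 1 / (1 + 2^(-m))

# Truncated normal via inverse-CDF (exact, no rejection loop).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

abort_bad_arg <- function(msg) rlang::abort(msg, class = "methcycle_error")

check_same_probes <- function(a, b, what_a = "first", what_b = "second") {
  if (!identical(a$probe_id, b$probe_id)) {
    abort_bad_arg(sprintf(
      "probe ids of the %s and %s tables must be identical and in the same order",
      what_a, what_b
    ))
  }
  invisible(TRUE)
}

# Sample-sheet sanity: every subject has exactly one sample in each phase.
check_paired_sheet <- function(sheet) {
  req <- c("sample_id", "subject_id", "phase", "age")
  missing <- setdiff(req, names(sheet))
  if (length(missing)) {
    abort_bad_arg(paste0("sample sheet lacks columns: ", paste(missing, collapse = ", ")))
  }
  bad_phase <- setdiff(unique(sheet$phase), c("LH+2", "LH+8"))
  if (length(bad_phase)) {
    abort_bad_arg(paste0("unknown phase labels: ", paste(bad_phase, collapse = ", ")))
  }
  tab <- table(sheet$subject_id, sheet$phase)
  bad <- rownames(tab)[rowSums(tab == 1) != 2 | rowSums(tab) != 2]
  if (length(bad)) {
    abort_bad_arg(paste0(
      "subjects without exactly one sample per phase: ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Scoped RNG: run `expr` under `seed` (if non-NULL) and restore the caller's
# RNG state afterwards, so seeded helpers do not perturb outer simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

SUBREGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
CGI_CATEGORIES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
FIVE_PRIME_REGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
GENE_BODY_REGIONS <- c("Body", "3'UTR")

region_group <- function(region) {
  dplyr::case_when(
    region %in% FIVE_PRIME_REGIONS ~ "5' region",
    region %in% GENE_BODY_REGIONS ~ "gene body",
    TRUE ~ NA_character_
  )
}

# Parse "GENE1:Body;GENE2:TSS200" annotation tokens into a tibble
# (one row per token). Empty string -> zero rows.
parse_gene_annot <- function(probe_id, gene_annot) {
  keep <- !is.na(gene_annot) & gene_annot != ""
  if (!any(keep)) {
    return(tibble::tibble(
      probe_id = character(), gene_id = character(), region = character()
    ))
  }
  toks <- strsplit(gene_annot[keep], ";", fixed = TRUE)
  out <- tibble::tibble(
    probe_id = rep(probe_id[keep], lengths(toks)),
    token = unlist(toks, use.names = FALSE)
  )
  bad <- !grepl("^[^:]+:[^:]+$", out$token)
  if (any(bad)) {
    abort_bad_arg(paste0(
      "malformed gene annotation tokens: ",
      paste(utils::head(unique(out$token[bad]), 5), collapse = ", ")
    ))
  }
  out$gene_id <- sub(":.*$", "", out$token)
  out$region <- sub("^[^:]*:", "", out$token)
  bad_region <- setdiff(unique(out$region), SUBREGIONS)
  if (length(bad_region)) {
    abort_bad_arg(paste0(
      "unknown gene subregions: ", paste(bad_region, collapse = ", ")
    ))
  }
  out[c("probe_id", "gene_id", "region")]
}
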