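test_that("manifest generation respects counts, ordering and categories", {
  cfg <- sim_config(n_probes = 1000, seed = 1)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), 1000)
  expect_false(anyDuplicated(man$probe_id) > 0)
  by_chrom <- split(man$pos, man$chrom)
  expect_true(all(vapply(by_chrom, function(p) all(diff(p) > 0), TRUE)))
  expect_true(all(man$cgi_relation %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")))
  ann <- methcycle:::parse_gene_annot(man$probe_id, man$gene_annot)
  expect_true(all(ann$region %in%
                    c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")))
  # flagged minorities exist but stay minorities
  expect_gt(sum(man$snp_flag), 0)
  expect_lt(mean(man$crossreactive_flag), 0.2)
})

test_that("manifest generation handles the empty and invalid cases", {
  expect_equal(nrow(generate_manifest(sim_config(n_probes = 0, n_dmr_blocks = 0))), 0)
  expect_error(sim_config(n_probes = -5), class = "methcycle_error")
  expect_error(sim_config(frac_dmc = 1.5), class = "methcycle_error")
  expect_error(sim_config(n_probes = 10, n_dmr_blocks = 5), class = "methcycle_error")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 1000, n_dmr_blocks = 3, seed = 1)
  expect_identical(generate_manifest(cfg), generate_manifest(cfg))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  expect_identical(simulate_methylation(man, sh, cfg),
                   simulate_methylation(man, sh, cfg))
})

test_that("cohort has two phased samples and one age per subject", {
  sh <- generate_cohort(sim_config(n_subjects = 17))
  expect_equal(nrow(sh), 34)
  expect_equal(as.integer(table(sh$phase)), c(17L, 17L))
  expect_true(all(tapply(sh$age, sh$subject_id, function(a) length(unique(a))) == 1))
  sh2 <- generate_cohort(sim_config(n_subjects = 2))
  expect_equal(nrow(sh2), 4)
})

test_that("noise-free null methylation gives phase-identical beta per probe", {
  cfg <- sim_config(n_probes = 200, n_subjects = 4, sigma_m = 0, subject_sd = 0,
                    frac_dmc = 0, n_dmr_blocks = 0, frac_detect_fail = 0, seed = 3)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  beta <- compute_beta(sim$m, sim$u)
  b <- methcycle:::tbl_to_mat(beta)
  pre <- b[, sh$sample_id[sh$phase == "LH+2"]]
  rec <- b[, sh$sample_id[sh$phase == "LH+8"]]
  # total intensity still varies sample to sample, so the +100 offset leaves
  # a small residual difference on the beta scale ...
  expect_lt(max(abs(pre - rec)), 0.05)
  # ... while the recomputed M-values are phase-identical up to the +1 offset
  mm <- methcycle:::tbl_to_mat(compute_m(sim$m, sim$u))
  expect_lt(max(abs(mm[, sh$sample_id[sh$phase == "LH+2"]] -
                      mm[, sh$sample_id[sh$phase == "LH+8"]])), 0.01)
  expect_true(all(sim$truth$true_delta_beta == 0))
})

test_that("a planted block yields positive paired beta-differences at all members", {
  cfg <- sim_config(n_probes = 300, n_subjects = 6, sigma_m = 0.05, subject_sd = 0.05,
                    frac_dmc = 0.02, frac_increase = 1, n_dmr_blocks = 1,
                    effect_delta_beta = c(0.15, 0.25), seed = 4)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  block_probes <- sim$truth$probe_id[!is.na(sim$truth$dmr_block_id)]
  expect_gte(length(block_probes), 3)
  # block spans <= 500 bp with same-sign planted effects
  bp <- man[man$probe_id %in% block_probes, ]
  expect_lte(max(bp$pos) - min(bp$pos), 500)
  beta <- compute_beta(sim$m, sim$u)
  diffs <- paired_differences(compute_m(sim$m, sim$u), beta, sh)
  mean_dbeta <- rowMeans(diffs$dbeta)[match(block_probes, diffs$probe_id)]
  expect_true(all(mean_dbeta > 0))
})

test_that("DMC count is binomial around frac_dmc * n_probes", {
  cfg <- sim_config(n_probes = 20000, frac_dmc = 0.05, n_dmr_blocks = 0, seed = 5)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  n_dmc <- sum(sim$truth$is_dmc)
  expect_equal(n_dmc, round(0.05 * 20000))  # count is deterministic by design
  # planted fractions of increase follow frac_increase within 3 binomial SD
  frac_up <- mean(sim$truth$true_delta_beta[sim$truth$is_dmc] > 0)
  tol <- 3 * sqrt(0.845 * 0.155 / n_dmc)
  expect_lt(abs(frac_up - 0.845), tol)
})

test_that("marginal landscape fractions match configured weights (null config)", {
  cfg <- sim_config(n_probes = 20000, frac_dmc = 0, n_dmr_blocks = 0, seed = 11)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  beta <- compute_beta(sim$m, sim$u)
  states <- classify_states(beta, sh)
  g <- glance(states)
  tol_hypo <- 3 * sqrt(0.33 * 0.67 / 20000)
  tol_hyper <- 3 * sqrt(0.19 * 0.81 / 20000)
  expect_lt(abs(g$frac_hypo - 0.33), tol_hypo)
  expect_lt(abs(g$frac_hyper - 0.19), tol_hyper)
})

test_that("planted effects are faithfully recovered in paired beta-differences", {
  cfg <- sim_config(n_probes = 5000, sigma_m = 0.2, subject_sd = 0.2, seed = 6)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  beta <- compute_beta(sim$m, sim$u)
  diffs <- paired_differences(compute_m(sim$m, sim$u), beta, sh)
  truth <- sim$truth
  dmc <- truth$is_dmc
  obs <- rowMeans(diffs$dbeta)[match(truth$probe_id[dmc], diffs$probe_id)]
  expect_gt(stats::cor(obs, truth$true_delta_beta[dmc]), 0.95)
})

test_that("expression coupling with strength 1 and zero noise is exactly monotone", {
  cfg <- sim_config(n_probes = 300, n_subjects = 7, sigma_m = 0.3, subject_sd = 0.3,
                    frac_dmc = 0.1, n_dmr_blocks = 0, frac_corr_pairs = 0,
                    expr_noise_sd = 0, coupling_strength = 1, seed = 8)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  # hand-plant exactly one coupled pair (negative), all other genes constant
  ann <- methcycle:::parse_gene_annot(man$probe_id, man$gene_annot)
  pick <- ann[ann$probe_id %in% sim$truth$probe_id[sim$truth$is_dmc], ][1, ]
  truth <- sim$truth
  i <- match(pick$probe_id, truth$probe_id)
  truth$coupled_gene[i] <- pick$gene_id
  truth$coupling_sign[i] <- -1
  truth$coupling_strength[i] <- 1
  counts <- simulate_expression(man, sh, truth, cfg, sim)
  expr_cpm <- cpm(counts)
  mv <- compute_m(sim$m, sim$u)
  x <- as.numeric(methcycle:::tbl_to_mat(mv)[pick$probe_id, sh$sample_id])
  y <- as.numeric(methcycle:::tbl_to_mat(expr_cpm, "gene_id")[pick$gene_id, sh$sample_id])
  expect_equal(stats::cor(x, y, method = "spearman"), -1)
})

test_that("uncoupled expression is uncorrelated with methylation on average", {
  cfg <- sim_config(n_probes = 500, n_subjects = 7, frac_corr_pairs = 0, seed = 9)
  man <- generate_manifest(cfg)
  sh <- generate_cohort(cfg)
  sim <- simulate_methylation(man, sh, cfg)
  counts <- simulate_expression(man, sh, sim$truth, cfg, sim)
  expr_cpm <- cpm(counts)
  ann <- methcycle:::parse_gene_annot(man$probe_id, man$gene_annot)
  ann <- ann[!duplicated(ann$gene_id), ]
  ann <- ann[seq_len(min(100, nrow(ann))), ]
  e <- methcycle:::tbl_to_mat(expr_cpm, "gene_id")
  mv <- methcycle:::tbl_to_mat(compute_m(sim$m, sim$u))
  rhos <- vapply(seq_len(nrow(ann)), function(i) {
    stats::cor(mv[ann$probe_id[i], sh$sample_id], e[ann$gene_id[i], sh$sample_id],
               method = "spearman")
  }, 0)
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("negative coupling at strength 0.9 recovers a negative rho in >= 95% of seeds", {
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(n_probes = 60, n_subjects = 7, frac_dmc = 0.2,
                      n_dmr_blocks = 0, frac_corr_pairs = 0,
                      coupling_strength = 0.9, expr_noise_sd = 0.3, seed = 1000 + s)
    man <- generate_manifest(cfg)
    sh <- generate_cohort(cfg)
    sim <- simulate_methylation(man, sh, cfg)
    ann <- methcycle:::parse_gene_annot(man$probe_id, man$gene_annot)
    pick <- ann[ann$probe_id %in% sim$truth$probe_id[sim$truth$is_dmc], ]
    if (nrow(pick) == 0) return(NA)
    pick <- pick[1, ]
    truth <- sim$truth
    i <- match(pick$probe_id, truth$probe_id)
    truth$coupled_gene[i] <- pick$gene_id
    truth$coupling_sign[i] <- -1
    truth$coupling_strength[i] <- 0.9
    counts <- simulate_expression(man, sh, truth, cfg, sim)
    e <- methcycle:::tbl_to_mat(cpm(counts), "gene_id")
    mv <- methcycle:::tbl_to_mat(compute_m(sim$m, sim$u))
    stats::cor(mv[pick$probe_id, sh$sample_id], e[pick$gene_id, sh$sample_id],
               method = "spearman") < 0
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("invalid coupling strength is rejected", {
  expect_error(sim_config(coupling_strength = 0), class = "methcycle_error")
  expect_error(sim_config(coupling_strength = 1.2), class = "methcycle_error")
})
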