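test_that("paired differences follow the receptive-minus-pre-receptive convention", {
  sheet <- make_sheet(2)
  # S01: M 1.0 -> 1.5 ; S02: M 2.0 -> 1.8
  mv <- make_tbl(matrix(c(1.0, 1.5, 2.0, 1.8), 1), samples = sheet$sample_id)
  beta <- make_tbl(matrix(c(0.30, 0.42, 0.5, 0.5), 1), samples = sheet$sample_id)
  diffs <- paired_differences(mv, beta, sheet)
  expect_equal(unname(diffs$d[1, ]), c(0.5, -0.2))
  expect_equal(unname(diffs$dbeta[1, "S01"]), 0.12)
  # swapping phase labels flips every sign
  sheet_sw <- sheet
  sheet_sw$phase <- ifelse(sheet$phase == "LH+2", "LH+8", "LH+2")
  diffs_sw <- paired_differences(mv, beta, sheet_sw)
  expect_equal(diffs_sw$d, -diffs$d, ignore_attr = TRUE)
  # unpaired subject errors with its name
  expect_error(paired_differences(mv[, 1:3], beta[, 1:3], sheet[-4, ]), "S02")
})

test_that("moderated test with d0 = 0 equals the ordinary t statistic", {
  diffs <- make_diffs(rbind(c(1, 2, 3)))
  res <- moderated_paired_test(diffs, adjust_age = FALSE,
                               moderation = list(d0 = 0, s0sq = 1))
  # hand oracle: mean 2, sd 1, t = 2/(1/sqrt(3)) = 3.4641
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2))
  # and equals t.test on the same data
  tt <- stats::t.test(c(1, 2, 3))
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("moderated test with d0 = Inf pools all variances to s0sq", {
  set.seed(5)
  diffs <- make_diffs(matrix(stats::rnorm(50), 10, 5))
  res <- moderated_paired_test(diffs, adjust_age = FALSE,
                               moderation = list(d0 = Inf, s0sq = 2))
  expect_equal(res$statistic,
               rowMeans(diffs$d) / sqrt(2 / 5), tolerance = 1e-12)
})

test_that("moment-matched moderation agrees with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(6)
  n <- 8
  d <- matrix(stats::rnorm(500 * n, 0, rep(stats::rchisq(500, 4) / 4, n)), 500, n)
  diffs <- make_diffs(d)
  res <- moderated_paired_test(diffs, adjust_age = FALSE)
  fit <- limma::lmFit(d, design = matrix(1, n, 1))
  eb <- limma::eBayes(fit)
  m <- attr(res, "moderation")
  expect_equal(m$d0, eb$df.prior, tolerance = 0.05)
  expect_equal(m$s0sq, eb$s2.prior, tolerance = 0.02)
  expect_equal(res$statistic, eb$t[, 1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p_value, eb$p.value[, 1], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("age adjustment absorbs an age-linked component of the differences", {
  set.seed(7)
  ages <- c(24, 26, 28, 30, 32, 34)
  age_part <- 0.5 * (ages - mean(ages))
  # pure age effect, no true shift: the adjusted intercept stays null
  diffs0 <- make_diffs(rbind(age_part + stats::rnorm(6, 0, 0.01)), ages = ages)
  adj0 <- moderated_paired_test(diffs0, adjust_age = TRUE,
                                moderation = list(d0 = 0, s0sq = 1))
  expect_lt(abs(adj0$estimate), 0.02)
  expect_gt(adj0$p_value, 0.05)
  # true shift on top of the age effect: adjusting removes the age-driven
  # residual variance, so the shift is detected far more sharply
  diffs1 <- make_diffs(rbind(1 + age_part + stats::rnorm(6, 0, 0.01)), ages = ages)
  adj1 <- moderated_paired_test(diffs1, adjust_age = TRUE,
                                moderation = list(d0 = 0, s0sq = 1))
  raw1 <- moderated_paired_test(diffs1, adjust_age = FALSE,
                                moderation = list(d0 = 0, s0sq = 1))
  expect_equal(adj1$estimate, 1, tolerance = 0.05)
  expect_gt(abs(adj1$statistic), abs(raw1$statistic))
  expect_lt(adj1$p_value, raw1$p_value)
})

test_that("Wilcoxon exact p matches the hand enumerations", {
  d1 <- make_diffs(rbind(c(1, 2, 3, 4, 5)))
  r1 <- wilcoxon_paired_test(d1)
  expect_equal(r1$statistic, 15)
  expect_equal(r1$p_value, 0.0625)
  d2 <- make_diffs(rbind(c(2, -1, 3)))
  r2 <- wilcoxon_paired_test(d2)
  expect_equal(r2$statistic, 5)
  expect_equal(r2$p_value, 0.5)
  # symmetry: all-negative gives W = 0 and the same p as all-positive
  d3 <- make_diffs(rbind(c(-1, -2, -3, -4, -5)))
  r3 <- wilcoxon_paired_test(d3)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("Wilcoxon exact p equals the sign-enumeration oracle on random instances", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 3 || anyDuplicated(abs(d))) next
    res <- wilcoxon_paired_test(make_diffs(rbind(d)))
    orc <- oracle_signrank(d)
    expect_equal(res$statistic, orc$W)
    expect_equal(res$p_value, orc$p)
  }
})

test_that("Wilcoxon handles zeros and ties", {
  # all zero differences: p = 1, flagged via n_used = 0
  rz <- wilcoxon_paired_test(make_diffs(rbind(c(0, 0, 0, 0))))
  expect_equal(rz$p_value, 1)
  expect_equal(rz$n_used, 0)
  # ties fall back to the corrected normal approximation
  rt <- wilcoxon_paired_test(make_diffs(rbind(c(1, 1, 2, -1, 3, 2))))
  expect_false(rt$exact)
  expect_true(rt$p_value > 0 && rt$p_value <= 1)
  # large n uses the approximation too, close to the exact value
  set.seed(9)
  d <- stats::rnorm(30) + 0.5
  r_apx <- wilcoxon_paired_test(make_diffs(rbind(d)), exact_max_n = 25)
  r_ex <- wilcoxon_paired_test(make_diffs(rbind(d)), exact_max_n = 30)
  expect_equal(r_apx$p_value, r_ex$p_value, tolerance = 0.15)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)), c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "methcycle_error")
  # random vectors: equals the oracle, monotone in p, capped at 1, q >= p
  set.seed(10)
  for (i in 1:20) {
    p <- stats::runif(sample(5:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q <= 1) && all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("segment construction follows the gap and sign rules", {
  # 3 probes within 500 bp and identical d vectors: one segment whose
  # unadjusted p equals the single-probe test on that d vector
  d <- c(0.4, 0.9, -0.3, 0.7, 0.2)
  diffs <- make_diffs(rbind(d, d, d))
  man <- make_manifest(diffs$probe_id, "chr1", c(100, 300, 550))
  seg <- segment_test(diffs, man, max_gap = 500, adjust_age = FALSE)
  expect_equal(length(unique(seg$segment_id)), 1)
  single <- moderated_paired_test(make_diffs(rbind(d)), adjust_age = FALSE,
                                  moderation = list(d0 = 0, s0sq = 1))
  expect_equal(unique(seg$p_unadjusted), single$p_value)
  expect_equal(unique(seg$statistic), single$statistic)

  # a 600 bp gap breaks the run
  man2 <- make_manifest(diffs$probe_id, "chr1", c(100, 300, 900))
  seg2 <- segment_test(diffs, man2, max_gap = 500, adjust_age = FALSE)
  expect_equal(length(unique(seg2$segment_id)), 2)

  # a sign change breaks the run even within the gap
  diffs3 <- make_diffs(rbind(d, d, -d))
  seg3 <- segment_test(diffs3, man, max_gap = 500, adjust_age = FALSE)
  expect_equal(length(unique(seg3$segment_id)), 2)

  expect_error(segment_test(diffs, man[c(2, 1, 3), ]), class = "methcycle_error")
})

test_that("segment means shrink noise variance by about 1/k", {
  set.seed(11)
  n <- 10; k <- 4; reps <- 300
  # k probes of pure noise in one segment vs single probes: compare the
  # variance of the segment-mean estimate across replicates
  seg_means <- replicate(reps, {
    d <- matrix(stats::rnorm(k * n), k, n)
    d <- d * sign(rowMeans(d))[1]  # force same sign so they stay one segment
    mean(colMeans(d))
  })
  single_means <- replicate(reps, mean(stats::rnorm(n)))
  ratio <- stats::var(seg_means) / stats::var(single_means)
  expect_lt(ratio, 2 / k)  # well below the single-probe variance
})

test_that("consensus is the three-way intersection and is order-invariant", {
  set.seed(12)
  d <- matrix(stats::rnorm(5 * 6), 5, 6)
  diffs <- make_diffs(d)
  mk <- function(q) tibble::tibble(probe_id = diffs$probe_id,
                                   statistic = 0, p_value = q, q_value = q)
  qa <- c(0.01, 0.01, 0.01, 0.20, 0.20)  # sig: 1,2,3
  qb <- c(0.20, 0.01, 0.01, 0.01, 0.20)  # sig: 2,3,4
  qc <- c(0.20, 0.01, 0.01, 0.20, 0.20)  # sig: 2,3
  s1 <- consensus_sites(mk(qa), mk(qb), mk(qc), diffs)
  expect_equal(s1$probe_id[s1$consensus], diffs$probe_id[2:3])
  s2 <- consensus_sites(mk(qc), mk(qa), mk(qb), diffs)
  expect_equal(s1$consensus, s2$consensus)
  # 2-of-3 significance is excluded; empty intersection is fine
  qd <- c(0.2, 0.2, 0.2, 0.01, 0.01)
  s3 <- consensus_sites(mk(qa), mk(qb), mk(qd), diffs)
  expect_false(any(s3$consensus[1:3]))
  s4 <- consensus_sites(mk(rep(0.9, 5)), mk(qa), mk(qb), diffs)
  expect_equal(sum(s4$consensus), 0)
  # direction follows the sign of delta-beta
  expect_equal(s1$direction, ifelse(rowMeans(diffs$dbeta) >= 0, "increased", "decreased"))
})

test_that("q-values never undercut their p-values in the full analysis", {
  cfg <- sim_config(n_probes = 800, n_dmr_blocks = 3, seed = 13)
  st <- simulate_study(cfg)
  beta <- compute_beta(st$m, st$u)
  diffs <- paired_differences(compute_m(st$m, st$u), beta, st$sheet)
  sites <- test_differential_methylation(diffs, st$manifest)
  expect_true(all(sites$q_moderated >= sites$p_moderated - 1e-12))
  expect_true(all(sites$q_wilcoxon >= sites$p_wilcoxon - 1e-12))
  g <- glance(sites)
  expect_equal(g$n_increased + g$n_decreased, g$n_consensus)
})
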