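# Univariate scans, directionality, stratified estimates, recovery,
# polygenic scores.

# A cohort with strong, sign-coupled marginal and interaction effects used
# by several downstream tests.
coupled_cohort <- function(panel, seed = 200, n_causal = 30, coupling = 0.5) {
  set.seed(seed)
  n <- n_ind(panel)
  m <- n_snp(panel)
  causal <- sort(sample(m, n_causal))
  beta_g <- rnorm(n_causal)
  beta_ge <- coupling * beta_g # perfectly sign-coupled
  e <- rnorm(n)
  g_comp <- as.vector(panel$dosage[, causal] %*% beta_g)
  ge_comp <- as.vector((panel$dosage[, causal] * e) %*% beta_ge)
  g_comp <- g_comp * sqrt(0.25) / sd(g_comp)
  ge_comp <- ge_comp * sqrt(0.15) / sd(ge_comp)
  y <- g_comp + ge_comp + rnorm(n, sd = sqrt(0.6))
  list(y = y, e = e, causal = causal)
}

test_that("univariate scan finds strong effects and is calibrated under the null", {
  panel <- midsize_panel()
  sim <- coupled_cohort(panel)
  prep <- prepare(sim$y, sim$e, hetero_adjust = "none")
  scan <- univariate_scan(panel, prep, seed = 201)
  expect_equal(nrow(scan$table), n_snp(panel))
  expect_length(intersect(scan$discovery, scan$validation), 0)
  expect_equal(length(scan$discovery), round(0.8 * n_ind(panel)))
  # a SNP explaining ~1% of variance in 8,000 discovery individuals
  strongest <- sim$causal[which.max(abs(as.vector(
    crossprod(panel$dosage[, sim$causal], prep$y))))]
  expect_lt(scan$table$p_g[strongest], 1e-10)
  # null SNPs: marginal p-values approximately uniform. SNPs near a causal
  # SNP carry signal through LD, so only SNPs far from every causal one
  # (AR(1) correlation 0.6^25 ~ 1e-6) are truly null.
  dist_to_causal <- vapply(seq_len(n_snp(panel)),
                           function(j) min(abs(j - sim$causal)), numeric(1))
  null_snps <- which(dist_to_causal > 25)
  ks <- suppressWarnings(ks.test(scan$table$p_g[null_snps], "punif"))
  expect_gt(ks$p.value, 0.01)
  # determinism under the split seed
  scan2 <- univariate_scan(panel, prep, seed = 201)
  expect_identical(scan$table$p_ge, scan2$table$p_ge)
})

test_that("coupled effects give high concordance, independent effects give 0.5", {
  panel <- midsize_panel()
  sim <- coupled_cohort(panel)
  prep <- prepare(sim$y, sim$e, hetero_adjust = "none")
  scan <- univariate_scan(panel, prep, seed = 202)
  tab <- directionality(scan, panel, p_thresholds = c(1, 1e-2),
                        ld_prune_r2 = 0.5)
  strict <- tab[tab$criterion == "p_ge" & tab$threshold == 1e-2, ]
  expect_gt(strict$concordance, 0.9)
  expect_lt(strict$p_value, 0.05)
  # independent coefficients: concordance compatible with 0.5
  set.seed(203)
  y0 <- rnorm(n_ind(panel))
  prep0 <- prepare(y0, sim$e, hetero_adjust = "none")
  scan0 <- univariate_scan(panel, prep0, seed = 204)
  tab0 <- directionality(scan0, panel, p_thresholds = 1, ld_prune_r2 = 0.5)
  all0 <- tab0[tab0$criterion == "p_g", ]
  expect_lt(abs(all0$concordance - 0.5),
            3 * sqrt(0.25 / all0$n_snps))
})

test_that("the two-proportion Z statistic matches the hand formula", {
  # 60/40 split of 1,000 SNPs against the null 0.5
  z <- two_proportion_z(0.6, 0.5, 1000, 1000)
  pooled <- (0.6 + 0.5) / 2
  expect_equal(z, 0.1 / sqrt(pooled * (1 - pooled) * 2 / 1000))
})

test_that("stratified estimates reduce to the genome-wide estimate", {
  panel <- small_panel()
  cohort <- simulate_cohort(scenario_spec(2), panel, seed = 210)
  prep <- prepare(cohort$y, cohort$e, hetero_adjust = "none")
  # single all-encompassing stratum
  tab <- stratified_r2(panel, prep, maf_breaks = c(0, 0.5),
                       ld_probs = c(0, 1))
  expect_equal(nrow(tab), 1)
  est <- estimate_gxe(panel, prep, partition_blocks(panel, m_max = 199))
  expect_lt(abs(tab$r2_g - est$g$estimate), 0.02)
  expect_equal(tab$r2_g_per_snp, tab$r2_g / n_snp(panel))
  # binning from 0 covers all SNPs across strata
  tab20 <- stratified_r2(panel, prep,
                         maf_breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                         ld_probs = c(0, 0.5, 1))
  expect_equal(sum(tab20$m), n_snp(panel))
})

test_that("variance recovery is 1 at threshold 1 and monotone in the threshold", {
  panel <- midsize_panel()
  sim <- coupled_cohort(panel, seed = 220)
  prep <- prepare(sim$y, sim$e, hetero_adjust = "none")
  scan <- univariate_scan(panel, prep, seed = 221)
  rec <- recovery_analysis(scan, panel, prep, thresholds = c(1, 1e-2, 1e-6))
  full <- rec[rec$criterion == "p_g" & rec$threshold == 1, ]
  expect_equal(full$recovery_g, 1, tolerance = 1e-12)
  expect_equal(full$n_snps, n_snp(panel))
  g_rec <- rec$recovery_g[rec$criterion == "p_g"]
  expect_true(all(diff(g_rec) <= 0.1)) # non-increasing as threshold tightens
  # strong-marginal selection recovers most of the signal here
  expect_gt(rec$recovery_g[rec$criterion == "p_g" & rec$threshold == 1e-6],
            0.5)
})

test_that("polygenic scores with interactions beat genetic-only scores on coupled cohorts", {
  panel <- midsize_panel()
  sim <- coupled_cohort(panel, seed = 230, coupling = 1)
  prep <- prepare(sim$y, sim$e, hetero_adjust = "none")
  scan <- univariate_scan(panel, prep, seed = 231)
  ps <- build_ps(scan, panel, prep, p_g_threshold = 1e-3,
                 p_ge_threshold = 1e-3, n_boot = 200, seed = 232)
  expect_true(all(ps$interactions %in% ps$snps))
  expect_gt(ps$r2_ge, ps$r2_g)
  expect_lt(ps$p_improvement, 0.05)
  expect_equal(nrow(ps$scores), length(scan$validation))
  # excluding every interaction makes the two scores identical
  ps0 <- build_ps(scan, panel, prep, p_g_threshold = 1e-3,
                  p_ge_threshold = 1e-300, n_boot = 50, seed = 233)
  expect_identical(ps0$scores$ps_g, ps0$scores$ps_ge)
  expect_equal(ps0$r2_g, ps0$r2_ge)
})

test_that("null scores do not leak validation signal", {
  panel <- small_panel()
  set.seed(240)
  y <- rnorm(n_ind(panel))
  e <- rnorm(n_ind(panel))
  prep <- prepare(y, e, hetero_adjust = "none")
  scan <- univariate_scan(panel, prep, seed = 241)
  ps <- build_ps(scan, panel, prep, p_g_threshold = 0.5, p_ge_threshold = 0.5,
                 n_boot = 50, seed = 242)
  expect_lt(ps$r2_g, 0.02) # null prediction R2 near zero out of sample
})
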