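# Scenario specifications and cohort simulation.

test_that("scenario defaults follow the validation design", {
  s1 <- scenario_spec(1)
  expect_equal(s1$r2_gwei, 0)
  expect_equal(s1$model, "base")
  s2 <- scenario_spec(2)
  expect_equal(s2$r2_gwei, 0.1)
  expect_equal(scenario_spec(3)$r2_e_on_y, 0.1)
  expect_equal(scenario_spec(4)$ge_restriction, "top-ld")
  expect_equal(scenario_spec(5)$ge_restriction, "top-ld-bottom-maf")
  expect_equal(scenario_spec(6)$beta_ge_dist, "exponential")
  expect_equal(scenario_spec(7)$beta_ge_dist, "beta")
  expect_equal(scenario_spec(8)$exposure_type, "dichotomous")
  for (s in 9:12) expect_equal(scenario_spec(s)$model, "collider")
  expect_equal(scenario_spec(10)$ge_overlap, "disjoint")
  expect_equal(scenario_spec(11)$r2_gwei, 0)
  expect_equal(scenario_spec(12)$exposure_het_frac, 0.2)
  expect_error(scenario_spec(2, r2_gw = 0.7, r2_gwei = 0.3), "budget")
})

test_that("base cohorts honor the variance decomposition and causal fractions", {
  panel <- midsize_panel()
  cohort <- simulate_base(scenario_spec(2), panel, seed = 101)
  m <- n_snp(panel)
  expect_length(cohort$causal_g, round(0.2 * m))
  expect_length(cohort$causal_ge, round(0.02 * m))
  expect_true(all(cohort$causal_ge %in% cohort$causal_g)) # default subset rule
  expect_equal(unname(cohort$truth$realized["r2_gw"]), 0.2, tolerance = 0.015)
  expect_equal(unname(cohort$truth$realized["r2_gwei"]), 0.1, tolerance = 0.015)
  # null interaction scenario has an identically-zero component
  null <- simulate_base(scenario_spec(1), panel, seed = 102)
  expect_length(null$causal_ge, 0)
  expect_equal(unname(null$truth$realized["r2_gwei"]), 0)
})

test_that("same seed reproduces a cohort bitwise", {
  panel <- small_panel()
  a <- simulate_cohort(scenario_spec(2), panel, seed = 7)
  b <- simulate_cohort(scenario_spec(2), panel, seed = 7)
  expect_identical(a$y, b$y)
  expect_identical(a$e, b$e)
  expect_identical(a$causal_ge, b$causal_ge)
})

test_that("LD/MAF-restricted scenarios sample interaction SNPs from the right strata", {
  panel <- small_panel()
  c4 <- simulate_base(scenario_spec(4), panel, seed = 104)
  ld_q3 <- quantile(panel$ldscore, 0.75)
  expect_true(all(panel$ldscore[c4$causal_ge] >= ld_q3))
  # LD score and MAF are coupled in thresholded AR(1) panels, which can
  # empty the joint stratum at this scale; decouple the metadata to test
  # the sampling rule itself.
  panel5 <- panel
  set.seed(1050)
  panel5$ldscore <- runif(n_snp(panel5), 1, 30)
  c5 <- simulate_base(scenario_spec(5), panel5, seed = 105)
  expect_true(all(panel5$ldscore[c5$causal_ge] >=
                    quantile(panel5$ldscore, 0.75)))
  expect_true(all(panel5$maf[c5$causal_ge] <= quantile(panel5$maf, 0.25)))
})

test_that("collider cohorts induce the set Y-E correlation without causal paths", {
  panel <- midsize_panel()
  c9 <- simulate_collider(scenario_spec(9), panel, seed = 109)
  expect_equal(c9$truth$collider_r2_realized, 0.2, tolerance = 0.03)
  expect_equal(unname(c9$truth$realized["r2_gw"]), 0.2, tolerance = 0.015)
  expect_equal(unname(c9$truth$realized["r2_gwei"]), 0.1, tolerance = 0.015)
  # disjoint overlap: no shared causal SNPs
  c10 <- simulate_collider(scenario_spec(10), panel, seed = 110)
  expect_length(intersect(c10$causal_g, c10$causal_ge), 0)
  expect_gt(length(c10$causal_ge), 0)
})

test_that("heritable-exposure collider cohorts carry exposure heritability", {
  panel <- midsize_panel()
  c12 <- simulate_collider(scenario_spec(12), panel, seed = 112)
  # regress the exposure itself on the panel. The additive 16% is fully
  # recoverable; of the heterogeneous 4% (effects switched by an unobserved
  # binary), exactly half projects onto the additive span: expect ~18%.
  set.seed(113)
  prep_e <- prepare(c12$e, rnorm(length(c12$e)), hetero_adjust = "none")
  est <- estimate_gxe(panel, prep_e, partition_blocks(panel, m_max = 500))
  expect_lt(abs(est$g$estimate - 0.18), 4 * sqrt(est$g$variance))
})

test_that("dichotomous outcomes match the target prevalence", {
  panel <- small_panel()
  spec <- scenario_spec(2, r2_gwei = 0)
  cohort <- simulate_dichotomous_outcome(spec, panel, prevalence = 0.1,
                                         seed = 120)
  expect_true(all(cohort$y %in% c(0, 1)))
  expect_equal(cohort$prevalence, 0.1, tolerance = 0.011)
  expect_error(simulate_dichotomous_outcome(spec, panel, prevalence = 1.2),
               "prevalence")
})

test_that("mean imputation replaces the requested fractions and nothing else", {
  panel <- small_panel()
  cohort <- simulate_cohort(scenario_spec(2), panel, seed = 130)
  same <- apply_mean_imputation(cohort, 0.2, 0.2, same_individuals = TRUE,
                                seed = 1)
  expect_equal(sum(cohort$e != same$e), 0.2 * length(cohort$e),
               tolerance = 0.01 * length(cohort$e))
  imp_e <- which(cohort$e != same$e)
  imp_y <- which(cohort$y != same$y)
  expect_true(all(imp_y %in% imp_e)) # same individuals
  disj <- apply_mean_imputation(cohort, 0.2, 0.2, same_individuals = FALSE,
                                seed = 2)
  expect_length(intersect(which(cohort$e != disj$e),
                          which(cohort$y != disj$y)), 0)
  untouched <- apply_mean_imputation(cohort, 0, 0)
  expect_identical(untouched$y, cohort$y)
  expect_identical(untouched$e, cohort$e)
  expect_error(apply_mean_imputation(cohort, 0.2, 0.1, same_individuals = TRUE),
               "frac_e == frac_y")
})
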