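# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small standardized panel shared by fast unit tests.
small_panel <- function() {
  fixture("small_panel", function() {
    standardize(generate_synthetic_panel(2000, 120, n_chrom = 2, seed = 42))
  })
}

# Acceptance-scale panel: n = 20,000 individuals, m = 2,000 SNPs over two
# chromosomes. Built once and shared by the scenario-recovery tests.
acceptance_panel <- function() {
  fixture("acceptance_panel", function() {
    standardize(generate_synthetic_panel(20000, 2000, n_chrom = 2,
                                         seed = derive_seed(1, "panel")))
  })
}

# Moderate panel for collider / imputation experiments.
midsize_panel <- function() {
  fixture("midsize_panel", function() {
    standardize(generate_synthetic_panel(10000, 1000, n_chrom = 2,
                                         seed = derive_seed(2, "panel")))
  })
}

# Run one simulated scenario replicate through the full pipeline.
run_scenario_rep <- function(panel, spec, rep, m_max = 1000, master = 1) {
  cohort <- simulate_cohort(spec, panel,
                            seed = derive_seed(master, paste0("scen", spec$scenario), rep))
  prep <- prepare(cohort$y, cohort$e,
                  outcome_type = cohort$outcome_type,
                  exposure_type = cohort$exposure_type)
  est <- estimate_gxe(panel, prep, partition_blocks(panel, m_max = m_max))
  list(cohort = cohort, prep = prep, est = est)
}
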