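#' Declarative specification of a validation scenario
#'
#' Twelve scenarios probe the estimator: (1) null interaction, (2) non-null
#' base case, (3) non-null with a causal exposure effect on the outcome,
#' (4) interaction effects confined to the top LD-score quartile, (5) to the
#' top LD-score and bottom MAF quartiles, (6-7) interaction effect sizes
#' drawn from exponential and centered Beta(0.5, 0.5) (positive kurtosis)
#' distributions, (8) dichotomous exposure, (9-11) collider structures in
#' which an unobserved confounder induces cor^2(Y, E) = 0.2 with no causal
#' path and the interaction-causal SNP set is respectively random, disjoint
#' from, or a strict subset of the marginal-causal set, and (12) a collider
#' with a heritable exposure whose genetic variance is partly heterogeneous.
#' Unless overridden, heritability is 0.20, interaction variance 0.1 (0 for
#' the null scenarios 1, 11 and 12), 20 percent of SNPs carry marginal
#' effects and 2 percent carry interaction effects.
#'
#' @param scenario Integer 1-12.
#' @param r2_gw True genome-wide additive genetic variance of the outcome.
#' @param r2_gwei True genome-wide interaction variance (scenario default
#'   when `NULL`).
#' @param r2_e_on_y Outcome variance explained causally by the exposure.
#' @param causal_frac_g Fraction of SNPs with marginal effects.
#' @param causal_frac_ge Fraction of SNPs with interaction effects.
#' @param beta_ge_dist `"normal"`, `"exponential"` or `"beta"`.
#' @param ge_restriction `"none"`, `"top-ld"` or `"top-ld-bottom-maf"`.
#' @param exposure_type `"continuous"` or `"dichotomous"`.
#' @param exposure_h2 Exposure heritability (collider scenarios).
#' @param exposure_het_frac Fraction of the exposure's genetic variance that
#'   is heterogeneous (scenario 12).
#' @param collider_r2 Squared confounder-induced correlation between outcome
#'   and exposure (collider scenarios).
#' @param seed Integer seed stored with the specification.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario, r2_gw = 0.20, r2_gwei = NULL,
                          r2_e_on_y = NULL, causal_frac_g = 0.20,
                          causal_frac_ge = 0.02, beta_ge_dist = NULL,
                          ge_restriction = NULL, exposure_type = NULL,
                          exposure_h2 = NULL, exposure_het_frac = NULL,
                          collider_r2 = NULL, seed = NULL) {
  stopifnot(scenario %in% 1:12)
  model <- if (scenario >= 9) "collider" else "base"
  defaults <- list(
    r2_gwei = if (scenario %in% c(1, 11, 12)) 0 else 0.1,
    r2_e_on_y = if (scenario == 3) 0.1 else 0,
    beta_ge_dist = switch(as.character(scenario), "6" = "exponential",
                          "7" = "beta", "normal"),
    ge_restriction = switch(as.character(scenario), "4" = "top-ld",
                            "5" = "top-ld-bottom-maf", "none"),
    exposure_type = if (scenario == 8) "dichotomous" else "continuous",
    ge_overlap = switch(as.character(scenario), "9" = "random",
                        "10" = "disjoint", "11" = "subset", "subset"),
    exposure_h2 = if (model == "collider") 0.2 else 0,
    exposure_het_frac = if (scenario == 12) 0.2 else 0,
    collider_r2 = if (model == "collider") 0.2 else NULL)
  spec <- list(
    scenario = as.integer(scenario), model = model, r2_gw = r2_gw,
    r2_gwei = r2_gwei %||% defaults$r2_gwei,
    r2_e_on_y = r2_e_on_y %||% defaults$r2_e_on_y,
    causal_frac_g = causal_frac_g, causal_frac_ge = causal_frac_ge,
    beta_ge_dist = beta_ge_dist %||% defaults$beta_ge_dist,
    ge_restriction = ge_restriction %||% defaults$ge_restriction,
    exposure_type = exposure_type %||% defaults$exposure_type,
    ge_overlap = defaults$ge_overlap,
    exposure_h2 = exposure_h2 %||% defaults$exposure_h2,
    exposure_het_frac = exposure_het_frac %||% defaults$exposure_het_frac,
    collider_r2 = collider_r2 %||% defaults$collider_r2,
    outcome_type = "continuous", seed = seed)
  budget <- spec$r2_gw + spec$r2_gwei + spec$r2_e_on_y
  if (model == "collider") budget <- budget + sqrt(spec$collider_r2)
  if (budget >= 1) stop("infeasible variance budget: components sum to >= 1")
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec %d (%s model): r2_gw = %.2f, r2_gwei = %.2f, r2_e_on_y = %.2f\n",
              x$scenario, x$model, x$r2_gw, x$r2_gwei, x$r2_e_on_y))
  invisible(x)
}

# Rescale a component vector to an exact sample-variance target.
.scale_component <- function(x, target) {
  if (target <= 0) return(numeric(length(x)))
  s <- stats::sd(x)
  if (s == 0) stop("infeasible variance budget: degenerate component")
  x * sqrt(target) / s
}

# Draw interaction effect sizes under the scenario's distribution.
.draw_beta_ge <- function(k, dist) {
  switch(dist,
         normal = stats::rnorm(k),
         exponential = stats::rexp(k),
         beta = stats::rbeta(k, 0.5, 0.5) - 0.5,
         stop("unknown interaction effect distribution: ", dist))
}

# Sample the interaction-causal SNP set under the scenario's restriction /
# overlap rules.
.sample_causal_ge <- function(spec, panel, causal_g, k_ge) {
  m <- n_snp(panel)
  if (k_ge == 0) return(integer(0))
  eligible <- seq_len(m)
  if (spec$ge_restriction == "top-ld") {
    ld <- panel$ldscore %||% compute_ldscore(panel)
    eligible <- which(ld >= stats::quantile(ld, 0.75))
  } else if (spec$ge_restriction == "top-ld-bottom-maf") {
    ld <- panel$ldscore %||% compute_ldscore(panel)
    eligible <- which(ld >= stats::quantile(ld, 0.75) &
                        panel$maf <= stats::quantile(panel$maf, 0.25))
  } else if (spec$ge_overlap == "subset") {
    eligible <- causal_g
  } else if (spec$ge_overlap == "disjoint") {
    eligible <- setdiff(seq_len(m), causal_g)
  }
  if (length(eligible) < k_ge) {
    stop("not enough eligible SNPs for the interaction-causal set")
  }
  sort(sample(eligible, k_ge))
}

.audit_cohort <- function(realized, targets, n, tol = 0.01) {
  if (n < 20000) return(invisible(NULL))
  dev <- abs(realized - targets)
  if (any(dev > tol)) {
    stop(sprintf("variance decomposition audit failed: max deviation %.4f > %.2f",
                 max(dev), tol))
  }
  invisible(NULL)
}

#' Simulate an outcome/exposure cohort under a base scenario
#'
#' Generates `Y = bG G + bE E + bGE (G * E) + eps` on a standardized panel:
#' marginal and interaction effect SNPs are sampled per the specification,
#' effect sizes drawn from the specified distributions, and every component
#' rescaled so its realized variance fraction equals the scenario truth.
#'
#' @param spec A base-model `scenario_spec`.
#' @param panel A `genotype_panel` (standardized on the fly if raw).
#' @param seed Integer seed (overrides `spec$seed`).
#' @return A `simulated_cohort`: `y`, `e`, `truth` (set and realized variance
#'   fractions), causal index sets, and type flags.
#' @export
simulate_base <- function(spec, panel, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$model != "base") stop("simulate_base() needs a base-model scenario")
  if (!panel$standardized) panel <- standardize(panel)
  n <- n_ind(panel)
  m <- n_snp(panel)
  with_seed(seed %||% spec$seed, {
    causal_g <- sort(sample(m, round(spec$causal_frac_g * m)))
    causal_ge <- .sample_causal_ge(spec, panel, causal_g,
                                   if (spec$r2_gwei > 0)
                                     round(spec$causal_frac_ge * m) else 0L)
    e <- if (spec$exposure_type == "dichotomous") {
      stats::rbinom(n, 1, 0.5)
    } else {
      stats::rnorm(n)
    }
    comp_g <- .scale_component(
      as.vector(panel$dosage[, causal_g, drop = FALSE] %*%
                  stats::rnorm(length(causal_g))), spec$r2_gw)
    comp_ge <- if (length(causal_ge) > 0) {
      W <- panel$dosage[, causal_ge, drop = FALSE] * e
      .scale_component(as.vector(W %*% .draw_beta_ge(length(causal_ge),
                                                     spec$beta_ge_dist)),
                       spec$r2_gwei)
    } else numeric(n)
    comp_e <- .scale_component(e, spec$r2_e_on_y)
    resid_var <- 1 - spec$r2_gw - spec$r2_gwei - spec$r2_e_on_y
    eps <- .scale_component(stats::rnorm(n), resid_var)
    y <- comp_g + comp_e + comp_ge + eps
    realized <- c(r2_gw = stats::var(comp_g),
                  r2_gwei = if (length(causal_ge) > 0) stats::var(comp_ge) else 0,
                  r2_e_on_y = stats::var(comp_e)) / stats::var(y)
    .audit_cohort(realized,
                  c(spec$r2_gw, spec$r2_gwei, spec$r2_e_on_y), n)
    structure(list(y = y, e = as.numeric(e),
                   truth = list(r2_gw = spec$r2_gw, r2_gwei = spec$r2_gwei,
                                r2_e_on_y = spec$r2_e_on_y,
                                realized = realized),
                   causal_g = causal_g, causal_ge = causal_ge, uc = NULL,
                   outcome_type = "continuous",
                   exposure_type = spec$exposure_type,
                   prevalence = NULL, spec = spec),
              class = "simulated_cohort")
  })
}

#' Simulate a cohort under a collider scenario
#'
#' An unobserved standard-normal confounder loads symmetrically on outcome
#' and exposure so that their squared correlation equals the scenario's
#' `collider_r2` with no causal path between them. The exposure carries 20
#' percent additive genetic variance (partly heterogeneous, via interaction
#' with a random binary variable, in scenario 12); the outcome carries the
#' set additive and interaction variances with the interaction-causal SNP
#' set random, disjoint or a strict subset per the scenario.
#'
#' @inheritParams simulate_base
#' @return A `simulated_cohort` with the confounder stored in `uc`.
#' @export
simulate_collider <- function(spec, panel, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$model != "collider") {
    stop("simulate_collider() needs a collider-model scenario")
  }
  if (!panel$standardized) panel <- standardize(panel)
  n <- n_ind(panel)
  m <- n_snp(panel)
  with_seed(seed %||% spec$seed, {
    uc <- stats::rnorm(n)
    uc_share <- sqrt(spec$collider_r2) # symmetric loadings on Y and E

    # Exposure: additive (and optionally heterogeneous) genetic variance,
    # confounder loading, independent noise.
    causal_e <- sort(sample(m, round(0.2 * m)))
    var_add <- spec$exposure_h2 * (1 - spec$exposure_het_frac)
    var_het <- spec$exposure_h2 * spec$exposure_het_frac
    e_g <- .scale_component(
      as.vector(panel$dosage[, causal_e, drop = FALSE] %*%
                  stats::rnorm(length(causal_e))), var_add)
    e_het <- if (var_het > 0) {
      bin <- stats::rbinom(n, 1, 0.5)
      sub <- sort(sample(causal_e, max(1, round(0.2 * length(causal_e)))))
      .scale_component(
        as.vector((panel$dosage[, sub, drop = FALSE] * bin) %*%
                    stats::rnorm(length(sub))), var_het)
    } else numeric(n)
    e_noise_var <- 1 - spec$exposure_h2 - uc_share
    if (e_noise_var <= 0) stop("infeasible correlation budget for the exposure")
    e <- e_g + e_het + .scale_component(uc, uc_share) +
      .scale_component(stats::rnorm(n), e_noise_var)

    causal_g <- sort(sample(m, round(spec$causal_frac_g * m)))
    causal_ge <- if (spec$r2_gwei > 0) {
      .sample_causal_ge(spec, panel, causal_g, round(spec$causal_frac_ge * m))
    } else integer(0)
    comp_g <- .scale_component(
      as.vector(panel$dosage[, causal_g, drop = FALSE] %*%
                  stats::rnorm(length(causal_g))), spec$r2_gw)
    comp_ge <- if (length(causal_ge) > 0) {
      W <- panel$dosage[, causal_ge, drop = FALSE] * e
      .scale_component(as.vector(W %*% .draw_beta_ge(length(causal_ge),
                                                     spec$beta_ge_dist)),
                       spec$r2_gwei)
    } else numeric(n)
    resid_var <- 1 - spec$r2_gw - spec$r2_gwei - uc_share
    if (resid_var <= 0) stop("infeasible correlation budget for the outcome")
    y <- comp_g + comp_ge + .scale_component(uc, uc_share) +
      .scale_component(stats::rnorm(n), resid_var)
    realized <- c(r2_gw = stats::var(comp_g),
                  r2_gwei = if (length(causal_ge) > 0) stats::var(comp_ge) else 0,
                  r2_e_on_y = 0) / stats::var(y)
    .audit_cohort(realized[1:2], c(spec$r2_gw, spec$r2_gwei), n)
    structure(list(y = y, e = e,
                   truth = list(r2_gw = spec$r2_gw, r2_gwei = spec$r2_gwei,
                                r2_e_on_y = 0,
                                collider_r2 = spec$collider_r2,
                                collider_r2_realized = stats::cor(y, e)^2,
                                realized = realized),
                   causal_g = causal_g, causal_ge = causal_ge, uc = uc,
                   outcome_type = "continuous",
                   exposure_type = "continuous",
                   prevalence = NULL, spec = spec),
              class = "simulated_cohort")
  })
}

#' Simulate a cohort and dispatch on the scenario's model
#'
#' @inheritParams simulate_base
#' @return A `simulated_cohort`.
#' @export
simulate_cohort <- function(spec, panel, seed = NULL) {
  if (spec$model == "collider") simulate_collider(spec, panel, seed = seed)
  else simulate_base(spec, panel, seed = seed)
}

#' Simulate a dichotomous outcome by thresholding a liability
#'
#' Generates a continuous liability under the base scenario and dichotomizes
#' it at the (1 - prevalence) quantile. Truth values remain on the liability
#' scale.
#'
#' @inheritParams simulate_base
#' @param prevalence Case fraction in (0, 1).
#' @return A `simulated_cohort` with a 0/1 outcome and recorded prevalence.
#' @export
simulate_dichotomous_outcome <- function(spec, panel, prevalence = 0.5,
                                         seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  cohort <- simulate_base(spec, panel, seed = seed)
  thr <- stats::quantile(cohort$y, 1 - prevalence)
  cohort$y <- as.numeric(cohort$y > thr)
  cohort$outcome_type <- "dichotomous"
  cohort$prevalence <- mean(cohort$y)
  cohort
}

#' Mean-impute a fraction of exposure and/or outcome values
#'
#' Replaces randomly selected entries with the sample mean of the remaining
#' entries, either in the same individuals for both variables or in disjoint
#' sets -- the two designs that respectively inflate and attenuate
#' downstream interaction estimates.
#'
#' @param cohort A `simulated_cohort`.
#' @param frac_e Fraction of exposure values to impute, in \[0, 1).
#' @param frac_y Fraction of outcome values to impute, in \[0, 1).
#' @param same_individuals If `TRUE`, the same individuals are imputed for
#'   both variables (requires `frac_e == frac_y`); if `FALSE` the two sets
#'   are disjoint.
#' @param seed Integer seed.
#' @return The modified `simulated_cohort` (truth record unchanged).
#' @export
apply_mean_imputation <- function(cohort, frac_e = 0, frac_y = 0,
                                  same_individuals = FALSE, seed = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"),
            frac_e >= 0, frac_e < 1, frac_y >= 0, frac_y < 1)
  n <- length(cohort$y)
  with_seed(seed, {
    if (same_individuals) {
      if (frac_e != frac_y) {
        stop("same_individuals = TRUE requires frac_e == frac_y")
      }
      idx_e <- idx_y <- sample(n, round(frac_e * n))
    } else {
      idx_e <- sample(n, round(frac_e * n))
      idx_y <- sample(setdiff(seq_len(n), idx_e), round(frac_y * n))
    }
    if (length(idx_e) > 0) cohort$e[idx_e] <- mean(cohort$e[-idx_e])
    if (length(idx_y) > 0) cohort$y[idx_y] <- mean(cohort$y[-idx_y])
    cohort
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: n = %d, scenario %d (%s), truths gw = %.2f gwei = %.2f\n",
              length(x$y), x$spec$scenario, x$spec$model,
              x$truth$r2_gw, x$truth$r2_gwei))
  invisible(x)
}
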