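# Genome-wide aggregation of per-block adjusted R-squared values, the
# asymptotic variance of the squared multiple correlation, and the
# liability-scale transformation for dichotomous outcomes.

# Exact first two moments of the squared multiple correlation R2 of a
# response on m multivariate-normal predictors at sample size n when the
# population squared multiple correlation is rho2. Uses the classical
# mixture representation: R2 | J ~ Beta(m/2 + J, (n-m-1)/2) with J negative
# binomial (size (n-1)/2, success probability rho2). Equivalent to the
# hypergeometric-function moments of Stuart, Ord & Arnold; the series is
# truncated where the negative-binomial weight mass drops below 1e-14.
.r2_moments <- function(rho2, n, m) {
  b <- (n - m - 1) / 2
  if (rho2 <= 0) {
    a <- m / 2
    m1 <- a / (a + b)
    m2 <- a * (a + 1) / ((a + b) * (a + b + 1))
    return(c(mean = m1, var = m2 - m1^2))
  }
  size <- (n - 1) / 2
  prob <- 1 - rho2
  jlo <- stats::qnbinom(1e-14, size, prob)
  jhi <- stats::qnbinom(1e-14, size, prob, lower.tail = FALSE)
  j <- jlo:jhi
  w <- stats::dnbinom(j, size, prob)
  w <- w / sum(w)
  a <- m / 2 + j
  m1 <- sum(w * a / (a + b))
  m2 <- sum(w * a * (a + 1) / ((a + b) * (a + b + 1)))
  c(mean = m1, var = m2 - m1^2)
}

#' Asymptotic variance of a block's adjusted R-squared
#'
#' Sampling variance of the squared multiple correlation coefficient of a
#' response on `m` predictors at sample size `n`, evaluated at population
#' value `r2`, mapped to the adjusted scale by the factor
#' `((n - 1) / (n - m - 1))^2` and scaled by `(1 - r2_ey)` to account for
#' the outcome having been residualized on the exposure. The underlying
#' variance of the raw R-squared uses the exact Kendall-Stuart moments
#' (hypergeometric series) of the multivariate-normal sampling distribution.
#'
#' @param r2 Population squared multiple correlation, in \[0, 1).
#' @param n Sample size (must exceed `m + 1`).
#' @param m Number of predictors.
#' @param r2_ey Exposure-outcome coefficient of determination (default 0).
#' @return Non-negative variance of the adjusted R-squared.
#' @export
r2_variance <- function(r2, n, m, r2_ey = 0) {
  stopifnot(n > m + 1, r2 >= 0, r2 < 1, r2_ey >= 0, r2_ey <= 1)
  # The negative-binomial window widens as r2 -> 1 while the variance
  # itself vanishes; cap the evaluation point (exact fits produce adjusted
  # R2 of 1, far outside the regime where the variance matters).
  r2 <- min(r2, 0.99)
  v_raw <- .r2_moments(r2, n, m)[["var"]]
  (1 - r2_ey) * ((n - 1) / (n - m - 1))^2 * v_raw
}

#' Aggregate block results into a genome-wide estimate
#'
#' Sums adjusted R-squared over blocks, scales by `(1 - r2_ey)` to undo the
#' exposure residualization of the outcome, sums the per-block asymptotic
#' variances, and forms the 95 percent Wald confidence interval. Negative
#' genome-wide estimates are reported as-is, never truncated.
#'
#' @param blocks List of [block_r2()] results over disjoint SNP blocks with
#'   a common sample size.
#' @param r2_ey Exposure-outcome coefficient of determination.
#' @param outcome_type `"continuous"` or `"dichotomous"` (carried through for
#'   the liability transform).
#' @return A `gw_estimate` with fields `estimate`, `variance`, `ci`, `j`,
#'   `n`, `m_total`, `r2_ey`, `scale` and a per-block summary data frame.
#' @export
aggregate_blocks <- function(blocks, r2_ey = 0,
                             outcome_type = c("continuous", "dichotomous")) {
  outcome_type <- match.arg(outcome_type)
  if (length(blocks) == 0) stop("empty block list")
  stopifnot(all(vapply(blocks, inherits, logical(1), "block_r2")))
  n <- unique(vapply(blocks, `[[`, integer(1), "n"))
  if (length(n) != 1) stop("blocks were fitted at different sample sizes")
  adj <- vapply(blocks, `[[`, numeric(1), "r2_adj")
  vars <- vapply(blocks, `[[`, numeric(1), "variance")
  estimate <- (1 - r2_ey) * sum(adj)
  variance <- sum(vars)
  half <- 1.96 * sqrt(variance)
  structure(list(
    estimate = estimate, variance = variance,
    ci = c(lower = estimate - half, upper = estimate + half),
    j = length(blocks), n = n,
    m_total = sum(vapply(blocks, `[[`, integer(1), "m")),
    r2_ey = r2_ey, scale = "observed", outcome_type = outcome_type,
    blocks = data.frame(
      block = vapply(blocks, function(b) as.character(b$block), character(1)),
      m = vapply(blocks, `[[`, integer(1), "m"),
      r2_raw = vapply(blocks, `[[`, numeric(1), "r2_raw"),
      r2_adj = adj, variance = vars)),
    class = "gw_estimate")
}

#' @export
print.gw_estimate <- function(x, ...) {
  cat(sprintf("gw_estimate (%s scale): %.4f  95%% CI [%.4f, %.4f]\n",
              x$scale, x$estimate, x$ci[1], x$ci[2]))
  cat(sprintf("  j = %d blocks, n = %d, m_total = %d, r2_ey = %.4f\n",
              x$j, x$n, x$m_total, x$r2_ey))
  invisible(x)
}

#' Liability-scale transformation of a genome-wide estimate
#'
#' Converts an observed-scale estimate for a dichotomous outcome to the
#' liability scale with the Robertson-type multiplier
#' `K^2 (1-K)^2 / (z^2 P (1-P))`, where `K` is the population prevalence,
#' `P` the sample prevalence and `z` the standard-normal density at the
#' K-quantile. Point estimate and CI endpoints are multiplied by the factor
#' and the variance by its square.
#'
#' @param estimate A `gw_estimate` for a dichotomous outcome on the observed
#'   scale.
#' @param sample_prevalence Case fraction in the analyzed sample, in (0, 1).
#' @param population_prevalence Population case prevalence, in (0, 1).
#' @return The transformed `gw_estimate` with `scale = "liability"`.
#' @export
liability_transform <- function(estimate, sample_prevalence,
                                population_prevalence) {
  stopifnot(inherits(estimate, "gw_estimate"))
  if (!identical(estimate$outcome_type, "dichotomous")) {
    stop("liability transform applies to dichotomous outcomes only")
  }
  if (identical(estimate$scale, "liability")) {
    stop("estimate is already on the liability scale")
  }
  K <- population_prevalence
  P <- sample_prevalence
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  if (estimate$estimate > 0.2) {
    warning("observed-scale estimate exceeds 0.2; the normality assumption ",
            "behind the liability transformation may be violated")
  }
  z <- stats::dnorm(stats::qnorm(K))
  mult <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  estimate$estimate <- estimate$estimate * mult
  estimate$ci <- estimate$ci * mult
  estimate$variance <- estimate$variance * mult^2
  estimate$scale <- "liability"
  estimate
}

#' Genome-wide heritability and GxE interaction variance
#'
#' Runs the full block-regression pipeline on a prepared cohort: for every
#' block of the plan it fits the outcome on the standardized genotype block
#' (additive genetic signal) and on the per-column normalized
#' genotype-exposure product block (interaction signal), aggregates both
#' series of adjusted R-squared values genome-wide with asymptotic variances
#' and Wald confidence intervals, and -- for dichotomous outcomes -- applies
#' the liability-scale transformation.
#'
#' @param panel A standardized `genotype_panel` (raw panels are standardized
#'   on the fly).
#' @param prepared A `prepared_cohort` from [prepare()], row-aligned with the
#'   panel.
#' @param plan A `block_plan`; defaults to [partition_blocks()] with `m_max`.
#' @param solver `"direct"` or `"cg"`.
#' @param m_max Block-size cap used when `plan` is `NULL`.
#' @param population_prevalence Population prevalence for the liability
#'   transform (defaults to the sample prevalence).
#' @return A `gxe_estimate`: list with `gw_estimate` components `g` and
#'   `gxe`.
#' @export
estimate_gxe <- function(panel, prepared, plan = NULL,
                         solver = c("direct", "cg"), m_max = 25000,
                         population_prevalence = NULL) {
  solver <- match.arg(solver)
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(prepared, "prepared_cohort"))
  if (n_ind(panel) != length(prepared$y)) {
    stop("panel and prepared cohort have different numbers of individuals")
  }
  if (!panel$standardized) panel <- standardize(panel)
  if (is.null(plan)) plan <- partition_blocks(panel, m_max = m_max)
  g_blocks <- vector("list", nrow(plan))
  ge_blocks <- vector("list", nrow(plan))
  for (b in seq_len(nrow(plan))) {
    idx <- plan$start[b]:plan$end[b]
    G <- panel$dosage[, idx, drop = FALSE]
    GE <- build_interaction_block(G, prepared$e, prepared$exposure_type)
    g_blocks[[b]] <- block_r2(G, prepared$y, solver = solver,
                              r2_ey = prepared$r2_ey, block_id = plan$block[b])
    ge_blocks[[b]] <- block_r2(GE, prepared$y, solver = solver,
                               r2_ey = prepared$r2_ey, block_id = plan$block[b])
  }
  g <- aggregate_blocks(g_blocks, r2_ey = prepared$r2_ey,
                        outcome_type = prepared$outcome_type)
  gxe <- aggregate_blocks(ge_blocks, r2_ey = prepared$r2_ey,
                          outcome_type = prepared$outcome_type)
  if (prepared$outcome_type == "dichotomous") {
    K <- population_prevalence %||% prepared$prevalence
    g <- liability_transform(g, prepared$prevalence, K)
    gxe <- liability_transform(gxe, prepared$prevalence, K)
  }
  structure(list(g = g, gxe = gxe), class = "gxe_estimate")
}

#' @export
print.gxe_estimate <- function(x, ...) {
  cat("Genome-wide estimates:\n  additive genetic (G):   ")
  cat(sprintf("%.4f [%.4f, %.4f]\n",
              x$g$estimate, x$g$ci[1], x$g$ci[2]))
  cat("  interaction (GxE):      ")
  cat(sprintf("%.4f [%.4f, %.4f]  (%s scale)\n",
              x$gxe$estimate, x$gxe$ci[1], x$gxe$ci[2], x$gxe$scale))
  invisible(x)
}

#' Write genome-wide estimates as a tab-separated table
#'
#' @param x A `gxe_estimate`.
#' @param path Output file path.
#' @param outcome,exposure Labels recorded in the table.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(x, path, outcome = "outcome", exposure = "exposure") {
  stopifnot(inherits(x, "gxe_estimate"))
  df <- data.frame(outcome = outcome, exposure = exposure,
                   scale = x$g$scale,
                   r2_gw = x$g$estimate,
                   r2_gw_ci_low = x$g$ci[1], r2_gw_ci_high = x$g$ci[2],
                   r2_gwei = x$gxe$estimate,
                   r2_gwei_ci_low = x$gxe$ci[1], r2_gwei_ci_high = x$gxe$ci[2],
                   j = x$g$j, n = x$g$n, m_total = x$g$m_total,
                   r2_ey = x$g$r2_ey)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
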