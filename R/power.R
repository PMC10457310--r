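# Detection power for genome-wide variance estimates via non-central-F
# sampling of per-block R-squared values.

#' Balanced block sizes for a total predictor count split into j blocks
#'
#' @param m_total Total number of predictors.
#' @param j Number of blocks.
#' @return Integer vector of block sizes differing by at most 1.
#' @export
balanced_blocks <- function(m_total, j) {
  base <- m_total %/% j
  extra <- m_total %% j
  c(rep(base + 1L, extra), rep(base, j - extra))
}

#' Power of the genome-wide Wald test at one grid point
#'
#' Per simulation, each block's observed R-squared is drawn from the
#' non-central F distribution of a multiple regression with `m_i` predictors
#' at sample size `n` whose noncentrality is implied by the block's share of
#' the true genome-wide R-squared (allocated proportionally to block size by
#' default). Block values are converted to adjusted R-squared, summed with
#' their asymptotic variances, and a two-sided Wald p-value formed; power is
#' the fraction of simulations with p below `alpha`.
#'
#' @param n Sample size.
#' @param blocks Integer vector of per-block predictor counts.
#' @param true_r2 True genome-wide R-squared, in \[0, 1).
#' @param n_sims Number of simulations (default 10000).
#' @param alpha Significance level of the two-sided Wald test.
#' @param seed Integer seed.
#' @param allocation `"proportional"` (to block size) or `"equal"` split of
#'   the true R-squared across blocks.
#' @return Power as a fraction, with attribute `"se"` carrying the binomial
#'   standard error `sqrt(p (1 - p) / n_sims)`.
#' @export
power_cell <- function(n, blocks, true_r2, n_sims = 10000, alpha = 0.05,
                       seed = NULL, allocation = c("proportional", "equal")) {
  allocation <- match.arg(allocation)
  blocks <- as.integer(blocks)
  stopifnot(true_r2 >= 0, true_r2 < 1, all(blocks >= 1), n_sims >= 1,
            alpha > 0, alpha < 1)
  if (n <= max(blocks) + 2) stop("sample size too small for the block sizes")
  j <- length(blocks)
  share <- switch(allocation,
                  proportional = blocks / sum(blocks),
                  equal = rep(1 / j, j))
  rho2 <- true_r2 * share
  with_seed(seed, {
    est <- numeric(n_sims)
    varsum <- numeric(n_sims)
    var_spline <- list() # variance of adjusted R2 vs rho2, per block size
    for (i in seq_len(j)) {
      m <- blocks[i]
      df2 <- n - m - 1
      lambda <- n * rho2[i] / (1 - rho2[i])
      f <- stats::rf(n_sims, df1 = m, df2 = df2, ncp = lambda)
      t <- f * m / df2
      r2 <- t / (1 + t)
      adj <- 1 - (1 - r2) * (n - 1) / df2
      key <- as.character(m)
      if (is.null(var_spline[[key]])) {
        hi <- min(max(stats::quantile(pmax(adj, 0), 0.999) * 1.5,
                      2 * true_r2 / j, 1e-4), 0.99)
        grid <- seq(0, hi, length.out = 48)
        vg <- vapply(grid, r2_variance, numeric(1), n = n, m = m)
        var_spline[[key]] <- stats::splinefun(grid, vg, method = "natural")
      }
      est <- est + adj
      varsum <- varsum + pmax(var_spline[[key]](pmin(pmax(adj, 0), 0.99)), 0)
    }
    z <- est / sqrt(varsum)
    p <- 2 * stats::pnorm(-abs(z))
    power <- mean(p < alpha)
    structure(power, se = sqrt(power * (1 - power) / n_sims))
  })
}

#' Power surface over sample sizes and true R-squared values
#'
#' Maps [power_cell()] over the Cartesian grid of sample sizes and true
#' genome-wide R-squared values, deterministically under `seed`.
#'
#' @param n_grid Vector of sample sizes.
#' @param r2_grid Vector of true genome-wide R-squared values.
#' @param blocks Integer vector of block sizes, or `NULL` to derive a
#'   balanced layout from `m_total` and `j`.
#' @param m_total,j Total predictors and block count used when `blocks` is
#'   `NULL`.
#' @param n_sims Simulations per cell.
#' @param alpha Significance level.
#' @param seed Integer master seed (one sub-stream per cell).
#' @param allocation Passed to [power_cell()].
#' @return A `power_grid` data frame with columns `n`, `true_r2`, `power`
#'   and `se`.
#' @export
power_surface <- function(n_grid, r2_grid, blocks = NULL, m_total = NULL,
                          j = NULL, n_sims = 1000, alpha = 0.05, seed = NULL,
                          allocation = c("proportional", "equal")) {
  allocation <- match.arg(allocation)
  if (is.null(blocks)) {
    stopifnot(!is.null(m_total), !is.null(j))
    blocks <- balanced_blocks(m_total, j)
  }
  cells <- expand.grid(n = n_grid, true_r2 = r2_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, "power_cell", i)
    p <- power_cell(cells$n[i], blocks, cells$true_r2[i], n_sims = n_sims,
                    alpha = alpha, seed = s, allocation = allocation)
    data.frame(n = cells$n[i], true_r2 = cells$true_r2[i],
               power = as.numeric(p), se = attr(p, "se"))
  })
  out <- do.call(rbind, res)
  class(out) <- c("power_grid", "data.frame")
  attr(out, "blocks") <- blocks
  attr(out, "n_sims") <- n_sims
  attr(out, "alpha") <- alpha
  out
}
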