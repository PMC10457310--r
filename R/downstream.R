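# Post-estimation analyses: univariate marginal/interaction scans,
# effect-direction concordance, MAF/LD-stratified estimates, variance
# recovery across association thresholds, and polygenic scores with
# interaction terms.

#' Per-SNP marginal and interaction association scan
#'
#' Splits individuals into discovery and validation sets, then on the
#' discovery set fits, for every SNP, (i) the outcome on the single SNP
#' (marginal effect and two-sided t-test p-value) and (ii) the outcome
#' jointly on the SNP and its normalized SNP-exposure product, testing the
#' interaction coefficient.
#'
#' @param panel A standardized `genotype_panel`.
#' @param prepared A `prepared_cohort`.
#' @param discovery_frac Fraction of individuals in the discovery set.
#' @param seed Integer seed fixing the split.
#' @return A `univariate_scan`: per-SNP table (`snp`, `beta_g`, `p_g`,
#'   `beta_ge`, `p_ge`) plus the discovery/validation index sets.
#' @export
univariate_scan <- function(panel, prepared, discovery_frac = 0.8,
                            seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(prepared, "prepared_cohort"))
  if (!panel$standardized) panel <- standardize(panel)
  n <- n_ind(panel)
  discovery <- with_seed(seed, sort(sample(n, round(discovery_frac * n))))
  validation <- setdiff(seq_len(n), discovery)
  nd <- length(discovery)

  G <- panel$dosage[discovery, , drop = FALSE]
  G <- sweep(G, 2, colMeans(G), "-")
  W <- build_interaction_block(panel$dosage[discovery, , drop = FALSE],
                               prepared$e[discovery], prepared$exposure_type)
  W <- sweep(W, 2, colMeans(W), "-")
  y <- prepared$y[discovery]
  y <- y - mean(y)
  yy <- sum(y^2)

  gg <- colSums(G^2)
  gy <- as.vector(crossprod(G, y))
  beta_g <- gy / gg
  rss_g <- pmax(yy - beta_g * gy, 0)
  se_g <- sqrt(rss_g / (nd - 2) / gg)
  p_g <- 2 * stats::pt(-abs(beta_g / se_g), df = nd - 2)

  # Joint two-predictor fit per SNP (g, g*e), closed-form 2x2 solve.
  ww <- colSums(W^2)
  gw <- colSums(G * W)
  wy <- as.vector(crossprod(W, y))
  det <- gg * ww - gw^2
  bg2 <- (ww * gy - gw * wy) / det
  bw2 <- (gg * wy - gw * gy) / det
  rss2 <- pmax(yy - bg2 * gy - bw2 * wy, 0)
  sigma2 <- rss2 / (nd - 3)
  se_w <- sqrt(sigma2 * gg / det)
  p_ge <- 2 * stats::pt(-abs(bw2 / se_w), df = nd - 3)

  structure(list(
    table = data.frame(snp = panel$snp_id, beta_g = beta_g, p_g = pmax(p_g, 1e-300),
                       beta_ge = bw2, p_ge = pmax(p_ge, 1e-300)),
    discovery = discovery, validation = validation),
    class = "univariate_scan")
}

#' @export
print.univariate_scan <- function(x, ...) {
  cat(sprintf("univariate_scan: %d SNPs, %d discovery / %d validation individuals\n",
              nrow(x$table), length(x$discovery), length(x$validation)))
  invisible(x)
}

# Greedy LD pruning over the whole panel, visiting SNPs by ascending
# priority value; a SNP is kept when its r^2 with every kept SNP stays at or
# below the threshold.
.prune_by_priority <- function(panel, priority, r2_max) {
  Z <- if (panel$standardized) panel$dosage else
    .scale_columns(panel$dosage)
  nm1 <- nrow(Z) - 1
  kept <- integer(0)
  for (j in order(priority)) {
    if (length(kept) == 0) { kept <- j; next }
    r <- as.vector(crossprod(Z[, kept, drop = FALSE], Z[, j])) / nm1
    if (all(r^2 <= r2_max)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Direction-of-effect concordance between marginal and interaction effects
#'
#' Among LD-pruned SNPs passing each p-value threshold (separately for the
#' marginal and the interaction p-value), computes the fraction of SNPs
#' whose marginal and interaction coefficient share a sign, and a two-sided
#' two-proportion Z-test of that fraction against the null value 0.5.
#'
#' @param scan A `univariate_scan`.
#' @param panel The `genotype_panel` the scan was run on (for LD pruning).
#' @param p_thresholds P-value thresholds applied to each criterion.
#' @param ld_prune_r2 Pairwise r^2 ceiling for the pruned SNP set; pruning is
#'   greedy by ascending interaction p-value.
#' @return Data frame with one row per (criterion, threshold): SNP count,
#'   concordant fraction, Z statistic and p-value (`NA`-flagged when no SNP
#'   passes).
#' @export
directionality <- function(scan, panel,
                           p_thresholds = c(1, 1e-1, 1e-2, 1e-3),
                           ld_prune_r2 = 0.1) {
  stopifnot(inherits(scan, "univariate_scan"))
  tab <- scan$table
  pruned <- .prune_by_priority(panel, tab$p_ge, ld_prune_r2)
  rows <- list()
  for (criterion in c("p_g", "p_ge")) {
    for (thr in p_thresholds) {
      idx <- pruned[tab[[criterion]][pruned] < thr]
      k <- length(idx)
      if (k == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          criterion = criterion, threshold = thr, n_snps = 0L,
          concordance = NA_real_, z = NA_real_, p_value = NA_real_)
        next
      }
      conc <- mean(sign(tab$beta_g[idx]) == sign(tab$beta_ge[idx]))
      z <- two_proportion_z(conc, 0.5, k, k)
      rows[[length(rows) + 1]] <- data.frame(
        criterion = criterion, threshold = thr, n_snps = k,
        concordance = conc, z = z, p_value = 2 * stats::pnorm(-abs(z)))
    }
  }
  do.call(rbind, rows)
}

#' Two-proportion Z statistic
#'
#' Pooled two-proportion Z statistic comparing proportions `p1` and `p2`
#' observed in samples of sizes `n1` and `n2`.
#'
#' @param p1,p2 Observed proportions.
#' @param n1,n2 Sample sizes.
#' @return The Z statistic.
#' @export
two_proportion_z <- function(p1, p2, n1, n2) {
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
}

# Estimate G and GxE variance over an arbitrary SNP subset and individual
# subset, re-blocking so every block keeps n > 10 m.
.estimate_subset <- function(panel, prepared, snps, individuals,
                             solver = "direct") {
  n <- length(individuals)
  m <- length(snps)
  if (m == 0) return(NULL)
  max_m <- max(1L, (n - 1L) %/% 10L)
  k <- ceiling(m / max_m)
  sizes <- balanced_blocks(m, k)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  y <- prepared$y[individuals]
  e <- prepared$e[individuals]
  g_blocks <- list()
  ge_blocks <- list()
  for (b in seq_len(k)) {
    cols <- snps[starts[b]:ends[b]]
    G <- panel$dosage[individuals, cols, drop = FALSE]
    G <- tryCatch(.scale_columns(G), error = function(err) {
      sweep(G, 2, colMeans(G), "-") # tolerate degenerate subset columns
    })
    GE <- build_interaction_block(G, e, prepared$exposure_type)
    g_blocks[[b]] <- block_r2(G, y, solver = solver, r2_ey = prepared$r2_ey,
                              block_id = b)
    ge_blocks[[b]] <- block_r2(GE, y, solver = solver, r2_ey = prepared$r2_ey,
                               block_id = b)
  }
  list(g = aggregate_blocks(g_blocks, r2_ey = prepared$r2_ey),
       gxe = aggregate_blocks(ge_blocks, r2_ey = prepared$r2_ey))
}

#' MAF- and LD-stratified per-SNP variance estimates
#'
#' Stratifies SNPs into MAF bins crossed with LD-score quantile bins, runs
#' the block estimator within each stratum, and divides each estimate by the
#' stratum's SNP count to give a per-SNP R-squared comparable across bins.
#'
#' @param panel A standardized `genotype_panel` with `maf` and `ldscore`
#'   metadata.
#' @param prepared A `prepared_cohort`.
#' @param maf_breaks MAF bin edges (default 0.05-0.1-0.2-0.3-0.4-0.5).
#' @param ld_probs LD-score quantile probabilities bounding the LD bins
#'   (default quartile cuts at 0.25/0.5/0.75/0.9; SNPs above the top cut are
#'   left unbinned).
#' @param solver Passed to the block solver.
#' @return Data frame with one row per stratum: SNP count, G and GxE
#'   estimates and their per-SNP values (`NA` for empty strata).
#' @export
stratified_r2 <- function(panel, prepared,
                          maf_breaks = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                          ld_probs = c(0, 0.25, 0.5, 0.75, 0.9),
                          solver = "direct") {
  stopifnot(!is.null(panel$maf))
  ld <- panel$ldscore %||% compute_ldscore(panel)
  ld_cuts <- stats::quantile(ld, probs = ld_probs)
  maf_bin <- cut(panel$maf, breaks = maf_breaks, include.lowest = TRUE)
  ld_bin <- cut(ld, breaks = ld_cuts, include.lowest = TRUE)
  rows <- list()
  for (mb in levels(maf_bin)) {
    for (lb in levels(ld_bin)) {
      snps <- which(!is.na(maf_bin) & !is.na(ld_bin) &
                      maf_bin == mb & ld_bin == lb)
      if (length(snps) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          maf_bin = mb, ld_bin = lb, m = 0L, r2_g = NA_real_,
          r2_g_per_snp = NA_real_, r2_gxe = NA_real_,
          r2_gxe_per_snp = NA_real_)
        next
      }
      est <- .estimate_subset(panel, prepared, snps,
                              seq_len(n_ind(panel)), solver = solver)
      rows[[length(rows) + 1]] <- data.frame(
        maf_bin = mb, ld_bin = lb, m = length(snps),
        r2_g = est$g$estimate,
        r2_g_per_snp = est$g$estimate / length(snps),
        r2_gxe = est$gxe$estimate,
        r2_gxe_per_snp = est$gxe$estimate / length(snps))
    }
  }
  do.call(rbind, rows)
}

#' Variance recovery across association thresholds
#'
#' For each p-value threshold applied to the discovery-set marginal
#' (`p_g`) or interaction (`p_ge`) p-values, estimates the G and GxE
#' variance over the selected SNP subset in the validation set (re-blocked
#' to keep n > 10 m) and reports it as a fraction of the all-SNP validation
#' estimate.
#'
#' @param scan A `univariate_scan` (fixes the discovery/validation split).
#' @param panel The `genotype_panel` scanned.
#' @param prepared The `prepared_cohort`.
#' @param thresholds P-value thresholds (default 1, 1e-1, ..., 1e-5).
#' @param solver Passed to the block solver.
#' @return Data frame with one row per (criterion, threshold): selected SNP
#'   count, validation G and GxE estimates, and recovery fractions relative
#'   to the all-SNP estimates.
#' @export
recovery_analysis <- function(scan, panel, prepared,
                              thresholds = 10^(0:-5), solver = "direct") {
  stopifnot(inherits(scan, "univariate_scan"))
  val <- scan$validation
  all_est <- .estimate_subset(panel, prepared, seq_len(n_snp(panel)), val,
                              solver = solver)
  rows <- list()
  for (criterion in c("p_g", "p_ge")) {
    for (thr in thresholds) {
      snps <- which(scan$table[[criterion]] < thr)
      est <- .estimate_subset(panel, prepared, snps, val, solver = solver)
      rows[[length(rows) + 1]] <- data.frame(
        criterion = criterion, threshold = thr, n_snps = length(snps),
        r2_g_val = if (is.null(est)) NA_real_ else est$g$estimate,
        r2_gxe_val = if (is.null(est)) NA_real_ else est$gxe$estimate,
        recovery_g = if (is.null(est)) NA_real_ else
          est$g$estimate / all_est$g$estimate,
        recovery_gxe = if (is.null(est)) NA_real_ else
          est$gxe$estimate / all_est$gxe$estimate)
    }
  }
  do.call(rbind, rows)
}

#' Polygenic scores with and without interaction terms
#'
#' Selects SNPs by the discovery-set marginal p-value threshold (set `O`)
#' and interactions by the interaction p-value threshold among already
#' selected SNPs (set `P`, a subset of `O`), fits joint multiple-regression
#' coefficients on the discovery set as a single block, and evaluates both
#' scores on the validation set: the genetic score sums `G beta_G` over `O`;
#' the interaction-aware score adds `(G x E) beta_GE` over `P`. Prediction
#' R-squared of each score and a paired-bootstrap p-value for the
#' improvement of the interaction-aware score are recorded.
#'
#' @param scan A `univariate_scan`.
#' @param panel The `genotype_panel`.
#' @param prepared The `prepared_cohort`.
#' @param p_g_threshold Marginal p-value threshold for SNP inclusion.
#' @param p_ge_threshold Interaction p-value threshold for interaction
#'   inclusion.
#' @param n_boot Paired bootstrap resamples for the improvement test.
#' @param seed Integer seed for the bootstrap.
#' @param solver Passed to the joint fit.
#' @return A `polygenic_score`: per-individual scores on the validation set,
#'   SNP and interaction index sets, prediction R-squared values and the
#'   improvement p-value.
#' @export
build_ps <- function(scan, panel, prepared, p_g_threshold = 1e-2,
                     p_ge_threshold = 1e-2, n_boot = 1000, seed = NULL,
                     solver = "direct") {
  stopifnot(inherits(scan, "univariate_scan"))
  O <- which(scan$table$p_g < p_g_threshold)
  if (length(O) == 0) stop("empty SNP selection at the marginal threshold")
  P <- O[scan$table$p_ge[O] < p_ge_threshold]
  d <- scan$discovery
  v <- scan$validation
  yd <- prepared$y[d]
  yv <- prepared$y[v]

  Gd <- panel$dosage[d, O, drop = FALSE]
  Gv <- panel$dosage[v, O, drop = FALSE]
  beta_g <- solve_direct(Gd, yd)
  ps_g <- as.vector(Gv %*% beta_g)

  if (length(P) > 0) {
    Wd <- build_interaction_block(panel$dosage[d, P, drop = FALSE],
                                  prepared$e[d], prepared$exposure_type)
    Wv <- build_interaction_block(panel$dosage[v, P, drop = FALSE],
                                  prepared$e[v], prepared$exposure_type)
    beta_joint <- solve_direct(cbind(Gd, Wd), yd)
    ps_ge <- as.vector(cbind(Gv, Wv) %*% beta_joint)
  } else {
    ps_ge <- ps_g
  }

  r2_g <- stats::cor(ps_g, yv)^2
  r2_ge <- stats::cor(ps_ge, yv)^2
  p_improvement <- with_seed(seed, {
    diffs <- replicate(n_boot, {
      idx <- sample(length(v), replace = TRUE)
      stats::cor(ps_ge[idx], yv[idx])^2 - stats::cor(ps_g[idx], yv[idx])^2
    })
    mean(diffs <= 0)
  })
  structure(list(
    scores = data.frame(id = panel$individual_id[v], ps_g = ps_g,
                        ps_ge = ps_ge),
    snps = O, interactions = P, r2_g = r2_g, r2_ge = r2_ge,
    p_improvement = p_improvement),
    class = "polygenic_score")
}

#' @export
print.polygenic_score <- function(x, ...) {
  cat(sprintf("polygenic_score: |O| = %d SNPs, |P| = %d interactions\n",
              length(x$snps), length(x$interactions)))
  cat(sprintf("  validation R2: genetic %.4f, with interactions %.4f (p_improve = %.3f)\n",
              x$r2_g, x$r2_ge, x$p_improvement))
  invisible(x)
}
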