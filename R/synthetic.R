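#' Generate a synthetic LD-structured genotype panel
#'
#' Emulates a post-QC biobank genotype panel at reduced scale. Each SNP's
#' dosage is the sum of two independent haplotypes; a haplotype carries the
#' alternate allele when a latent AR(1) Gaussian (lag-1 correlation `ld_rho`
#' within a chromosome, independent across chromosomes and haplotypes) falls
#' below the per-SNP MAF quantile. Target MAFs are drawn uniformly from
#' `maf_range`; the panel records realized (sample) MAFs and windowed LD
#' scores. Deterministic under `seed`.
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range Interval of target minor allele frequencies, within
#'   \[0.05, 0.5\].
#' @param ld_rho Lag-1 correlation of the latent Gaussian, in \[0, 1).
#' @param n_chrom Number of chromosomes SNPs are spread over (as evenly as
#'   possible).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A raw (unstandardized) `genotype_panel`.
#' @export
generate_synthetic_panel <- function(n, m, maf_range = c(0.05, 0.5),
                                     ld_rho = 0.6, n_chrom = 2, seed = NULL) {
  stopifnot(n >= 2, m >= 1, n_chrom >= 1, n_chrom <= m)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within [0.05, 0.5]")
  }
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    base <- m %/% n_chrom
    extra <- m %% n_chrom
    sizes <- c(rep(base + 1L, extra), rep(base, n_chrom - extra))
    chrom <- rep(seq_len(n_chrom), times = sizes)
    pos <- unlist(lapply(sizes, function(s) seq_len(s) * 1000L))

    dosage <- matrix(0, n, m)
    thr <- stats::qnorm(maf)
    s <- sqrt(1 - ld_rho^2)
    z1 <- z2 <- numeric(n)
    prev_chrom <- 0L
    for (j in seq_len(m)) {
      if (chrom[j] != prev_chrom) { # LD does not cross chromosome boundaries
        z1 <- stats::rnorm(n)
        z2 <- stats::rnorm(n)
        prev_chrom <- chrom[j]
      } else {
        z1 <- ld_rho * z1 + s * stats::rnorm(n)
        z2 <- ld_rho * z2 + s * stats::rnorm(n)
      }
      dosage[, j] <- (z1 < thr[j]) + (z2 < thr[j])
    }
    # Guard against monomorphic draws at tiny n: redraw marginally.
    mono <- which(colMeans(dosage^2) - colMeans(dosage)^2 == 0)
    for (j in mono) {
      for (try in 1:100) {
        dj <- stats::rbinom(n, 2, maf[j])
        if (stats::var(dj) > 0) { dosage[, j] <- dj; break }
      }
    }
    panel <- genotype_panel(dosage, chrom = chrom, pos = pos)
    panel$ldscore <- compute_ldscore(panel)
    panel
  })
}
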