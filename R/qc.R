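#' Quality-filter a genotype panel by MAF and pairwise LD
#'
#' Removes SNPs with minor allele frequency below `maf_min` (or monomorphic)
#' and then LD-prunes: scanning left to right within each chromosome, a SNP
#' is dropped when its squared correlation with any retained SNP among the
#' preceding `window` retained SNPs exceeds `ld_r2_max` (the earlier SNP of a
#' violating pair is kept). The scan over retained SNPs makes a second pass a
#' no-op, so filtering is idempotent.
#'
#' @param panel A raw (unstandardized) `genotype_panel`.
#' @param maf_min Minimum minor allele frequency, in (0, 0.5).
#' @param ld_r2_max Maximum allowed squared correlation, in (0, 1].
#' @param window Number of preceding retained SNPs compared against.
#' @return The filtered `genotype_panel`, with an attribute `"qc_report"`
#'   listing counts removed per filter. Errors if no SNP survives.
#' @export
qc_filter <- function(panel, maf_min = 0.05, ld_r2_max = 0.9, window = 1000) {
  stopifnot(maf_min > 0, maf_min < 0.5, ld_r2_max > 0, ld_r2_max <= 1,
            window >= 1)
  if (panel$standardized) {
    stop("qc_filter() expects raw dosages; apply before standardize()")
  }
  m <- n_snp(panel)
  maf <- .dosage_maf(panel$dosage)
  sds <- apply(panel$dosage, 2, stats::sd, na.rm = TRUE)
  pass_maf <- maf >= maf_min & sds > 0
  n_maf_removed <- sum(!pass_maf)
  if (!any(pass_maf)) stop("all SNPs removed by the MAF filter: empty panel")

  keep_idx <- which(pass_maf)
  retained <- logical(length(keep_idx))
  X <- panel$dosage[, keep_idx, drop = FALSE]
  if (anyNA(X)) { # mean-impute only for the correlation computation
    for (j in which(colSums(is.na(X)) > 0)) {
      xj <- X[, j]; xj[is.na(xj)] <- mean(xj, na.rm = TRUE); X[, j] <- xj
    }
  }
  Z <- .scale_columns(X)
  nm1 <- nrow(Z) - 1
  chrom_of <- panel$chrom[keep_idx]
  for (ch in unique(chrom_of)) {
    cols <- which(chrom_of == ch)
    kept <- integer(0)
    for (j in cols) {
      cand <- kept[max(1, length(kept) - window + 1):length(kept)]
      ok <- TRUE
      if (length(kept) > 0) {
        r <- crossprod(Z[, cand, drop = FALSE], Z[, j]) / nm1
        ok <- all(r^2 <= ld_r2_max)
      }
      if (ok) {
        kept <- c(kept, j)
        retained[j] <- TRUE
      }
    }
  }
  n_ld_removed <- sum(!retained)
  final <- keep_idx[retained]
  if (length(final) == 0) stop("all SNPs removed by LD pruning: empty panel")
  out <- subset_panel(panel, snps = final)
  out$maf <- maf[final]
  out$ldscore <- compute_ldscore(out)
  attr(out, "qc_report") <- list(n_input = m,
                                 n_maf_removed = n_maf_removed,
                                 n_ld_removed = n_ld_removed,
                                 n_retained = length(final))
  out
}

#' Partition retained SNPs into chromosome-bounded regression blocks
#'
#' Each chromosome with `m_c` SNPs is split into `ceiling(m_c / m_max)`
#' blocks -- the minimum possible -- with sizes as equal as possible
#' (differing by at most 1). Estimation validity requires the sample size to
#' exceed ten times the largest block; violating chromosomes raise an error.
#'
#' @param panel A `genotype_panel` sorted by (chromosome, position).
#' @param m_max Maximum SNPs per block (default 25000).
#' @param n Sample size used for the n > 10 m check (default the panel's).
#' @return A `block_plan` data frame with columns `block`, `chrom`, `start`,
#'   `end` (1-based inclusive column indices into the panel) and `m`.
#' @export
partition_blocks <- function(panel, m_max = 25000, n = n_ind(panel)) {
  stopifnot(m_max >= 1)
  rows <- list()
  offset <- 0L
  bid <- 0L
  for (ch in unique(panel$chrom)) {
    mc <- sum(panel$chrom == ch)
    k <- ceiling(mc / m_max)
    base <- mc %/% k
    extra <- mc %% k
    sizes <- c(rep(base + 1L, extra), rep(base, k - extra))
    if (n <= 10 * max(sizes)) {
      stop(sprintf(
        "chromosome %s: balanced split gives blocks of %d SNPs but n = %d <= 10 m; %s",
        ch, max(sizes), n, "reduce m_max or supply more individuals"))
    }
    ends <- offset + cumsum(sizes)
    starts <- c(offset + 1L, utils::head(ends, -1) + 1L)
    for (b in seq_len(k)) {
      bid <- bid + 1L
      rows[[bid]] <- data.frame(block = bid, chrom = ch, start = starts[b],
                                end = ends[b], m = sizes[b])
    }
    offset <- offset + mc
  }
  plan <- do.call(rbind, rows)
  class(plan) <- c("block_plan", "data.frame")
  attr(plan, "m_max") <- m_max
  attr(plan, "n") <- n
  plan
}
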