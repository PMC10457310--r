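#' Genotype panel
#'
#' Container for an individuals-by-SNPs dosage matrix with per-SNP metadata.
#' Dosages use additive coding \{0, 1, 2\} before standardization and are
#' real-valued (column mean 0, standard deviation 1) afterwards. SNPs are
#' kept sorted by (chromosome, position).
#'
#' @param dosage Numeric matrix, n individuals x m SNPs.
#' @param chrom Integer vector of chromosome codes, length m.
#' @param pos Integer vector of base-pair positions (1-based), length m.
#' @param snp_id Character vector of SNP identifiers; generated if `NULL`.
#' @param maf Minor allele frequencies in (0, 0.5]; computed from raw dosages
#'   when `NULL`.
#' @param ldscore Per-SNP LD scores (>= 1, self included); computed lazily by
#'   [compute_ldscore()] when `NULL`.
#' @param individual_id Character vector of individual identifiers; generated
#'   if `NULL`.
#' @param standardized Logical flag: have columns been standardized?
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, chrom, pos, snp_id = NULL, maf = NULL,
                           ldscore = NULL, individual_id = NULL,
                           standardized = FALSE) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  n <- nrow(dosage)
  stopifnot(length(chrom) == m, length(pos) == m)
  chrom <- as.integer(chrom)
  pos <- as.integer(pos)
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    dosage <- dosage[, ord, drop = FALSE]
    chrom <- chrom[ord]
    pos <- pos[ord]
    if (!is.null(snp_id)) snp_id <- snp_id[ord]
    if (!is.null(maf)) maf <- maf[ord]
    if (!is.null(ldscore)) ldscore <- ldscore[ord]
  }
  if (is.null(snp_id)) snp_id <- sprintf("chr%d_snp%d", chrom, pos)
  if (is.null(individual_id)) individual_id <- sprintf("ind%d", seq_len(n))
  if (is.null(maf) && !standardized) maf <- .dosage_maf(dosage)
  structure(
    list(dosage = dosage, snp_id = as.character(snp_id), chrom = chrom,
         pos = pos, maf = maf, ldscore = ldscore,
         individual_id = as.character(individual_id),
         standardized = isTRUE(standardized)),
    class = "genotype_panel")
}

# Folded allele frequency of the counted allele; NA dosages are skipped.
.dosage_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs (%d chromosome%s)\n",
              n_ind(x), n_snp(x), length(unique(x$chrom)),
              if (length(unique(x$chrom)) > 1) "s" else ""))
  cat(sprintf("  standardized: %s\n", x$standardized))
  if (!is.null(x$maf)) {
    cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(x$maf), max(x$maf)))
  }
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_ind <- function(panel) nrow(panel$dosage)

#' Number of SNPs in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_snp <- function(panel) ncol(panel$dosage)

#' Subset a panel by SNP and/or individual indices
#'
#' @param panel A `genotype_panel`.
#' @param snps Integer indices of SNPs to keep (default all).
#' @param individuals Integer indices of individuals to keep (default all).
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, snps = seq_len(n_snp(panel)),
                         individuals = seq_len(n_ind(panel))) {
  genotype_panel(panel$dosage[individuals, snps, drop = FALSE],
                 chrom = panel$chrom[snps], pos = panel$pos[snps],
                 snp_id = panel$snp_id[snps],
                 maf = if (!is.null(panel$maf)) panel$maf[snps],
                 ldscore = if (!is.null(panel$ldscore)) panel$ldscore[snps],
                 individual_id = panel$individual_id[individuals],
                 standardized = panel$standardized)
}

#' Windowed LD scores
#'
#' The LD score of a SNP is the sum of squared sample correlations with all
#' SNPs within `window` positions on the same chromosome, including itself
#' (so every score is >= 1).
#'
#' @param panel A `genotype_panel`.
#' @param window Number of flanking SNPs on each side to include.
#' @return Numeric vector of LD scores, one per SNP.
#' @export
compute_ldscore <- function(panel, window = 50) {
  m <- n_snp(panel)
  out <- rep(1, m)
  chunk_size <- 512L
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    mc <- length(idx)
    if (mc < 2) next
    Z <- .scale_columns(panel$dosage[, idx, drop = FALSE])
    nm1 <- nrow(Z) - 1
    for (cs in seq(1, mc, by = chunk_size)) {
      ce <- min(cs + chunk_size - 1, mc)
      ns <- max(1, cs - window)
      ne <- min(mc, ce + window)
      R <- crossprod(Z[, ns:ne, drop = FALSE], Z[, cs:ce, drop = FALSE]) / nm1
      for (k in seq_len(ce - cs + 1)) {
        j <- cs + k - 1 # column index within the chromosome
        nb <- setdiff(max(1, j - window):min(mc, j + window), j)
        out[idx[j]] <- out[idx[j]] + sum(R[nb - ns + 1, k]^2)
      }
    }
  }
  out
}

#' Standardize a genotype panel
#'
#' Centers every SNP column to mean 0 and scales to standard deviation 1.
#' Sporadic missing hard calls are mean-imputed per SNP beforehand, with a
#' warning; monomorphic (zero-variance) columns are an error since the MAF
#' filter should have removed them.
#'
#' @param panel A `genotype_panel` with raw or already-standardized dosages.
#' @return A standardized `genotype_panel`. Standardizing an
#'   already-standardized panel is a no-op up to numerical tolerance.
#' @export
standardize <- function(panel) {
  X <- panel$dosage
  if (anyNA(X)) {
    warning("missing dosages mean-imputed per SNP before standardization")
    for (j in which(colSums(is.na(X)) > 0)) {
      xj <- X[, j]
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      X[, j] <- xj
    }
  }
  Z <- tryCatch(.scale_columns(X), error = function(e) {
    stop("monomorphic SNP column(s) cannot be standardized; ",
         "apply the MAF filter first (", conditionMessage(e), ")")
  })
  panel$dosage <- Z
  panel$standardized <- TRUE
  panel
}
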