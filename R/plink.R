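# PLINK 1.9 binary genotype triple (.bed/.bim/.fam) input and output.
# The .bed format is SNP-major: magic bytes 0x6c 0x1b 0x01 followed by
# ceiling(n/4) bytes per SNP, two bits per individual (low bits first):
# 00 = homozygous A1 (dosage 2 of the counted allele), 10 = heterozygous,
# 11 = homozygous A2 (dosage 0), 01 = missing.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1.9 binary genotype triple
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must all exist.
#' @return A raw `genotype_panel` with missing genotypes as `NA`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing PLINK file member(s): ", paste(missing, collapse = ", "))
  }
  bim <- utils::read.table(paths[2], header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  nb <- ceiling(n / 4)
  size <- file.size(paths[1])
  raw <- readBin(paths[1], "raw", n = size)
  if (length(raw) < 3 || !identical(raw[1:3], .BED_MAGIC)) {
    stop("malformed .bed magic bytes in ", paths[1])
  }
  if (length(raw) != 3 + nb * m) {
    stop(sprintf(".bed/.bim/.fam dimension mismatch: %d bytes of genotypes for %d SNPs x %d individuals (expected %d)",
                 length(raw) - 3, m, n, nb * m))
  }
  body <- as.integer(raw[-(1:3)])
  # Unpack the four 2-bit codes of every byte, then map codes to dosages.
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  lookup <- c(2, NA, 1, 0) # code 0,1,2,3
  dosage <- matrix(lookup[codes + 1L], nrow = 4 * nb)[seq_len(n), , drop = FALSE]
  genotype_panel(dosage, chrom = bim$chrom, pos = bim$pos, snp_id = bim$id,
                 individual_id = fam[[2]])
}

#' Write a genotype panel as a PLINK 1.9 binary triple
#'
#' @param panel A raw (unstandardized) `genotype_panel` with dosages in
#'   \{0, 1, 2, NA\}.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  if (panel$standardized) {
    stop("write_plink() needs raw additive dosages, not a standardized panel")
  }
  X <- panel$dosage
  if (!all(X %in% c(0, 1, 2, NA))) stop("dosages must be hard calls in {0, 1, 2}")
  n <- nrow(X)
  m <- ncol(X)
  nb <- ceiling(n / 4)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, 4 * nb, m)
  code[seq_len(n), ] <- ifelse(is.na(X), 1L, c(3L, 2L, 0L)[X + 1L])
  code[-seq_len(n), ] <- 0L # padding bits
  bytes <- code[seq(1, 4 * nb, by = 4), , drop = FALSE] +
    4L * code[seq(2, 4 * nb, by = 4), , drop = FALSE] +
    16L * code[seq(3, 4 * nb, by = 4), , drop = FALSE] +
    64L * code[seq(4, 4 * nb, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(panel$chrom, panel$snp_id, 0, panel$pos, "A", "G"),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$individual_id, panel$individual_id, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
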