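# PLINK 1 binary (.bed/.bim/.fam) codec.
#
# The .bed payload is SNP-major: each variant occupies ceil(n/4) bytes, four
# samples per byte, two bits per sample starting at the low-order bits.
# 2-bit codes: 00 = homozygous A1, 01 = missing, 10 = heterozygous,
# 11 = homozygous A2. We count copies of A1 (the effect allele), so the
# dosage map is 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA.

.plink_magic <- as.raw(c(0x6c, 0x1b))

# dosage value for each 2-bit code 0..3
.plink_code_to_dosage <- c(2, NA_real_, 1, 0)

# 256 x 4 lookup: dosages of the four samples packed in one byte
.plink_byte_lut <- local({
  b <- 0:255
  vapply(0:3, function(s) .plink_code_to_dosage[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L],
         numeric(256))
})

#' Read a PLINK 1 binary genotype file set
#'
#' Decodes the 2-bit SNP-major `.bed` encoding into effect-allele dosages.
#' The effect allele is PLINK A1 (fifth column of the `.bim` file) so that
#' homozygous-A1 genotypes decode to dosage 2, heterozygotes to 1,
#' homozygous-A2 to 0 and the missing code to `NA`.
#'
#' @param bed_path Path to the `.bed` file (or a bare prefix; `.bim`/`.fam`
#'   paths are derived when not given).
#' @param bim_path,fam_path Paths to the variant and sample files.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (!grepl("\\.bed$", bed_path)) {
    prefix <- bed_path
    bed_path <- paste0(prefix, ".bed")
  } else prefix <- sub("\\.bed$", "", bed_path)
  if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
  if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("FID", "IID", "PAT", "MAT", "SEX", "PHENO"))
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "variant_id", "cm",
                                         "position", "A1", "A2"))
  n <- nrow(fam); p <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != .plink_magic[1] || raw[2] != .plink_magic[2])
    stop(".bed format error: wrong magic bytes (expected 0x6c 0x1b)", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop(".bed format error: only SNP-major mode (0x01) is supported", call. = FALSE)
  bpc <- ceiling(n / 4)  # bytes per variant column
  if (length(raw) != 3 + bpc * p)
    stop(sprintf(".bed corruption: payload is %d bytes, expected ceil(n/4)*p = %d",
                 length(raw) - 3L, bpc * p), call. = FALSE)

  if (p == 0 || n == 0) {
    X <- matrix(numeric(0), nrow = n, ncol = p)
  } else {
    payload <- as.integer(raw[-(1:3)]) + 1L          # 1-based into the LUT
    # decode all bytes at once: (bpc*p) x 4 dosage block, then trim padding
    dec <- .plink_byte_lut[payload, , drop = FALSE]
    dec <- matrix(t(dec), nrow = 4L * bpc)           # samples down the rows, per variant
    X <- dec[seq_len(n), , drop = FALSE]
  }

  genotype_matrix(
    X,
    variants = tibble::tibble(
      variant_id = as.character(bim$variant_id),
      chromosome = as.character(bim$chromosome),
      position = as.integer(bim$position),
      effect_allele = as.character(bim$A1),
      other_allele = as.character(bim$A2)
    ),
    sample_ids = as.character(fam$IID)
  )
}

#' Write a genotype matrix as a PLINK 1 binary file set
#'
#' Inverse of [read_plink()]. Dosages must be hard calls (0, 1, 2 or `NA`);
#' imputed fractional dosages cannot be represented in the 2-bit encoding.
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix; writes `prefix.bed/.bim/.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  if (!all(is.na(X) | X %in% c(0, 1, 2)))
    stop("write_plink requires hard-call dosages in {0, 1, 2, NA}", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  # dosage -> 2-bit code
  codes <- matrix(1L, nrow = n, ncol = p)            # missing = 01
  codes[!is.na(X) & X == 2] <- 0L
  codes[!is.na(X) & X == 1] <- 2L
  codes[!is.na(X) & X == 0] <- 3L
  bpc <- ceiling(n / 4)
  payload <- raw(bpc * p)
  if (n > 0 && p > 0) {
    padded <- matrix(0L, nrow = 4L * bpc, ncol = p)  # PLINK pads trailing bits with zeros
    padded[seq_len(n), ] <- codes
    shifts <- 2L * (0:3)
    byte_mat <- matrix(0L, nrow = bpc, ncol = p)
    for (s in 1:4) {
      rows <- seq(s, by = 4L, length.out = bpc)
      byte_mat <- byte_mat + bitwShiftL(padded[rows, , drop = FALSE], shifts[s])
    }
    payload <- as.raw(byte_mat)
  }
  writeBin(c(.plink_magic, as.raw(0x01), payload), paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(G$variants$chromosome, G$variants$variant_id, 0L,
               G$variants$position, G$variants$effect_allele,
               G$variants$other_allele),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  utils::write.table(
    data.frame(G$sample_ids, G$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}
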