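#' PLINK 1 binary input/output
#'
#' Readers and writers for the PLINK bed/bim/fam triplet. Only the
#' variant-major layout (third header byte `0x01`) is supported — the layout
#' every modern PLINK emits. Dosages count copies of the bim A1 allele, so
#' the 2-bit code `00` (homozygous A1) maps to dosage 2, `11` to 0, `10` to
#' 1 and `01` to missing.
#'
#' @name plink_io
NULL

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_MODE_VARIANT_MAJOR <- as.raw(0x01)

# dosage -> 2-bit code and back; index 1..4 of .CODE_TO_DOSAGE is code 0..3
.DOSAGE_TO_CODE <- c(`0` = 3L, `1` = 2L, `2` = 0L) # NA handled separately -> 1
.CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)

# 256 x 4 lookup: byte value (0-255) -> codes of the 4 packed samples,
# sample 1 in the two least-significant bits.
.byte_code_lut <- local({
  b <- 0:255
  cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
})

#' Decode one bed byte into four genotype codes
#'
#' @param b integer 0-255 (or a raw byte).
#' @return Integer vector of four dosages in `{0, 1, 2, NA}`, first packed
#'   sample first.
#' @export
decode_bed_byte <- function(b) {
  b <- as.integer(b)
  if (length(b) != 1 || is.na(b) || b < 0 || b > 255)
    stopf("byte value must be a single integer in 0..255")
  .CODE_TO_DOSAGE[.byte_code_lut[b + 1L, ] + 1L]
}

#' Encode four genotype codes into one bed byte
#'
#' Inverse of [decode_bed_byte()]; missing trailing samples pad with
#' dosage-2 (code 00) bits, PLINK's zero-pad convention.
#'
#' @param dosages up to four dosages in `{0, 1, 2, NA}`.
#' @return Integer byte value 0-255.
#' @export
encode_bed_byte <- function(dosages) {
  if (length(dosages) < 1 || length(dosages) > 4)
    stopf("a bed byte packs 1 to 4 samples")
  d <- c(dosages, rep(2L, 4 - length(dosages)))
  code <- ifelse(is.na(d), 1L, .DOSAGE_TO_CODE[as.character(d)])
  if (any(is.na(code)))
    stopf("dosages must be 0, 1, 2 or NA")
  sum(code * c(1L, 4L, 16L, 64L))
}

.normalize_chrom <- function(x) {
  x <- toupper(as.character(x))
  map <- c(X = 23L, Y = 24L, XY = 25L, MT = 26L, M = 26L)
  out <- ifelse(x %in% names(map), map[x], suppressWarnings(as.integer(x)))
  if (any(is.na(out)))
    stopf("unrecognised chromosome label(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  as.integer(out)
}

#' Read a PLINK 1 binary fileset
#'
#' @param prefix path stem; `<prefix>.bed`, `.bim` and `.fam` must all exist.
#' @return A [genotype_matrix()] with variants in bim order and samples in
#'   fam order.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths)))
    stopf("triplet incomplete: missing %s",
          paste(basename(paths[!file.exists(paths)]), collapse = ", "))

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"),
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "allele1", "allele2"))
  bim$chrom <- .normalize_chrom(bim$chrom)
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "integer"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "phenotype"))
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_variant <- ceiling(n / 4)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], BED_MAGIC) ||
      !identical(raw[3], BED_MODE_VARIANT_MAJOR))
    stopf("unsupported bed layout: expected magic 6c 1b and variant-major mode 01")
  if (length(raw) != 3 + bytes_per_variant * m)
    stopf("truncated bed: expected %d payload bytes, found %d",
          bytes_per_variant * m, length(raw) - 3)

  codes <- .byte_code_lut[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
  # codes rows follow byte order: variant-major blocks of bytes_per_variant
  codes <- matrix(t(codes), nrow = 4 * bytes_per_variant, ncol = m)
  dosages <- matrix(.CODE_TO_DOSAGE[codes[seq_len(n), , drop = FALSE] + 1L],
                    nrow = n, ncol = m)
  genotype_matrix(dosages, bim, fam)
}

#' Write a PLINK 1 binary fileset
#'
#' Emits `<prefix>.bed` (variant-major, zero pad bits), `.bim` and `.fam`.
#' Output is byte-identical across repeated calls on the same input.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  if (n_samples(G) == 0) stopf("no samples")
  if (n_variants(G) == 0) stopf("no variants")
  n <- n_samples(G)
  m <- n_variants(G)
  bytes_per_variant <- ceiling(n / 4)

  d <- G$dosages
  code <- matrix(0L, nrow = 4 * bytes_per_variant, ncol = m)
  code[seq_len(n), ] <- ifelse(is.na(d), 1L,
                               ifelse(d == 2L, 0L, ifelse(d == 1L, 2L, 3L)))
  idx1 <- seq(1, 4 * bytes_per_variant, by = 4)
  bytes <- code[idx1, , drop = FALSE] +
    4L * code[idx1 + 1L, , drop = FALSE] +
    16L * code[idx1 + 2L, , drop = FALSE] +
    64L * code[idx1 + 3L, , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(BED_MAGIC, BED_MODE_VARIANT_MAJOR), con)
  writeBin(as.raw(as.vector(bytes)), con)

  v <- G$variants
  utils::write.table(
    data.frame(v$chrom, v$snp_id, v$cm, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  s <- G$samples
  utils::write.table(
    data.frame(s$fid, s$iid, s$pat, s$mat, s$sex, s$phenotype),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
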