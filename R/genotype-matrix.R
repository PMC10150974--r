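#' Genotype matrix container
#'
#' Bundles an additive-dosage genotype matrix with its variant map and sample
#' sheet, mirroring the three members of a PLINK 1 binary fileset. Dosages
#' count copies of `allele1` (the bim A1 allele): 2 = homozygous A1,
#' 1 = heterozygous, 0 = homozygous A2, `NA` = missing call.
#'
#' @param dosages integer matrix, samples in rows, variants in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `chrom` (integer 1-26; 23 = X,
#'   24 = Y, 25 = XY, 26 = MT), `snp_id`, `cm`, `pos`, `allele1`, `allele2`.
#' @param samples data frame with columns `fid`, `iid`, `pat`, `mat`,
#'   `sex` (0 unknown / 1 male / 2 female) and `phenotype`
#'   (1 control / 2 case / 0 or -9 missing).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  need_v <- c("chrom", "snp_id", "cm", "pos", "allele1", "allele2")
  need_s <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  if (!all(need_v %in% names(variants)))
    stopf("variants table must have columns: %s", paste(need_v, collapse = ", "))
  if (!all(need_s %in% names(samples)))
    stopf("samples table must have columns: %s", paste(need_s, collapse = ", "))
  if (nrow(samples) != nrow(dosages) || nrow(variants) != ncol(dosages))
    stopf("dosage matrix is %d x %d but there are %d samples and %d variants",
          nrow(dosages), ncol(dosages), nrow(samples), nrow(variants))
  if (anyDuplicated(variants$snp_id))
    stopf("duplicate snp_id in variant map")
  if (anyDuplicated(paste(samples$fid, samples$iid, sep = "\r")))
    stopf("duplicate (fid, iid) in sample sheet")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stopf("dosages must be 0, 1, 2 or NA")
  if (any(!samples$phenotype %in% c(-9L, 0L, 1L, 2L)))
    stopf("phenotype codes must be in {-9, 0, 1, 2}")
  if (any(variants$pos < 0))
    stopf("variant positions must be non-negative")
  if (any(!nzchar(variants$allele1)) || any(!nzchar(variants$allele2)))
    stopf("allele strings must be non-empty")

  colnames(dosages) <- variants$snp_id
  rownames(dosages) <- NULL
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants
#' @param G a [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(G) nrow(G$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(G) ncol(G$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  ph <- x$samples$phenotype
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d cases, %d controls)\n",
              n_samples(x), n_variants(x), sum(ph == 2L), sum(ph == 1L)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$variants$chrom)), collapse = " ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param keep logical or integer index over variants (resp. samples).
#' @return A new `genotype_matrix`.
#' @export
subset_variants <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  G$variants[keep, , drop = FALSE],
                  G$samples)
}

#' @rdname subset_variants
#' @export
subset_samples <- function(G, keep) {
  genotype_matrix(G$dosages[keep, , drop = FALSE],
                  G$variants,
                  G$samples[keep, , drop = FALSE])
}

#' Case/control phenotype as 0/1
#'
#' @param G a [genotype_matrix()].
#' @return Integer vector: 1 for cases (phenotype 2), 0 for controls
#'   (phenotype 1), `NA` for missing phenotype.
#' @export
phenotype01 <- function(G) {
  ph <- G$samples$phenotype
  out <- rep(NA_integer_, length(ph))
  out[ph == 2L] <- 1L
  out[ph == 1L] <- 0L
  out
}

#' Per-variant allele1 frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing calls only.
#'
#' @param G a [genotype_matrix()].
#' @return For `allele1_freq`, the frequency of A1; for `maf`,
#'   `pmin(freq, 1 - freq)`. Monomorphic-with-no-calls variants yield `NaN`.
#' @export
allele1_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' @rdname allele1_freq
#' @export
maf <- function(G) {
  f <- allele1_freq(G)
  pmin(f, 1 - f)
}

#' Per-sample and per-variant call rates
#' @param G a [genotype_matrix()].
#' @return Fraction of non-missing calls.
#' @export
sample_call_rate <- function(G) rowMeans(!is.na(G$dosages))

#' @rdname sample_call_rate
#' @export
variant_call_rate <- function(G) colMeans(!is.na(G$dosages))
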