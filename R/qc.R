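#' Quality-control thresholds
#'
#' Defaults follow standard GWAS practice for a cohort of a few hundred
#' samples: SNPs are dropped above 2% missingness, samples above 20%;
#' the sex check calls male at X-homozygosity F > 0.8 and female at
#' F < 0.2; the minor-allele-frequency floor is 0.05; exact
#' Hardy-Weinberg tests run first in controls at 1e-6 and then in cases
#' at 1e-10; relatedness is pruned above pi-hat 0.2.
#'
#' @param snp_missing_max,sample_missing_max maximum missing-call fractions.
#' @param maf_min minimum minor allele frequency (kept when MAF >= floor).
#' @param hwe_controls_p,hwe_cases_p exact-test removal thresholds.
#' @param f_male_min,f_female_max X-homozygosity bounds for sex inference.
#' @param pihat_max relatedness ceiling.
#' @param allowed_ethnicities optional label set for the stratification step.
#' @param sex_remove remove sex-discrepant samples (default) or only flag.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(snp_missing_max = 0.02,
                          sample_missing_max = 0.2,
                          maf_min = 0.05,
                          hwe_controls_p = 1e-6,
                          hwe_cases_p = 1e-10,
                          f_male_min = 0.8,
                          f_female_max = 0.2,
                          pihat_max = 0.2,
                          allowed_ethnicities = NULL,
                          sex_remove = TRUE) {
  th <- list(snp_missing_max = snp_missing_max,
             sample_missing_max = sample_missing_max,
             maf_min = maf_min,
             hwe_controls_p = hwe_controls_p,
             hwe_cases_p = hwe_cases_p,
             f_male_min = f_male_min,
             f_female_max = f_female_max,
             pihat_max = pihat_max,
             allowed_ethnicities = allowed_ethnicities,
             sex_remove = sex_remove)
  rates <- c(th$snp_missing_max, th$sample_missing_max, th$maf_min)
  if (any(rates < 0 | rates > 1))
    stopf("rates and frequencies must lie in [0, 1]")
  if (th$hwe_controls_p <= 0 || th$hwe_controls_p >= 1 ||
      th$hwe_cases_p <= 0 || th$hwe_cases_p >= 1)
    stopf("HWE thresholds must lie in (0, 1)")
  structure(th, class = "qc_thresholds")
}

#' Filter SNPs by missingness
#'
#' @param G a [genotype_matrix()].
#' @param max_rate maximum tolerated missing fraction.
#' @return A list with the filtered matrix `G` and `removed` SNP ids.
#' @export
filter_snp_missingness <- function(G, max_rate = 0.02) {
  miss <- 1 - variant_call_rate(G)
  drop <- miss > max_rate + 1e-12
  list(G = subset_variants(G, !drop), removed = G$variants$snp_id[drop])
}

#' Filter samples by missingness
#'
#' @inheritParams filter_snp_missingness
#' @return A list with the filtered matrix `G` and `removed` sample iids.
#' @export
filter_sample_missingness <- function(G, max_rate = 0.2) {
  miss <- 1 - sample_call_rate(G)
  drop <- miss > max_rate + 1e-12
  list(G = subset_samples(G, !drop), removed = G$samples$iid[drop])
}

#' X-chromosome homozygosity sex check
#'
#' Computes, per sample, the inbreeding-style homozygosity coefficient
#' F = (observed hom - expected hom) / (n used - expected hom) over
#' non-missing X genotypes (expected homozygosity from cohort allele
#' frequencies), infers sex from F, and flags disagreements with the
#' recorded fam sex.
#'
#' @param G a [genotype_matrix()].
#' @param f_male_min,f_female_max inference bounds.
#' @return A data frame (iid, n_used, f, inferred_sex, recorded_sex,
#'   discrepancy), or `NULL` with a warning when no X variants are present.
#' @export
sex_check <- function(G, f_male_min = 0.8, f_female_max = 0.2) {
  on_x <- G$variants$chrom == 23L
  if (!any(on_x)) {
    warnf("sex check skipped: no X-chromosome variants")
    return(NULL)
  }
  d <- G$dosages[, on_x, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  h_exp <- 1 - 2 * p * (1 - p) # per-SNP expected homozygosity
  nonmiss <- !is.na(d)
  n_used <- rowSums(nonmiss)
  e_hom <- as.vector(nonmiss %*% h_exp)
  o_hom <- rowSums(d == 0L | d == 2L, na.rm = TRUE)
  f <- (o_hom - e_hom) / (n_used - e_hom)
  f[n_used == 0] <- NA_real_
  inferred <- ifelse(is.na(f), NA_integer_,
                     ifelse(f > f_male_min, 1L,
                            ifelse(f < f_female_max, 2L, NA_integer_)))
  recorded <- G$samples$sex
  data.frame(iid = G$samples$iid, n_used = n_used, f = f,
             inferred_sex = inferred, recorded_sex = recorded,
             discrepancy = !is.na(inferred) & recorded %in% 1:2 &
               inferred != recorded,
             stringsAsFactors = FALSE)
}

#' Keep autosomal variants only
#'
#' @param G a [genotype_matrix()].
#' @return A list with `G` restricted to chromosomes 1-22 and `removed` ids.
#' @export
filter_autosomes <- function(G) {
  drop <- !(G$variants$chrom %in% 1:22)
  list(G = subset_variants(G, !drop), removed = G$variants$snp_id[drop])
}

#' Filter SNPs by minor allele frequency
#'
#' Variants are retained when MAF >= `min_maf` (PLINK `--maf` semantics).
#' Variants with no non-missing calls are removed.
#'
#' @param G a [genotype_matrix()].
#' @param min_maf frequency floor.
#' @return A list with the filtered matrix `G` and `removed` SNP ids.
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  f <- maf(G)
  drop <- is.na(f) | f < min_maf
  list(G = subset_variants(G, !drop), removed = G$variants$snp_id[drop])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums
#' the probabilities of all heterozygote counts (of the attainable parity)
#' whose conditional probability does not exceed that of the observed
#' configuration.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (hom A1 / het / hom A2).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || sum(counts) < 1)
    stopf("genotype counts must be non-negative with total >= 1")
  n <- sum(counts)
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  if (min(nA, nB) == 0) return(1) # monomorphic: single configuration
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logw <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

.hwe_pvals <- function(d) {
  vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    hwe_exact_test(sum(g == 2L, na.rm = TRUE),
                   sum(g == 1L, na.rm = TRUE),
                   sum(g == 0L, na.rm = TRUE))
  }, numeric(1))
}

#' Hardy-Weinberg filter, controls then cases
#'
#' Two sequential passes: variants failing the exact test within controls
#' at `controls_p` are removed first, then the survivors are tested within
#' cases at `cases_p`.
#'
#' @param G a [genotype_matrix()].
#' @param controls_p,cases_p removal thresholds (remove when p < threshold).
#' @return A list with the filtered matrix `G`, `removed` ids, and the
#'   per-pass id lists `removed_controls` / `removed_cases`.
#' @export
filter_hwe <- function(G, controls_p = 1e-6, cases_p = 1e-10) {
  y <- phenotype01(G)
  removed_controls <- character(0)
  if (!any(y == 0L, na.rm = TRUE)) {
    warnf("controls pass skipped: no controls present")
  } else if (n_variants(G) > 0) {
    p <- .hwe_pvals(G$dosages[which(y == 0L), , drop = FALSE])
    removed_controls <- G$variants$snp_id[p < controls_p]
    G <- subset_variants(G, !(G$variants$snp_id %in% removed_controls))
  }
  removed_cases <- character(0)
  if (any(y == 1L, na.rm = TRUE) && n_variants(G) > 0) {
    p <- .hwe_pvals(G$dosages[which(phenotype01(G) == 1L), , drop = FALSE])
    removed_cases <- G$variants$snp_id[p < cases_p]
    G <- subset_variants(G, !(G$variants$snp_id %in% removed_cases))
  }
  list(G = G, removed = c(removed_controls, removed_cases),
       removed_controls = removed_controls, removed_cases = removed_cases)
}

# Method-of-moments IBD estimation from IBS counts and allele frequencies.
# e0 = E[#IBS0 | IBD0], e10 = E[#IBS1 | IBD0], e11 = E[#IBS1 | IBD1],
# all per the full SNP panel; observed counts are over `n_valid` sites, so
# expectations are scaled by n_valid / m.
.pihat_from_ibs <- function(ibs0, ibs1, n_valid, e0, e10, e11, m) {
  scale <- n_valid / m
  k0 <- ibs0 / (e0 * scale)
  k1 <- (ibs1 - k0 * e10 * scale) / (e11 * scale)
  k0 <- pmax(0, pmin(1, k0))
  k1 <- pmax(0, pmin(1, k1))
  over <- (k0 + k1) > 1
  if (any(over)) {
    tot <- (k0 + k1)[over]
    k0[over] <- k0[over] / tot
    k1[over] <- k1[over] / tot
  }
  k2 <- pmax(0, 1 - k0 - k1)
  pmax(0, pmin(1, k1 / 2 + k2))
}

.ibs_expectations <- function(p) {
  q <- 1 - p
  list(e0 = sum(2 * p^2 * q^2),
       e10 = sum(4 * p^3 * q + 4 * p * q^3),
       e11 = sum(2 * p * q))
}

#' Pairwise relatedness (pi-hat) for one sample pair
#'
#' PLINK-style method-of-moments estimate: identity-by-state counts over
#' the overlapping non-missing autosomal calls are converted to estimated
#' identity-by-descent probabilities using cohort allele frequencies,
#' clipped to the probability simplex; pi-hat = P(IBD=1)/2 + P(IBD=2).
#'
#' @param G a [genotype_matrix()].
#' @param i,j sample indices or iids.
#' @param min_overlap minimum overlapping non-missing autosomal calls.
#' @return A list (iid1, iid2, n_snps, pi_hat); `pi_hat` is `NA` with a
#'   warning when the overlap is insufficient.
#' @export
estimate_pi_hat <- function(G, i, j, min_overlap = 100) {
  if (is.character(i)) i <- match(i, G$samples$iid)
  if (is.character(j)) j <- match(j, G$samples$iid)
  auto <- G$variants$chrom %in% 1:22
  gi <- G$dosages[i, auto]
  gj <- G$dosages[j, auto]
  ok <- !is.na(gi) & !is.na(gj)
  out <- list(iid1 = G$samples$iid[i], iid2 = G$samples$iid[j],
              n_snps = sum(ok), pi_hat = NA_real_)
  if (sum(ok) < min_overlap) {
    warnf("pair skipped: only %d overlapping calls", sum(ok))
    return(out)
  }
  p <- colMeans(G$dosages[, auto, drop = FALSE], na.rm = TRUE)[ok] / 2
  diffs <- abs(gi[ok] - gj[ok])
  e <- .ibs_expectations(p)
  out$pi_hat <- .pihat_from_ibs(sum(diffs == 2), sum(diffs == 1), sum(ok),
                                e$e0, e$e10, e$e11, sum(ok))
  out
}

# All-pairs pi-hat over founders, by indicator-matrix products. Expectation
# sums use the full autosomal panel scaled by each pair's valid overlap.
.pairwise_pihat <- function(G, sample_idx) {
  auto <- which(G$variants$chrom %in% 1:22)
  d <- G$dosages[sample_idx, auto, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p)
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  m <- ncol(d)
  A0 <- (!is.na(d) & d == 0L) * 1
  A1 <- (!is.na(d) & d == 1L) * 1
  A2 <- (!is.na(d) & d == 2L) * 1
  M <- (!is.na(d)) * 1
  ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  ibs0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  nval <- tcrossprod(M)
  ibs1 <- nval - ibs2 - ibs0
  e <- .ibs_expectations(p)
  pihat <- matrix(NA_real_, nrow(d), nrow(d))
  lower <- lower.tri(pihat)
  pihat[lower] <- .pihat_from_ibs(ibs0[lower], ibs1[lower], nval[lower],
                                  e$e0, e$e10, e$e11, m)
  pihat
}

#' Remove one member of each related pair
#'
#' Founders only (pat and mat both "0") are screened. For every pair with
#' pi-hat above `pihat_max` the member with the lower call rate is removed;
#' ties break toward the lexicographically larger iid.
#'
#' @param G a [genotype_matrix()].
#' @param pihat_max relatedness ceiling.
#' @return A list with the filtered matrix `G`, `removed` iids, and the
#'   detected `pairs` data frame (iid1, iid2, pi_hat).
#' @export
filter_related <- function(G, pihat_max = 0.2) {
  founders <- which(G$samples$pat == "0" & G$samples$mat == "0")
  if (length(founders) < 2)
    return(list(G = G, removed = character(0),
                pairs = data.frame(iid1 = character(0), iid2 = character(0),
                                   pi_hat = numeric(0))))
  ph <- .pairwise_pihat(G, founders)
  hits <- which(!is.na(ph) & ph > pihat_max, arr.ind = TRUE)
  call_rate <- sample_call_rate(G)
  iid <- G$samples$iid
  pairs <- data.frame(
    iid1 = iid[founders[hits[, 2]]],
    iid2 = iid[founders[hits[, 1]]],
    pi_hat = ph[hits],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$pi_hat), , drop = FALSE]
  removed <- character(0)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$iid1[r]; b <- pairs$iid2[r]
    if (a %in% removed || b %in% removed) next
    cra <- call_rate[match(a, iid)]
    crb <- call_rate[match(b, iid)]
    drop_id <- if (cra < crb) a else if (crb < cra) b else max(a, b)
    removed <- c(removed, drop_id)
  }
  list(G = subset_samples(G, !(iid %in% removed)),
       removed = removed, pairs = pairs)
}

#' Filter samples by ethnicity metadata
#'
#' @param G a [genotype_matrix()].
#' @param metadata data frame with columns `iid` and `ethnicity`.
#' @param allowed character vector of permitted labels.
#' @return A list with the filtered matrix `G` and `removed` iids.
#' @export
filter_ethnicity <- function(G, metadata, allowed) {
  idx <- match(G$samples$iid, metadata$iid)
  if (anyNA(idx))
    stopf("unlabelled sample: %s",
          paste(G$samples$iid[is.na(idx)], collapse = ", "))
  drop <- !(metadata$ethnicity[idx] %in% allowed)
  list(G = subset_samples(G, !drop), removed = G$samples$iid[drop])
}

#' Run the full quality-control cascade
#'
#' Applies, in order: SNP missingness, sample missingness, sex check,
#' autosome restriction, MAF floor, Hardy-Weinberg (controls then cases),
#' relatedness, and — when metadata is supplied — ethnicity. The returned
#' report reconciles exactly with the dimension changes.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param metadata optional data frame (`iid`, `ethnicity`); the
#'   stratification step is skipped when absent.
#' @return A list with the filtered matrix `G` and a `qc_report`.
#' @export
run_qc <- function(G, thresholds = qc_thresholds(), metadata = NULL) {
  dim_in <- dim(G)
  steps <- list()
  log_step <- function(name, type, ids, threshold) {
    steps[[length(steps) + 1]] <<- list(step = name, item_type = type,
                                        n_removed = length(ids),
                                        ids = ids, threshold = threshold)
  }

  r <- filter_snp_missingness(G, thresholds$snp_missing_max)
  G <- r$G
  log_step("snp_missingness", "variant", r$removed, thresholds$snp_missing_max)

  r <- filter_sample_missingness(G, thresholds$sample_missing_max)
  G <- r$G
  log_step("sample_missingness", "sample", r$removed,
           thresholds$sample_missing_max)

  sex <- if (any(G$variants$chrom == 23L))
    sex_check(G, thresholds$f_male_min, thresholds$f_female_max) else NULL
  sex_removed <- character(0)
  if (!is.null(sex) && thresholds$sex_remove) {
    sex_removed <- sex$iid[sex$discrepancy]
    G <- subset_samples(G, !(G$samples$iid %in% sex_removed))
  }
  log_step("sex_check", "sample", sex_removed,
           sprintf("F>%g male, F<%g female", thresholds$f_male_min,
                   thresholds$f_female_max))

  r <- filter_autosomes(G)
  G <- r$G
  log_step("autosomes", "variant", r$removed, "chrom 1-22")

  r <- filter_maf(G, thresholds$maf_min)
  G <- r$G
  log_step("maf", "variant", r$removed, thresholds$maf_min)

  r <- filter_hwe(G, thresholds$hwe_controls_p, thresholds$hwe_cases_p)
  G <- r$G
  log_step("hwe_controls", "variant", r$removed_controls,
           thresholds$hwe_controls_p)
  log_step("hwe_cases", "variant", r$removed_cases, thresholds$hwe_cases_p)

  r <- filter_related(G, thresholds$pihat_max)
  G <- r$G
  log_step("relatedness", "sample", r$removed, thresholds$pihat_max)

  if (!is.null(metadata) && !is.null(thresholds$allowed_ethnicities)) {
    r <- filter_ethnicity(G, metadata, thresholds$allowed_ethnicities)
    G <- r$G
    log_step("ethnicity", "sample", r$removed,
             paste(thresholds$allowed_ethnicities, collapse = ","))
  }

  if (n_samples(G) == 0 || n_variants(G) == 0)
    stopf("QC removed all data")
  report <- structure(list(steps = steps, dim_in = dim_in, dim_out = dim(G),
                           sex_check = sex),
                      class = "qc_report")
  list(G = G, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC cascade: %d x %d -> %d x %d (samples x variants)\n",
              x$dim_in[1], x$dim_in[2], x$dim_out[1], x$dim_out[2]))
  for (s in x$steps)
    cat(sprintf("  %-18s removed %5d %-8s (threshold %s)\n",
                s$step, s$n_removed, paste0(s$item_type, "s"),
                as.character(s$threshold)))
  invisible(x)
}

#' Summarise a QC report as a data frame
#' @param object a `qc_report`.
#' @param ... unused.
#' @return Data frame with one row per cascade step.
#' @export
summary.qc_report <- function(object, ...) {
  do.call(rbind, lapply(object$steps, function(s)
    data.frame(step = s$step, item_type = s$item_type,
               n_removed = s$n_removed,
               threshold = as.character(s$threshold),
               stringsAsFactors = FALSE)))
}
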