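#' Simulation configuration for a synthetic case-control cohort
#'
#' Defines a diploid biallelic cohort: haplotypes follow a first-order
#' Markov chain along the variant map (an allele copies its left neighbour
#' with probability `ld_rho`, otherwise it is a fresh Bernoulli draw at the
#' SNP's allele frequency), disease liability follows an additive logistic
#' model over planted causal SNPs, and case/control quotas are met by
#' rejection sampling. Optional defect classes — missingness, excess
#' heterozygosity, duplicated (related) samples, mislabelled sex — exercise
#' the quality-control cascade.
#'
#' @param n_cases,n_controls sample quotas.
#' @param n_snps_per_chrom named integer vector, chromosome label to SNP
#'   count. Chromosome 23 (X) is allowed; males then carry one haplotype
#'   stored as homozygous diploid codes.
#' @param maf_range allele-frequency interval within (0, 0.5] from which
#'   per-SNP frequencies are drawn uniformly.
#' @param ld_rho copy probability of the haplotype Markov chain, in [0, 1).
#' @param causal_spec `NULL` for a null cohort, otherwise a data frame with
#'   columns `index` (variant index in map order, autosomal) and `or`
#'   (per-allele odds ratio, > 0).
#' @param target_prevalence population disease probability used to solve
#'   the logistic intercept.
#' @param snp_missing_rate global missing-completely-at-random call rate.
#' @param n_hwe_violators number of SNPs regenerated with heterozygote
#'   excess (inbreeding coefficient F = -0.5; their frequencies are redrawn
#'   in [0.35, 0.5], where the F = -0.5 genotype law is well defined).
#' @param n_related_pairs duplicated sample pairs (1% per-site redraw).
#' @param n_sex_errors samples whose recorded (fam) sex is flipped.
#' @param n_high_missing_snps,n_high_missing_samples planted high-missingness
#'   defects, with per-call missing rates `high_missing_snp_rate` /
#'   `high_missing_sample_rate`.
#' @param high_missing_snp_rate,high_missing_sample_rate see above.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 174,
                       n_controls = 214,
                       n_snps_per_chrom = snps_per_chrom(5000, 1:22),
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.4,
                       causal_spec = NULL,
                       target_prevalence = 0.15,
                       snp_missing_rate = 0.002,
                       n_hwe_violators = 0,
                       n_related_pairs = 0,
                       n_sex_errors = 0,
                       n_high_missing_snps = 0,
                       n_high_missing_samples = 0,
                       high_missing_snp_rate = 0.05,
                       high_missing_sample_rate = 0.25,
                       seed = 1L) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_snps_per_chrom = n_snps_per_chrom,
              maf_range = maf_range, ld_rho = ld_rho,
              causal_spec = causal_spec,
              target_prevalence = target_prevalence,
              snp_missing_rate = snp_missing_rate,
              n_hwe_violators = n_hwe_violators,
              n_related_pairs = n_related_pairs,
              n_sex_errors = n_sex_errors,
              n_high_missing_snps = n_high_missing_snps,
              n_high_missing_samples = n_high_missing_samples,
              high_missing_snp_rate = high_missing_snp_rate,
              high_missing_sample_rate = high_missing_sample_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Spread a total SNP count over chromosomes
#' @param total total SNP count.
#' @param chroms chromosome labels (subset of 1:23).
#' @return Named integer vector.
#' @export
snps_per_chrom <- function(total, chroms = 1:22) {
  k <- length(chroms)
  counts <- rep(total %/% k, k)
  counts[seq_len(total %% k)] <- counts[seq_len(total %% k)] + 1L
  stats::setNames(as.integer(counts), chroms)
}

validate_sim_config <- function(cfg) {
  stopifnot(is_count(cfg$n_cases), is_count(cfg$n_controls),
            cfg$n_cases + cfg$n_controls > 0)
  chroms <- as.integer(names(cfg$n_snps_per_chrom))
  if (any(is.na(chroms)) || any(chroms < 1) || any(chroms > 23))
    stopf("n_snps_per_chrom names must be chromosome labels 1-23")
  if (!(is.numeric(cfg$maf_range) && length(cfg$maf_range) == 2 &&
        cfg$maf_range[1] > 0 && cfg$maf_range[2] <= 0.5 &&
        cfg$maf_range[1] <= cfg$maf_range[2]))
    stopf("maf_range must lie within (0, 0.5]")
  if (!is_prob(cfg$ld_rho) || cfg$ld_rho >= 1)
    stopf("ld_rho must be in [0, 1)")
  if (!is.null(cfg$causal_spec)) {
    cs <- cfg$causal_spec
    if (!all(c("index", "or") %in% names(cs)) || any(cs$or <= 0))
      stopf("causal_spec needs columns index and or, with or > 0")
  }
  stopifnot(is_prob(cfg$target_prevalence), cfg$target_prevalence > 0,
            cfg$target_prevalence < 1, is_prob(cfg$snp_missing_rate))
  invisible(cfg)
}

# Build the variant map for a config: positions strictly increasing within
# each chromosome, distinct allele pairs, per-SNP base frequencies.
.sim_variant_map <- function(cfg) {
  chroms <- as.integer(names(cfg$n_snps_per_chrom))
  counts <- as.integer(cfg$n_snps_per_chrom)
  chrom <- rep(chroms, counts)
  m <- length(chrom)
  pos <- unlist(lapply(counts, function(k)
    cumsum(sample(1000:20000, k, replace = TRUE))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  shift <- sample(1:3, m, replace = TRUE)
  a2 <- bases[((match(a1, bases) - 1L + shift) %% 4L) + 1L]
  data.frame(chrom = chrom,
             snp_id = sprintf("rs%06d", seq_len(m)),
             cm = 0, pos = pos, allele1 = a1, allele2 = a2,
             stringsAsFactors = FALSE)
}

# One batch of haplotypes: nb x m 0/1 matrix. The Markov copying acts on a
# latent uniform per haplotype (carried over with probability ld_rho,
# redrawn otherwise, restarting at each chromosome's first SNP); the allele
# is the latent uniform thresholded at the SNP's frequency. This keeps every
# SNP's marginal frequency exactly at its drawn value while adjacent SNPs
# share the latent draw with probability ld_rho (correlation = ld_rho when
# their frequencies agree).
.sim_haplotypes <- function(nb, base_freq, ld_rho, chrom) {
  m <- length(base_freq)
  h <- matrix(0L, nrow = nb, ncol = m)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
  u <- stats::runif(nb)
  h[, 1] <- as.integer(u < base_freq[1])
  if (m > 1) {
    for (j in 2:m) {
      fresh <- stats::runif(nb)
      if (new_chrom[j] || ld_rho == 0) {
        u <- fresh
      } else {
        keep <- stats::runif(nb) < ld_rho
        u <- ifelse(keep, u, fresh)
      }
      h[, j] <- as.integer(u < base_freq[j])
    }
  }
  h
}

# Solve the logistic intercept so that population prevalence matches the
# target, by Monte Carlo over causal genotypes drawn from their marginals.
.solve_intercept <- function(beta, freq, target, n_mc = 20000) {
  if (length(beta) == 0) return(logit(target))
  g <- vapply(freq, function(f) stats::rbinom(n_mc, 2, f),
              numeric(n_mc))
  eta <- as.vector(g %*% beta)
  obj <- function(a) mean(sigmoid(a + eta)) - target
  lo <- -30; hi <- 30
  if (obj(lo) > 0 || obj(hi) < 0)
    stopf("effect sizes inconsistent with prevalence")
  stats::uniroot(obj, c(lo, hi), tol = 1e-8)$root
}

#' Simulate a case-control genotype cohort
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `G` (a [genotype_matrix()]) and `truth`
#'   (causal SNP ids with log-odds effects, the solved intercept, and the
#'   injected defect lists).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, .simulate_cohort_impl(cfg))
}

.simulate_cohort_impl <- function(cfg) {
  variants <- .sim_variant_map(cfg)
  m <- nrow(variants)
  base_freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  freq <- base_freq # the latent-uniform chain preserves marginals exactly
  is_x <- variants$chrom == 23L

  causal_idx <- integer(0)
  beta <- numeric(0)
  if (!is.null(cfg$causal_spec)) {
    causal_idx <- as.integer(cfg$causal_spec$index)
    if (any(causal_idx < 1 | causal_idx > m))
      stopf("causal_spec index out of range")
    if (any(is_x[causal_idx]))
      stopf("causal SNPs must be autosomal")
    beta <- log(cfg$causal_spec$or)
  }
  alpha <- .solve_intercept(beta, freq[causal_idx], cfg$target_prevalence)

  n_need <- c(cases = cfg$n_cases, controls = cfg$n_controls)
  pool <- list(cases = list(), controls = list())
  sex_pool <- list(cases = integer(0), controls = integer(0))
  got <- c(cases = 0L, controls = 0L)
  batch <- 512L
  for (rep in 1:400) {
    if (all(got >= n_need)) break
    sex <- sample(1:2, batch, replace = TRUE)
    h1 <- .sim_haplotypes(batch, base_freq, cfg$ld_rho, variants$chrom)
    h2 <- .sim_haplotypes(batch, base_freq, cfg$ld_rho, variants$chrom)
    if (any(is_x)) {
      male <- sex == 1L
      h2[male, is_x] <- h1[male, is_x] # hemizygous, stored homozygous
    }
    g <- h1 + h2
    eta <- alpha + if (length(causal_idx))
      as.vector(g[, causal_idx, drop = FALSE] %*% beta) else 0
    is_case <- stats::runif(batch) < sigmoid(eta)
    for (grp in c("cases", "controls")) {
      sel <- if (grp == "cases") is_case else !is_case
      take <- min(sum(sel), n_need[[grp]] - got[[grp]])
      if (take > 0) {
        idx <- which(sel)[seq_len(take)]
        pool[[grp]] <- c(pool[[grp]], list(g[idx, , drop = FALSE]))
        sex_pool[[grp]] <- c(sex_pool[[grp]], sex[idx])
        got[[grp]] <- got[[grp]] + take
      }
    }
  }
  if (!all(got >= n_need))
    stopf("effect sizes inconsistent with prevalence")

  dosages <- rbind(do.call(rbind, pool$cases), do.call(rbind, pool$controls))
  n <- nrow(dosages)
  samples <- data.frame(
    fid = sprintf("FAM%04d", seq_len(n)),
    iid = sprintf("IND%04d", seq_len(n)),
    pat = "0", mat = "0",
    sex = c(sex_pool$cases, sex_pool$controls),
    phenotype = rep(c(2L, 1L), times = c(cfg$n_cases, cfg$n_controls)),
    stringsAsFactors = FALSE)

  defects <- list(hwe_violators = character(0),
                  related_pairs = data.frame(iid1 = character(0),
                                             iid2 = character(0)),
                  sex_errors = character(0),
                  high_missing_snps = character(0),
                  high_missing_samples = character(0))
  reserved_snps <- causal_idx
  reserved_samples <- integer(0)

  # related pairs: copy genotypes with 1% per-site redraw from the marginal
  if (cfg$n_related_pairs > 0) {
    avail <- setdiff(seq_len(n), reserved_samples)
    picks <- matrix(sample(avail, 2 * cfg$n_related_pairs), ncol = 2)
    for (r in seq_len(nrow(picks))) {
      i <- picks[r, 1]; j <- picks[r, 2]
      dosages[j, ] <- dosages[i, ]
      samples$sex[j] <- samples$sex[i]
      redraw <- which(stats::runif(m) < 0.01)
      if (length(redraw))
        dosages[j, redraw] <- stats::rbinom(length(redraw), 2, freq[redraw])
    }
    reserved_samples <- c(reserved_samples, as.vector(picks))
    defects$related_pairs <- data.frame(iid1 = samples$iid[picks[, 1]],
                                        iid2 = samples$iid[picks[, 2]])
  }

  # HWE violators: heterozygote excess (F = -0.5) in every sample
  if (cfg$n_hwe_violators > 0) {
    avail <- setdiff(which(!is_x), reserved_snps)
    hwe_idx <- sample(avail, cfg$n_hwe_violators)
    for (j in hwe_idx) {
      p <- stats::runif(1, 0.35, 0.5)
      q <- 1 - p
      probs <- c(q^2 - 0.5 * p * q, 3 * p * q, p^2 - 0.5 * p * q)
      dosages[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    }
    reserved_snps <- c(reserved_snps, hwe_idx)
    defects$hwe_violators <- variants$snp_id[hwe_idx]
  }

  # sex-labelling errors: flip the recorded sex only
  if (cfg$n_sex_errors > 0) {
    avail <- setdiff(seq_len(n), reserved_samples)
    flip <- sample(avail, cfg$n_sex_errors)
    samples$sex[flip] <- 3L - samples$sex[flip]
    reserved_samples <- c(reserved_samples, flip)
    defects$sex_errors <- samples$iid[flip]
  }

  # missingness: planted high-missingness defects, then the global MCAR rate
  if (cfg$n_high_missing_snps > 0) {
    avail <- setdiff(seq_len(m), reserved_snps)
    hm <- sample(avail, cfg$n_high_missing_snps)
    for (j in hm) {
      kill <- stats::runif(n) < cfg$high_missing_snp_rate
      dosages[kill, j] <- NA_integer_
    }
    reserved_snps <- c(reserved_snps, hm)
    defects$high_missing_snps <- variants$snp_id[hm]
  }
  if (cfg$n_high_missing_samples > 0) {
    avail <- setdiff(seq_len(n), reserved_samples)
    hm <- sample(avail, cfg$n_high_missing_samples)
    for (i in hm) {
      kill <- stats::runif(m) < cfg$high_missing_sample_rate
      dosages[i, kill] <- NA_integer_
    }
    defects$high_missing_samples <- samples$iid[hm]
  }
  if (cfg$snp_missing_rate > 0) {
    kill <- stats::runif(n * m) < cfg$snp_missing_rate
    dosages[matrix(kill, n, m)] <- NA_integer_
  }

  G <- genotype_matrix(dosages, variants, samples)
  truth <- list(
    causal = if (length(causal_idx))
      data.frame(snp_id = variants$snp_id[causal_idx],
                 beta = beta, or = exp(beta), stringsAsFactors = FALSE)
    else data.frame(snp_id = character(0), beta = numeric(0), or = numeric(0)),
    intercept = alpha,
    base_freq = base_freq,
    defects = defects)
  list(G = G, truth = truth)
}

#' Canonical study-condition configurations
#'
#' `planted_cohort_config()` is the planted-signal benchmark cohort the
#' package's evaluation is built around: 174 cases / 214 controls, 5,000
#' autosomal SNPs over chromosomes 1-22 with moderate adjacent-SNP LD
#' (`ld_rho` = 0.4), and 10 causal SNPs of per-allele odds ratio 2.5 spaced
#' evenly along the map. `defect_cohort_config()` is the same cohort with
#' every QC defect class injected: 500 X-chromosome SNPs for the sex
#' check, planted high-missingness SNPs and samples, heterozygote-excess
#' SNPs, 3 duplicated (related) pairs and 3 sex-labelling errors.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
planted_cohort_config <- function(seed = 1L) {
  sim_config(
    causal_spec = data.frame(index = round(seq(250, 4750, length.out = 10)),
                             or = 2.5),
    seed = seed)
}

#' @rdname planted_cohort_config
#' @export
defect_cohort_config <- function(seed = 1L) {
  sim_config(
    n_snps_per_chrom = c(snps_per_chrom(4100, 1:22), `23` = 500L),
    causal_spec = NULL,
    n_hwe_violators = 5,
    n_related_pairs = 3,
    n_sex_errors = 3,
    n_high_missing_snps = 6,
    n_high_missing_samples = 3,
    seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Emits the PLINK triplet, a JSON file with the causal truth and injected
#' defects, and a per-SNP summary TSV (drawn frequency, empirical MAF,
#' call rate).
#'
#' @param G a [genotype_matrix()].
#' @param truth the `truth` element of [simulate_cohort()].
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_cohort <- function(G, truth, prefix) {
  write_plink(G, prefix)
  jsonlite::write_json(
    list(causal = truth$causal, intercept = truth$intercept,
         defects = truth$defects),
    paste0(prefix, ".truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  summ <- data.frame(snp_id = G$variants$snp_id,
                     base_freq = truth$base_freq,
                     empirical_maf = maf(G),
                     call_rate = variant_call_rate(G))
  utils::write.table(summ, paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
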