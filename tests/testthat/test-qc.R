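# helper: build a genotype_matrix from an explicit dosage matrix
gm_from <- function(d, chrom = NULL, pheno = NULL, sex = NULL) {
  n <- nrow(d); m <- ncol(d)
  variants <- data.frame(chrom = chrom %||% rep(1L, m),
                         snp_id = sprintf("rs%04d", 1:m), cm = 0,
                         pos = 1:m * 50L, allele1 = "A", allele2 = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(fid = sprintf("F%03d", 1:n),
                        iid = sprintf("I%03d", 1:n), pat = "0", mat = "0",
                        sex = sex %||% rep(1L, n),
                        phenotype = pheno %||% rep_len(c(1L, 2L), n),
                        stringsAsFactors = FALSE)
  genotype_matrix(d, variants, samples)
}

test_that("SNP missingness filter removes exactly the over-threshold variants", {
  set.seed(1)
  n <- 100
  d <- matrix(sample(0:2, n * 10, TRUE), n, 10)
  for (j in 1:10) d[seq_len(j - 1), j] <- NA # missing counts 0..9
  G <- gm_from(d)
  res <- filter_snp_missingness(G, 0.02)
  expect_identical(length(res$removed), 7L) # counts 3..9 exceed 2/100
  expect_identical(res$removed, sprintf("rs%04d", 4:10))
  expect_identical(length(filter_snp_missingness(G, 1.0)$removed), 0L)
  # idempotent
  res2 <- filter_snp_missingness(res$G, 0.02)
  expect_identical(n_variants(res2$G), n_variants(res$G))
})

test_that("sample missingness filter removes exactly the over-threshold samples", {
  set.seed(2)
  m <- 100
  d <- matrix(sample(0:2, 4 * m, TRUE), 4, m)
  rates <- c(0.1, 0.19, 0.21, 0.5)
  for (i in 1:4) d[i, seq_len(round(rates[i] * m))] <- NA
  G <- gm_from(d)
  res <- filter_sample_missingness(G, 0.2)
  expect_identical(res$removed, c("I003", "I004"))
  full <- gm_from(matrix(1L, 5, 10))
  expect_identical(length(filter_sample_missingness(full, 0.2)$removed), 0L)
})

test_that("autosome filter keeps chromosomes 1-22 only", {
  d <- matrix(1L, 4, 4)
  G <- gm_from(d, chrom = c(1L, 22L, 23L, 26L))
  res <- filter_autosomes(G)
  expect_identical(res$G$variants$chrom, c(1L, 22L))
  expect_identical(res$removed, c("rs0003", "rs0004"))
  G2 <- gm_from(matrix(1L, 3, 3), chrom = c(23L, 23L, 23L))
  expect_identical(n_variants(filter_autosomes(G2)$G), 0L)
})

test_that("MAF filter uses a >= boundary and is monotone", {
  # 100 samples, A1 allele count 10/200 -> MAF exactly 0.05: retained
  d5 <- c(rep(1L, 10), rep(0L, 90))
  mono <- rep(0L, 100)
  common <- rep_len(c(0L, 1L, 2L), 100)
  G <- gm_from(cbind(d5, mono, common))
  res <- filter_maf(G, 0.05)
  expect_identical(res$removed, "rs0002") # only the monomorphic variant
  for (thr in c(0.01, 0.05, 0.1, 0.3)) {
    r_lo <- filter_maf(G, thr / 2)
    r_hi <- filter_maf(G, thr)
    expect_lte(length(r_lo$removed), length(r_hi$removed))
  }
})

test_that("HWE exact test matches the enumeration oracle and edge cases", {
  expect_identical(hwe_exact_test(0, 0, 100), 1)
  expect_lt(abs(hwe_exact_test(25, 50, 25) - oracle_hwe_exact(25, 50, 25)),
            1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  # spot sweep at mixed totals
  set.seed(3)
  for (rep in 1:100) {
    cnt <- rmultinom(1, sample(3:50, 1), prob = runif(3))[, 1]
    expect_lt(abs(hwe_exact_test(cnt[1], cnt[2], cnt[3]) -
                    oracle_hwe_exact(cnt[1], cnt[2], cnt[3])), 1e-10)
  }
})

test_that("HWE filter runs controls then cases at their own thresholds", {
  set.seed(4)
  n_ctl <- 200; n_cas <- 200
  pheno <- c(rep(1L, n_ctl), rep(2L, n_cas))
  # column 1: control-side violator (all het in controls)
  col1 <- c(rep(1L, n_ctl), sample(0:2, n_cas, TRUE, prob = c(.25, .5, .25)))
  # column 2: case-side deviation with 1e-10 < p < 1e-6 -> must survive
  cas2 <- c(rep(2L, 29), rep(1L, 142), rep(0L, 29))
  p_cas2 <- hwe_exact_test(29, 142, 29)
  expect_gt(p_cas2, 1e-10)
  expect_lt(p_cas2, 1e-6)
  col2 <- c(sample(0:2, n_ctl, TRUE, prob = c(.25, .5, .25)), cas2)
  # column 3: in HWE everywhere
  col3 <- sample(0:2, n_ctl + n_cas, TRUE, prob = c(.25, .5, .25))
  G <- gm_from(cbind(col1, col2, col3), pheno = pheno)
  res <- filter_hwe(G, 1e-6, 1e-10)
  expect_identical(res$removed_controls, "rs0001")
  expect_identical(res$removed_cases, character(0))
  expect_identical(n_variants(res$G), 2L)
})

test_that("sex check computes F and flags recorded/inferred conflicts", {
  set.seed(5)
  n_x <- 500
  p <- runif(n_x, 0.2, 0.5)
  male_row <- 2L * rbinom(n_x, 1, p) # hemizygous: always homozygous
  fem_rows <- t(replicate(6, rbinom(n_x, 1, p) + rbinom(n_x, 1, p)))
  d <- rbind(male_row, fem_rows)
  G <- gm_from(d, chrom = rep(23L, n_x),
               sex = c(1L, 2L, 2L, 2L, 2L, 2L, 1L)) # last is a mislabel
  sc <- sex_check(G)
  expect_equal(sc$f[1], 1, tolerance = 1e-12)
  expect_identical(sc$inferred_sex[1], 1L)
  expect_true(all(abs(sc$f[-1]) < 0.2))
  expect_identical(sc$inferred_sex[7], 2L)
  expect_true(sc$discrepancy[7])
  expect_false(any(sc$discrepancy[1:6]))
  # no X variants: warning, NULL
  expect_warning(res <- sex_check(gm_from(matrix(1L, 3, 3))),
                 "sex check skipped")
  expect_null(res)
})

test_that("pi-hat behaves for duplicates, unrelated pairs and parent-child", {
  set.seed(6)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  hap <- function() rbinom(m, 1, p)
  h_a <- hap(); h_b <- hap(); h_c <- hap(); h_d <- hap(); h_e <- hap()
  parent <- h_a + h_b
  child <- h_a + h_c # shares one haplotype
  other <- h_d + h_e
  dup <- parent
  d <- rbind(parent, child, other, dup)
  G <- gm_from(d)
  expect_gte(estimate_pi_hat(G, 1, 4)$pi_hat, 0.95) # duplicate
  expect_lt(estimate_pi_hat(G, 2, 3)$pi_hat, 0.05) # unrelated
  ph_pc <- estimate_pi_hat(G, 1, 2)$pi_hat # parent-child
  expect_gt(ph_pc, 0.4)
  expect_lt(ph_pc, 0.6)
  # insufficient overlap warns and returns NA
  d2 <- d
  d2[1, 1:(m - 50)] <- NA
  G2 <- gm_from(d2)
  expect_warning(res <- estimate_pi_hat(G2, 1, 2), "pair skipped")
  expect_true(is.na(res$pi_hat))
})

test_that("relatedness filter removes the lower-call-rate member once per pair", {
  cfg <- sim_config(n_cases = 60, n_controls = 60,
                    n_snps_per_chrom = snps_per_chrom(4000, 1:10),
                    n_related_pairs = 2, seed = 44)
  sim <- simulate_cohort(cfg)
  res <- filter_related(sim$G, 0.2)
  pairs <- sim$truth$defects$related_pairs
  expect_identical(length(res$removed), 2L)
  cr <- sample_call_rate(sim$G)
  names(cr) <- sim$G$samples$iid
  for (r in 1:2) {
    a <- pairs$iid1[r]; b <- pairs$iid2[r]
    expect_identical(sum(c(a, b) %in% res$removed), 1L)
    worse <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else max(a, b)
    expect_true(worse %in% res$removed)
  }
  # a cohort without planted pairs loses nobody
  sim0 <- simulate_cohort(sim_config(n_cases = 60, n_controls = 60,
                                     n_snps_per_chrom = snps_per_chrom(4000, 1:10),
                                     seed = 45))
  expect_identical(filter_related(sim0$G, 0.2)$removed, character(0))
})

test_that("ethnicity filter removes disallowed labels and demands coverage", {
  G <- gm_from(matrix(1L, 10, 5))
  meta <- data.frame(iid = G$samples$iid,
                     ethnicity = rep(c("EUR", "EAS"), each = 5),
                     stringsAsFactors = FALSE)
  res <- filter_ethnicity(G, meta, "EUR")
  expect_identical(length(res$removed), 5L)
  expect_identical(n_samples(filter_ethnicity(G, meta, c("EUR", "EAS"))$G), 10L)
  expect_error(filter_ethnicity(G, meta[1:8, ], "EUR"), "unlabelled sample")
})

test_that("the QC cascade report reconciles with dimension changes", {
  sim <- simulate_cohort(sim_config(
    n_cases = 100, n_controls = 200,
    n_snps_per_chrom = c(snps_per_chrom(900, 1:6), `23` = 150L),
    n_hwe_violators = 3, n_high_missing_snps = 4,
    n_high_missing_samples = 2, seed = 19))
  res <- run_qc(sim$G)
  rep <- res$report
  by_type <- tapply(vapply(rep$steps, `[[`, numeric(1), "n_removed"),
                    vapply(rep$steps, `[[`, character(1), "item_type"),
                    sum)
  expect_equal(unname(by_type[["variant"]]),
               rep$dim_in[2] - rep$dim_out[2])
  expect_equal(unname(by_type[["sample"]]),
               rep$dim_in[1] - rep$dim_out[1])
  # planted defects are caught by their own steps
  steps <- setNames(rep$steps, vapply(rep$steps, `[[`, character(1), "step"))
  expect_true(all(sim$truth$defects$high_missing_snps %in%
                    steps$snp_missingness$ids))
  expect_true(all(sim$truth$defects$hwe_violators %in%
                    steps$hwe_controls$ids))
})

test_that("a defect-free complete cohort passes QC untouched", {
  sim <- simulate_cohort(sim_config(n_cases = 50, n_controls = 50,
                                    n_snps_per_chrom = snps_per_chrom(3000, 1:8),
                                    maf_range = c(0.2, 0.5),
                                    snp_missing_rate = 0, seed = 23))
  res <- run_qc(sim$G)
  expect_identical(dim(res$G), dim(sim$G))
  expect_true(all(vapply(res$report$steps, `[[`, numeric(1),
                         "n_removed") == 0))
})
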