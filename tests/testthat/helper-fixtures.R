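# Shared fixture builders; everything is generated in code at test time.

random_genotype_matrix <- function(n, m, seed = 1, miss_rate = 0.05,
                                   chroms = c(1L, 2L),
                                   pheno = NULL) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (miss_rate > 0)
      d[matrix(runif(n * m) < miss_rate, n, m)] <- NA_integer_
    chrom <- sort(rep_len(chroms, m))
    pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
      cumsum(sample(100:1000, length(ix), replace = TRUE))), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- bases[((match(a1, bases) + sample(0:2, m, TRUE)) %% 4) + 1]
    variants <- data.frame(chrom = chrom, snp_id = sprintf("rs%05d", 1:m),
                           cm = 0, pos = pos, allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE)
    samples <- data.frame(fid = sprintf("F%04d", 1:n),
                          iid = sprintf("I%04d", 1:n),
                          pat = "0", mat = "0",
                          sex = sample(1:2, n, replace = TRUE),
                          phenotype = pheno %||%
                            rep_len(c(1L, 2L), n),
                          stringsAsFactors = FALSE)
    genotype_matrix(d, variants, samples)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent bed-byte oracle: decode via R's bit utilities, not the
# package's arithmetic lookup table.
oracle_decode_byte <- function(b) {
  bits <- as.integer(rawToBits(as.raw(b)))
  sapply(c(1, 3, 5, 7), function(i) {
    code <- bits[i] + 2L * bits[i + 1] # low bit first
    switch(code + 1L, 2L, NA_integer_, 1L, 0L)
  })
}

# Exact-factorial HWE enumeration oracle (valid for totals <= ~80)
oracle_hwe_exact <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  if (min(nA, nB) == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  w <- sapply(hets, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((nB - h) / 2)) * 2^h
  })
  pr <- w / sum(w)
  sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-12)])
}

# Grid-then-polish MLE oracle for the 2-parameter logistic model on an
# additive-genotype table; independent of the IRLS path.
oracle_logistic_mle <- function(g, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * g
    sum(log(1 + exp(eta))) - sum(y * eta)
  }
  grid <- expand.grid(b0 = seq(-3, 3, by = 0.25), b1 = seq(-3, 3, by = 0.25))
  vals <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

# A small cohort with a few strong causal SNPs, used across model tests
toy_planted_cohort <- function(seed = 5, n_cases = 80, n_controls = 100,
                               m = 600, causal = c(100, 300, 500), or = 3) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_snps_per_chrom = snps_per_chrom(m, 1:6),
                    causal_spec = data.frame(index = causal, or = or),
                    seed = seed)
  simulate_cohort(cfg)
}
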