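#' Single-SNP logistic regression
#'
#' Maximum-likelihood fit of `logit P(case) = b0 + b * g` by iteratively
#' reweighted least squares (log-likelihood tolerance 1e-8, at most 50
#' iterations), with a two-sided Wald p-value. Under (near) complete
#' separation (|b| > 15 at convergence failure) the Wald p is meaningless
#' and the likelihood-ratio p is reported instead, with `separated = TRUE`.
#'
#' @param g additive genotype dosages (0/1/2; `NA` dropped listwise).
#' @param y binary phenotype (0 control / 1 case), aligned with `g`.
#' @return A list (beta, se, z, p, n_used, separated).
#' @export
fit_snp_logistic <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- as.numeric(g[ok])
  y <- as.numeric(y[ok])
  if (length(unique(y)) < 2)
    stopf("both phenotype classes must be present")
  if (length(unique(g)) < 2)
    stopf("degenerate predictor")
  x <- cbind(1, g)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  beta <- fit$coefficients[2]
  cov <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(cov[2, 2])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  separated <- abs(beta) > 15
  if (separated) {
    # likelihood-ratio fallback against the intercept-only model
    p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
  }
  list(beta = unname(beta), se = unname(se), z = unname(z),
       p = unname(max(p, .Machine$double.xmin)),
       n_used = length(y), separated = separated)
}

#' Genome-wide association scan
#'
#' Fits [fit_snp_logistic()] for every variant. Degenerate variants
#' (monomorphic after listwise deletion) are kept as flagged rows with `NA`
#' statistics; the scan never aborts.
#'
#' @param G a QC'd [genotype_matrix()] with case/control phenotypes.
#' @return Data frame in map order: snp_id, chrom, pos, beta, se, z, p,
#'   n_used, status ("ok", "degenerate" or "separated").
#' @export
run_association <- function(G) {
  y <- phenotype01(G)
  if (all(is.na(y)) || length(unique(stats::na.omit(y))) < 2)
    stopf("both phenotype classes must be present")
  m <- n_variants(G)
  out <- data.frame(snp_id = G$variants$snp_id,
                    chrom = G$variants$chrom,
                    pos = G$variants$pos,
                    beta = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, n_used = NA_integer_,
                    status = "degenerate",
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    res <- tryCatch(fit_snp_logistic(G$dosages[, j], y),
                    error = function(e) NULL)
    if (is.null(res)) next
    out$beta[j] <- res$beta
    out$se[j] <- res$se
    out$z[j] <- res$z
    out$p[j] <- res$p
    out$n_used[j] <- res$n_used
    out$status[j] <- if (res$separated) "separated" else "ok"
  }
  out
}

#' Select the top-k SNPs by association p-value
#'
#' @param table an association table from [run_association()].
#' @param k number of SNPs (default 1000, the screen size used upstream of
#'   feature selection). Ties break by (chromosome, position).
#' @return The selected rows, ordered by increasing p.
#' @export
select_top_k <- function(table, k = 1000) {
  if (k < 1) stopf("k must be >= 1")
  usable <- table[!is.na(table$p), , drop = FALSE]
  if (k > nrow(usable)) {
    warnf("k = %d exceeds the %d usable rows; returning all", k, nrow(usable))
    k <- nrow(usable)
  }
  ord <- order(usable$p, usable$chrom, usable$pos)
  usable[ord[seq_len(k)], , drop = FALSE]
}

#' Genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and reports
#' lambda = median(chi-square) / median of the null chi-square(1)
#' distribution (`qchisq(0.5, 1)` = 0.4549...).
#'
#' @param p vector of p-values (at least 100).
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stopf("at least 100 p-values are required")
  if (any(p <= 0 | p > 1)) stopf("invalid p-value")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Manhattan-plot table
#'
#' Adds a cumulative genome coordinate (chromosomes laid end-to-end in
#' order) and -log10 p to an association table, together with the
#' genome-wide significance reference `-log10(5e-8)`.
#'
#' @param table an association table from [run_association()].
#' @return Data frame (snp_id, chrom, pos, genome_pos, neglog10_p) with
#'   attribute `genomewide_line`.
#' @export
manhattan_table <- function(table) {
  if (nrow(table) == 0) stopf("empty association table")
  tab <- table[order(table$chrom, table$pos), , drop = FALSE]
  offsets <- c(0, cumsum(tapply(tab$pos, tab$chrom, max)))
  chrom_levels <- sort(unique(tab$chrom))
  off <- offsets[match(tab$chrom, chrom_levels)]
  out <- data.frame(snp_id = tab$snp_id, chrom = tab$chrom, pos = tab$pos,
                    genome_pos = tab$pos + off,
                    neglog10_p = -log10(tab$p),
                    stringsAsFactors = FALSE)
  attr(out, "genomewide_line") <- -log10(5e-8)
  out
}

#' QQ-plot table
#'
#' Expected quantiles are `(i - 0.5) / m` for the i-th smallest p-value.
#'
#' @param p vector of p-values.
#' @return Data frame (expected, observed), both on the -log10 scale,
#'   ordered from the largest p to the smallest.
#' @export
qq_table <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stopf("no p-values")
  m <- length(p)
  obs <- sort(p, decreasing = TRUE)
  expd <- (m:1 - 0.5) / m
  data.frame(expected = -log10(expd), observed = -log10(obs))
}
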