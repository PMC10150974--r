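#' One-hot genotype encoding
#'
#' Expands each SNP into three binary indicator features named
#' `<snp>_<genotype>`, with genotype labels spelled from the bim alleles:
#' homozygous A1 (`A1A1`, dosage 2), heterozygous (`A1A2`, dosage 1) and
#' homozygous A2 (`A2A2`, dosage 0). A missing call leaves all three
#' indicators at 0.
#'
#' @param G a [genotype_matrix()].
#' @param snp_ids SNPs to encode (default: all), in the order given.
#' @return An `encoded_features` object: list with the binary matrix `X`
#'   (samples x 3.SNPs) and `map` (feature, snp_id, genotype, dosage).
#' @export
one_hot_encode <- function(G, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- G$variants$snp_id
  idx <- match(snp_ids, G$variants$snp_id)
  if (anyNA(idx))
    stopf("unknown SNP id(s): %s",
          paste(snp_ids[is.na(idx)], collapse = ", "))
  v <- G$variants[idx, , drop = FALSE]
  d <- G$dosages[, idx, drop = FALSE]
  n <- nrow(d); k <- length(idx)

  labels <- cbind(paste0(v$allele1, v$allele1),
                  paste0(v$allele1, v$allele2),
                  paste0(v$allele2, v$allele2))
  feat <- as.vector(t(cbind(paste0(v$snp_id, "_", labels[, 1]),
                            paste0(v$snp_id, "_", labels[, 2]),
                            paste0(v$snp_id, "_", labels[, 3]))))
  X <- matrix(0L, nrow = n, ncol = 3 * k)
  X[, seq(1, 3 * k, by = 3)] <- (!is.na(d) & d == 2L) * 1L
  X[, seq(2, 3 * k, by = 3)] <- (!is.na(d) & d == 1L) * 1L
  X[, seq(3, 3 * k, by = 3)] <- (!is.na(d) & d == 0L) * 1L
  colnames(X) <- feat
  map <- data.frame(feature = feat,
                    snp_id = rep(v$snp_id, each = 3),
                    genotype = as.vector(t(labels)),
                    dosage = rep(c(2L, 1L, 0L), times = k),
                    stringsAsFactors = FALSE)
  structure(list(X = X, map = map), class = "encoded_features")
}

#' @export
print.encoded_features <- function(x, ...) {
  cat(sprintf("encoded_features: %d samples x %d indicators (%d SNPs)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$snp_id))))
  invisible(x)
}

#' Parent SNP of a one-hot feature name
#' @param feature feature names of the form `<snp>_<genotype>`.
#' @return SNP id vector.
#' @export
feature_parent <- function(feature) sub("_[^_]*$", "", feature)

.new_ranking <- function(feature, score, method, decision = NULL) {
  ord <- order(-score, feature)
  out <- data.frame(feature = feature[ord], score = score[ord],
                    rank = seq_along(feature),
                    decision = if (is.null(decision)) NA_character_
                    else decision[ord],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "universe") <- sort(feature)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' PCA loading importance
#'
#' Centres the feature matrix, computes the principal-component rotation,
#' and scores each feature by the sum of absolute rotation entries over the
#' components retained up to `var_explained` cumulative explained variance.
#' Components follow a deterministic sign convention (the largest-magnitude
#' loading of each component is made positive); the absolute sum is
#' invariant to it, but the stored rotation is reproducible.
#'
#' @param X an `encoded_features` object or a numeric matrix.
#' @param var_explained cumulative variance cutoff in (0, 1].
#' @param weight_by_variance multiply each component's absolute loadings by
#'   its explained-variance share before summing (off by default).
#' @return An `importance_ranking` data frame (feature, score, rank),
#'   ordered by decreasing score, ties broken by feature name.
#' @export
pca_importance <- function(X, var_explained = 0.95,
                           weight_by_variance = FALSE) {
  if (inherits(X, "encoded_features")) X <- X$X
  if (nrow(X) < 2 || ncol(X) < 2)
    stopf("need at least 2 samples and 2 features")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  if (sum(vars) <= 0) stopf("no variation")
  share <- vars / sum(vars)
  n_keep <- which(cumsum(share) >= var_explained - 1e-12)[1]
  if (is.na(n_keep)) n_keep <- length(share)
  rot <- pc$rotation[, seq_len(n_keep), drop = FALSE]
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  w <- if (weight_by_variance) share[seq_len(n_keep)] else rep(1, n_keep)
  score <- as.vector(abs(rot) %*% w)
  .new_ranking(colnames(X), score, "pca")
}

#' Boruta all-relevant feature selection
#'
#' The shadow-feature formulation: each iteration appends a row-shuffled
#' copy of every still-active column, fits a random forest, and credits a
#' "hit" to every real feature whose impurity importance exceeds the
#' maximum shadow importance. After each iteration, two-sided binomial
#' tests of the hit counts against Binomial(iterations, 0.5), Bonferroni
#' corrected over the original feature count, confirm clearly-relevant
#' features and reject clearly-irrelevant ones (which leave the forest).
#' Undecided features at `max_iter` stay `tentative` and are treated as
#' rejected downstream.
#'
#' @param X an `encoded_features` object or a numeric matrix.
#' @param y binary response (0/1 or two-level factor).
#' @param n_trees trees per forest (default 300).
#' @param max_iter iteration cap (default 100).
#' @param alpha familywise significance level for the decisions.
#' @param seed RNG seed; the run is fully reproducible from it.
#' @return An `importance_ranking` (feature, score = mean importance across
#'   the iterations the feature was active, rank, decision).
#' @export
boruta_select <- function(X, y, n_trees = 300, max_iter = 100,
                          alpha = 0.05, seed = 1L) {
  if (inherits(X, "encoded_features")) X <- X$X
  y <- factor(y)
  if (nlevels(y) != 2) stopf("y must have exactly two classes")
  if (ncol(X) < 1) stopf("X must be non-empty")
  m0 <- ncol(X)
  feat <- colnames(X) %||% paste0("f", seq_len(m0))
  colnames(X) <- feat

  hits <- integer(m0)
  iters <- integer(m0)
  imp_sum <- numeric(m0)
  decision <- rep("tentative", m0)
  active <- seq_len(m0)

  with_seed(seed, {
    for (t in seq_len(max_iter)) {
      if (!any(decision[active] == "tentative") && t > 1) break
      Xa <- X[, active, drop = FALSE]
      Xs <- apply(Xa, 2, sample)
      colnames(Xs) <- paste0(".shadow.", colnames(Xa))
      fit <- ranger::ranger(x = cbind(Xa, Xs), y = y,
                            num.trees = n_trees, importance = "impurity",
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      real_imp <- imp[seq_along(active)]
      shadow_max <- max(imp[-seq_along(active)])
      hits[active] <- hits[active] + (real_imp > shadow_max)
      iters[active] <- iters[active] + 1L
      imp_sum[active] <- imp_sum[active] + real_imp

      undecided <- active[decision[active] == "tentative"]
      k <- hits[undecided]; ti <- iters[undecided]
      p_hi <- stats::pbinom(k - 1, ti, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(k, ti, 0.5)
      p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
      sig <- p_two < alpha / m0
      decision[undecided[sig & k / ti > 0.5]] <- "confirmed"
      newly_rejected <- undecided[sig & k / ti < 0.5]
      decision[newly_rejected] <- "rejected"
      active <- setdiff(active, newly_rejected)
      if (length(active) == 0) break
    }
  })
  score <- ifelse(iters > 0, imp_sum / pmax(iters, 1L), 0)
  .new_ranking(feat, score, "boruta", decision)
}

#' Association-screen importance for one-hot features
#'
#' Maps each encoded feature to its parent SNP's logistic-regression
#' p-value; the score is -log10 p. Used for the "original feature set"
#' experiment, where the screen's own ranking drives selection.
#'
#' @param assoc association table from [run_association()].
#' @param encoded an `encoded_features` object.
#' @return An `importance_ranking`.
#' @export
logistic_importance <- function(assoc, encoded) {
  p <- assoc$p[match(encoded$map$snp_id, assoc$snp_id)]
  if (anyNA(p))
    stopf("encoded features reference SNPs absent from the association table")
  .new_ranking(encoded$map$feature, -log10(p), "logistic")
}

#' Top-quartile selection from a ranking
#'
#' @param ranking an `importance_ranking`.
#' @param quartile fraction to keep (default 0.25); `ceiling(quartile * m)`
#'   features are selected.
#' @return A `selected_features` data frame (feature, score, rank), a
#'   prefix of the ranking, with the ranking's universe attached.
#' @export
top_quartile <- function(ranking, quartile = 0.25) {
  if (nrow(ranking) == 0) stopf("empty ranking")
  k <- ceiling(quartile * nrow(ranking))
  out <- ranking[seq_len(k), c("feature", "score", "rank"), drop = FALSE]
  attr(out, "universe") <- attr(ranking, "universe")
  attr(out, "method") <- attr(ranking, "method")
  class(out) <- c("selected_features", "data.frame")
  out
}

#' Intersect two selected feature sets
#'
#' Keeps features present in both sets, ordered by the mean of the two
#' ranks. The sets must come from the same feature universe.
#'
#' @param A,B `selected_features` objects.
#' @return A `selected_features` data frame (feature, score = negative mean
#'   rank, rank).
#' @export
intersect_sets <- function(A, B) {
  ua <- attr(A, "universe"); ub <- attr(B, "universe")
  if (!is.null(ua) && !is.null(ub) && length(intersect(ua, ub)) == 0)
    stopf("feature universes are disjoint")
  common <- intersect(A$feature, B$feature)
  if (length(common) == 0)
    warnf("intersection of the selected sets is empty")
  mean_rank <- (A$rank[match(common, A$feature)] +
                  B$rank[match(common, B$feature)]) / 2
  ord <- order(mean_rank, common)
  out <- data.frame(feature = common[ord], score = -mean_rank[ord],
                    rank = seq_along(common), stringsAsFactors = FALSE)
  attr(out, "universe") <- sort(union(ua, ub))
  attr(out, "method") <- "hybrid"
  class(out) <- c("selected_features", "data.frame")
  out
}

#' Expand a selected set with map-adjacent neighbour SNPs
#'
#' For every unique parent SNP of the selection, takes up to `k` variants
#' on each side in map order within the same chromosome (truncated at
#' chromosome ends), unions and deduplicates the windows, and one-hot
#' encodes the union as the deep feature space.
#'
#' @param selected a `selected_features` object (one-hot features).
#' @param G the QC'd [genotype_matrix()] supplying the variant map.
#' @param k window half-width in map positions (default 6).
#' @return A `neighbour_expansion`: list(wide = `selected`,
#'   deep = `encoded_features` of the window union, deep_snps, k).
#' @export
neighbour_expand <- function(selected, G, k = 6) {
  parents <- unique(feature_parent(selected$feature))
  idx <- match(parents, G$variants$snp_id)
  if (anyNA(idx))
    stopf("parent SNP(s) absent from the variant map: %s",
          paste(parents[is.na(idx)], collapse = ", "))
  chrom <- G$variants$chrom
  take <- logical(n_variants(G))
  for (i in idx) {
    lo <- max(1, i - k); hi <- min(n_variants(G), i + k)
    win <- lo:hi
    take[win[chrom[win] == chrom[i]]] <- TRUE
  }
  deep_snps <- G$variants$snp_id[take] # map order
  structure(list(wide = selected,
                 deep = one_hot_encode(G, deep_snps),
                 deep_snps = deep_snps, k = k),
            class = "neighbour_expansion")
}

#' @export
print.neighbour_expansion <- function(x, ...) {
  cat(sprintf(
    "neighbour_expansion: %d wide features; %d deep SNPs (k = %d) -> %d deep features\n",
    nrow(x$wide), length(x$deep_snps), x$k, ncol(x$deep$X)))
  invisible(x)
}
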