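#' Extract decision rules from the best tree of a random forest
#'
#' Picks the forest tree with the highest accuracy on a validation set
#' (ties broken toward fewer leaves, then the lower tree index) and turns
#' every root-to-leaf path into a human-readable rule. Splits on one-hot
#' genotype indicators are rendered in genotype vocabulary: indicator = 1
#' reads `snp = genotype`, indicator = 0 reads `snp != genotype`. The rule
#' set partitions the feature space, so it is mutually exclusive and
#' exhaustive by construction.
#'
#' @param rf an `rf_classifier` from [train_rf()].
#' @param X_val validation feature matrix (binary one-hot columns).
#' @param y_val validation labels (0/1).
#' @param X_support,y_support data over which rule support and confidence
#'   are counted (defaults to the validation set; pass the training set to
#'   report training support).
#' @return A `rule_set`: list of rules (conditions, class, support,
#'   confidence, text), the source `tree_id`, its validation accuracy and
#'   leaf count.
#' @export
extract_rules <- function(rf, X_val, y_val,
                          X_support = X_val, y_support = y_val) {
  if (!inherits(rf, "rf_classifier")) stopf("untrained or invalid model")
  if (nrow(as.matrix(X_val)) == 0) stopf("validation set is empty")
  Xv <- as.data.frame(X_val)[, rf$features, drop = FALSE]
  y_lab <- ifelse(as.numeric(y_val) == 1, "case", "control")

  votes <- stats::predict(rf$fit, Xv, predict.all = TRUE)$individual
  acc <- colMeans(votes == y_lab)
  leaves <- vapply(seq_len(rf$fit$ntree), function(t)
    sum(randomForest::getTree(rf$fit, t)[, "status"] == -1), numeric(1))
  ord <- order(-acc, leaves, seq_along(acc))
  best <- ord[1]

  tree <- randomForest::getTree(rf$fit, best, labelVar = TRUE)
  rules <- list()
  walk <- function(node, feats, vals) {
    if (tree$status[node] == -1) {
      rules[[length(rules) + 1]] <<- list(
        features = feats, values = vals,
        class = as.character(tree$prediction[node]))
      return(invisible())
    }
    var <- as.character(tree$`split var`[node])
    walk(tree$`left daughter`[node], c(feats, var), c(vals, 0L))
    walk(tree$`right daughter`[node], c(feats, var), c(vals, 1L))
  }
  walk(1L, character(0), integer(0))

  Xs <- as.matrix(as.data.frame(X_support)[, rf$features, drop = FALSE])
  ys_lab <- ifelse(as.numeric(y_support) == 1, "case", "control")
  rules <- lapply(rules, function(r) {
    hit <- rep(TRUE, nrow(Xs))
    for (k in seq_along(r$features))
      hit <- hit & (Xs[, r$features[k]] == r$values[k])
    r$support <- sum(hit)
    r$confidence <- if (r$support > 0) mean(ys_lab[hit] == r$class)
    else NA_real_
    r$text <- .render_rule(r)
    r
  })
  structure(list(rules = rules, tree_id = best,
                 tree_accuracy = acc[best], n_leaves = leaves[best],
                 features = rf$features),
            class = "rule_set")
}

.render_rule <- function(r) {
  if (length(r$features) == 0) {
    cond <- "TRUE"
  } else {
    snp <- feature_parent(r$features)
    gt <- sub("^.*_", "", r$features)
    cond <- paste(ifelse(r$values == 1L, paste(snp, "=", gt),
                         paste(snp, "!=", gt)),
                  collapse = " AND ")
  }
  sprintf("IF %s THEN %s [support %d, confidence %s]", cond, r$class,
          r$support,
          if (is.na(r$confidence)) "NA" else sprintf("%.2f", r$confidence))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d rules from tree %d (validation accuracy %.3f, %d leaves)\n",
              length(x$rules), x$tree_id, x$tree_accuracy, x$n_leaves))
  for (r in x$rules) cat(" ", r$text, "\n")
  invisible(x)
}

#' Classify a sample with an extracted rule set
#'
#' @param ruleset a `rule_set`.
#' @param sample named numeric vector (or single-row matrix) of one-hot
#'   features covering every feature the rules condition on.
#' @return A list (class, rule_index, rule_text); exactly one rule matches.
#' @export
apply_rules <- function(ruleset, sample) {
  x <- if (is.matrix(sample) || is.data.frame(sample))
    unlist(as.data.frame(sample)[1, , drop = TRUE]) else sample
  needed <- unique(unlist(lapply(ruleset$rules, `[[`, "features")))
  absent <- setdiff(needed, names(x))
  if (length(absent))
    stopf("missing feature(s): %s", paste(absent, collapse = ", "))
  match_idx <- which(vapply(ruleset$rules, function(r) {
    all(x[r$features] == r$values)
  }, logical(1)))
  if (length(match_idx) != 1)
    stopf("rule set matched %d rules; expected exactly 1", length(match_idx))
  r <- ruleset$rules[[match_idx]]
  list(class = r$class, rule_index = match_idx, rule_text = r$text)
}

#' Write a rule set as a plain-text report
#'
#' @param ruleset a `rule_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rules <- function(ruleset, path) {
  writeLines(c(sprintf("# tree %d, validation accuracy %.3f",
                       ruleset$tree_id, ruleset$tree_accuracy),
               vapply(ruleset$rules, `[[`, character(1), "text")), path)
  invisible(path)
}
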