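#' Stratified train/test split
#'
#' @param y binary response (0/1 or factor).
#' @param train_frac training fraction (default 0.7).
#' @param seed RNG seed; the split is deterministic given it.
#' @return A list with integer index vectors `train` and `test`; class
#'   proportions are preserved within one sample.
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2)
    stopf("both classes need at least 2 samples")
  train <- integer(0)
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      n_tr <- round(train_frac * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Stratified k-fold assignments
#'
#' @param y binary response.
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold labels (1..folds), one per sample;
#'   folds are disjoint, exhaustive, and class-balanced within one sample.
#' @export
kfold_indices <- function(y, folds = 5, seed = 1L) {
  y <- as.factor(y)
  if (folds < 2) stopf("folds must be >= 2")
  if (folds > min(table(y)))
    stopf("folds exceed the size of the smallest class")
  assign <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Majority vote over tree predictions
#'
#' @param votes character vector of class labels ("control"/"case").
#' @return A list with the modal `class` and its vote `fraction`; ties
#'   break toward "control", the conservative call for a diagnosis.
#' @export
majority_vote <- function(votes) {
  if (length(votes) == 0) stopf("no votes")
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  cls <- if ("control" %in% top) "control" else sort(top)[1]
  list(class = cls, fraction = as.numeric(max(tab)) / length(votes))
}

#' Random forest classifier
#'
#' Bagged decision trees: a bootstrap sample per tree, a random feature
#' subset per split, class by majority vote, probability = case-vote
#' fraction. A thin, seeded wrapper around the classic Breiman-Cutler
#' forest so that individual trees remain available for rule extraction.
#'
#' @param X numeric feature matrix.
#' @param y binary response (0/1); 1 is the case class.
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `sqrt(p)` rounded down).
#' @param max_depth optional depth cap, enforced as `maxnodes = 2^depth`.
#' @param bootstrap sample with replacement per tree (disable together
#'   with `mtry = p` to grow a single plain decision tree).
#' @param seed RNG seed.
#' @return An `rf_classifier`.
#' @export
train_rf <- function(X, y, n_trees = 500, mtry = NULL, max_depth = NULL,
                     bootstrap = TRUE, seed = 1L) {
  X <- as.data.frame(X)
  yf <- factor(ifelse(as.numeric(y) == 1, "case", "control"),
               levels = c("control", "case"))
  args <- list(x = X, y = yf, ntree = n_trees,
               mtry = mtry %||% max(1, floor(sqrt(ncol(X)))),
               replace = bootstrap)
  if (!bootstrap) args$sampsize <- nrow(X)
  if (!is.null(max_depth)) args$maxnodes <- 2^max_depth
  fit <- with_seed(seed, do.call(randomForest::randomForest, args))
  structure(list(fit = fit, features = colnames(X),
                 config = list(n_trees = n_trees, mtry = args$mtry,
                               max_depth = max_depth, bootstrap = bootstrap,
                               seed = seed)),
            class = "rf_classifier")
}

#' @export
predict.rf_classifier <- function(object, X,
                                  type = c("prob", "class", "votes"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(X)[, object$features, drop = FALSE]
  if (type == "votes") {
    ind <- stats::predict(object$fit, X, predict.all = TRUE)$individual
    return(ind)
  }
  prob <- stats::predict(object$fit, X, type = "prob")[, "case"]
  if (type == "prob") return(unname(prob))
  # strict majority for "case": a 50/50 tie goes to control
  ifelse(prob > 0.5, "case", "control")
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts; cases are the positive class.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stopf("counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = harmonic mean of precision and recall. A ratio with a zero
#' denominator is reported as 0 and listed in `undefined`.
#'
#' @param counts a [confusion_counts()].
#' @return A list (accuracy, precision, recall, f1, counts, undefined).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) stopf("no evaluated samples")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1, counts = counts, undefined = undefined)
}

# threshold sweep shared by roc_points / pr_points: returns cumulative
# TP/FP at each distinct score, descending
.score_sweep <- function(scores, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  list(tp = cumsum(yy)[last_of_group],
       fp = cumsum(1 - yy)[last_of_group],
       thresholds = s[last_of_group],
       n_pos = sum(y), n_neg = sum(1 - y))
}

#' ROC curve and area
#'
#' Threshold sweep over the distinct scores; the area is trapezoidal
#' (equal to the Mann-Whitney U statistic over n1*n0, ties counted half).
#'
#' @param scores numeric case scores.
#' @param y binary labels (0/1).
#' @return A list (fpr, tpr, thresholds, auc); the curve starts at (0, 0).
#' @export
roc_points <- function(scores, y) {
  sw <- .score_sweep(scores, y)
  fpr <- c(0, sw$fp / sw$n_neg)
  tpr <- c(0, sw$tp / sw$n_pos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, sw$thresholds), auc = auc)
}

#' Precision-recall curve and area
#'
#' Threshold sweep over the distinct scores; the area uses step
#' interpolation (average precision): sum over thresholds of
#' (recall increment) x (precision at that threshold).
#'
#' @inheritParams roc_points
#' @return A list (recall, precision, thresholds, auc).
#' @export
pr_points <- function(scores, y) {
  sw <- .score_sweep(scores, y)
  recall <- sw$tp / sw$n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, thresholds = sw$thresholds,
       auc = auc)
}

#' Evaluate case scores against labels
#'
#' Classifies at `threshold` (a score strictly above it is called a case,
#' so an exact 0.5 vote tie goes to control) and assembles confusion
#' counts, the four summary metrics, and ROC / PR curves with areas.
#'
#' @param scores numeric case scores or probabilities.
#' @param y binary labels (0/1).
#' @param threshold decision threshold.
#' @return An `evaluation_report` list.
#' @export
evaluate_scores <- function(scores, y, threshold = 0.5) {
  y <- as.numeric(y)
  pred <- as.numeric(scores > threshold)
  counts <- confusion_counts(tp = sum(pred == 1 & y == 1),
                             tn = sum(pred == 0 & y == 0),
                             fp = sum(pred == 1 & y == 0),
                             fn = sum(pred == 0 & y == 1))
  metrics <- compute_metrics(counts)
  structure(c(metrics,
              list(roc = roc_points(scores, y), pr = pr_points(scores, y),
                   threshold = threshold, n = length(y))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (n = %d): acc %.3f, prec %.3f, rec %.3f, F1 %.3f, ROC-AUC %.3f, PR-AUC %.3f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$roc$auc, x$pr$auc))
  invisible(x)
}

#' Default experiment configuration
#'
#' @param top_k association-screen size fed to feature selection.
#' @param quartile top fraction kept from each ranking.
#' @param neighbour_k window half-width for the deep feature space.
#' @param boruta list of [boruta_select()] arguments.
#' @param nn list of [mlp_train()] training arguments.
#' @param rf list of [train_rf()] arguments.
#' @param train_frac,folds evaluation protocol.
#' @param leakage `"fold-safe"` fits the screen and selection on the
#'   training partition only; `"paper-protocol"` selects on the whole
#'   dataset before splitting (prone to optimistic bias).
#' @param cv run 5-fold cross-validation inside the training partition.
#' @param seed global seed; every stochastic stage derives from it.
#' @return A named list.
#' @export
experiment_config <- function(top_k = 1000, quartile = 0.25,
                              neighbour_k = 6,
                              boruta = list(n_trees = 300, max_iter = 100,
                                            alpha = 0.05),
                              nn = list(lr = 1e-3, batch_size = 32,
                                        epochs = 200, patience = 20),
                              rf = list(n_trees = 500),
                              train_frac = 0.7, folds = 5,
                              leakage = c("fold-safe", "paper-protocol"),
                              cv = TRUE, seed = 1L) {
  list(top_k = top_k, quartile = quartile, neighbour_k = neighbour_k,
       boruta = boruta, nn = nn, rf = rf, train_frac = train_frac,
       folds = folds, leakage = match.arg(leakage), cv = cv,
       seed = as.integer(seed))
}

# Fit one model kind on a feature matrix (and optional wide matrix)
.fit_model <- function(kind, X, y, config, seed, X_wide = NULL) {
  nn_args <- config$nn
  switch(kind,
         rf = do.call(train_rf, c(list(X = X, y = y, seed = seed),
                                  config$rf)),
         wnn = do.call(train_wnn, c(list(X = X, y = y, seed = seed),
                                    nn_args)),
         dnn = do.call(train_dnn, c(list(X = X, y = y, seed = seed),
                                    nn_args)),
         wdnn = do.call(train_wide_deep,
                        c(list(X_wide = X_wide, X_deep = X, y = y,
                               seed = seed), nn_args)),
         stopf("unknown model kind '%s'", kind))
}

.predict_model <- function(model, X, X_wide = NULL) {
  if (inherits(model, "rf_classifier")) predict(model, X, type = "prob")
  else if (model$has_wide) predict(model, X_deep = X, X_wide = X_wide)
  else predict(model, X_deep = X)
}

# CV + hold-out evaluation of one model kind on fixed feature matrices
.evaluate_model <- function(kind, X, y, split, config, seed,
                            X_wide = NULL) {
  tr <- split$train; te <- split$test
  fold_metrics <- NULL
  if (isTRUE(config$cv)) {
    fold_id <- kfold_indices(y[tr], folds = config$folds, seed = seed + 7L)
    fold_metrics <- lapply(seq_len(config$folds), function(f) {
      fit_rows <- tr[fold_id != f]
      val_rows <- tr[fold_id == f]
      mod <- .fit_model(kind, X[fit_rows, , drop = FALSE], y[fit_rows],
                        config, seed + 100L + f,
                        X_wide = if (is.null(X_wide)) NULL
                        else X_wide[fit_rows, , drop = FALSE])
      sc <- .predict_model(mod, X[val_rows, , drop = FALSE],
                           if (is.null(X_wide)) NULL
                           else X_wide[val_rows, , drop = FALSE])
      ev <- evaluate_scores(sc, y[val_rows])
      data.frame(fold = f, accuracy = ev$accuracy, precision = ev$precision,
                 recall = ev$recall, f1 = ev$f1, roc_auc = ev$roc$auc,
                 pr_auc = ev$pr$auc)
    })
    fold_metrics <- do.call(rbind, fold_metrics)
  }
  final <- .fit_model(kind, X[tr, , drop = FALSE], y[tr], config, seed,
                      X_wide = if (is.null(X_wide)) NULL
                      else X_wide[tr, , drop = FALSE])
  sc <- .predict_model(final, X[te, , drop = FALSE],
                       if (is.null(X_wide)) NULL
                       else X_wide[te, , drop = FALSE])
  list(model = final, holdout = evaluate_scores(sc, y[te]),
       cv = fold_metrics)
}

#' Run one of the five classification experiments
#'
#' Assembles the experiment's feature set from a QC'd cohort and trains
#' and evaluates its classifiers with the 70/30 + 5-fold protocol:
#' \describe{
#'   \item{1}{intersection of the PCA and Boruta top quartiles (RF, wide
#'     NN, deep NN)}
#'   \item{2}{Boruta top quartile (RF, wide NN, deep NN)}
#'   \item{3}{PCA top quartile (RF, wide NN, deep NN)}
#'   \item{4}{wide-and-deep network: experiment-1 features on the wide
#'     path, their neighbour-SNP windows on the deep path; a deep-only
#'     ablation is evaluated alongside}
#'   \item{5}{association-screen (logistic) top quartile (RF, wide NN,
#'     deep NN)}
#' }
#'
#' @param exp_id integer 1-5.
#' @param G a QC'd [genotype_matrix()].
#' @param config an [experiment_config()].
#' @return An `experiment_report`: list with `exp_id`, `features` (wide
#'   feature names), `deep_snps` (experiment 4), `selection` (the rankings
#'   used) and `models` (per-model list of final model, hold-out
#'   `evaluation_report` and per-fold CV metrics).
#' @export
run_experiment <- function(exp_id, G, config = experiment_config()) {
  if (!exp_id %in% 1:5) stopf("exp_id must be 1..5")
  y <- phenotype01(G)
  split <- stratified_split(y, config$train_frac, seed = config$seed)
  sel_rows <- if (config$leakage == "fold-safe") split$train
  else seq_along(y)

  G_sel <- subset_samples(G, sel_rows)
  assoc <- run_association(G_sel)
  top <- select_top_k(assoc, config$top_k)
  encoded <- one_hot_encode(G, top$snp_id)
  X_all <- encoded$X
  X_sel <- X_all[sel_rows, , drop = FALSE]
  y_sel <- y[sel_rows]

  selection <- list()
  need_pca <- exp_id %in% c(1, 3, 4)
  need_boruta <- exp_id %in% c(1, 2, 4)
  if (need_pca)
    selection$pca <- pca_importance(X_sel)
  if (need_boruta)
    selection$boruta <- do.call(boruta_select,
                                c(list(X = X_sel, y = y_sel,
                                       seed = config$seed + 13L),
                                  config$boruta))
  wide_set <- switch(as.character(exp_id),
                     `1` = , `4` = intersect_sets(
                       top_quartile(selection$pca, config$quartile),
                       top_quartile(selection$boruta, config$quartile)),
                     `2` = top_quartile(selection$boruta, config$quartile),
                     `3` = top_quartile(selection$pca, config$quartile),
                     `5` = top_quartile(
                       logistic_importance(assoc, encoded), config$quartile))
  if (nrow(wide_set) == 0) stopf("empty feature set")
  X_wide <- X_all[, wide_set$feature, drop = FALSE]

  models <- list()
  if (exp_id == 4) {
    expansion <- neighbour_expand(wide_set, G, config$neighbour_k)
    X_deep <- expansion$deep$X
    models$wdnn <- .evaluate_model("wdnn", X_deep, y, split, config,
                                   config$seed + 41L, X_wide = X_wide)
    models$dnn_deep_only <- .evaluate_model("dnn", X_deep, y, split, config,
                                            config$seed + 41L)
  } else {
    for (kind in c("rf", "wnn", "dnn"))
      models[[kind]] <- .evaluate_model(kind, X_wide, y, split, config,
                                        config$seed + 41L)
  }
  structure(list(exp_id = exp_id,
                 features = wide_set$feature,
                 deep_snps = if (exp_id == 4) expansion$deep_snps else NULL,
                 selection = selection,
                 split = split,
                 models = models,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment %d: %d wide features%s\n", x$exp_id,
              length(x$features),
              if (!is.null(x$deep_snps))
                sprintf(", %d deep SNPs", length(x$deep_snps)) else ""))
  for (nm in names(x$models)) {
    h <- x$models[[nm]]$holdout
    cat(sprintf(
      "  %-14s hold-out: acc %.3f prec %.3f rec %.3f F1 %.3f AUC %.3f\n",
      nm, h$accuracy, h$precision, h$recall, h$f1, h$roc$auc))
  }
  invisible(x)
}
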