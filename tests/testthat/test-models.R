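test_that("stratified splitting preserves class balance within one sample", {
  y <- rep(c(1, 0), times = c(100, 100))
  sp <- stratified_split(y, 0.7, seed = 1)
  expect_identical(length(sp$train), 140L)
  expect_identical(sum(y[sp$train]), 70)
  expect_identical(sum(y[sp$test]), 30)

  # the 174-case / 214-control cohort geometry
  y2 <- rep(c(1, 0), times = c(174, 214))
  sp2 <- stratified_split(y2, 0.7, seed = 2)
  expect_true(length(sp2$train) %in% c(271L, 272L))
  case_frac_global <- 174 / 388
  case_frac_train <- sum(y2[sp2$train]) / length(sp2$train)
  expect_lt(abs(case_frac_train - case_frac_global),
            1 / length(sp2$train) + 1e-12)

  expect_identical(stratified_split(y, 0.7, seed = 9)$train,
                   stratified_split(y, 0.7, seed = 9)$train)
  expect_error(stratified_split(rep(1, 10), 0.7, 1), "both classes")
})

test_that("k-fold assignments are disjoint, exhaustive and stratified", {
  y <- rep(c(0, 1), each = 25)
  f <- kfold_indices(y, folds = 5, seed = 3)
  expect_identical(as.integer(table(f)), rep(10L, 5))
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f == k), 10L)
    expect_lte(abs(sum(y[f == k]) / 10 - 0.5), 0.1 + 1e-12)
  }
  expect_error(kfold_indices(c(0, 0, 1), folds = 2), "smallest class")
})

test_that("majority vote picks the modal class and breaks ties to control", {
  v <- majority_vote(c("control", "control", "case"))
  expect_identical(v$class, "control")
  expect_equal(v$fraction, 2 / 3)
  expect_identical(majority_vote(rep("case", 5))$class, "case")
  expect_identical(majority_vote(c("case", "case", "control", "control"))$class,
                   "control")
})

test_that("metric identities reproduce printed precision/recall -> F1 rows", {
  # fractional confusion cells realise each printed (precision, recall)
  cells <- function(prec, rec) {
    tp <- rec
    confusion_counts(tp = tp, tn = 1, fp = tp * (1 / prec - 1), fn = 1 - rec)
  }
  m1 <- compute_metrics(cells(0.96, 0.81))
  expect_equal(round(100 * m1$f1), 88)
  m2 <- compute_metrics(cells(0.99, 0.68))
  expect_equal(round(100 * m2$f1), 81)
  m3 <- compute_metrics(cells(0.99, 0.81))
  expect_equal(round(100 * m3$f1), 89)

  perfect <- compute_metrics(confusion_counts(50, 50, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  degenerate <- compute_metrics(confusion_counts(0, 10, 0, 5))
  expect_identical(degenerate$precision, 0)
  expect_true("precision" %in% degenerate$undefined)
})

test_that("ROC area equals the Mann-Whitney statistic and PR behaves", {
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.4, 0.4, 0.2, 0.1)
  y <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  roc <- roc_points(scores, y)
  w <- wilcox.test(scores[y == 1], scores[y == 0], exact = FALSE)
  expect_equal(roc$auc, unname(w$statistic) / (sum(y) * sum(1 - y)),
               tolerance = 1e-12)

  perfect <- roc_points(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(pr_points(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)

  set.seed(31)
  s <- runif(2000); yy <- rep_len(0:1, 2000)
  expect_gt(roc_points(s, yy)$auc, 0.47)
  expect_lt(roc_points(s, yy)$auc, 0.53)
  expect_error(roc_points(1:5, rep(1, 5)), "both classes")
})

test_that("ROC/PR agree with the pROC cross-check on a noisy fixture", {
  skip_if_not_installed("pROC")
  set.seed(32)
  y <- rbinom(200, 1, 0.4)
  s <- y * 0.3 + rnorm(200)
  ours <- roc_points(s, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("a single unbagged full-mtry tree matches a CART oracle's predictions", {
  skip_if_not_installed("rpart")
  set.seed(33)
  X <- data.frame(a = rep(0:1, each = 10), b = rep_len(0:1, 20),
                  c = rbinom(20, 1, 0.5))
  y <- as.numeric(X$a == 1 | (X$b == 1 & X$c == 1))
  rf <- train_rf(X, y, n_trees = 1, mtry = 3, bootstrap = FALSE, seed = 1)
  ours <- predict(rf, X, type = "class")
  cart <- rpart::rpart(factor(y) ~ ., data = X, method = "class",
                       control = rpart::rpart.control(minsplit = 2, cp = 0))
  theirs <- ifelse(predict(cart, X, type = "class") == "1", "case", "control")
  expect_identical(unname(ours), unname(theirs))
})

test_that("random forest fits separable data and emits vote probabilities", {
  set.seed(34)
  X <- data.frame(x1 = c(rnorm(40, -2), rnorm(40, 2)), x2 = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  rf <- train_rf(X, y, n_trees = 100, seed = 5)
  expect_equal(mean((predict(rf, X, type = "class") == "case") == y), 1)
  pr <- predict(rf, X, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  votes <- predict(rf, X[1:3, ], type = "votes")
  expect_identical(dim(votes), c(3L, 100L))
  # vote fractions over the two classes sum to one
  p_case <- unname(rowMeans(votes == "case"))
  expect_equal(p_case + unname(rowMeans(votes == "control")), rep(1, 3))
  expect_equal(unname(pr[1:3]), unname(p_case))
  # reproducible under seed
  rf2 <- train_rf(X, y, n_trees = 100, seed = 5)
  expect_identical(predict(rf, X), predict(rf2, X))
})

test_that("the wide network learns XOR structure", {
  set.seed(35)
  X <- cbind(a = rep(0:1, each = 40), b = rep_len(rep(0:1, each = 20), 80))
  y <- as.numeric(xor(X[, 1], X[, 2]))
  net <- train_wnn(X, y, width = 8, epochs = 400, patience = 400,
                   val_frac = 0, lr = 0.01, seed = 2)
  acc <- mean((predict(net, X) > 0.5) == y)
  expect_gte(acc, 0.95)
})

test_that("network training is deterministic and untrained nets sit at chance", {
  set.seed(36)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- rep_len(0:1, 60)
  n1 <- train_dnn(X, y, widths = c(8, 4), epochs = 15, seed = 7)
  n2 <- train_dnn(X, y, widths = c(8, 4), epochs = 15, seed = 7)
  expect_identical(n1$par, n2$par)
  n0 <- train_dnn(X, y, widths = c(8, 4), epochs = 0, seed = 7)
  auc <- roc_points(predict(n0, X), y)$auc
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
  expect_error(train_dnn(cbind(X, NA), y), "non-finite")
})

test_that("deep network separates a linearly separable toy set", {
  set.seed(37)
  X <- rbind(matrix(rnorm(200, -1.5), 100, 2), matrix(rnorm(200, 1.5), 100, 2))
  y <- rep(c(0, 1), each = 100)
  sp <- stratified_split(y, 0.7, seed = 1)
  net <- train_dnn(X[sp$train, ], y[sp$train], widths = c(16, 8),
                   epochs = 150, lr = 5e-3, seed = 3)
  acc <- mean((predict(net, X[sp$test, ]) > 0.5) == y[sp$test])
  expect_gte(acc, 0.95)
})

test_that("wide-and-deep wiring obeys the shape law and its degeneracies", {
  set.seed(38)
  Xd <- matrix(rnorm(50 * 6), 50, 6)
  Xw <- matrix(rbinom(50 * 4, 1, 0.5), 50, 4)
  y <- rep_len(0:1, 50)
  wd <- train_wide_deep(Xw, Xd, y, widths = c(8, 5), epochs = 5, seed = 4)
  # output unit consumes last deep width + wide feature count
  expect_identical(dim(wd$par$w_out), c(5L + 4L, 1L))

  # an empty wide block reduces exactly to the deep network
  wd0 <- train_wide_deep(Xw[, 0], Xd, y, widths = c(8, 5), epochs = 5,
                         seed = 4)
  dn <- train_dnn(Xd, y, widths = c(8, 5), epochs = 5, seed = 4)
  expect_equal(predict(wd0, Xd), predict(dn, Xd), tolerance = 1e-12)
  expect_error(train_wide_deep(Xw[1:10, ], Xd, y), "same number of rows")
})

test_that("informative wide features rescue an all-noise deep path", {
  set.seed(39)
  n <- 240
  y <- rep_len(0:1, n)
  Xw <- cbind(y + rnorm(n, sd = 0.6), y + rnorm(n, sd = 0.8))
  Xd <- matrix(rnorm(n * 30), n, 30)
  sp <- stratified_split(y, 0.7, seed = 2)
  args <- list(widths = c(16, 8), epochs = 80, seed = 6)
  wd <- do.call(train_wide_deep,
                c(list(X_wide = Xw[sp$train, ], X_deep = Xd[sp$train, ],
                       y = y[sp$train]), args))
  dn <- do.call(train_dnn, c(list(X = Xd[sp$train, ], y = y[sp$train]), args))
  auc_wd <- roc_points(predict(wd, Xd[sp$test, ], Xw[sp$test, ]),
                       y[sp$test])$auc
  auc_dn <- roc_points(predict(dn, Xd[sp$test, ]), y[sp$test])$auc
  expect_gte(auc_wd, auc_dn)
})

test_that("wide and deep networks land close together on planted features", {
  sim <- toy_planted_cohort(seed = 41)
  G <- run_qc(sim$G)$G
  y <- phenotype01(G)
  enc <- one_hot_encode(G, sim$truth$causal$snp_id)
  sp <- stratified_split(y, 0.7, seed = 3)
  args <- list(epochs = 80, seed = 8)
  wnn <- do.call(train_wnn, c(list(X = enc$X[sp$train, ], y = y[sp$train],
                                   width = 64), args))
  dnn <- do.call(train_dnn, c(list(X = enc$X[sp$train, ], y = y[sp$train],
                                   widths = c(32, 16)), args))
  auc_w <- roc_points(predict(wnn, enc$X[sp$test, ]), y[sp$test])$auc
  auc_d <- roc_points(predict(dnn, enc$X[sp$test, ]), y[sp$test])$auc
  expect_lt(abs(auc_w - auc_d), 0.1)
})

test_that("experiment runner wires feature sets and reports consistently", {
  sim <- toy_planted_cohort(seed = 42)
  G <- run_qc(sim$G)$G
  ec <- experiment_config(top_k = 120,
                          boruta = list(n_trees = 100, max_iter = 15),
                          nn = list(epochs = 25, patience = 10),
                          rf = list(n_trees = 100),
                          cv = FALSE, seed = 11)
  rep5 <- run_experiment(5, G, ec)
  expect_setequal(names(rep5$models), c("rf", "wnn", "dnn"))
  expect_identical(length(rep5$features), as.integer(ceiling(0.25 * 3 * 120)))
  # EXP5 ranking = association order mapped to one-hot features
  assoc <- run_association(subset_samples(G, rep5$split$train))
  top <- select_top_k(assoc, 120)
  best <- top$snp_id[1]
  expect_true(any(feature_parent(rep5$features) == best))
  for (m in rep5$models) {
    h <- m$holdout
    expect_identical(h$n, length(rep5$split$test))
    expect_true(all(unlist(h[c("accuracy", "precision", "recall", "f1")]) >= 0))
  }
  # rerunning with the same config reproduces the reports exactly
  rep5b <- run_experiment(5, G, ec)
  expect_equal(rep5$models$wnn$holdout$roc$auc,
               rep5b$models$wnn$holdout$roc$auc, tolerance = 1e-12)
  expect_error(run_experiment(6, G, ec), "exp_id")
})
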