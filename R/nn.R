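#' Feed-forward classifiers for genotype features
#'
#' A small fully-connected network family trained by mini-batch Adam on
#' binary cross-entropy, with ReLU hidden units, a sigmoid output, a
#' held-back validation split and early stopping. Three architectures share
#' the engine: the wide network (one broad hidden layer), the deep network
#' (a narrowing stack), and the wide-and-deep network, whose curated wide
#' features are concatenated with the last hidden representation of the
#' deep stack immediately before the output unit — the wide path therefore
#' feeds the final decision directly while the deep path supplies learned
#' interactions from the larger feature space.
#'
#' @name mlp
NULL

.relu <- function(x) (x > 0) * x

.mlp_init <- function(p_deep, p_wide, widths) {
  W <- list(); b <- list()
  fan <- p_deep
  for (l in seq_along(widths)) {
    W[[l]] <- matrix(stats::rnorm(fan * widths[l], sd = sqrt(2 / fan)),
                     fan, widths[l])
    b[[l]] <- numeric(widths[l])
    fan <- widths[l]
  }
  p_out <- fan + p_wide
  list(W = W, b = b,
       w_out = matrix(stats::rnorm(p_out, sd = sqrt(1 / max(p_out, 1))),
                      p_out, 1),
       b_out = 0)
}

.mlp_forward <- function(par, X_deep, X_wide) {
  A <- X_deep
  Z <- vector("list", length(par$W))
  As <- vector("list", length(par$W) + 1)
  As[[1]] <- A
  for (l in seq_along(par$W)) {
    Z[[l]] <- sweep(A %*% par$W[[l]], 2, par$b[[l]], `+`)
    A <- .relu(Z[[l]])
    As[[l + 1]] <- A
  }
  C <- if (is.null(X_wide)) A else cbind(A, X_wide)
  eta <- as.vector(C %*% par$w_out) + par$b_out
  list(p = sigmoid(eta), C = C, Z = Z, As = As)
}

.bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# One Adam step over the flattened parameter list
.adam_update <- function(par, grads, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

.flatten_par <- function(par) {
  out <- list()
  for (l in seq_along(par$W)) {
    out[[paste0("W", l)]] <- par$W[[l]]
    out[[paste0("b", l)]] <- par$b[[l]]
  }
  out$w_out <- par$w_out
  out$b_out <- par$b_out
  out
}

.unflatten_par <- function(flat, n_layers) {
  W <- list(); b <- list()
  for (l in seq_len(n_layers)) {
    W[[l]] <- flat[[paste0("W", l)]]
    b[[l]] <- flat[[paste0("b", l)]]
  }
  list(W = W, b = b, w_out = flat$w_out, b_out = flat$b_out)
}

.mlp_grads <- function(par, X_deep, X_wide, y) {
  nb <- nrow(X_deep)
  fwd <- .mlp_forward(par, X_deep, X_wide)
  dz <- matrix((fwd$p - y) / nb, ncol = 1)
  grads <- list(w_out = crossprod(fwd$C, dz), b_out = sum(dz))
  nL <- length(par$W)
  dC <- dz %*% t(par$w_out)
  dA <- if (nL > 0) dC[, seq_len(ncol(fwd$As[[nL + 1]])), drop = FALSE]
  else NULL
  for (l in rev(seq_len(nL))) {
    dZ <- dA * (fwd$Z[[l]] > 0)
    grads[[paste0("W", l)]] <- crossprod(fwd$As[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(par$W[[l]])
  }
  grads
}

.check_matrix <- function(X, what) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stopf("%s contains non-finite values", what)
  X
}

#' Train a feed-forward classifier
#'
#' Engine behind [train_wnn()], [train_dnn()] and [train_wide_deep()].
#'
#' @param X_deep numeric matrix fed to the hidden stack.
#' @param y binary response (0/1).
#' @param X_wide optional matrix concatenated before the output unit.
#' @param widths hidden-layer widths (may be empty: logistic model).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience, in epochs without validation
#'   improvement.
#' @param val_frac fraction of rows held back for validation.
#' @param seed RNG seed; training is deterministic given it.
#' @return An `mlp_classifier`.
#' @export
mlp_train <- function(X_deep, y, X_wide = NULL, widths = c(64, 32, 16),
                      lr = 1e-3, batch_size = 32, epochs = 200,
                      patience = 20, val_frac = 0.15, seed = 1L) {
  X_deep <- .check_matrix(X_deep, "X_deep")
  if (!is.null(X_wide)) {
    if (ncol(as.matrix(X_wide)) == 0) X_wide <- NULL
    else {
      X_wide <- .check_matrix(X_wide, "X_wide")
      if (nrow(X_wide) != nrow(X_deep))
        stopf("X_wide and X_deep must have the same number of rows")
    }
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  n <- nrow(X_deep)
  widths <- as.integer(widths)

  with_seed(seed, {
    par <- .mlp_init(ncol(X_deep), if (is.null(X_wide)) 0 else ncol(X_wide),
                     widths)
    par <- .flatten_par(par)
    par <- .unflatten_par(par, length(widths)) # canonical shape
    n_val <- max(0L, min(n - 2L, round(val_frac * n)))
    val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    state <- list(m = lapply(.flatten_par(par), function(x) x * 0),
                  v = lapply(.flatten_par(par), function(x) x * 0))
    best <- list(par = par, loss = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    step <- 0L
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, length(ord))]
        grads <- .mlp_grads(par, X_deep[rows, , drop = FALSE],
                            if (is.null(X_wide)) NULL
                            else X_wide[rows, , drop = FALSE],
                            y[rows])
        step <- step + 1L
        flat <- .flatten_par(par)
        upd <- .adam_update(flat, grads, state, lr, step)
        par <- .unflatten_par(upd$par, length(widths))
        state <- upd$state
      }
      tr_loss <- .bce(.mlp_forward(par, X_deep[tr_idx, , drop = FALSE],
                                   if (is.null(X_wide)) NULL
                                   else X_wide[tr_idx, , drop = FALSE])$p,
                      y[tr_idx])
      val_loss <- if (n_val > 0)
        .bce(.mlp_forward(par, X_deep[val_idx, , drop = FALSE],
                          if (is.null(X_wide)) NULL
                          else X_wide[val_idx, , drop = FALSE])$p,
             y[val_idx])
      else tr_loss
      history <- rbind(history, data.frame(epoch = ep, train_loss = tr_loss,
                                           val_loss = val_loss))
      if (val_loss < best$loss - 1e-8) {
        best <- list(par = par, loss = val_loss, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    if (epochs > 0 && best$epoch > 0) par <- best$par
    structure(list(par = par, widths = widths,
                   has_wide = !is.null(X_wide),
                   p_deep = ncol(X_deep),
                   p_wide = if (is.null(X_wide)) 0L else ncol(X_wide),
                   deep_features = colnames(X_deep),
                   wide_features = if (is.null(X_wide)) NULL
                   else colnames(X_wide),
                   history = history,
                   config = list(lr = lr, batch_size = batch_size,
                                 epochs = epochs, patience = patience,
                                 val_frac = val_frac, seed = seed)),
              class = "mlp_classifier")
  })
}

#' Predicted case probabilities from a trained network
#'
#' @param object an `mlp_classifier`.
#' @param X_deep matrix for the deep path (the only input for wide-only and
#'   deep-only networks).
#' @param X_wide matrix for the wide path (wide-and-deep networks only).
#' @param ... unused.
#' @return Numeric vector of case probabilities.
#' @export
predict.mlp_classifier <- function(object, X_deep, X_wide = NULL, ...) {
  X_deep <- .check_matrix(X_deep, "X_deep")
  if (object$has_wide) {
    if (is.null(X_wide)) stopf("this network requires X_wide")
    X_wide <- .check_matrix(X_wide, "X_wide")
  } else {
    X_wide <- NULL
  }
  .mlp_forward(object$par, X_deep, X_wide)$p
}

#' @export
print.mlp_classifier <- function(x, ...) {
  arch <- if (length(x$widths) == 0) "<linear>"
  else paste(x$widths, collapse = "-")
  cat(sprintf("mlp_classifier: deep %d -> [%s]%s -> sigmoid (%d epochs)\n",
              x$p_deep, arch,
              if (x$has_wide) sprintf(" + wide %d", x$p_wide) else "",
              max(x$history$epoch, 0)))
  invisible(x)
}

#' Wide neural network
#'
#' One broad hidden layer (default 256 ReLU units) over the curated feature
#' set.
#'
#' @param X feature matrix.
#' @param y binary response (0/1).
#' @param width hidden-layer width.
#' @param ... passed to [mlp_train()].
#' @return An `mlp_classifier`.
#' @export
train_wnn <- function(X, y, width = 256, ...) {
  mlp_train(X, y, X_wide = NULL, widths = width, ...)
}

#' Deep neural network
#'
#' A narrowing ReLU stack (default 64-32-16).
#'
#' @inheritParams train_wnn
#' @param widths hidden-layer widths.
#' @return An `mlp_classifier`.
#' @export
train_dnn <- function(X, y, widths = c(64, 32, 16), ...) {
  mlp_train(X, y, X_wide = NULL, widths = widths, ...)
}

#' Wide-and-deep neural network
#'
#' The deep stack consumes `X_deep`; `X_wide` joins the last hidden
#' representation immediately before the sigmoid output, so the output
#' unit sees `last deep width + wide feature count` inputs.
#'
#' @param X_wide curated wide features.
#' @param X_deep expanded deep features (row-aligned with `X_wide`).
#' @param y binary response (0/1).
#' @param widths deep-stack widths.
#' @param ... passed to [mlp_train()].
#' @return An `mlp_classifier`.
#' @export
train_wide_deep <- function(X_wide, X_deep, y, widths = c(64, 32, 16), ...) {
  mlp_train(X_deep, y, X_wide = X_wide, widths = widths, ...)
}
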