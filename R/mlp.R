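# Dense classification heads: tanh hidden layers, Glorot-normal weights,
# inverted dropout on one hidden layer, sigmoid output, trained full-batch
# with Adam under binary cross-entropy + L2.

#' Binary cross-entropy with L2 regularization
#'
#' Mean binary cross-entropy over the batch (predictions clipped to
#' `[eps, 1 - eps]`) plus `(1/2) * lambda * sum(||W_k||^2)` over the supplied
#' weight matrices. This is the single training loss shared by both branch
#' heads and the attention stage.
#'
#' @param y_true Binary labels.
#' @param y_pred Predicted probabilities.
#' @param weights List of weight matrices entering the L2 term.
#' @param lambda Regularization coefficient (>= 0).
#' @param eps Probability clipping bound in (0, 0.5).
#' @return The scalar loss.
#' @export
bce_l2_loss <- function(y_true, y_pred, weights = list(), lambda = 0,
                        eps = 1e-7) {
  if (length(y_true) != length(y_pred)) abort("length mismatch.")
  if (lambda < 0) abort("`lambda` must be >= 0.")
  assert_fraction(eps, "eps", lo_open = TRUE, hi = 0.5, hi_open = TRUE)
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  bce <- -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  l2 <- 0.5 * lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  bce + l2
}

init_dense_head <- function(input_dim, units, seed, dropout_after = 2L) {
  dims <- c(input_dim, units, 1L)
  with_seed(seed, {
    W <- lapply(seq_len(length(dims) - 1L),
                function(i) glorot_matrix(dims[i + 1L], dims[i]))
  })
  b <- lapply(seq_len(length(dims) - 1L), function(i) rep(0, dims[i + 1L]))
  list(W = W, b = b, dropout_after = as.integer(dropout_after),
       n_hidden = length(units))
}

# Forward pass; X is n x input_dim. mask (n x units[dropout_after]) applies
# inverted dropout when given. Returns activations for backprop.
head_forward <- function(head, X, dropout_rate = 0, mask = NULL) {
  L <- head$n_hidden
  H <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% t(head$W[[l]]) + matrix(head$b[[l]], nrow(A), length(head$b[[l]]),
                                       byrow = TRUE)
    H[[l]] <- tanh(Z)
    A <- H[[l]]
    if (!is.null(mask) && l == head$dropout_after && dropout_rate > 0) {
      A <- A * mask / (1 - dropout_rate)
      H[[l]] <- A   # store post-dropout activation; tanh grad uses pre-dropout
      attr(H[[l]], "pre") <- tanh(Z)
    }
  }
  z_out <- as.vector(A %*% t(head$W[[L + 1L]])) + head$b[[L + 1L]]
  list(p = sigmoid(z_out), H = H)
}

head_weights <- function(head) head$W

# Full-batch analytic gradient of bce_l2_loss wrt all head parameters.
head_grad <- function(head, X, y, lambda, dropout_rate = 0, mask = NULL) {
  n <- nrow(X)
  L <- head$n_hidden
  fw <- head_forward(head, X, dropout_rate, mask)
  dW <- vector("list", L + 1L)
  db <- vector("list", L + 1L)
  delta <- matrix((fw$p - y) / n, ncol = 1)            # d loss / d z_out
  A_last <- fw$H[[L]]
  dW[[L + 1L]] <- t(delta) %*% A_last + lambda * head$W[[L + 1L]]
  db[[L + 1L]] <- sum(delta)
  dA <- delta %*% head$W[[L + 1L]]
  for (l in rev(seq_len(L))) {
    act <- fw$H[[l]]
    pre <- attr(act, "pre")
    if (!is.null(pre) && dropout_rate > 0) {
      # undo dropout scaling on the gradient, then tanh'
      dA <- dA * mask / (1 - dropout_rate)
      dZ <- dA * (1 - pre^2)
    } else {
      dZ <- dA * (1 - act^2)
    }
    A_prev <- if (l == 1L) X else {
      a <- fw$H[[l - 1L]]
      a
    }
    dW[[l]] <- t(dZ) %*% A_prev + lambda * head$W[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1L) dA <- dZ %*% head$W[[l]]
  }
  list(dW = dW, db = db, p = fw$p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Train a dense head with full-batch Adam. Loss history is evaluated without
# dropout after each epoch. Optional early stopping on validation AUC.
train_dense_head <- function(X, y, units, seed, epochs = 30, lr = 1e-3,
                             lambda = 1e-4, dropout_rate = 0.5,
                             dropout_after = 2L, val_fraction = 0,
                             patience = 5) {
  head <- init_dense_head(ncol(X), units, seed, dropout_after)
  val_idx <- integer(0)
  if (val_fraction > 0) {
    val_idx <- train_test_split(y, val_fraction, seed + 7L)$test
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  n_drop_units <- units[dropout_after]
  flat <- function(h) c(h$W, h$b)
  unflat <- function(v, h) {
    h$W <- v[seq_along(h$W)]
    h$b <- v[length(h$W) + seq_along(h$b)]
    h
  }
  state <- adam_init(flat(head))
  history <- numeric(epochs)
  best <- list(auc = -Inf, head = head, epoch = 0L)
  mask_seed <- substream_seed(seed, "dropout")
  for (e in seq_len(epochs)) {
    mask <- if (dropout_rate > 0) {
      with_seed(mask_seed + e,
                matrix(runif(nrow(Xtr) * n_drop_units) >= dropout_rate,
                       nrow(Xtr), n_drop_units) * 1)
    } else NULL
    g <- head_grad(head, Xtr, ytr, lambda, dropout_rate, mask)
    upd <- adam_step(flat(head), c(g$dW, g$db), state, lr)
    head <- unflat(upd$params, head)
    state <- upd$state
    p_eval <- head_forward(head, Xtr)$p
    history[e] <- bce_l2_loss(ytr, p_eval, head_weights(head), lambda)
    if (length(val_idx) > 0) {
      pv <- head_forward(head, X[val_idx, , drop = FALSE])$p
      auc_v <- if (length(unique(y[val_idx])) > 1L) auc_score(y[val_idx], pv) else NA
      if (!is.na(auc_v) && auc_v > best$auc) {
        best <- list(auc = auc_v, head = head, epoch = e)
      } else if (e - best$epoch >= patience && best$epoch > 0L) {
        head <- best$head
        history <- history[seq_len(e)]
        break
      }
    }
  }
  if (length(val_idx) > 0 && best$epoch > 0L) head <- best$head
  p_final <- head_forward(head, X)$p
  list(head = head, loss_history = history,
       train_acc = mean((p_final >= 0.5) == (y == 1L)))
}
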