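# Modality-specific convolutional branches. Both branches share one
# primitive set: constant-initialized stride-1 same-padded convolutions,
# per-channel matrix-product fusion, multi-pooling blocks, and a dense tanh
# head with dropout and a sigmoid output unit. The convolutional trunks are
# constant-initialized deterministic feature extractors; gradient training
# under the shared loss applies to the dense heads.

branch_config <- function(type, input_side, n_filters, kernel_init_constant,
                          dense_units, dropout_rate, dropout_after,
                          pool_window, seed) {
  assert_count(input_side, "input_side", min = 4L)
  assert_count(n_filters, "n_filters")
  assert_fraction(dropout_rate, "dropout_rate", hi_open = TRUE)
  structure(list(type = type, input_side = as.integer(input_side),
                 n_filters = as.integer(n_filters),
                 kernel_init_constant = kernel_init_constant,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 dropout_after = as.integer(dropout_after),
                 pool_window = as.integer(pool_window),
                 seed = as.integer(seed)),
            class = c(paste0(type, "_branch_config"), "branch_config"))
}

#' EEG branch configuration
#'
#' @param input_side Side `D` of the `1 x D x D` input map.
#' @param n_filters Channels of every trunk convolution (default 8).
#' @param kernel_init_constant Constant filling all trunk kernels (default 0.1).
#' @param dense_units Dense head layer sizes (default 150, 100, 50).
#' @param dropout_rate Dropout on the designated hidden layer (default 0.5).
#' @param dropout_after Index of the hidden layer carrying dropout
#'   (default 2, the 100-unit layer).
#' @param pool_window Pooling window of the multi-pooling blocks (default 2).
#' @param seed Seed for the Glorot-initialized dense head.
#' @return An `eeg_branch_config`.
#' @export
eeg_branch_config <- function(input_side = 8, n_filters = 8,
                              kernel_init_constant = 0.1,
                              dense_units = c(150, 100, 50),
                              dropout_rate = 0.5, dropout_after = 2,
                              pool_window = 2, seed = 1) {
  branch_config("eeg", input_side, n_filters, kernel_init_constant,
                dense_units, dropout_rate, dropout_after, pool_window, seed)
}

#' sMRI branch configuration
#'
#' Same conventions as [eeg_branch_config()]; the dense head has layer sizes
#' 200, 150, 50 with dropout after the 150-unit layer.
#'
#' @inheritParams eeg_branch_config
#' @return An `smri_branch_config`.
#' @export
smri_branch_config <- function(input_side = 8, n_filters = 8,
                               kernel_init_constant = 0.1,
                               dense_units = c(200, 150, 50),
                               dropout_rate = 0.5, dropout_after = 2,
                               pool_window = 2, seed = 1) {
  branch_config("smri", input_side, n_filters, kernel_init_constant,
                dense_units, dropout_rate, dropout_after, pool_window, seed)
}

# EEG trunk (multipool = FALSE gives the ablation variant that lacks the
# multi-pooling blocks: the raw products S1/S2 feed the closing fusion).
eeg_trunk <- function(map, config, multipool = TRUE) {
  nf <- config$n_filters; kc <- config$kernel_init_constant
  X1 <- conv_same(conv_same(map, 2, nf, kc), 2, nf, kc)
  X2 <- conv_same(conv_same(X1, 3, nf, kc), 4, nf, kc)
  X3 <- conv_same(conv_same(X1, 3, nf, kc), 4, nf, kc)
  S1 <- matmul_fuse(X1, X2)
  S2 <- matmul_fuse(X1, X3)
  if (multipool) {
    B1 <- multipool_block(S1, nf, kc, config$pool_window)
    B2 <- multipool_block(S2, nf, kc, config$pool_window)
  } else {
    B1 <- S1; B2 <- S2
  }
  P <- matmul_fuse(B1, B2)
  features <- concat_channels(P, X1)
  list(X1 = X1, X2 = X2, X3 = X3, S1 = S1, S2 = S2, B1 = B1, B2 = B2,
       P = P, features = features)
}

# sMRI trunk: stem of two k=2 convs, then two sequential extraction paths
# (k3 -> k4 and k4 -> k2), per-path matrix products Q1/Q2, channel
# concatenation A1, and the dual-pooling fusion A2 (skipped when
# multipool = FALSE; A1 then feeds the head directly).
smri_trunk <- function(map, config, multipool = TRUE) {
  nf <- config$n_filters; kc <- config$kernel_init_constant
  stem <- conv_same(conv_same(map, 2, nf, kc), 2, nf, kc)
  a1 <- conv_same(stem, 3, nf, kc)
  a2 <- conv_same(a1, 4, nf, kc)
  a3 <- conv_same(stem, 4, nf, kc)
  a4 <- conv_same(a3, 2, nf, kc)
  Q1 <- matmul_fuse(a1, a2)
  Q2 <- matmul_fuse(a3, a4)
  A1 <- concat_channels(Q1, Q2)
  A2 <- if (multipool) {
    dual_pool_fuse(A1, dim(A1)[1], kc, config$pool_window)
  } else {
    A1
  }
  list(stem = stem, a1 = a1, a2 = a2, a3 = a3, a4 = a4, Q1 = Q1, Q2 = Q2,
       A1 = A1, A2 = A2, features = A2)
}

branch_feature_map <- function(map, config, multipool = TRUE) {
  if (config$type == "eeg") {
    eeg_trunk(map, config, multipool)$features
  } else {
    smri_trunk(map, config, multipool)$features
  }
}

# Head input: reducing max-pool (window 2, stride 2) then flatten.
branch_head_input <- function(features) {
  as.vector(flatten_spatial(pool_reduce(features, 2, "max")))
}

#' Forward pass of the EEG branch
#'
#' Runs the full EEG extractor on one `1 x D x D` input: stem of two k=2
#' convolutions (`X1`), two stacked k=3/k=4 branch paths (`X2`, `X3`),
#' matrix-product fusions `S1 = X1 x X2` and `S2 = X1 x X3`, a multi-pooling
#' block on each, the product of the two block outputs, channel concatenation
#' with `X1`, and the dense head (Glorot-initialized from `config$seed`,
#' dropout disabled at inference) ending in a sigmoid unit.
#'
#' @param map A `1 x D x D` feature map.
#' @param config An [eeg_branch_config()].
#' @return A list: `features` (the pre-flatten concatenated map stack),
#'   `probability`, and all named intermediates.
#' @export
eeg_forward <- function(map, config = eeg_branch_config(dim(map)[2])) {
  map <- as_feature_map(map)
  if (dim(map)[1] != 1L || dim(map)[2] != dim(map)[3]) {
    abort("input must be a 1 x D x D map.")
  }
  tr <- eeg_trunk(map, config)
  x <- branch_head_input(tr$features)
  head <- init_dense_head(length(x), config$dense_units, config$seed,
                          config$dropout_after)
  p <- head_forward(head, matrix(x, 1))$p
  c(tr, list(probability = as.numeric(p)))
}

#' Forward pass of the sMRI branch
#'
#' Runs the full sMRI extractor on one `1 x D x D` input: stem of two k=2
#' convolutions, sequential extraction paths k3->k4 (`a1`, `a2`) and k4->k2
#' (`a3`, `a4`), matrix products `Q1`/`Q2`, concatenation `A1`, dual-pooling
#' fusion `A2`, and the dense head ending in a sigmoid unit.
#'
#' @param map A `1 x D x D` feature map.
#' @param config An [smri_branch_config()].
#' @return A list: `features` (= `A2`), `probability`, and all intermediates.
#' @export
smri_forward <- function(map, config = smri_branch_config(dim(map)[2])) {
  map <- as_feature_map(map)
  if (dim(map)[1] != 1L || dim(map)[2] != dim(map)[3]) {
    abort("input must be a 1 x D x D map.")
  }
  tr <- smri_trunk(map, config)
  x <- branch_head_input(tr$features)
  head <- init_dense_head(length(x), config$dense_units, config$seed,
                          config$dropout_after)
  p <- head_forward(head, matrix(x, 1))$p
  c(tr, list(probability = as.numeric(p)))
}

# Fit one branch on a list of input maps: extract trunk features once
# (the trunk is deterministic), then train the dense head under
# bce_l2_loss with full-batch Adam.
fit_branch <- function(maps, y, config, multipool = TRUE, epochs = 30,
                       lr = 1e-3, lambda = 1e-4, val_fraction = 0,
                       patience = 5) {
  feats <- lapply(maps, branch_feature_map, config = config,
                  multipool = multipool)
  X <- do.call(rbind, lapply(feats, branch_head_input))
  # Standardize head inputs per column (training statistics): the constant-
  # initialized matrix products leave channel groups on very different
  # scales, and tanh units need inputs of order 1 to learn.
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  X <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  fit <- train_dense_head(X, y, config$dense_units, config$seed,
                          epochs = epochs, lr = lr, lambda = lambda,
                          dropout_rate = config$dropout_rate,
                          dropout_after = config$dropout_after,
                          val_fraction = val_fraction, patience = patience)
  structure(list(config = config, multipool = multipool, head = fit$head,
                 input_center = mu, input_scale = sg,
                 loss_history = fit$loss_history, train_acc = fit$train_acc),
            class = "cnn_branch")
}

branch_scores <- function(branch, maps) {
  feats <- lapply(maps, branch_feature_map, config = branch$config,
                  multipool = branch$multipool)
  X <- do.call(rbind, lapply(feats, branch_head_input))
  X <- sweep(sweep(X, 2, branch$input_center, "-"), 2, branch$input_scale, "/")
  as.vector(head_forward(branch$head, X)$p)
}

#' @export
print.cnn_branch <- function(x, ...) {
  cat(sprintf("<cnn_branch:%s> D=%d nf=%d multipool=%s train_acc=%.3f\n",
              x$config$type, x$config$input_side, x$config$n_filters,
              x$multipool, x$train_acc))
  invisible(x)
}
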