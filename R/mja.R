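# Multimodal joint attention (MJA). Each branch's feature stack is projected
# by three 1x1 convolutions into query/key (channels reduced to
# max(1, floor(G/8))) and value (full G channels). Sigmoid spatial attention
# maps S = sigmoid(t(query) %*% key) are N x N over the flattened spatial
# grid (N = H * W). Cross routing sends each branch's value stack through the
# OTHER branch's attention map (Ca = A_value x Sb, Cb = B_value x Sa), and
# the attended stacks are concatenated onto the original inputs. The
# projections are the only trainable part; analytic gradients are verified
# against finite differences in the test suite.

reduced_channels <- function(G) max(1L, G %/% 8L)

mja_init <- function(G_a, G_b, seed) {
  ga <- reduced_channels(G_a); gb <- reduced_channels(G_b)
  with_seed(seed, list(
    Wq_a = glorot_matrix(ga, G_a), Wk_a = glorot_matrix(ga, G_a),
    Wv_a = glorot_matrix(G_a, G_a),
    Wq_b = glorot_matrix(gb, G_b), Wk_b = glorot_matrix(gb, G_b),
    Wv_b = glorot_matrix(G_b, G_b)
  ))
}

#' Query/key/value projection of a feature map
#'
#' Applies three independent 1x1 convolutions (Glorot-normal, seeded) to a
#' `G x H x W` map and returns the results flattened row-major over the
#' spatial grid: `query` and `key` with `max(1, floor(G/8))` channels,
#' `value` with the full `G` channels, each as a `(channels x N)` matrix
#' with `N = H * W`.
#'
#' @param map A feature map.
#' @param seed Integer seed for the projection weights.
#' @return A list `query`, `key`, `value`, plus `H`, `W`.
#' @export
qkv_project <- function(map, seed = 1) {
  map <- as_feature_map(map)
  d <- dim(map)
  if (d[1] < 1L) abort("empty map.")
  gr <- reduced_channels(d[1])
  w <- with_seed(seed, list(q = glorot_matrix(gr, d[1]),
                            k = glorot_matrix(gr, d[1]),
                            v = glorot_matrix(d[1], d[1])))
  X <- flatten_spatial(map)
  list(query = w$q %*% X, key = w$k %*% X, value = w$v %*% X,
       H = d[2], W = d[3])
}

#' Sigmoid spatial attention map
#'
#' `S = sigmoid(t(query) %*% key)`, entrywise sigmoid of the N x N score
#' matrix. Every entry lies strictly in (0, 1); zero projections give a map
#' of exactly 0.5 everywhere. No row normalization is applied.
#'
#' @param query,key `(G' x N)` matrices sharing both dimensions.
#' @return The `N x N` attention matrix.
#' @export
attention_map <- function(query, key) {
  if (!identical(dim(query), dim(key))) abort("query and key must share shape.")
  sigmoid(crossprod(query, key))
}

#' Route a value stack through an attention map
#'
#' `C = value %*% S_other`, reshaped row-major to `G x H x W`. Used with the
#' other branch's attention map for cross-modal guidance.
#'
#' @param value `(G x N)` value matrix.
#' @param S_other `(N x N)` attention matrix.
#' @param H,W Spatial dims with `H * W = N`.
#' @return A `G x H x W` feature map.
#' @export
cross_attend <- function(value, S_other, H, W) {
  if (ncol(value) != nrow(S_other) || nrow(S_other) != ncol(S_other)) {
    abort("value and attention map are not conformable.")
  }
  if (H * W != ncol(value)) abort("H * W must equal the flattened length N.")
  unflatten_spatial(value %*% S_other, H, W)
}

mja_forward_one <- function(w, Xa, Xb, mode = c("cross", "self")) {
  mode <- match.arg(mode)
  qa <- w$Wq_a %*% Xa; ka <- w$Wk_a %*% Xa; Va <- w$Wv_a %*% Xa
  qb <- w$Wq_b %*% Xb; kb <- w$Wk_b %*% Xb; Vb <- w$Wv_b %*% Xb
  Sa <- sigmoid(crossprod(qa, ka))
  Sb <- sigmoid(crossprod(qb, kb))
  if (mode == "cross") {
    Ca <- Va %*% Sb; Cb <- Vb %*% Sa
  } else {
    Ca <- Va %*% Sa; Cb <- Vb %*% Sb
  }
  list(Sa = Sa, Sb = Sb, Ca = Ca, Cb = Cb, Va = Va, Vb = Vb,
       qa = qa, ka = ka, qb = qb, kb = kb)
}

#' Joint-attention fusion of two branch feature maps
#'
#' Computes query/key/value for both branches, the sigmoid attention maps
#' `Sa`/`Sb`, the cross-attended stacks `Ca = A_value x Sb` and
#' `Cb = B_value x Sa`, and the refined outputs
#' `A_refined = concat(A_map, Ca)`, `B_refined = concat(B_map, Cb)`
#' (each with doubled channels; the first `G` channels equal the input
#' exactly).
#'
#' @param A_map,B_map Feature maps sharing spatial shape `(H, W)` (channel
#'   counts may differ).
#' @param seed Seed for the projection weights (ignored when `weights`
#'   given).
#' @param weights Optional projection weights from a trained fusion stage.
#' @param mode `"cross"` (joint attention) or `"self"` (each branch refined
#'   by its own attention map only; the bimodal-attention ablation).
#' @return A `refined_pair`: `A_refined`, `B_refined`, `Ca`, `Cb`, `Sa`,
#'   `Sb`, and the inputs `N_in`, `M_in`.
#' @export
mja_fuse <- function(A_map, B_map, seed = 1, weights = NULL,
                     mode = c("cross", "self")) {
  mode <- match.arg(mode)
  A_map <- as_feature_map(A_map); B_map <- as_feature_map(B_map)
  da <- dim(A_map); db <- dim(B_map)
  if (!identical(da[2:3], db[2:3])) {
    abort("branches must share spatial shape for joint attention.")
  }
  if (is.null(weights)) weights <- mja_init(da[1], db[1], seed)
  Xa <- flatten_spatial(A_map); Xb <- flatten_spatial(B_map)
  fw <- mja_forward_one(weights, Xa, Xb, mode)
  H <- da[2]; W <- da[3]
  structure(list(
    A_refined = concat_channels(A_map, unflatten_spatial(fw$Ca, H, W)),
    B_refined = concat_channels(B_map, unflatten_spatial(fw$Cb, H, W)),
    Ca = unflatten_spatial(fw$Ca, H, W), Cb = unflatten_spatial(fw$Cb, H, W),
    Sa = fw$Sa, Sb = fw$Sb, N_in = A_map, M_in = B_map,
    weights = weights, mode = mode
  ), class = "refined_pair")
}

#' Stack a refined pair into a classifier feature vector
#'
#' `flatten`: row-major concatenation of all channels of `A_refined` then
#' `B_refined` (length `2 * G_A * H * W + 2 * G_B * H * W`). `gap`: global
#' average pooling, one spatial mean per channel
#' (length `2 * G_A + 2 * G_B`).
#'
#' @param pair A `refined_pair` from [mja_fuse()].
#' @param mode `"flatten"` or `"gap"`.
#' @return A numeric feature vector.
#' @export
stack_features <- function(pair, mode = c("flatten", "gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "refined_pair"))
  if (mode == "flatten") {
    c(as.vector(t(flatten_spatial(pair$A_refined))),
      as.vector(t(flatten_spatial(pair$B_refined))))
  } else {
    c(apply(pair$A_refined, 1, mean), apply(pair$B_refined, 1, mean))
  }
}

# Train the MJA projections plus a small linear sigmoid head under
# bce_l2_loss with full-batch Adam. The head consumes the same stacked
# representation the downstream classifier uses: global-average-pooled
# ("gap") or fully flattened ("flatten") refined features, so the projection
# gradients shape exactly the features that are classified later.
# Xa_list / Xb_list are per-subject flattened (G x N) trunk feature maps;
# the trunks are frozen, so they are precomputed once.
train_mja <- function(Xa_list, Xb_list, y, H, W, seed, epochs = 20,
                      lr = 1e-3, lambda = 1e-4, mode = c("cross", "self"),
                      head_mode = c("gap", "flatten")) {
  mode <- match.arg(mode)
  head_mode <- match.arg(head_mode)
  n <- length(Xa_list)
  G_a <- nrow(Xa_list[[1]]); G_b <- nrow(Xb_list[[1]])
  N <- H * W
  w <- mja_init(G_a, G_b, seed)
  blk <- if (head_mode == "gap") c(G_a, G_a, G_b, G_b) else N * c(G_a, G_a, G_b, G_b)
  Fdim <- sum(blk)
  with_seed(seed + 1L, {
    u <- as.vector(glorot_matrix(1L, Fdim))
  })
  b0 <- 0
  params <- c(w, list(u = u, b0 = b0))
  state <- adam_init(params)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    st <- mja_stage_grad(params, Xa_list, Xb_list, y, mode, head_mode, lambda)
    upd <- adam_step(params, st$grads, state, lr)
    params <- upd$params; state <- upd$state
    history[e] <- st$loss
  }
  list(weights = params[c("Wq_a", "Wk_a", "Wv_a", "Wq_b", "Wk_b", "Wv_b")],
       u = params$u, b0 = params$b0, loss_history = history, mode = mode,
       head_mode = head_mode)
}

# Analytic full-batch gradient of the attention-stage loss with respect to
# every trainable parameter (projections + linear head). Verified against
# central finite differences in the tests.
mja_stage_grad <- function(params, Xa_list, Xb_list, y, mode = "cross",
                           head_mode = "gap", lambda = 0) {
  n <- length(Xa_list)
  G_a <- nrow(Xa_list[[1]]); G_b <- nrow(Xb_list[[1]])
  N <- ncol(Xa_list[[1]])
  part_a <- mja_part_fun(head_mode)
  blk_a <- if (head_mode == "gap") G_a else G_a * N
  blk_b <- if (head_mode == "gap") G_b else G_b * N
  i_ca <- blk_a + seq_len(blk_a)
  i_cb <- 2L * blk_a + blk_b + seq_len(blk_b)
  grads <- lapply(params, function(p) p * 0)
  preds <- numeric(n)
  feats <- matrix(0, 2L * (blk_a + blk_b), n)
  fws <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- mja_forward_one(params, Xa_list[[i]], Xb_list[[i]], mode)
    fws[[i]] <- fw
    f <- c(part_a(Xa_list[[i]]), part_a(fw$Ca),
           part_a(Xb_list[[i]]), part_a(fw$Cb))
    feats[, i] <- f
    preds[i] <- sigmoid(sum(params$u * f) + params$b0)
  }
  err <- (preds - y) / n
  for (i in seq_len(n)) {
    fw <- fws[[i]]
    Xa <- Xa_list[[i]]; Xb <- Xb_list[[i]]
    e_i <- err[i]
    if (head_mode == "gap") {
      dCa <- (e_i / N) * tcrossprod(params$u[i_ca], rep(1, N))
      dCb <- (e_i / N) * tcrossprod(params$u[i_cb], rep(1, N))
    } else {
      dCa <- e_i * matrix(params$u[i_ca], G_a, N, byrow = TRUE)
      dCb <- e_i * matrix(params$u[i_cb], G_b, N, byrow = TRUE)
    }
    if (mode == "cross") {
      dVa <- dCa %*% t(fw$Sb); dSb <- crossprod(fw$Va, dCa)
      dVb <- dCb %*% t(fw$Sa); dSa <- crossprod(fw$Vb, dCb)
    } else {
      dVa <- dCa %*% t(fw$Sa); dSa <- crossprod(fw$Va, dCa)
      dVb <- dCb %*% t(fw$Sb); dSb <- crossprod(fw$Vb, dCb)
    }
    dZa <- dSa * fw$Sa * (1 - fw$Sa)
    dZb <- dSb * fw$Sb * (1 - fw$Sb)
    grads$Wq_a <- grads$Wq_a + (fw$ka %*% t(dZa)) %*% t(Xa)
    grads$Wk_a <- grads$Wk_a + (fw$qa %*% dZa) %*% t(Xa)
    grads$Wv_a <- grads$Wv_a + dVa %*% t(Xa)
    grads$Wq_b <- grads$Wq_b + (fw$kb %*% t(dZb)) %*% t(Xb)
    grads$Wk_b <- grads$Wk_b + (fw$qb %*% dZb) %*% t(Xb)
    grads$Wv_b <- grads$Wv_b + dVb %*% t(Xb)
    grads$u <- grads$u + e_i * feats[, i]
    grads$b0 <- grads$b0 + e_i
  }
  wm <- c("Wq_a", "Wk_a", "Wv_a", "Wq_b", "Wk_b", "Wv_b", "u")
  for (nm in wm) grads[[nm]] <- grads[[nm]] + lambda * params[[nm]]
  list(grads = grads, loss = bce_l2_loss(y, preds, params[wm], lambda),
       preds = preds)
}

mja_part_fun <- function(head_mode) {
  if (head_mode == "gap") function(M) rowMeans(M) else function(M) as.vector(t(M))
}

mja_head_scores <- function(fit, Xa_list, Xb_list) {
  part <- mja_part_fun(fit$head_mode %||% "gap")
  vapply(seq_along(Xa_list), function(i) {
    fw <- mja_forward_one(fit$weights, Xa_list[[i]], Xb_list[[i]], fit$mode)
    f <- c(part(Xa_list[[i]]), part(fw$Ca), part(Xb_list[[i]]), part(fw$Cb))
    sigmoid(sum(fit$u * f) + fit$b0)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Loss of the MJA stage for given parameters (used by finite-difference
# gradient checks in the tests).
mja_stage_loss <- function(params, Xa_list, Xb_list, y, mode = "cross",
                           lambda = 0, head_mode = "gap") {
  part <- mja_part_fun(head_mode)
  preds <- vapply(seq_along(Xa_list), function(i) {
    fw <- mja_forward_one(params, Xa_list[[i]], Xb_list[[i]], mode)
    f <- c(part(Xa_list[[i]]), part(fw$Ca), part(Xb_list[[i]]), part(fw$Cb))
    sigmoid(sum(params$u * f) + params$b0)
  }, numeric(1))
  wm <- c("Wq_a", "Wk_a", "Wv_a", "Wq_b", "Wk_b", "Wv_b", "u")
  bce_l2_loss(y, preds, params[wm], lambda)
}
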