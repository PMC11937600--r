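# Feature-map algebra. A feature map is a base-R array with dim = c(G, H, W):
# G channels over an H x W spatial grid. All stride-1 operations use "same"
# padding so spatial shape is preserved, which is what makes the per-channel
# matrix-product fusions conformable.

as_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    rlang::abort("a feature map must be a 3-d array (channels, height, width).")
  }
  if (!all(is.finite(x))) rlang::abort("feature map values must be finite.")
  x
}

map_dims <- function(map) {
  d <- dim(map)
  list(G = d[1], H = d[2], W = d[3])
}

# Row-major spatial flattening: column n of the result corresponds to spatial
# cell (h, w) with n = (h - 1) * W + w. This single convention is shared by
# every reshape in the package (attention, stacking, map construction).
flatten_spatial <- function(map) {
  d <- dim(map)
  matrix(aperm(map, c(1, 3, 2)), nrow = d[1])
}

unflatten_spatial <- function(mat, H, W) {
  stopifnot(ncol(mat) == H * W)
  aperm(array(mat, dim = c(nrow(mat), W, H)), c(1, 3, 2))
}

# Reshape a feature vector to a 1 x D x D map, zero-padding to D^2, row-major.
vector_to_map <- function(x, D = NULL) {
  if (is.null(D)) D <- ceiling(sqrt(length(x)))
  if (D < 1 || length(x) > D * D) {
    rlang::abort("`D` too small for the feature vector.")
  }
  padded <- c(as.numeric(x), rep(0, D * D - length(x)))
  out <- array(0, dim = c(1, D, D))
  out[1, , ] <- matrix(padded, D, D, byrow = TRUE)
  out
}

pad_offsets <- function(k) {
  # Asymmetric "same" padding for stride 1: k - 1 cells in total, the smaller
  # share leading (matches the usual even-kernel convention).
  pb <- (k - 1L) %/% 2L
  c(pb, k - 1L - pb)
}

# Stride-1 cross-correlation with same padding. `weights` has
# dim = c(n_filters, G_in, k, k); `bias` is length n_filters.
conv2d_same <- function(map, weights, bias = NULL) {
  map <- as_feature_map(map)
  d <- dim(map)
  G <- d[1]; H <- d[2]; W <- d[3]
  wd <- dim(weights)
  stopifnot(length(wd) == 4L, wd[2] == G, wd[3] == wd[4])
  k <- wd[3]
  n_out <- wd[1]
  if (is.null(bias)) bias <- rep(0, n_out)
  pb <- pad_offsets(k)[1]
  Hp <- H + k - 1L
  Wp <- W + k - 1L
  padded <- array(0, dim = c(G, Hp, Wp))
  padded[, pb + seq_len(H), pb + seq_len(W)] <- map
  # im2col: rows ordered (g fastest, then di, then dj) to match the
  # column-major flattening of `weights`.
  P <- matrix(0, G * k * k, H * W)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sub <- padded[, di:(di + H - 1L), dj:(dj + W - 1L), drop = FALSE]
      rows <- (G * ((di - 1L) + k * (dj - 1L))) + seq_len(G)
      P[rows, ] <- matrix(sub, G, H * W)
    }
  }
  Wmat <- matrix(weights, n_out, G * k * k)
  out <- Wmat %*% P + bias
  array(out, dim = c(n_out, H, W))
}

#' Stride-1 convolution with constant-initialized kernels and same padding
#'
#' Applies a convolutional layer in the style used throughout the branch
#' networks: stride 1, symmetric zero padding chosen so the output spatial
#' shape equals the input's, every kernel weight initialized to a shared
#' constant and biases to zero.
#'
#' @param map A feature map: numeric array with dim `(channels, H, W)`.
#' @param kernel_size Side length of the square kernel.
#' @param n_filters Number of output channels.
#' @param init_constant Value filling every kernel weight.
#' @return A feature map with `n_filters` channels and the input's `(H, W)`.
#' @export
conv_same <- function(map, kernel_size, n_filters, init_constant = 0.1) {
  assert_count(kernel_size, "kernel_size")
  assert_count(n_filters, "n_filters")
  map <- as_feature_map(map)
  G <- dim(map)[1]
  weights <- array(init_constant, dim = c(n_filters, G, kernel_size, kernel_size))
  conv2d_same(map, weights)
}

# Stride-1 pooling with same padding. Average pooling divides by the number of
# in-bounds cells in each window (padding cells are excluded from both max and
# mean), so constant maps pool to themselves.
pool_same <- function(map, window = 2, type = c("max", "avg")) {
  type <- match.arg(type)
  map <- as_feature_map(map)
  d <- dim(map)
  G <- d[1]; H <- d[2]; W <- d[3]
  pb <- pad_offsets(window)[1]
  acc <- if (type == "max") array(-Inf, d) else array(0, d)
  cnt <- array(0L, d)
  for (dj in seq_len(window)) {
    for (di in seq_len(window)) {
      oi <- di - 1L - pb
      oj <- dj - 1L - pb
      ri <- max(1L, 1L - oi):min(H, H - oi)
      rj <- max(1L, 1L - oj):min(W, W - oj)
      if (length(ri) < 1L || length(rj) < 1L) next
      src <- map[, ri + oi, rj + oj, drop = FALSE]
      if (type == "max") {
        acc[, ri, rj] <- pmax(acc[, ri, rj, drop = FALSE], src)
      } else {
        acc[, ri, rj] <- acc[, ri, rj, drop = FALSE] + src
        cnt[, ri, rj] <- cnt[, ri, rj, drop = FALSE] + 1L
      }
    }
  }
  if (type == "avg") acc / cnt else acc
}

# Non-overlapping reducing pool (stride = window); trailing cells that do not
# fill a window are dropped. Used only in front of the flatten layer.
pool_reduce <- function(map, window = 2, type = c("max", "avg")) {
  type <- match.arg(type)
  map <- as_feature_map(map)
  d <- dim(map)
  Ho <- d[2] %/% window
  Wo <- d[3] %/% window
  stopifnot(Ho >= 1, Wo >= 1)
  out <- array(if (type == "max") -Inf else 0, dim = c(d[1], Ho, Wo))
  for (dj in seq_len(window)) {
    for (di in seq_len(window)) {
      src <- map[, (seq_len(Ho) - 1L) * window + di,
                 (seq_len(Wo) - 1L) * window + dj, drop = FALSE]
      out <- if (type == "max") pmax(out, src) else out + src
    }
  }
  if (type == "avg") out / (window * window) else out
}

#' Per-channel matrix-product fusion of two equal-shaped feature maps
#'
#' Combines two feature maps by true matrix multiplication of the
#' corresponding `H x W` channel slices (`out[g] = A[g] %*% B[g]`), the
#' fusion used to mix important and hidden features inside both branch
#' networks. Requires square spatial dimensions.
#'
#' @param A,B Feature maps with identical dim `(G, H, W)` and `H == W`.
#' @return A feature map of the same shape.
#' @export
matmul_fuse <- function(A, B) {
  A <- as_feature_map(A); B <- as_feature_map(B)
  if (!identical(dim(A), dim(B))) rlang::abort("feature maps must share shape.")
  d <- dim(A)
  if (d[2] != d[3]) rlang::abort("matrix-product fusion needs square spatial dims.")
  out <- array(0, d)
  for (g in seq_len(d[1])) out[g, , ] <- A[g, , ] %*% B[g, , ]
  out
}

#' Channelwise concatenation of two feature maps
#'
#' @param A,B Feature maps sharing spatial shape `(H, W)`.
#' @return A feature map with `G_A + G_B` channels: the channels of `A`
#'   followed by the channels of `B`.
#' @export
concat_channels <- function(A, B) {
  A <- as_feature_map(A); B <- as_feature_map(B)
  da <- dim(A); db <- dim(B)
  if (!identical(da[2:3], db[2:3])) {
    rlang::abort("spatial shapes must match for channel concatenation.")
  }
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- A
  out[da[1] + seq_len(db[1]), , ] <- B
  out
}

#' Multi-pooling fusion block
#'
#' The deep-feature block shared by both branches: the input map is passed in
#' parallel through stride-1 same-padded average and max pooling, each pooled
#' map goes through a constant-initialized convolution with kernel size 2, and
#' the two results are combined by per-channel matrix product
#' (average-pooled path times max-pooled path). Spatial shape is preserved.
#'
#' @param S Input feature map (square spatial dims).
#' @param n_filters Output channels of the two internal convolutions; defaults
#'   to the input channel count.
#' @param init_constant Constant filling the convolution kernels.
#' @param pool_window Pooling window side (default 2).
#' @return A feature map `(n_filters, H, W)`.
#' @export
multipool_block <- function(S, n_filters = dim(S)[1], init_constant = 0.1,
                            pool_window = 2) {
  S <- as_feature_map(S)
  avg <- pool_same(S, pool_window, "avg")
  mx <- pool_same(S, pool_window, "max")
  ca <- conv_same(avg, 2, n_filters, init_constant)
  cm <- conv_same(mx, 2, n_filters, init_constant)
  matmul_fuse(ca, cm)
}

#' Dual-pooling fusion of a concatenated map
#'
#' The closing fusion of the sMRI branch: average- and max-pool the
#' concatenated map (stride 1, same padding), convolve each pooled map with a
#' kernel of size 2, and fuse the two results by per-channel matrix product.
#' Identical in structure to [multipool_block()]; exposed separately because
#' it closes the second branch rather than refining an intermediate product.
#'
#' @inheritParams multipool_block
#' @param A1 Input feature map (square spatial dims).
#' @return A feature map `(n_filters, H, W)`.
#' @export
dual_pool_fuse <- function(A1, n_filters = dim(A1)[1], init_constant = 0.1,
                           pool_window = 2) {
  multipool_block(A1, n_filters = n_filters, init_constant = init_constant,
                  pool_window = pool_window)
}
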