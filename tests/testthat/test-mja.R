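# Joint-attention fusion: projections, sigmoid attention, cross routing,
# refinement invariants, and gradient correctness.

test_that("qkv_project reduces channels by 1/8 with a floor of 1", {
  p8 <- qkv_project(random_map(8, 4), seed = 1)
  expect_identical(nrow(p8$query), 1L)
  expect_identical(nrow(p8$key), 1L)
  expect_identical(nrow(p8$value), 8L)
  expect_identical(ncol(p8$query), 16L)
  p4 <- qkv_project(random_map(4, 4), seed = 1)
  expect_identical(nrow(p4$query), 1L)
  p16 <- qkv_project(random_map(16, 3), seed = 1)
  expect_identical(nrow(p16$query), 2L)
})

test_that("attention_map: sigmoid(0) = 0.5 exactly, hand case, open range", {
  z <- matrix(0, 2, 5)
  S <- attention_map(z, z)
  expect_true(all(S == 0.5))
  q <- matrix(c(1, 0), 1, 2)
  k <- matrix(c(2, 3), 1, 2)
  S2 <- attention_map(q, k)
  sig <- function(x) 1 / (1 + exp(-x))
  expect_equal(S2, matrix(c(sig(2), 0.5, sig(3), 0.5), 2, 2), tolerance = 1e-12)
  set.seed(2)
  S3 <- attention_map(matrix(rnorm(12), 2, 6), matrix(rnorm(12), 2, 6))
  expect_true(all(S3 > 0 & S3 < 1))
})

test_that("attention_map agrees with the nested-loop oracle", {
  set.seed(4)
  for (i in 1:10) {
    q <- matrix(rnorm(8), 2, 4); k <- matrix(rnorm(8), 2, 4)
    expect_equal(attention_map(q, k), oracle_attention(q, k), tolerance = 1e-10)
  }
})

test_that("cross_attend: constant-attention closed form and oracle", {
  v <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4)
  S <- matrix(0.5, 4, 4)
  out <- cross_attend(v, S, 2, 2)
  # every output element is 0.5 * (row sum of value)
  for (g in 1:2) expect_true(all(abs(out[g, , ] - 0.5 * sum(v[g, ])) < 1e-12))
  set.seed(6)
  for (i in 1:10) {
    v2 <- matrix(rnorm(8), 2, 4)
    S2 <- matrix(runif(16), 4, 4)
    expect_equal(cross_attend(v2, S2, 2, 2), oracle_cross_attend(v2, S2, 2, 2),
                 tolerance = 1e-10)
  }
  expect_error(cross_attend(v, matrix(0.5, 3, 3), 2, 2), "conformable")
})

test_that("mja_fuse doubles channels and preserves the inputs bit-for-bit", {
  set.seed(8)
  A <- random_map(8, 4); B <- random_map(6, 4)
  pair <- mja_fuse(A, B, seed = 3)
  expect_identical(dim(pair$A_refined), c(16L, 4L, 4L))
  expect_identical(dim(pair$B_refined), c(12L, 4L, 4L))
  expect_identical(pair$A_refined[1:8, , ], A)
  expect_identical(pair$B_refined[1:6, , ], B)
  expect_true(all(pair$Sa > 0 & pair$Sa < 1))
  expect_error(mja_fuse(A, random_map(6, 5)), "spatial")
})

test_that("swapping branches with swapped projection seeds swaps outputs", {
  set.seed(10)
  A <- random_map(8, 4); B <- random_map(8, 4)
  w <- mcnnrf:::mja_init(8, 8, seed = 5)
  wsw <- list(Wq_a = w$Wq_b, Wk_a = w$Wk_b, Wv_a = w$Wv_b,
              Wq_b = w$Wq_a, Wk_b = w$Wk_a, Wv_b = w$Wv_a)
  p1 <- mja_fuse(A, B, weights = w)
  p2 <- mja_fuse(B, A, weights = wsw)
  expect_equal(p2$A_refined, p1$B_refined, tolerance = 1e-12)
  expect_equal(p2$B_refined, p1$A_refined, tolerance = 1e-12)
})

test_that("full mja_fuse matches an independent nested-loop composition", {
  set.seed(12)
  for (i in 1:5) {
    A <- random_map(8, 4); B <- random_map(8, 4)
    w <- mcnnrf:::mja_init(8, 8, seed = 100 + i)
    pair <- mja_fuse(A, B, weights = w)
    Xa <- oracle_flatten(A); Xb <- oracle_flatten(B)
    Sa <- oracle_attention(w$Wq_a %*% Xa, w$Wk_a %*% Xa)
    Sb <- oracle_attention(w$Wq_b %*% Xb, w$Wk_b %*% Xb)
    Ca <- oracle_cross_attend(w$Wv_a %*% Xa, Sb, 4, 4)
    Cb <- oracle_cross_attend(w$Wv_b %*% Xb, Sa, 4, 4)
    expect_equal(pair$Ca, Ca, tolerance = 1e-8)
    expect_equal(pair$Cb, Cb, tolerance = 1e-8)
  }
})

test_that("cross-guidance is live: perturbing B changes Ca", {
  set.seed(14)
  A <- random_map(4, 3); B <- random_map(4, 3)
  w <- mcnnrf:::mja_init(4, 4, seed = 2)
  base <- mja_fuse(A, B, weights = w)$Ca
  B2 <- B; B2[1, 1, 1] <- B2[1, 1, 1] + 1e-4
  pert <- mja_fuse(A, B2, weights = w)$Ca
  expect_gt(max(abs(pert - base)), 0)
})

test_that("analytic stage gradients match central finite differences", {
  set.seed(16)
  n <- 6
  Xa <- lapply(1:n, function(i) matrix(rnorm(4 * 9), 4, 9))
  Xb <- lapply(1:n, function(i) matrix(rnorm(4 * 9), 4, 9))
  y <- rep(c(0, 1), 3)
  for (mode in c("cross", "self")) {
    w <- mcnnrf:::mja_init(4, 4, seed = 3)
    params <- c(w, list(u = rnorm(16, sd = 0.3), b0 = 0.1))
    g <- mcnnrf:::mja_stage_grad(params, Xa, Xb, y, mode = mode,
                                 head_mode = "gap", lambda = 0.01)
    h <- 1e-6
    for (nm in c("Wq_a", "Wk_b", "Wv_a", "u", "b0")) {
      idx <- if (length(params[[nm]]) > 1) c(1L, length(params[[nm]])) else 1L
      for (ii in idx) {
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
        pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - h
        num <- (mcnnrf:::mja_stage_loss(pp, Xa, Xb, y, mode, 0.01, "gap") -
                mcnnrf:::mja_stage_loss(pm, Xa, Xb, y, mode, 0.01, "gap")) / (2 * h)
        expect_equal(unname(g$grads[[nm]][ii]), num, tolerance = 1e-4)
      }
    }
    expect_gt(sum(abs(g$grads$Wq_a)) + sum(abs(g$grads$Wq_b)), 0)
  }
})

test_that("training the attention stage lowers the shared loss", {
  set.seed(18)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  Xa <- lapply(seq_len(n), function(i) matrix(rnorm(4 * 9, mean = y[i]), 4, 9))
  Xb <- lapply(seq_len(n), function(i) matrix(rnorm(4 * 9, mean = y[i]), 4, 9))
  fit <- mcnnrf:::train_mja(Xa, Xb, y, 3, 3, seed = 4, epochs = 30, lr = 1e-2)
  expect_lt(fit$loss_history[30], fit$loss_history[1])
  sc <- mcnnrf:::mja_head_scores(fit, Xa, Xb)
  expect_true(all(sc > 0 & sc < 1))
})
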