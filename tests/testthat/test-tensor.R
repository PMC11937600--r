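# Feature-map algebra: convolution, pooling, matrix-product fusion and the
# pooling blocks, checked against independent nested-loop oracles.

test_that("conv_same matches the nested-loop oracle on random maps", {
  set.seed(101)
  for (case in 1:20) {
    G <- sample(1:3, 1); H <- sample(4:6, 1); k <- sample(2:4, 1)
    nf <- sample(1:4, 1)
    m <- random_map(G, H)
    got <- conv_same(m, k, nf, 0.1)
    expect_equal(got, oracle_conv(m, k, nf, 0.1), tolerance = 1e-10)
    expect_identical(dim(got), c(nf, H, H))
  }
})

test_that("conv_same interior response to a constant input is G*k^2*c*w", {
  G <- 2; c0 <- 0.7; w0 <- 0.1; k <- 3
  m <- array(c0, c(G, 6, 6))
  out <- conv_same(m, k, 1, w0)
  expect_equal(out[1, 3, 3], G * k^2 * c0 * w0)
})

test_that("matmul_fuse: hand case, identity and annihilator", {
  A <- array(0, c(1, 2, 2)); A[1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  B <- array(0, c(1, 2, 2)); B[1, , ] <- matrix(c(5, 6, 7, 8), 2, byrow = TRUE)
  out <- matmul_fuse(A, B)
  expect_equal(out[1, , ], matrix(c(19, 22, 43, 50), 2, byrow = TRUE))
  Id <- array(0, c(3, 4, 4))
  for (g in 1:3) Id[g, , ] <- diag(4)
  M <- random_map(3, 4)
  expect_equal(matmul_fuse(M, Id), M)
  expect_equal(matmul_fuse(M * 0, M), M * 0)
  expect_error(matmul_fuse(random_map(1, 3), random_map(1, 4)), "share shape")
  expect_error(matmul_fuse(array(1, c(1, 2, 3)), array(1, c(1, 2, 3))),
               "square")
})

test_that("stride-1 pooling matches the oracle and preserves constants", {
  set.seed(7)
  for (case in 1:10) {
    m <- random_map(2, 5)
    expect_equal(mcnnrf:::pool_same(m, 2, "max"), oracle_pool(m, 2, "max"))
    expect_equal(mcnnrf:::pool_same(m, 2, "avg"), oracle_pool(m, 2, "avg"),
                 tolerance = 1e-12)
  }
  const <- array(3.5, c(1, 4, 4))
  expect_equal(mcnnrf:::pool_same(const, 2, "max"), const)
  expect_equal(mcnnrf:::pool_same(const, 2, "avg"), const)
})

test_that("multipool_block matches pool->conv->product oracle and keeps shape", {
  set.seed(11)
  for (case in 1:10) {
    G <- sample(1:3, 1); H <- sample(4:6, 1)
    m <- random_map(G, H)
    got <- multipool_block(m, G, 0.1, 2)
    expect_equal(got, oracle_multipool(m, G, 0.1, 2), tolerance = 1e-8)
    expect_identical(dim(got), dim(m))
  }
})

test_that("constant input makes the two pooled paths identical", {
  m <- array(2, c(2, 4, 4))
  avg <- mcnnrf:::pool_same(m, 2, "avg")
  mx <- mcnnrf:::pool_same(m, 2, "max")
  expect_identical(avg, mx)
  ca <- conv_same(avg, 2, 2, 0.1)
  expect_equal(multipool_block(m, 2, 0.1, 2), matmul_fuse(ca, ca))
})

test_that("dual_pool_fuse agrees with the shared block oracle", {
  set.seed(13)
  m <- random_map(4, 4)
  expect_equal(dual_pool_fuse(m, 4, 0.1, 2), oracle_multipool(m, 4, 0.1, 2),
               tolerance = 1e-8)
})

test_that("concat_channels preserves order and errors on spatial mismatch", {
  A <- random_map(3, 4); B <- random_map(2, 4)
  out <- concat_channels(A, B)
  expect_identical(dim(out), c(5L, 4L, 4L))
  expect_identical(out[1:3, , ], A)
  expect_identical(out[4:5, , ], B)
  expect_error(concat_channels(A, random_map(2, 5)), "spatial")
})

test_that("spatial flattening is row-major and invertible", {
  m <- random_map(3, 4, 4)
  fl <- mcnnrf:::flatten_spatial(m)
  expect_equal(fl, oracle_flatten(m))
  expect_equal(mcnnrf:::unflatten_spatial(fl, 4, 4), m)
})

test_that("vector_to_map zero-pads row-major", {
  v <- 1:5
  m <- mcnnrf:::vector_to_map(v, 3)
  expect_equal(m[1, 1, ], c(1, 2, 3))
  expect_equal(m[1, 2, ], c(4, 5, 0))
  expect_equal(m[1, 3, ], c(0, 0, 0))
})
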