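# Imputation, normalization and MRMR selection.

test_that("impute_wknn is the identity on complete tables", {
  tbl <- tibble::as_tibble(matrix(runif(40), 10, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  expect_equal(impute_wknn(tbl, 3), tbl)
})

test_that("impute_wknn matches the brute-force oracle on a 4x2 hand case", {
  m <- matrix(c(1, 2,
                1.1, NA,
                5, 9,
                1.2, 4), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  got <- impute_wknn(tibble::as_tibble(m), 2)
  expect_equal(as.matrix(got), oracle_wknn(m, 2), tolerance = 1e-12)
})

test_that("equidistant neighbours average equally", {
  m <- matrix(c(0, 10,
                1, 2,
                -1, 6,
                NA, 4), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  # subject 4 has only column b observed; neighbours 2 (|2-4|=2) and 3
  # (|6-4|=2) are equidistant, subject 1 (|10-4|=6) is excluded at k=2
  got <- impute_wknn(tibble::as_tibble(m), 2)
  expect_equal(got$a[4], mean(c(1, -1)), tolerance = 1e-9)
})

test_that("impute_wknn errors on under-observed columns", {
  m <- matrix(c(1, NA, 2, NA, 3, NA), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(impute_wknn(tibble::as_tibble(m), 2), "2 observed")
})

test_that("minmax_normalize maps exemplar and degenerate columns correctly", {
  tbl <- tibble::tibble(a = c(2, 4, 6), b = c(3, 3, 3))
  out <- minmax_normalize(tbl)
  expect_equal(out$data$a, c(0, 0.5, 1))
  expect_equal(out$data$b, c(0, 0, 0))
  # stored ranges reproduce the transform on the same data exactly
  expect_equal(apply_minmax(tbl, out$ranges), out$data, tolerance = 1e-12)
})

test_that("normalized outputs always lie in [0, 1]", {
  set.seed(3)
  for (i in 1:10) {
    tbl <- tibble::as_tibble(matrix(rnorm(60, sd = 10), 12, 5,
                                    dimnames = list(NULL, paste0("f", 1:5))))
    out <- minmax_normalize(tbl)$data
    expect_true(all(as.matrix(out) >= 0 & as.matrix(out) <= 1))
  }
})

test_that("a label-matching feature is ranked first by MRMR", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 120
    y <- rep(c(0L, 1L), each = n / 2)[sample(n)]
    m <- matrix(runif(n * 8), n, 8)
    m[, 4] <- y  # exact copy of the label
    colnames(m) <- paste0("f", 1:8)
    r <- mrmr_rank(tibble::as_tibble(m), y, mrmr_config(n_bins = 4))
    if (r$index[1] == 4L) wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("a duplicated top feature is penalized below an independent one", {
  set.seed(17)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)[sample(n)]
  x1 <- y + rnorm(n, sd = 0.3)
  x3 <- y + rnorm(n, sd = 0.3)   # equally relevant, independent noise
  m <- cbind(x1 = x1, x2 = x1, x3 = x3, x4 = runif(n))
  r <- mrmr_rank(tibble::as_tibble(m), y, mrmr_config(n_bins = 6))
  # whichever of x1/x2 goes first, the exact duplicate must rank after x3
  expect_lt(match("x3", r$feature), max(match(c("x1", "x2"), r$feature)))
})

test_that("full MRMR ranking is a permutation and order-invariant up to ties", {
  set.seed(5)
  n <- 100
  y <- rep(c(0L, 1L), each = 50)[sample(n)]
  m <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m[, 2] <- m[, 2] + y
  r <- mrmr_rank(tibble::as_tibble(m), y)
  expect_setequal(r$index, 1:6)
  perm <- c(4, 2, 6, 1, 3, 5)
  r2 <- mrmr_rank(tibble::as_tibble(m[, perm]), y)
  expect_identical(r$feature, r2$feature)
})

test_that("select_features clips the grid to the feature count", {
  set.seed(9)
  n <- 80
  y <- rep(c(0L, 1L), each = 40)[sample(n)]
  m <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  m[, 1:4] <- m[, 1:4] + 1.5 * y
  tbl <- minmax_normalize(tibble::as_tibble(m))$data
  cfg <- mrmr_config(scorer_trees = 50)
  r <- mrmr_rank(tbl, y, cfg)
  sel <- select_features(r, tbl, y, cfg)
  expect_lte(max(sel$grid$n_candidate), 40)
  expect_lte(sel$chosen_n, 40)
  expect_true(all(sel$chosen_indices %in% r$index))
})

test_that("stratified splits and folds keep sizes and coverage", {
  y <- c(rep(1L, 45), rep(0L, 44))
  sp <- train_test_split(y, 0.2, 3)
  expect_length(sp$test, 18)
  expect_length(sp$train, 71)
  expect_identical(sort(c(sp$train, sp$test)), 1:89)
  folds <- make_stratified_folds(y[sp$train], 10, 4)
  expect_identical(sort(unique(folds)), 1:10)
  expect_true(max(table(folds)) - min(table(folds)) <= 2)
})
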