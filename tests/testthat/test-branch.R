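# Branch networks: forward contracts, loss closed forms, head training.

test_that("eeg_forward keeps shapes, returns a probability, is deterministic", {
  m <- mcnnrf:::vector_to_map(runif(64), 8)
  cfg <- eeg_branch_config(input_side = 8, n_filters = 4, seed = 11)
  out <- eeg_forward(m, cfg)
  for (nm in c("X1", "X2", "X3", "S1", "S2", "B1", "B2", "P")) {
    expect_identical(dim(out[[nm]])[2:3], c(8L, 8L))
  }
  expect_identical(dim(out$features)[1], 8L)   # block product + X1 channels
  expect_gt(out$probability, 0)
  expect_lt(out$probability, 1)
  out2 <- eeg_forward(m, cfg)
  expect_identical(out$probability, out2$probability)
  expect_error(eeg_forward(random_map(2, 8)), "1 x D x D")
})

test_that("smri_forward obeys the concatenation arithmetic", {
  m <- mcnnrf:::vector_to_map(runif(64), 8)
  cfg <- smri_branch_config(input_side = 8, n_filters = 4, seed = 12)
  out <- smri_forward(m, cfg)
  expect_identical(dim(out$Q1)[1], 4L)
  expect_identical(dim(out$A1)[1], 8L)         # 2 * n_filters
  expect_identical(dim(out$A2), dim(out$A1))
  expect_gt(out$probability, 0)
  expect_lt(out$probability, 1)
})

test_that("loss closed forms hold", {
  expect_lt(bce_l2_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_l2_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_l2_loss(1, 1 - 1e-7, weights = list(matrix(c(1, 2), 1)),
                           lambda = 0.1),
               0.5 * 0.1 * (1 + 4), tolerance = 1e-6)
  expect_error(bce_l2_loss(c(1, 0), 0.5), "length")
  expect_error(bce_l2_loss(1, 0.5, lambda = -1), "lambda")
})

test_that("doubling all weights quadruples the L2 component exactly", {
  w <- list(matrix(rnorm(6), 2), matrix(rnorm(4), 2))
  l1 <- bce_l2_loss(1, 0.5, w, lambda = 0.3) - bce_l2_loss(1, 0.5)
  l2 <- bce_l2_loss(1, 0.5, lapply(w, `*`, 2), lambda = 0.3) -
    bce_l2_loss(1, 0.5)
  expect_equal(l2, 4 * l1, tolerance = 1e-12)
})

test_that("dense-head gradients match finite differences", {
  set.seed(21)
  X <- matrix(rnorm(5 * 7), 5, 7)
  y <- c(1, 0, 1, 0, 1)
  head <- mcnnrf:::init_dense_head(7, c(6, 4, 3), seed = 2)
  g <- mcnnrf:::head_grad(head, X, y, lambda = 0.01)
  h <- 1e-6
  loss_at <- function(hd) {
    p <- mcnnrf:::head_forward(hd, X)$p
    bce_l2_loss(y, p, hd$W, 0.01)
  }
  for (l in c(1L, 4L)) {
    for (ii in c(1L, length(head$W[[l]]))) {
      hp <- head; hp$W[[l]][ii] <- hp$W[[l]][ii] + h
      hm <- head; hm$W[[l]][ii] <- hm$W[[l]][ii] - h
      expect_equal(g$dW[[l]][ii], (loss_at(hp) - loss_at(hm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("branch heads train to high accuracy on separable cohorts", {
  ok_loss <- 0L; ok_acc <- 0L
  n_seeds <- 3L
  for (s in seq_len(n_seeds)) {
    ch <- generate_cohort(cohort_spec(
      n_subjects = 80, p_eeg = 36, p_smri = 4, n_informative_eeg = 8,
      n_informative_smri = 2, effect_size = 3, missing_rate = 0,
      seed = 500 + s))
    maps <- mcnnrf:::rows_to_maps(ch$eeg, 6)
    cfg <- eeg_branch_config(input_side = 6, n_filters = 4, seed = s)
    fit <- mcnnrf:::fit_branch(maps, ch$labels, cfg, epochs = 30)
    first5 <- fit$loss_history[1:5]
    if (all(diff(first5) < 0)) ok_loss <- ok_loss + 1L
    if (fit$train_acc >= 0.95) ok_acc <- ok_acc + 1L
  }
  expect_gte(ok_loss, n_seeds - 1L)
  expect_gte(ok_acc, n_seeds - 1L)
})

test_that("branch scores are deterministic across refits with one seed", {
  ch <- tiny_cohort(n = 30, p = 16, missing = 0)
  maps <- mcnnrf:::rows_to_maps(ch$eeg, 4)
  cfg <- smri_branch_config(input_side = 4, n_filters = 4, seed = 9)
  f1 <- mcnnrf:::fit_branch(maps, ch$labels, cfg, epochs = 5)
  f2 <- mcnnrf:::fit_branch(maps, ch$labels, cfg, epochs = 5)
  expect_identical(mcnnrf:::branch_scores(f1, maps),
                   mcnnrf:::branch_scores(f2, maps))
})
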