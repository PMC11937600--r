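# Synthetic cohort generator: determinism, planted-signal calibration,
# missingness bounds, and CSV round-tripping.

test_that("identical specs generate bitwise-identical cohorts", {
  sp <- cohort_spec(n_subjects = 40, p_eeg = 20, p_smri = 15, seed = 9)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$smri, b$smri)
  expect_identical(a$labels, b$labels)
  expect_identical(nrow(a$eeg), 40L)
  expect_identical(ncol(a$smri), 15L)
})

test_that("cohort has both classes and the requested counts", {
  ch <- generate_cohort(cohort_spec(n_subjects = 89, p_eeg = 10, p_smri = 10,
                                    missing_rate = 0, seed = 7))
  expect_length(ch$labels, 89)
  expect_setequal(unique(ch$labels), c(0L, 1L))
  expect_equal(sum(ch$labels), round(89 * 0.5))
})

test_that("zero effect size yields uniform per-feature t-test p-values", {
  ch <- generate_cohort(cohort_spec(n_subjects = 500, p_eeg = 120, p_smri = 4,
                                    n_informative_eeg = 40,
                                    n_informative_smri = 2,
                                    effect_size = 0, missing_rate = 0,
                                    seed = 21))
  m <- as.matrix(ch$eeg)
  pvals <- apply(m, 2, function(x) {
    stats::t.test(x[ch$labels == 1], x[ch$labels == 0])$p.value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("informative features carry the planted standardized shift", {
  d <- 1.5
  ch <- generate_cohort(cohort_spec(n_subjects = 4000, p_eeg = 12, p_smri = 4,
                                    n_informative_eeg = 6,
                                    n_informative_smri = 2, effect_size = d,
                                    shared_factor_weight = 0.5,
                                    missing_rate = 0, seed = 33))
  # range mapping rescales, so test the standardized (scale-free) shift
  m <- as.matrix(ch$eeg)[, ch$informative_eeg]
  shift <- apply(m, 2, function(x) {
    (mean(x[ch$labels == 1]) - mean(x[ch$labels == 0])) /
      sd(x[ch$labels == 0])
  })
  expect_equal(mean(shift), d, tolerance = 0.1)
})

test_that("inject_missing honors rate bounds and the 2-observed guarantee", {
  tbl <- tibble::as_tibble(matrix(runif(1000), 100, 10, dimnames =
                                    list(NULL, sprintf("f%02d", 1:10))))
  expect_identical(inject_missing(tbl, 0, 1), tbl)
  out <- inject_missing(tbl, 0.1, 5)
  n_miss <- sum(is.na(out))
  expect_gte(n_miss, qbinom(0.005, 1000, 0.1))
  expect_lte(n_miss, qbinom(0.995, 1000, 0.1))
  keep <- !is.na(as.matrix(out))
  expect_identical(as.matrix(out)[keep], as.matrix(tbl)[keep])
  small <- tibble::tibble(a = runif(3), b = runif(3))
  res <- try(inject_missing(small, 0.999, 3), silent = TRUE)
  if (!inherits(res, "try-error")) {
    expect_true(all(colSums(!is.na(res)) >= 2))
  }
  expect_error(inject_missing(tbl, 1.0, 1), "rate")
})

test_that("cohort CSV round trip is exact and validates structure", {
  dir <- withr::local_tempdir()
  ch <- tiny_cohort(n = 25, p = 8, missing = 0.05)
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$eeg, ch$eeg)
  expect_equal(back$smri, ch$smri)
  expect_identical(back$labels, ch$labels)
  expect_identical(back$subject_ids, ch$subject_ids)
  # missing cells written as empty fields load as NA
  expect_identical(which(is.na(back$eeg)), which(is.na(ch$eeg)))
  # truncate the label file -> row mismatch error
  lab <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  readr::write_csv(lab[-1, ], file.path(dir, "labels.csv"))
  expect_error(read_cohort(dir), "mismatch")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(class_balance = 0), "class_balance")
  expect_error(cohort_spec(n_informative_eeg = 20, p_eeg = 10), "informative")
})
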