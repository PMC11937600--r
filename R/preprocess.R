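# Preprocessing: weighted nearest-neighbour imputation, min-max
# normalization with reusable per-feature ranges, and MRMR feature selection
# with grid-based subset sizing plus permutation-importance verification.

#' Weighted k-nearest-neighbour imputation
#'
#' Fills each missing cell `(i, j)` with the inverse-distance-weighted mean of
#' column `j` over the `k` subjects nearest to subject `i`. Distances are
#' Euclidean over the columns observed in both subjects; neighbours must have
#' column `j` observed and share at least one observed column with subject
#' `i`. Weights are `1 / (d + 1e-8)`, so equidistant neighbours contribute
#' equally. Observed cells are returned unchanged.
#'
#' @param data A data frame / tibble of numeric features (missing as `NA`).
#' @param k Number of neighbours (default 5).
#' @return A complete tibble of the same shape.
#' @export
impute_wknn <- function(data, k = 5) {
  assert_count(k, "k")
  m <- as_feature_matrix(data)
  obs <- !is.na(m)
  if (any(colSums(obs) < 2L)) {
    abort("every column needs at least 2 observed values to impute.")
  }
  if (!anyNA(m)) return(tibble::as_tibble(m))
  out <- m
  m0 <- m
  m0[!obs] <- 0
  for (i in which(rowSums(!obs) > 0L)) {
    # squared distance from i to every row over mutually observed columns
    oi <- obs[i, ]
    shared <- obs %*% oi                         # per-row shared column count
    diff <- sweep(m0, 2, m0[i, ], "-")
    diff[!obs | matrix(!oi, nrow(m), ncol(m), byrow = TRUE)] <- 0
    d2 <- rowSums(diff^2)
    if (all(shared[-i] == 0)) {
      abort("a subject shares no observed column with any other subject.")
    }
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & shared > 0 & seq_len(nrow(m)) != i)
      if (length(cand) == 0L) {
        abort("no usable neighbour for a missing cell; too few shared columns.")
      }
      ord <- cand[order(d2[cand], cand)]
      nn <- ord[seq_len(min(k, length(ord)))]
      w <- 1 / (sqrt(d2[nn]) + 1e-8)
      out[i, j] <- sum(w * m[nn, j]) / sum(w)
    }
  }
  tibble::as_tibble(out)
}

#' Min-max normalization to [0, 1]
#'
#' Maps each column by `(x - min) / (max - min)` and records the per-feature
#' ranges so the identical transform can be applied to held-out data with
#' [apply_minmax()]. Constant columns map to all-zeros rather than erroring,
#' so degenerate cross-validation folds keep running.
#'
#' @param data A complete (no missing cells) data frame of numeric features.
#' @return A list with `data` (normalized tibble) and `ranges` (tibble with
#'   `feature`, `min`, `max`).
#' @export
minmax_normalize <- function(data) {
  m <- as_feature_matrix(data)
  if (anyNA(m)) abort("missing cells present; impute before normalizing.")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  out <- sweep(m, 2, lo, "-")
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  list(data = tibble::as_tibble(out),
       ranges = tibble::tibble(feature = colnames(m), min = lo, max = hi))
}

#' Apply stored min-max ranges to new data
#'
#' @param data A complete data frame with the same columns the ranges were
#'   fitted on.
#' @param ranges The `ranges` tibble returned by [minmax_normalize()].
#' @param clip Clamp results into `[0, 1]` (default `TRUE`), keeping held-out
#'   values inside the branch networks' input domain.
#' @return A normalized tibble.
#' @export
apply_minmax <- function(data, ranges, clip = TRUE) {
  m <- as_feature_matrix(data)
  if (anyNA(m)) abort("missing cells present; impute before normalizing.")
  stopifnot(identical(colnames(m), ranges$feature))
  span <- ranges$max - ranges$min
  out <- sweep(m, 2, ranges$min, "-")
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  tibble::as_tibble(out)
}

# Equal-width discretization into n_bins over the observed range; constant
# vectors collapse to a single bin.
discretize_ew <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  b <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  as.integer(b)
}

# Mutual information (nats) between two discretized integer vectors.
mi_disc <- function(xd, yd, nx, ny) {
  n <- length(xd)
  joint <- tabulate((xd - 1L) * ny + yd, nx * ny) / n
  px <- tabulate(xd, nx) / n
  py <- tabulate(yd, ny) / n
  pouter <- as.vector(outer(py, px))   # ordered to match joint's indexing
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pouter[nz]))
}

#' MRMR configuration
#'
#' @param n_grades Number of candidate subset sizes on the evaluation grid
#'   (default 10).
#' @param n_min,n_max Bounds of the candidate subset-size range
#'   (defaults 10 and 500); the grid is clipped to the available feature
#'   count.
#' @param n_bins Equal-width bins for mutual-information estimation
#'   (default 10).
#' @param scorer_trees Trees in the random-forest reference model used to
#'   score candidate subsets and to verify importances (default 100).
#' @param scorer_folds Stratified folds for the subset score (default 5).
#' @param seed Integer seed for the reference model and folds.
#' @return An `mrmr_config` object.
#' @export
mrmr_config <- function(n_grades = 10, n_min = 10, n_max = 500, n_bins = 10,
                        scorer_trees = 100, scorer_folds = 5, seed = 1) {
  assert_count(n_grades, "n_grades")
  assert_count(n_min, "n_min")
  assert_count(n_max, "n_max")
  if (n_min > n_max) abort("`n_min` must be <= `n_max`.")
  assert_count(n_bins, "n_bins", min = 2L)
  structure(list(n_grades = as.integer(n_grades), n_min = as.integer(n_min),
                 n_max = as.integer(n_max), n_bins = as.integer(n_bins),
                 scorer_trees = as.integer(scorer_trees),
                 scorer_folds = as.integer(scorer_folds),
                 seed = as.integer(seed)),
            class = "mrmr_config")
}

#' Greedy MRMR feature ranking
#'
#' Ranks features by minimum-redundancy maximum-relevance with the
#' mutual-information-difference criterion: the first feature maximizes
#' relevance `I(feature; label)`; each subsequent feature maximizes relevance
#' minus the mean mutual information with the features already selected.
#' Mutual information is estimated on `n_bins` equal-width bins. Ties break
#' toward the lower column index.
#'
#' @param data A complete, normalized feature data frame.
#' @param labels Binary labels (0/1), one per row.
#' @param config An [mrmr_config()].
#' @param n_rank How many features to rank (default: all).
#' @return A tibble with `rank`, `index`, `feature`, `score`, `relevance`,
#'   `redundancy`.
#' @export
mrmr_rank <- function(data, labels, config = mrmr_config(), n_rank = NULL) {
  m <- as_feature_matrix(data)
  if (anyNA(m)) abort("missing cells present; impute before ranking.")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("both classes must be present.")
  p <- ncol(m)
  if (p < 2L) abort("need at least 2 features to rank.")
  if (is.null(n_rank)) n_rank <- p
  n_rank <- min(n_rank, p)
  nb <- config$n_bins
  disc <- apply(m, 2, discretize_ew, n_bins = nb)
  yd <- labels + 1L
  rel <- vapply(seq_len(p), function(j) mi_disc(disc[, j], yd, nb, 2L), numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  scores <- numeric(n_rank); reds <- numeric(n_rank)
  for (step in seq_len(n_rank)) {
    if (step == 1L) {
      cand_score <- rel
      cand_red <- numeric(p)
    } else {
      cand_red <- red_sum / length(selected)
      cand_score <- rel - cand_red
    }
    cand_score[selected] <- -Inf
    pick <- which.max(cand_score)   # which.max breaks ties at lowest index
    selected <- c(selected, pick)
    scores[step] <- cand_score[pick]
    reds[step] <- cand_red[pick]
    if (step < n_rank) {
      mi_new <- vapply(seq_len(p), function(j) {
        if (j %in% selected) 0 else mi_disc(disc[, j], disc[, pick], nb, nb)
      }, numeric(1))
      red_sum <- red_sum + mi_new
    }
  }
  tibble::tibble(rank = seq_len(n_rank), index = selected,
                 feature = colnames(m)[selected], score = scores,
                 relevance = rel[selected], redundancy = reds)
}

# Stratified fold assignment: within each class, rows are shuffled and dealt
# round-robin, so fold sizes differ by at most one and class balance is kept.
#' Stratified fold assignment
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An integer vector of fold ids in `1..k`, one per row.
#' @export
make_stratified_folds <- function(labels, k, seed = 1) {
  assert_count(k, "k", min = 2L)
  labels <- as.integer(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified train/test split
#'
#' The test count is `round(n * test_fraction)` (round half up), allocated
#' across classes by largest remainder so each class contributes its
#' proportional share.
#'
#' @param labels Binary labels.
#' @param test_fraction Fraction in (0, 1) assigned to the test partition.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1) {
  assert_fraction(test_fraction, "test_fraction", lo_open = TRUE, hi_open = TRUE)
  labels <- as.integer(labels)
  n <- length(labels)
  n_test <- floor(n * test_fraction + 0.5)
  classes <- sort(unique(labels))
  quota <- vapply(classes, function(c) sum(labels == c) * test_fraction, numeric(1))
  base <- floor(quota)
  extra <- n_test - sum(base)
  if (extra > 0) {
    give <- order(quota - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  test <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      take <- min(base[ci], length(idx))
      test <- c(test, idx[sample.int(length(idx), take)])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

# Cross-validated AUC of a compact random-forest reference model on a feature
# subset; the shared scorer behind subset sizing.
rf_cv_auc <- function(m, labels, config) {
  folds <- make_stratified_folds(labels, config$scorer_folds, config$seed)
  df <- as.data.frame(m)
  names(df) <- sprintf("f%d", seq_len(ncol(m)))
  aucs <- vapply(seq_len(config$scorer_folds), function(f) {
    tr <- folds != f
    if (length(unique(labels[!tr])) < 2L) return(NA_real_)
    fit <- ranger::ranger(
      x = df[tr, , drop = FALSE], y = factor(labels[tr], levels = c(0, 1)),
      num.trees = config$scorer_trees, probability = TRUE,
      seed = config$seed + f, num.threads = 1
    )
    pr <- predict(fit, df[!tr, , drop = FALSE], num.threads = 1)$predictions[, "1"]
    auc_score(labels[!tr], pr)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Select the feature subset size on a grid and verify by importance
#'
#' Evaluates candidate subset sizes on an `n_grades`-point grid spanning
#' `[n_min, min(n_max, p)]`: for each size `N`, the top-`N` MRMR-ranked
#' features are scored by stratified cross-validated AUC of a compact
#' random-forest reference model. The best-scoring `N` (ties toward the
#' smaller size) is then verified with permutation importance under the same
#' reference model: chosen features whose importance is not positive are
#' dropped.
#'
#' @param ranked The ranking tibble from [mrmr_rank()].
#' @param data,labels The data the ranking was computed on.
#' @param config An [mrmr_config()].
#' @return A `selection_result`: `chosen_n`, `chosen_indices`,
#'   `chosen_features`, `importance` (tibble), `grid` (tibble of candidate
#'   sizes and scores), and the input `ranked`.
#' @export
select_features <- function(ranked, data, labels, config = mrmr_config()) {
  m <- as_feature_matrix(data)
  labels <- as.integer(labels)
  p <- nrow(ranked)
  lo <- min(config$n_min, p)
  hi <- min(config$n_max, p)
  if (hi < 1L || lo > hi) abort("candidate-size grid is empty after clipping.")
  grid <- unique(pmin(pmax(round(seq(lo, hi, length.out = config$n_grades)), 1L), p))
  scores <- vapply(grid, function(N) {
    rf_cv_auc(m[, ranked$index[seq_len(N)], drop = FALSE], labels, config)
  }, numeric(1))
  best_n <- grid[which.max(scores)]
  idx <- ranked$index[seq_len(best_n)]
  df <- as.data.frame(m[, idx, drop = FALSE])
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  fit <- ranger::ranger(
    x = df, y = factor(labels, levels = c(0, 1)),
    num.trees = config$scorer_trees, probability = TRUE,
    importance = "permutation", seed = config$seed, num.threads = 1
  )
  imp <- ranger::importance(fit)
  keep <- imp > 0
  structure(list(
    ranked = ranked,
    grid = tibble::tibble(n_candidate = grid, cv_auc = scores),
    grid_n = best_n,
    chosen_n = sum(keep),
    chosen_indices = idx[keep],
    chosen_features = ranked$feature[seq_len(best_n)][keep],
    importance = tibble::tibble(index = idx, feature = ranked$feature[seq_len(best_n)],
                                importance = unname(imp), kept = unname(keep))
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> grid best N = %d; kept %d features after importance check\n",
              x$grid_n, x$chosen_n))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$importance

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(grid_n = x$grid_n, chosen_n = x$chosen_n,
                 best_cv_auc = max(x$grid$cv_auc))
}

#' Serialize / load a selection result as structured text
#'
#' @param x A `selection_result`.
#' @param path Target JSON path.
#' @return `path` invisibly for write; a list for read.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(
    list(grid = x$grid, grid_n = x$grid_n, chosen_n = x$chosen_n,
         chosen_indices = x$chosen_indices, chosen_features = x$chosen_features,
         importance = x$importance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
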