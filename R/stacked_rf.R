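# Stacked random-forest cascade: level-1 forests produce out-of-fold
# positive-class probabilities which augment the feature matrix of a single
# level-2 forest (deep-forest-style stacking). Forests are ranger models,
# seeded and single-threaded for bitwise reproducibility.

#' Stacked random-forest configuration
#'
#' @param n_level1_forests Number of level-1 forests (default 2).
#' @param trees_per_forest Trees per forest (default 200).
#' @param max_depth Optional depth bound (`NULL` = unlimited).
#' @param oof_folds Internal folds for out-of-fold augmentation (default 5).
#' @param mtry_fraction Fraction of features tried per split (`NULL` uses the
#'   `sqrt(p)` forest default). A proportional mtry keeps the number of
#'   original-feature candidates per split constant when derived feature
#'   columns are appended, which matters for the fused strategies.
#' @param seed Integer seed.
#' @return A `stacked_rf_config`.
#' @export
stacked_rf_config <- function(n_level1_forests = 2, trees_per_forest = 200,
                              max_depth = NULL, oof_folds = 5,
                              mtry_fraction = NULL, seed = 1) {
  assert_count(n_level1_forests, "n_level1_forests")
  assert_count(trees_per_forest, "trees_per_forest")
  assert_count(oof_folds, "oof_folds", min = 2L)
  if (!is.null(mtry_fraction)) {
    assert_fraction(mtry_fraction, "mtry_fraction", lo_open = TRUE)
  }
  structure(list(n_level1_forests = as.integer(n_level1_forests),
                 trees_per_forest = as.integer(trees_per_forest),
                 max_depth = max_depth, oof_folds = as.integer(oof_folds),
                 mtry_fraction = mtry_fraction, seed = as.integer(seed)),
            class = "stacked_rf_config")
}

rf_fit <- function(x, y, trees, seed, max_depth = NULL, mtry_fraction = NULL) {
  mtry <- if (is.null(mtry_fraction)) NULL else {
    max(1L, min(ncol(x), ceiling(mtry_fraction * ncol(x))))
  }
  ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)), num.trees = trees,
    probability = TRUE, seed = seed, num.threads = 1, mtry = mtry,
    max.depth = if (is.null(max_depth)) 0 else max_depth
  )
}

rf_prob <- function(fit, x) {
  predict(fit, x, num.threads = 1)$predictions[, "1"]
}

#' Fit a stacked random forest
#'
#' Level 1 fits `n_level1_forests` probability forests (distinct seeds) and
#' computes their out-of-fold positive-class probabilities via stratified
#' internal folds; level 2 fits one forest on the features augmented with
#' those probability columns. For prediction, level-1 forests refit on the
#' full data supply the augmentation columns.
#'
#' @param X Feature matrix or data frame (rows = subjects).
#' @param y Binary labels (0/1) with both classes present.
#' @param config A [stacked_rf_config()].
#' @return A `stacked_rf` model.
#' @export
fit_stacked_rf <- function(X, y, config = stacked_rf_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) abort("both classes must be present.")
  m <- as_feature_matrix(X)
  if (nrow(m) != length(y)) abort("rows of X must match length of y.")
  df <- as.data.frame(m)
  names(df) <- sprintf("x%d", seq_len(ncol(df)))
  folds <- make_stratified_folds(y, config$oof_folds, config$seed)
  n_f <- config$n_level1_forests
  oof <- matrix(NA_real_, nrow(df), n_f)
  level1 <- vector("list", n_f)
  for (f in seq_len(n_f)) {
    fseed <- config$seed + 1000L * f
    for (k in seq_len(config$oof_folds)) {
      tr <- folds != k
      fit_k <- rf_fit(df[tr, , drop = FALSE], y[tr], config$trees_per_forest,
                      fseed + k, config$max_depth, config$mtry_fraction)
      oof[!tr, f] <- rf_prob(fit_k, df[!tr, , drop = FALSE])
    }
    level1[[f]] <- rf_fit(df, y, config$trees_per_forest, fseed,
                          config$max_depth, config$mtry_fraction)
  }
  aug <- as.data.frame(oof)
  names(aug) <- sprintf("p%d", seq_len(n_f))
  level2 <- rf_fit(cbind(df, aug), y, config$trees_per_forest,
                   config$seed + 99991L, config$max_depth,
                   config$mtry_fraction)
  structure(list(level1 = level1, level2 = level2, config = config,
                 n_features = ncol(df)), class = "stacked_rf")
}

#' Positive-class scores from a stacked random forest
#'
#' @param model A fitted `stacked_rf`.
#' @param X New data with the training feature width.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "stacked_rf"))
  m <- as_feature_matrix(X)
  if (ncol(m) != model$n_features) abort("feature width differs from training.")
  df <- as.data.frame(m)
  names(df) <- sprintf("x%d", seq_len(ncol(df)))
  aug <- as.data.frame(lapply(model$level1, function(f) rf_prob(f, df)))
  names(aug) <- sprintf("p%d", seq_along(model$level1))
  rf_prob(model$level2, cbind(df, aug))
}

#' @export
print.stacked_rf <- function(x, ...) {
  cat(sprintf("<stacked_rf> %d level-1 forests x %d trees; level-2 width %d + %d\n",
              length(x$level1), x$config$trees_per_forest, x$n_features,
              length(x$level1)))
  invisible(x)
}
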