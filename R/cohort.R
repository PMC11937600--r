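# Synthetic multimodal cohorts. Each subject carries two tabular feature
# vectors (EEG-derived and sMRI-derived) and a binary diagnosis label
# (1 = case). Class signal is planted as class-conditional Gaussian mean
# shifts on a subset of features in each modality, partly carried by a
# per-subject latent factor that loads on BOTH modalities, so that fusing
# the modalities is provably more informative than either alone.
#
# Informative feature j of subject i:
#   x_ij = noise_sd * ((1 - w) * d * y_i + w * z_i + sqrt(1 - w^2) * e_ij)
# with z_i ~ N(d * y_i, 1) shared across modalities, e_ij ~ N(0, 1),
# w = shared_factor_weight and d = effect_size. The class-conditional mean
# shift is d * noise_sd and the within-class variance is noise_sd^2, so d is
# the standardized (Cohen's d) separation. Non-informative features are pure
# N(0, noise_sd^2) noise. All features are then affinely mapped to [0, 1]
# using the empirical population min/max, and missing cells are injected
# after that mapping.

#' Specify a synthetic multimodal cohort
#'
#' @param n_subjects Number of subjects.
#' @param p_eeg,p_smri Feature counts per modality.
#' @param n_informative_eeg,n_informative_smri Class-associated feature counts.
#' @param effect_size Standardized class mean shift (Cohen's d) on informative
#'   features; 0 plants no signal.
#' @param shared_factor_weight Fraction in `[0, 1]` of the class signal carried
#'   by a latent factor loading on informative features of both modalities;
#'   values below 1 split the signal across modalities (complementarity).
#' @param noise_sd Residual standard deviation before range mapping.
#' @param class_balance Fraction in (0, 1) of positive (case) labels.
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 89, p_eeg = 256, p_smri = 256,
                        n_informative_eeg = max(1L, p_eeg %/% 8L),
                        n_informative_smri = max(1L, p_smri %/% 8L),
                        effect_size = 1, shared_factor_weight = 0.5,
                        noise_sd = 1, class_balance = 0.5,
                        missing_rate = 0.02, seed = 1) {
  assert_count(n_subjects, "n_subjects")
  assert_count(p_eeg, "p_eeg")
  assert_count(p_smri, "p_smri")
  assert_count(n_informative_eeg, "n_informative_eeg", min = 0L)
  assert_count(n_informative_smri, "n_informative_smri", min = 0L)
  if (n_informative_eeg > p_eeg || n_informative_smri > p_smri) {
    abort("informative feature counts cannot exceed the modality feature counts.")
  }
  if (!is.numeric(effect_size) || effect_size < 0) abort("`effect_size` must be >= 0.")
  assert_fraction(shared_factor_weight, "shared_factor_weight")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  assert_fraction(class_balance, "class_balance", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  structure(list(
    n_subjects = as.integer(n_subjects), p_eeg = as.integer(p_eeg),
    p_smri = as.integer(p_smri),
    n_informative_eeg = as.integer(n_informative_eeg),
    n_informative_smri = as.integer(n_informative_smri),
    effect_size = effect_size, shared_factor_weight = shared_factor_weight,
    noise_sd = noise_sd, class_balance = class_balance,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

new_cohort <- function(subject_ids, eeg, smri, labels, provenance,
                       informative_eeg = NULL, informative_smri = NULL) {
  structure(list(
    subject_ids = subject_ids,
    eeg = tibble::as_tibble(eeg), smri = tibble::as_tibble(smri),
    labels = as.integer(labels), provenance = provenance,
    informative_eeg = informative_eeg, informative_smri = informative_smri
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects | eeg: %d features | smri: %d features | %d cases / %d controls\n",
    length(x$subject_ids), ncol(x$eeg), ncol(x$smri),
    sum(x$labels == 1L), sum(x$labels == 0L)
  ))
  invisible(x)
}

range_map_01 <- function(m) {
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    m[, j] <- if (hi > lo) (m[, j] - lo) / (hi - lo) else 0
  }
  m
}

simulate_modality <- function(n, p, n_inf, d, w, noise_sd, y, z, prefix, seed) {
  with_seed(seed, {
    inf_idx <- if (n_inf > 0) sort(sample.int(p, n_inf)) else integer(0)
    m <- matrix(rnorm(n * p, sd = noise_sd), n, p)
    if (n_inf > 0 && d > 0) {
      signal <- noise_sd * ((1 - w) * d * y + w * z)
      m[, inf_idx] <- sqrt(1 - w^2) * m[, inf_idx] + signal
    }
    colnames(m) <- sprintf("%s_%03d", prefix, seq_len(p))
    list(values = range_map_01(m), informative = inf_idx)
  })
}

#' Generate a seeded synthetic multimodal cohort
#'
#' Draws labels, a shared latent factor, and two modality tables under
#' `spec`, maps all features to `[0, 1]` by the empirical population range,
#' and injects missing cells. Each source of randomness runs in a named
#' sub-stream of the master seed, so identical specs always produce
#' bitwise-identical cohorts and enlarging one modality does not perturb the
#' labels or the other modality.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort`: feature tibbles `eeg` and `smri`, integer `labels`
#'   (1 = case), `subject_ids`, the planted informative indices, and the spec
#'   as provenance.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_subjects
  n_pos <- round(n * spec$class_balance)
  if (n >= 2) n_pos <- min(max(n_pos, 1L), n - 1L)
  y <- integer(n)
  y[with_seed(substream_seed(spec$seed, "labels"), sample.int(n, n_pos))] <- 1L
  z <- with_seed(substream_seed(spec$seed, "latent"),
                 rnorm(n, mean = spec$effect_size * y))
  eeg <- simulate_modality(n, spec$p_eeg, spec$n_informative_eeg,
                           spec$effect_size, spec$shared_factor_weight,
                           spec$noise_sd, y, z, "eeg",
                           substream_seed(spec$seed, "eeg"))
  smri <- simulate_modality(n, spec$p_smri, spec$n_informative_smri,
                            spec$effect_size, spec$shared_factor_weight,
                            spec$noise_sd, y, z, "smri",
                            substream_seed(spec$seed, "smri"))
  eeg_tbl <- tibble::as_tibble(eeg$values)
  smri_tbl <- tibble::as_tibble(smri$values)
  if (spec$missing_rate > 0) {
    eeg_tbl <- inject_missing(eeg_tbl, spec$missing_rate,
                              substream_seed(spec$seed, "missingness_eeg"))
    smri_tbl <- inject_missing(smri_tbl, spec$missing_rate,
                               substream_seed(spec$seed, "missingness_smri"))
  }
  new_cohort(sprintf("S%04d", seq_len(n)), eeg_tbl, smri_tbl, y, spec,
             eeg$informative, smri$informative)
}

#' Inject missing cells into a feature table
#'
#' Sets each cell independently missing with probability `rate`, while
#' guaranteeing every column keeps at least 2 observed values (a column whose
#' draw violates this is re-drawn).
#'
#' @param data A data frame / tibble of numeric features.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble of the same shape with `NA` in the missing cells.
#' @export
inject_missing <- function(data, rate, seed = 1) {
  assert_fraction(rate, "rate", hi_open = TRUE)
  if (rate == 0) return(tibble::as_tibble(data))
  m <- as_feature_matrix(data)
  n <- nrow(m)
  with_seed(seed, {
    mask <- matrix(runif(n * ncol(m)) < rate, n, ncol(m))
    for (j in seq_len(ncol(m))) {
      tries <- 0L
      while (sum(!mask[, j]) < 2L) {
        mask[, j] <- runif(n) < rate
        tries <- tries + 1L
        if (tries > 1000L) {
          abort("could not keep 2 observed values per column at this rate.")
        }
      }
    }
    m[mask] <- NA_real_
  })
  tibble::as_tibble(m)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `eeg.csv`, `smri.csv` (subject_id + feature columns, missing cells
#' as empty fields) and `labels.csv` (subject_id, label).
#'
#' @param cohort A `cohort`.
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_ids), cohort$eeg),
    file.path(dir, "eeg.csv"), na = "")
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_ids), cohort$smri),
    file.path(dir, "smri.csv"), na = "")
  readr::write_csv(
    tibble::tibble(subject_id = cohort$subject_ids, label = cohort$labels),
    file.path(dir, "labels.csv"), na = "")
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of [write_cohort()]. Validates that the three files agree on the
#' number, identity and order of subjects and that subject ids are unique;
#' empty CSV fields load as missing values, never as zeros.
#'
#' @param dir Directory containing `eeg.csv`, `smri.csv`, `labels.csv`.
#' @return A `cohort` with `provenance = dir`.
#' @export
read_cohort <- function(dir) {
  read1 <- function(f) {
    readr::read_csv(file.path(dir, f), na = "", show_col_types = FALSE,
                    progress = FALSE)
  }
  eeg <- read1("eeg.csv"); smri <- read1("smri.csv"); lab <- read1("labels.csv")
  ids <- eeg$subject_id
  if (anyDuplicated(ids)) abort("duplicate subject ids in eeg.csv.")
  if (nrow(smri) != nrow(eeg) || nrow(lab) != nrow(eeg)) {
    abort("row-count mismatch between modality files and label file.")
  }
  if (!identical(smri$subject_id, ids) || !identical(lab$subject_id, ids)) {
    abort("subject ids differ in content or order across files.")
  }
  new_cohort(ids, dplyr::select(eeg, -"subject_id"),
             dplyr::select(smri, -"subject_id"), lab$label, dir)
}

# Row subset of a cohort, preserving order of `idx`.
cohort_subset <- function(cohort, idx) {
  new_cohort(cohort$subject_ids[idx], cohort$eeg[idx, , drop = FALSE],
             cohort$smri[idx, , drop = FALSE], cohort$labels[idx],
             cohort$provenance, cohort$informative_eeg, cohort$informative_smri)
}
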