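# Independent brute-force oracles, written as plain nested loops so they
# share no code path with the package implementations they check.

oracle_matmul <- function(A, B) {
  d <- dim(A)
  out <- array(0, d)
  for (g in seq_len(d[1])) {
    for (i in seq_len(d[2])) {
      for (j in seq_len(d[3])) {
        s <- 0
        for (m in seq_len(d[3])) s <- s + A[g, i, m] * B[g, m, j]
        out[g, i, j] <- s
      }
    }
  }
  out
}

# Same-padding stride-1 cross-correlation, constant-filled k x k kernels.
oracle_conv <- function(map, k, n_filters, const) {
  d <- dim(map)
  pb <- (k - 1) %/% 2
  out <- array(0, c(n_filters, d[2], d[3]))
  for (o in seq_len(n_filters)) {
    for (i in seq_len(d[2])) {
      for (j in seq_len(d[3])) {
        s <- 0
        for (g in seq_len(d[1])) {
          for (di in seq_len(k)) {
            for (dj in seq_len(k)) {
              ii <- i + di - 1 - pb
              jj <- j + dj - 1 - pb
              if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
                s <- s + const * map[g, ii, jj]
              }
            }
          }
        }
        out[o, i, j] <- s
      }
    }
  }
  out
}

# Stride-1 same-padded pooling; out-of-bounds cells excluded from the window.
oracle_pool <- function(map, window, type) {
  d <- dim(map)
  pb <- (window - 1) %/% 2
  out <- array(0, d)
  for (g in seq_len(d[1])) {
    for (i in seq_len(d[2])) {
      for (j in seq_len(d[3])) {
        vals <- c()
        for (di in seq_len(window)) {
          for (dj in seq_len(window)) {
            ii <- i + di - 1 - pb
            jj <- j + dj - 1 - pb
            if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
              vals <- c(vals, map[g, ii, jj])
            }
          }
        }
        out[g, i, j] <- if (type == "max") max(vals) else mean(vals)
      }
    }
  }
  out
}

oracle_multipool <- function(S, n_filters, const, window) {
  avg <- oracle_pool(S, window, "avg")
  mx <- oracle_pool(S, window, "max")
  oracle_matmul(oracle_conv(avg, 2, n_filters, const),
                oracle_conv(mx, 2, n_filters, const))
}

oracle_attention <- function(query, key) {
  Gp <- nrow(query); N <- ncol(query)
  S <- matrix(0, N, N)
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      z <- 0
      for (g in seq_len(Gp)) z <- z + query[g, m] * key[g, n]
      S[m, n] <- 1 / (1 + exp(-z))
    }
  }
  S
}

oracle_cross_attend <- function(value, S, H, W) {
  G <- nrow(value); N <- ncol(value)
  out <- array(0, c(G, H, W))
  for (g in seq_len(G)) {
    for (n in seq_len(N)) {
      s <- 0
      for (m in seq_len(N)) s <- s + value[g, m] * S[m, n]
      h <- (n - 1) %/% W + 1
      w <- (n - 1) %% W + 1
      out[g, h, w] <- s
    }
  }
  out
}

# Row-major flatten of a map, matching the package convention, written
# directly from the definition n = (h - 1) * W + w.
oracle_flatten <- function(map) {
  d <- dim(map)
  out <- matrix(0, d[1], d[2] * d[3])
  for (g in seq_len(d[1])) {
    for (h in seq_len(d[2])) {
      for (w in seq_len(d[3])) out[g, (h - 1) * d[3] + w] <- map[g, h, w]
    }
  }
  out
}

# Brute-force weighted-kNN imputation over all subject pairs.
oracle_wknn <- function(m, k) {
  out <- m
  n <- nrow(m)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) next
      cand <- c(); dist <- c()
      for (c in seq_len(n)) {
        if (c == i || is.na(m[c, j])) next
        shared <- which(!is.na(m[i, ]) & !is.na(m[c, ]))
        if (length(shared) == 0) next
        d <- sqrt(sum((m[i, shared] - m[c, shared])^2))
        cand <- c(cand, c); dist <- c(dist, d)
      }
      ord <- order(dist, cand)
      nn <- ord[seq_len(min(k, length(ord)))]
      w <- 1 / (dist[nn] + 1e-8)
      out[i, j] <- sum(w * m[cand[nn], j]) / sum(w)
    }
  }
  out
}

oracle_metrics <- function(tp, tn, fp, fn) {
  div0 <- function(a, b) if (b > 0) a / b else 0
  den <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  c(sn = div0(tp, tp + fn), sp = div0(tn, tn + fp), pre = div0(tp, tp + fp),
    acc = div0(tp + tn, tp + tn + fp + fn),
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

random_map <- function(G, H, W = H) {
  array(rnorm(G * H * W), c(G, H, W))
}

# Tiny deterministic cohort for pipeline tests.
tiny_cohort <- function(n = 60, p = 16, effect = 2, seed = 42,
                        missing = 0.02) {
  generate_cohort(cohort_spec(
    n_subjects = n, p_eeg = p, p_smri = p,
    n_informative_eeg = max(2, p %/% 8), n_informative_smri = max(2, p %/% 8),
    effect_size = effect, shared_factor_weight = 0.5,
    missing_rate = missing, seed = seed))
}

fast_config <- function(strategy = "mcnnrf", seed = 1) {
  pipeline_config(strategy = strategy, n_filters = 4,
                  head = list(epochs = 8), mja = list(epochs = 5),
                  rf = stacked_rf_config(trees_per_forest = 50, oof_folds = 3),
                  seed = seed)
}
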