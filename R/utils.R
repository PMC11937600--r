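#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif predict quantile sd
#' @importFrom utils head tail
NULL

# Deterministic derivation of named sub-stream seeds from a single master seed.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it anywhere.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(as.numeric(utf8ToInt(name)) * seq_len(nchar(name)))
  val <- (abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646
  as.integer(val) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s.", name,
                  if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"))
  }
  invisible(as.numeric(x))
}

# Glorot (Xavier) normal initializer.
glorot_matrix <- function(fan_out, fan_in) {
  matrix(rnorm(fan_out * fan_in, sd = sqrt(2 / (fan_in + fan_out))), fan_out, fan_in)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numeric feature matrix from a data frame / tibble / matrix, preserving names.
as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    m <- data
  } else {
    data <- as.data.frame(data)
    num <- vapply(data, is.numeric, logical(1))
    if (!all(num)) abort("all feature columns must be numeric.")
    m <- as.matrix(data)
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%03d", seq_len(ncol(m)))
  m
}
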