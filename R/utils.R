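# Small internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Moment-based sample skewness g1 = m3 / m2^(3/2), missing values dropped.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(0)
  mean(xc^3) / m2^1.5
}

# Covariance with divisor N (maximum-likelihood convention used throughout
# the estimation engine; see vignette on the chi-square convention).
cov_ml <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stats::cov(x) * (n - 1) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

log_det_chol <- function(m) 2 * sum(log(diag(chol(m))))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
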