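# Shared fixtures, built in code and memoised so expensive cohorts and fits
# are constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small default-structure cohort used by several module tests.
test_cohort <- function() memo("cohort_small", {
  generate_cohort(synth_config(n_subjects = 1500, n_biomarkers = 6,
                               n_true_mediators = 2, seed = 424L))
})

test_cohort_pp <- function() memo("cohort_small_pp", {
  preprocess_cohort(test_cohort()$cohort)
})

test_delta_fit <- function() memo("delta_small", {
  fit_delta(test_cohort_pp()$cohort)
})

# One-factor data for engine tests: five indicators, unit factor variance.
one_factor_data <- function(n = 1500, lam = c(0.8, 0.7, 0.6, 0.5, 0.75),
                            seed = 7) {
  set.seed(seed)
  f <- rnorm(n)
  X <- vapply(seq_along(lam), function(j)
    lam[j] * f + rnorm(n, sd = sqrt(1 - lam[j]^2)), numeric(n))
  colnames(X) <- paste0("y", seq_along(lam))
  as.data.frame(X)
}

one_factor_spec <- function(p = 5) {
  sem_spec(observed = paste0("y", 1:p), latent = "F",
           paths = data.frame(from = "F", to = paste0("y", 1:p)),
           covariances = data.frame(v1 = "F", v2 = "F", free = FALSE, value = 1))
}

# Recursive observed-variable path model y3 <- y1 + y2, y2 <- y1.
path_model_data <- function(n = 1000, b21 = 0.5, b31 = 0.3, b32 = 0.4,
                            seed = 11) {
  set.seed(seed)
  y1 <- rnorm(n)
  y2 <- b21 * y1 + rnorm(n)
  y3 <- b31 * y1 + b32 * y2 + rnorm(n)
  data.frame(y1 = y1, y2 = y2, y3 = y3)
}

path_model_spec <- function() {
  sem_spec(observed = c("y1", "y2", "y3"),
           paths = data.frame(from = c("y1", "y1", "y2"),
                              to = c("y2", "y3", "y3")))
}
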