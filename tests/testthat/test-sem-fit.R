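test_that("ml_discrepancy matches hand values and the eigen re-implementation", {
  S <- diag(2)
  expect_equal(ml_discrepancy(S, S), 0)
  # S = I, Sigma = 2I, p = 2: 2 ln 2 + 1 - 2
  expect_equal(ml_discrepancy(diag(2), 2 * diag(2)), 2 * log(2) - 1,
               tolerance = 1e-12)
  # second-form oracle: F = sum(e - log e) - p over eigenvalues of Sigma^-1 S
  eigen_form <- function(S, Sigma) {
    e <- eigen(solve(Sigma) %*% S, only.values = TRUE)$values
    sum(e - log(e)) - ncol(S)
  }
  set.seed(3)
  for (i in 1:100) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(p * p), p); S <- crossprod(A) + diag(p)
    B <- matrix(rnorm(p * p), p); Sigma <- crossprod(B) + diag(p)
    expect_equal(ml_discrepancy(S, Sigma), max(eigen_form(S, Sigma), 0),
                 tolerance = 1e-10)
    expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-10)
  }
  expect_error(ml_discrepancy(diag(2), matrix(0, 2, 2)), "positive definite")
})

test_that("analytic gradient agrees with finite differences", {
  dat <- one_factor_data(400)
  spec <- one_factor_spec()
  S <- deltamed:::cov_ml(dat)
  theta <- deltamed:::start_values(spec, S)
  fn <- function(t) ml_discrepancy(
    S, implied_covariance(spec, stats::setNames(t, free_labels(spec))))
  g_an <- deltamed:::ml_gradient(spec, theta, S)
  g_fd <- deltamed:::numeric_gradient(fn, theta)
  expect_lt(max(abs(g_an - g_fd)), 1e-7)
})

test_that("a saturated spec fits perfectly with zero df", {
  dat <- path_model_data(300)
  spec <- sem_spec(observed = c("y1", "y2", "y3"),
                   paths = data.frame(from = c("y1", "y1", "y2"),
                                      to = c("y2", "y3", "y3")),
                   covariances = NULL)
  fit <- sem_fit(spec, dat, se = FALSE)
  expect_equal(fit$df, 0)
  expect_lt(fit$F_min, 1e-10)
  expect_lt(fit$chisq, 1e-6)
})

test_that("one-factor loadings are recovered within 3 SE", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.75)
  dat <- one_factor_data(5000, lam, seed = 21)
  fit <- sem_fit(one_factor_spec(), dat)
  est <- coef(fit)[paste0("y", 1:5, "~F")]
  se <- fit$se[paste0("y", 1:5, "~F")]
  expect_true(fit$converged)
  expect_true(all(abs(abs(est) - lam) < 3 * se))
})

test_that("estimates match independent ML implementations (factanal, OLS)", {
  # factor model vs factanal on the same correlation matrix
  dat <- one_factor_data(2000, seed = 5)
  R <- cov2cor(deltamed:::cov_ml(dat))
  fit <- sem_fit(one_factor_spec(), sample_cov = R, sample_n = 2000)
  fa <- factanal(covmat = R, factors = 1, n.obs = 2000)
  expect_lt(max(abs(abs(coef(fit)[paste0("y", 1:5, "~F")]) -
                      abs(fa$loadings[, 1]))), 1e-5)
  expect_lt(max(abs(coef(fit)[paste0("y", 1:5, "~~y", 1:5)] -
                      fa$uniquenesses)), 1e-4)

  # recursive path model vs per-equation OLS (exact ML for this class)
  dat2 <- path_model_data(1200, seed = 13)
  fit2 <- sem_fit(path_model_spec(), dat2, se = FALSE)
  ols2 <- lm(y2 ~ y1, dat2); ols3 <- lm(y3 ~ y1 + y2, dat2)
  expect_equal(coef(fit2)[["y2~y1"]], unname(coef(ols2)["y1"]), tolerance = 1e-6)
  expect_equal(coef(fit2)[["y3~y1"]], unname(coef(ols3)["y1"]), tolerance = 1e-6)
  expect_equal(coef(fit2)[["y3~y2"]], unname(coef(ols3)["y2"]), tolerance = 1e-6)
  n <- nrow(dat2)
  expect_equal(coef(fit2)[["y3~~y3"]], sum(resid(ols3)^2) / n, tolerance = 1e-5)
})

test_that("estimates are invariant to observed-variable ordering", {
  dat <- one_factor_data(800, seed = 9)
  spec1 <- one_factor_spec()
  fit1 <- sem_fit(spec1, dat, se = FALSE)
  perm <- c("y3", "y1", "y5", "y2", "y4")
  spec2 <- sem_spec(observed = perm, latent = "F",
                    paths = data.frame(from = "F", to = perm),
                    covariances = data.frame(v1 = "F", v2 = "F",
                                             free = FALSE, value = 1))
  fit2 <- sem_fit(spec2, dat, se = FALSE)
  expect_equal(coef(fit1)[names(coef(fit1))],
               coef(fit2)[names(coef(fit1))], tolerance = 1e-6)
})

test_that("jittered starts reach the same minimum on the shipped specs", {
  X <- as.data.frame(scale(test_cohort_pp()$cohort[delta_indicators()]))
  spec <- build_deq_spec()
  base <- sem_fit(spec, X, se = FALSE)
  set.seed(31)
  for (r in 1:5) {
    st <- coef(base) * runif(length(coef(base)), 0.55, 1.7)
    f <- sem_fit(spec, X, start = st, se = FALSE)
    expect_lt(abs(f$F_min - base$F_min), 1e-6)
  }
})

test_that("fit object methods are coherent", {
  dat <- one_factor_data(600, seed = 15)
  fit <- sem_fit(one_factor_spec(), dat)
  expect_output(print(fit), "SEM fit")
  tab <- parameter_table(fit)
  expect_setequal(tab$parameter, names(coef(fit)))
  expect_true(all(tab$se > 0, na.rm = TRUE))
  expect_equal(residuals(fit), fit$S - fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 1, n = 50)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(50L, 5L))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)))
})
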