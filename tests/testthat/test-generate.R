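test_that("generating truth encodes mediation shares exactly", {
  # no mediation by construction
  cfg0 <- synth_config(n_subjects = 50, n_biomarkers = 4, n_true_mediators = 0,
                       path_c_vec = c(0.3, 0, 0.2, 0), path_b_vec = rep(0, 4),
                       seed = 1)
  tr0 <- generate_cohort(cfg0)$truth
  expect_equal(tr0$percent_mediated, rep(0, 4))
  expect_equal(tr0$class, c(2L, 4L, 2L, 4L))

  # full mediation when the direct path is zero
  cfg1 <- synth_config(n_subjects = 50, n_biomarkers = 1, n_true_mediators = 1,
                       path_a = 0, path_c_vec = 0.3, path_b_vec = 0.2, seed = 1)
  tr1 <- generate_cohort(cfg1)$truth
  expect_equal(tr1$percent_mediated, 100)
  expect_equal(tr1$class, 1L)

  # the exact formula on the default layout
  cfg <- synth_config(seed = 2)
  tr <- generate_cohort(synth_config(n_subjects = 20, seed = 2))$truth
  expect_equal(tr$percent_mediated,
               100 * abs(cfg$path_c_vec * cfg$path_b_vec) /
                 (abs(cfg$path_c_vec * cfg$path_b_vec) + abs(cfg$path_a)))
  expect_true(all(tr$percent_mediated >= 0 & tr$percent_mediated <= 100))
})

test_that("invalid configurations error naming the offending variable", {
  expect_error(synth_config(n_true_mediators = 200), "exceeds")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(loading_delta = c(0.9, 0.6, 0.6, 0.5, 0.9),
                            loading_gprime = c(0.9, 0.55, 0.5, 0.6, 0)),
               "unique variance for indicator lm2")
  expect_error(synth_config(n_biomarkers = 1, n_true_mediators = 1,
                            path_c_vec = 1.2, path_b_vec = 0.1),
               "biomarker_1")
  expect_error(synth_config(path_a = 0.9,
                            n_biomarkers = 2, n_true_mediators = 1,
                            path_c_vec = c(0.5, 0), path_b_vec = c(0.9, 0)),
               "delta")
  expect_error(synth_config(loading_gprime = c(0.5, 0.55, 0.5, 0.6, 0.3)),
               "IADL")
})

test_that("age-delta correlation matches the closed-form path-tracing value", {
  cfg <- synth_config(n_subjects = 2000, missing_rate = 0, outlier_rate = 0,
                      seed = 1)
  gen <- generate_cohort(cfg)
  # cov(age_std, delta) = a + sum(b_k c_k); covariates independent of age
  r_expected <- cfg$path_a + sum(cfg$path_b_vec * cfg$path_c_vec)
  age_std <- (gen$cohort$age - cfg$age_mean) / cfg$age_sd
  r_emp <- cor(age_std, gen$truth$delta)
  expect_lt(r_expected, 0)
  expect_lt(r_emp, 0)
  expect_lt(abs(r_emp - r_expected), 0.05)
})

test_that("the generating equations reproduce their implied covariance at scale", {
  # independent oracle: hand-derived population moments of the generating
  # model, checked against a large simulated sample
  cfg <- synth_config(n_subjects = 1e5, n_biomarkers = 3, n_true_mediators = 2,
                      path_c_vec = c(0.4, -0.3, 0.3),
                      path_b_vec = c(-0.15, -0.1, 0),
                      batch_sd = 0, skew_flag = FALSE,
                      missing_rate = 0, outlier_rate = 0, seed = 9)
  gen <- generate_cohort(cfg)
  age_std <- (gen$cohort$age - cfg$age_mean) / cfg$age_sd
  m <- as.matrix(gen$cohort[paste0("biomarker_", 1:3)])
  tol <- 0.02
  # var(delta) = 1 by construction
  expect_lt(abs(var(gen$truth$delta) - 1), tol)
  # cov(age, m_k) = c_k
  expect_lt(max(abs(drop(cov(age_std, m)) - cfg$path_c_vec)), tol)
  # cov(m_j, m_k) = c_j c_k
  expect_lt(abs(cov(m[, 1], m[, 2]) - cfg$path_c_vec[1] * cfg$path_c_vec[2]), tol)
  # cov(delta, m_k) = b_k + c_k * (a + sum_j b_j c_j) + c_k sum_{j != k} b_j c_j
  sbc <- sum(cfg$path_b_vec * cfg$path_c_vec)
  cov_dm <- cfg$path_b_vec * (1 - cfg$path_c_vec^2) +
    cfg$path_c_vec * (cfg$path_a + sbc)
  expect_lt(max(abs(drop(cov(gen$truth$delta, m)) - cov_dm)), tol)
  # indicator structure: cov(y_j, delta) = sd_j * lambda_delta_j
  sc <- deltamed:::indicator_scale()
  for (j in 1:5) {
    y <- gen$cohort[[sc$indicator[j]]]
    expect_lt(abs(cov(y, gen$truth$delta) / sc$sd[j] - cfg$loading_delta[j]),
              tol)
  }
})

test_that("cohorts are bit-identical under the same seed and config", {
  g1 <- generate_cohort(synth_config(n_subjects = 200, n_biomarkers = 5,
                                     n_true_mediators = 2, seed = 77))
  g2 <- generate_cohort(synth_config(n_subjects = 200, n_biomarkers = 5,
                                     n_true_mediators = 2, seed = 77))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$delta, g2$truth$delta)
  g3 <- generate_cohort(synth_config(n_subjects = 200, n_biomarkers = 5,
                                     n_true_mediators = 2, seed = 78))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("missingness injection honours rate, mechanism and protected columns", {
  gen <- generate_cohort(synth_config(n_subjects = 1000, n_biomarkers = 5,
                                      n_true_mediators = 2, missing_rate = 0,
                                      outlier_rate = 0, seed = 3))
  tab <- gen$cohort

  expect_identical(inject_missingness(tab, 0, "mcar", seed = 1), tab)
  expect_error(inject_missingness(tab, 1, "mcar", seed = 1), "rate")

  m <- inject_missingness(tab, 0.2, "mcar", seed = 5)
  cells <- as.matrix(m[c(delta_indicators(), paste0("biomarker_", 1:5))])
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.2), 0.02)            # binomial tolerance at 10^4 cells
  expect_false(anyNA(m$age))
  expect_false(anyNA(m$dx))
  expect_false(anyNA(tab))                     # input untouched

  mar <- inject_missingness(tab, 0.2, "mar_age", seed = 6)
  above <- tab$age > median(tab$age)
  cells_mar <- is.na(as.matrix(mar[c(delta_indicators(),
                                     paste0("biomarker_", 1:5))]))
  expect_gt(mean(cells_mar[above, ]), mean(cells_mar[!above, ]))
})

test_that("cohort CSV and truth JSON round-trip with the seed recorded", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(synth_config(n_subjects = 60, n_biomarkers = 3,
                                      n_true_mediators = 1, seed = 12))
  write_cohort(gen$cohort, gen$truth, dir)
  back <- read_cohort(dir)
  expect_equal(back$seed, 12)
  expect_equal(nrow(back$cohort), 60)
  expect_equal(back$truth$path_a, gen$truth$path_a)
  expect_equal(back$truth$class, gen$truth$class)
  expect_equal(back$truth$config$seed, 12)
})
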