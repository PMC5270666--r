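test_that("mediation arithmetic matches the product-of-coefficients formulas", {
  # direct -0.13 with indirect -0.107 gives a 45.1% share, the magnitude
  # class of the strongest mediator the formula is designed to express
  eff <- mediation_effect(-0.13, path_c = 1, path_b = -0.107,
                          se_c = 0.01, se_b = 0.01)
  expect_equal(eff$percent_mediated, 100 * 0.107 / (0.107 + 0.13),
               tolerance = 1e-12)
  expect_lt(abs(eff$percent_mediated - 45.2), 0.5)
  expect_equal(eff$direction, "attenuating")

  # zero indirect effect: share 0, z 0
  e0 <- mediation_effect(-0.2, 0.3, 0, se_c = 0.01, se_b = 0.01)
  expect_equal(e0$percent_mediated, 0)
  expect_equal(e0$sobel_z, 0)
  expect_equal(e0$p_indirect, 1)

  # zero direct effect: full mediation
  e100 <- mediation_effect(0, 0.3, -0.2, se_c = 0.01, se_b = 0.01)
  expect_equal(e100$percent_mediated, 100)
  expect_equal(e100$direction, "accentuating")

  # undefined share sentinel
  eNA <- mediation_effect(0, 0, 0, se_c = 0.01, se_b = 0.01)
  expect_true(is.na(eNA$percent_mediated))

  # accentuating when the indirect effect opposes the direct effect's sign
  eacc <- mediation_effect(-0.2, -0.3, -0.1, se_c = 0.01, se_b = 0.01)
  expect_equal(eacc$direction, "accentuating")
  expect_equal(sign(eacc$sobel_z), sign(-0.3 * -0.1))
})

test_that("percent mediated is invariant to rescaling age", {
  # rescaling age by k > 0 scales paths a and c by 1/k and leaves b alone
  a <- -0.2; cc <- 0.35; b <- -0.1
  for (k in c(0.1, 2, 9.5)) {
    e1 <- mediation_effect(a, cc, b, 0.01, 0.01)
    e2 <- mediation_effect(a / k, cc / k, b, 0.01 / k, 0.01)
    expect_equal(e2$percent_mediated, e1$percent_mediated, tolerance = 1e-12)
  }
})

test_that("Sobel z agrees with a parametric bootstrap on a toy configuration", {
  cc <- 0.5; b <- 0.3; se_c <- 0.05; se_b <- 0.05
  eff <- mediation_effect(-0.1, cc, b, se_c, se_b)
  set.seed(61)
  cs <- rnorm(2000, cc, se_c); bs <- rnorm(2000, b, se_b)
  z_boot <- mean(cs * bs) / sd(cs * bs)
  expect_lt(abs(eff$sobel_z - z_boot) / abs(z_boot), 0.10)
})

test_that("the Bonferroni gate is strict and the taxonomy follows it", {
  expect_true(bonferroni_gate(0.0005))
  expect_false(bonferroni_gate(0.001))   # strict inequality
  expect_false(bonferroni_gate(0.5))
  expect_error(bonferroni_gate(1.5), "p_value")

  expect_equal(classify_protein(1e-5, 1e-4), 1L)
  expect_equal(classify_protein(1e-5, 0.02), 2L)
  expect_equal(classify_protein(0.02, 1e-5), 3L)
  expect_equal(classify_protein(0.02, 0.02), 4L)
  expect_equal(classify_protein(c(1e-5, 0.5), c(1e-5, 1e-5)), c(1L, 3L))
})

test_that("model builders wire the labelled paths and adjustment structure", {
  base <- build_base_model()
  expect_true(all(c("total_age", "total_age_gprime") %in% free_labels(base)))
  med <- build_mediation_model("biomarker_1")
  expect_true(all(c("path_a", "path_b", "path_c") %in% free_labels(med)))
  # exactly one more observed variable than the base model
  expect_equal(length(med$observed), length(base$observed) + 1L)
  expect_error(build_mediation_model("biomarker_1", covariates = "nope"),
               NA)  # spec construction is lazy about data columns
  # but fitting with a missing column errors
  expect_error(sem_fit(med, data.frame(age = 1:5)), "lacks column")
})

test_that("paths are recovered within 3 SE in a mediated synthetic cohort", {
  cfg <- synth_config(n_subjects = 3000, n_biomarkers = 2, n_true_mediators = 1,
                      path_c_vec = c(0.4, 0), path_b_vec = c(-0.25, 0),
                      path_gprime_age = 0, missing_rate = 0, outlier_rate = 0,
                      skew_flag = FALSE, seed = 62)
  gen <- generate_cohort(cfg)
  scr <- run_screen(gen$cohort, config = screen_config())
  df <- as.data.frame(scr)
  med <- df[df$biomarker == "biomarker_1", ]
  nul <- df[df$biomarker == "biomarker_2", ]
  # the biomarker-side path is unattenuated: recovery against truth
  expect_lt(abs(med$path_c - 0.4), 3 * med$se_c)
  # phenotype-side paths act on the composite scale (validity v), so the
  # recovered b is v * b with v = delta determinacy^2
  v <- attr(scr, "delta_model")$determinacy[["delta"]]^2
  expect_lt(abs(med$path_b - v * (-0.25)), 3 * med$se_b)
  # null biomarker: both paths within 3 SE of zero
  expect_lt(abs(nul$path_b), 3 * nul$se_b)
  expect_lt(abs(nul$path_c), 3 * nul$se_c)
  # decomposition consistency: a + c*b equals the base-model total effect
  total <- attr(scr, "total_age_effect")
  se_tot <- sqrt(med$se_a^2 + (med$path_b * med$se_c)^2 +
                   (med$path_c * med$se_b)^2)
  expect_lt(abs(med$path_a + med$indirect - total), 2 * se_tot)
})

test_that("the screen output contract holds", {
  # empty biomarker list: empty table, no error
  gen <- test_cohort()
  s0 <- run_screen(test_cohort_pp()$cohort, biomarkers = character(),
                   config = screen_config(preprocess = FALSE),
                   delta_model = test_delta_fit())
  expect_equal(nrow(s0), 0L)

  scr <- run_screen(test_cohort_pp()$cohort,
                    config = screen_config(preprocess = FALSE),
                    delta_model = test_delta_fit())
  df <- as.data.frame(scr)
  # every class-1 row is a partial mediator: share strictly inside (0, 100)
  cls1 <- df[df$class == 1L, ]
  expect_true(all(cls1$percent_mediated > 0 & cls1$percent_mediated < 100))
  # percent only reported for class 1; sign identity of the Sobel z
  expect_true(all(is.na(df$percent_mediated[df$class != 1L])))
  nz <- df$indirect != 0
  expect_equal(sign(df$sobel_z[nz]), sign(df$indirect[nz]))
  # sorted by class
  expect_true(!is.unsorted(df$class))
  # no silent drops
  expect_equal(nrow(df), 6L)
  expect_true(all(!df$failed))
})

test_that("screen tables are written deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cohort <- test_cohort_pp()$cohort
  s1 <- run_screen(cohort, config = screen_config(preprocess = FALSE),
                   delta_model = test_delta_fit())
  s2 <- run_screen(cohort, config = screen_config(preprocess = FALSE),
                   delta_model = test_delta_fit())
  write_screen_tables(s1, dir1)
  write_screen_tables(s2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
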