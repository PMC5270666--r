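test_that("the bifactor spec has the documented structure", {
  spec <- build_deq_spec()
  # 5 delta loadings + 4 g' loadings + 5 residual variances = 14 free;
  # 15 distinct covariance moments -> df = 1
  expect_length(free_labels(spec), 14L)
  expect_equal(length(spec$observed) * (length(spec$observed) + 1) / 2 -
                 length(free_labels(spec)), 1)
  # IADL loads on delta only; factors orthogonal with unit variance
  expect_false(any(spec$paths$from == "gprime" & spec$paths$to == "iadl"))
  ct <- spec$covariances
  orth <- ct[ct$v1 == "delta" & ct$v2 == "gprime", ]
  expect_false(orth$free); expect_equal(orth$value, 0)

  expect_error(build_deq_spec(c("a", "b", "c", "d")), "exactly 5")
  expect_error(build_deq_spec(c("a", "b", "c", "d", "e")), "IADL")
})

test_that("factor-score weights match closed forms", {
  # one indicator, one factor: weight = lambda / (lambda^2 + theta)
  lam <- 0.8; theta <- 0.36
  toy_spec <- function(l, th) sem_spec(
    "y1", "F",
    paths = data.frame(from = "F", to = "y1", free = FALSE, value = l),
    covariances = data.frame(v1 = c("F", "y1"), v2 = c("F", "y1"),
                             free = FALSE, value = c(1, th)),
    auto_var = FALSE)
  fit <- structure(list(spec = toy_spec(lam, theta), converged = TRUE,
                        coefficients = numeric(0)), class = "sem_fit")
  W <- factor_score_weights(fit)
  expect_equal(W[1, 1], lam / (lam^2 + theta), tolerance = 1e-12)

  # zero loadings give zero weights
  fit0 <- structure(list(spec = toy_spec(0, 1), converged = TRUE,
                         coefficients = numeric(0)), class = "sem_fit")
  expect_equal(factor_score_weights(fit0)[1, 1], 0)

  # bifactor: the IADL row of the g' weight column is generally nonzero
  # even though IADL's g' loading is fixed at zero
  dm <- test_delta_fit()
  W2 <- dm$weights
  expect_false(isTRUE(all.equal(W2["iadl", "gprime"], 0)))
  # and W = Sigma^-1 Lambda Phi exactly, by direct matrix evaluation
  mm <- deltamed:::measurement_matrices(dm$fit)
  expect_equal(unclass(W2), solve(mm$Sigma) %*% mm$Lambda %*% mm$Phi,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("determinacy matches the closed form and the limiting case", {
  # 1 factor, loadings (.8,.8,.8), Theta = diag(.36):
  # rho = sqrt(lambda' Sigma^-1 lambda)
  lam <- rep(0.8, 3)
  Sigma <- tcrossprod(lam) + diag(0.36, 3)
  rho_oracle <- sqrt(drop(t(lam) %*% solve(Sigma) %*% lam))
  spec <- sem_spec(paste0("y", 1:3), "F",
                   paths = data.frame(from = "F", to = paste0("y", 1:3)),
                   covariances = data.frame(v1 = "F", v2 = "F",
                                            free = FALSE, value = 1))
  fit <- structure(list(
    spec = spec, converged = TRUE,
    coefficients = c("y1~F" = .8, "y2~F" = .8, "y3~F" = .8,
                     "y1~~y1" = .36, "y2~~y2" = .36, "y3~~y3" = .36)),
    class = "sem_fit")
  expect_equal(unname(factor_determinacy(fit)["F"]), rho_oracle,
               tolerance = 1e-10)

  # residual variances -> 0 drives determinacy -> 1
  fit2 <- fit
  fit2$coefficients[4:6] <- 1e-8
  expect_gt(factor_determinacy(fit2)["F"], 0.999)
})

test_that("composite scores behave as linear scores with complete-case rule", {
  dm <- test_delta_fit()
  cohort <- test_cohort_pp()$cohort
  s <- predict(dm, cohort)
  # all indicators at the fitting-sample mean score (0, 0)
  at_mean <- as.data.frame(as.list(dm$center))
  s0 <- composite_scores(dm$weights, at_mean, orthogonalize_gprime = FALSE)
  expect_equal(unname(unlist(s0)), c(0, 0), tolerance = 1e-12)
  # permuting subjects permutes scores identically
  set.seed(5)
  perm <- sample(nrow(cohort))
  s_perm <- predict(dm, cohort[perm, ])
  expect_equal(s_perm$delta, s$delta[perm])
  # rows with a missing indicator are scored missing
  c2 <- cohort; c2$lm2[3] <- NA
  s2 <- predict(dm, c2)
  expect_true(is.na(s2$delta[3]) && is.na(s2$gprime[3]))
  expect_error(composite_scores(dm$weights, data.frame(x = 1)), "unknown indicator")
})

test_that("delta determinacy equals the score-factor correlation on simulation", {
  gen <- test_cohort()
  pp <- test_cohort_pp()
  dm <- test_delta_fit()
  s <- predict(dm, pp$cohort)
  cc <- complete.cases(s)
  r_emp <- cor(s$delta[cc], gen$truth$delta[cc])
  expect_lt(abs(r_emp - dm$determinacy[["delta"]]), 0.03)
  expect_gt(dm$determinacy[["delta"]], 0.8)
})

test_that("AUC follows the Mann-Whitney identity with a pairwise oracle", {
  # perfect separation (cases lower)
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), rep(c("AD", "NC"), each = 3))$auc, 1)
  # chance level under independence
  set.seed(51)
  sc <- rnorm(2000); lab <- sample(c("AD", "NC"), 2000, TRUE)
  expect_lt(abs(auc_roc(sc, lab)$auc - 0.5), 0.03)
  # exhaustive pairwise oracle with ties counted one-half
  set.seed(52)
  sc2 <- sample(1:8, 60, TRUE); lab2 <- sample(c("AD", "NC"), 60, TRUE)
  case <- sc2[lab2 == "AD"]; ctrl <- sc2[lab2 == "NC"]
  brute <- mean(outer(case, ctrl, "<") + 0.5 * outer(case, ctrl, "=="))
  res <- auc_roc(sc2, lab2)
  expect_equal(res$auc, brute, tolerance = 1e-12)
  expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  expect_error(auc_roc(1:5, rep("AD", 5)), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  sc <- c(rnorm(80, 0), rnorm(120, 1))
  lab <- rep(c("AD", "NC"), c(80, 120))
  ours <- auc_roc(sc, lab, positive = "AD", negative = "NC")$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("AD", "NC"),
                                   direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("severity validation reports Pearson correlation with sign convention", {
  set.seed(54)
  s <- rnorm(300)
  exact <- validate_vs_severity(s, 3 - 2 * s)
  expect_equal(abs(exact$r), 1, tolerance = 1e-12)
  noise <- validate_vs_severity(rnorm(5000), rnorm(5000))
  expect_lt(abs(noise$r), 0.05)
  expect_error(validate_vs_severity(1:2, 1:2), "3 complete pairs")

  # on a synthetic cohort, higher delta means better function: negative r
  pp <- test_cohort_pp()
  s2 <- predict(test_delta_fit(), pp$cohort)
  v <- validate_vs_severity(s2$delta, pp$cohort$cdr)
  expect_lt(v$r, -0.5)
})
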