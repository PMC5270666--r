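# Per-biomarker mediation engine: base model, three-path mediation model,
# product-of-coefficients effect, Bonferroni gate, four-class taxonomy.
#
# PATH-LABEL CONVENTION (deliberately the one used in the delta literature,
# NOT the conventional mediation notation):
#   path_a = age -> phenotype composite, the *direct* (adjusted) effect
#            (conventionally written c');
#   path_b = biomarker -> phenotype composite (conventional b);
#   path_c = age -> biomarker (conventionally a).
# The indirect effect is path_c * path_b and the total age effect is
# path_a + path_c * path_b.

#' Base model: age's direct association with the composites
#'
#' Regresses the delta and g' composites jointly on age and the covariate
#' set; age is the only unadjusted exogenous variable and the exogenous
#' block is saturated (covariates freely intercorrelated).
#'
#' @param covariates covariate column names (see [covariate_names()]).
#' @param age,deq,gprime column names of age and the two composites.
#' @return a [sem_spec()].
#' @export
build_base_model <- function(covariates = covariate_names(), age = "age",
                             deq = "deq_v2", gprime = "gprime_v2") {
  exog <- c(age, covariates)
  paths <- rbind(
    data.frame(from = exog, to = deq,
               label = c("total_age", rep(NA_character_, length(covariates)))),
    data.frame(from = exog, to = gprime,
               label = c("total_age_gprime", rep(NA_character_, length(covariates)))))
  cov_pairs <- t(utils::combn(exog, 2))
  covs <- rbind(
    data.frame(v1 = cov_pairs[, 1], v2 = cov_pairs[, 2]),
    data.frame(v1 = deq, v2 = gprime))  # residual covariance free
  sem_spec(observed = c(deq, gprime, exog), paths = paths,
           covariances = covs)
}

#' Mediation model: age -> biomarker -> phenotype
#'
#' Extends the base model with one biomarker as intermediate variable:
#' `age -> biomarker` (path c), `biomarker -> delta composite` (path b),
#' and the adjusted direct path `age -> delta composite` (path a).  The
#' biomarker and both composites are covariate-adjusted; the g' outcome is
#' retained in parallel (with no biomarker path, and the composite
#' residual covariance fixed at zero because the composites are
#' orthogonalized).
#'
#' @param biomarker biomarker column name.
#' @inheritParams build_base_model
#' @return a [sem_spec()] with labelled paths `path_a`, `path_b`, `path_c`.
#' @export
build_mediation_model <- function(biomarker,
                                  covariates = covariate_names(),
                                  age = "age", deq = "deq_v2",
                                  gprime = "gprime_v2") {
  exog <- c(age, covariates)
  paths <- rbind(
    data.frame(from = c(age, biomarker, covariates), to = deq,
               label = c("path_a", "path_b",
                         rep(NA_character_, length(covariates)))),
    data.frame(from = c(age, covariates), to = biomarker,
               label = c("path_c", rep(NA_character_, length(covariates)))),
    data.frame(from = exog, to = gprime, label = NA_character_))
  cov_pairs <- t(utils::combn(exog, 2))
  covs <- rbind(
    data.frame(v1 = cov_pairs[, 1], v2 = cov_pairs[, 2],
               free = TRUE, value = NA_real_),
    data.frame(v1 = deq, v2 = gprime, free = FALSE, value = 0))
  sem_spec(observed = c(deq, gprime, biomarker, exog), paths = paths,
           covariances = covs)
}

#' Product-of-coefficients mediation effect
#'
#' Indirect effect `path_c * path_b`, delta-method Sobel test
#' `z = (c b) / sqrt(b^2 se_c^2 + c^2 se_b^2)`, and percent of the total
#' age effect carried by the biomarker,
#' `100 |c b| / (|c b| + |a|)` - unsigned so that attenuating and
#' accentuating mediators both report positive shares.  The signed
#' proportion `c b / (a + c b)` is returned as a diagnostic.
#'
#' @param path_a adjusted direct age effect.
#' @param path_c age -> biomarker coefficient.
#' @param path_b biomarker -> phenotype coefficient.
#' @param se_c,se_b standard errors of `path_c`, `path_b`.
#' @return list: `indirect`, `sobel_z`, `p_indirect`, `percent_mediated`
#'   (`NA` sentinel when both `path_a` and the indirect effect are zero),
#'   `prop_signed`, `direction` (`"attenuating"` when the indirect effect
#'   shares the direct effect's sign, else `"accentuating"`).
#' @export
mediation_effect <- function(path_a, path_c, path_b, se_c, se_b) {
  stopifnot(is.finite(path_a), is.finite(path_c), is.finite(path_b))
  if (!is.na(se_c) && se_c < 0 || !is.na(se_b) && se_b < 0)
    stop_("standard errors must be positive")
  indirect <- path_c * path_b
  if (indirect == 0) {
    z <- 0
  } else {
    denom <- sqrt(path_b^2 * se_c^2 + path_c^2 * se_b^2)
    z <- if (denom > 0) indirect / denom else Inf * sign(indirect)
  }
  denom_pct <- abs(indirect) + abs(path_a)
  percent <- if (denom_pct > 0) 100 * abs(indirect) / denom_pct else NA_real_
  total <- path_a + indirect
  list(indirect = indirect, sobel_z = z,
       p_indirect = 2 * stats::pnorm(-abs(z)),
       percent_mediated = percent,
       prop_signed = if (total != 0) indirect / total else NA_real_,
       direction = if (indirect == 0) NA_character_
                   else if (sign(indirect) == sign(path_a)) "attenuating"
                   else "accentuating")
}

#' Bonferroni significance gate
#'
#' `TRUE` iff `p` is strictly below the gate (default 0.001, the
#' Bonferroni-corrected level used for a ~100-protein panel).
#'
#' @param p_value p-value(s) in `[0, 1]`.
#' @param alpha gate level.
#' @return logical vector.
#' @export
bonferroni_gate <- function(p_value, alpha = 0.001) {
  stopifnot(all(p_value >= 0 & p_value <= 1, na.rm = TRUE))
  !is.na(p_value) & p_value < alpha
}

#' Four-class protein taxonomy
#'
#' Class 1: both the age->biomarker path (c) and the biomarker->phenotype
#' path (b) pass the gate (candidate mediator).  Class 2: only c passes
#' (age-related, phenotype-independent).  Class 3: only b passes
#' (age-independent phenotype correlate).  Class 4: neither.
#'
#' @param p_c,p_b gated p-values of paths c and b (vectorized).
#' @param alpha gate level passed to [bonferroni_gate()].
#' @return integer class labels 1-4.
#' @export
classify_protein <- function(p_c, p_b, alpha = 0.001) {
  gc_ <- bonferroni_gate(p_c, alpha)
  gb_ <- bonferroni_gate(p_b, alpha)
  ifelse(gc_ & gb_, 1L, ifelse(gc_, 2L, ifelse(gb_, 3L, 4L)))
}

#' Default screen configuration
#'
#' @param alpha Bonferroni gate level.
#' @param estimator `"ml"` or `"fiml"` for the per-biomarker models.
#' @param covariates covariate set for adjustment.
#' @param preprocess run [preprocess_cohort()] first.
#' @param outlier_cutoff,skew_threshold preprocessing thresholds.
#' @return list of screen settings.
#' @export
screen_config <- function(alpha = 0.001, estimator = "ml",
                          covariates = covariate_names(),
                          preprocess = TRUE, outlier_cutoff = 3.0,
                          skew_threshold = 1.0) {
  list(alpha = alpha, estimator = estimator, covariates = covariates,
       preprocess = preprocess, outlier_cutoff = outlier_cutoff,
       skew_threshold = skew_threshold)
}

#' Screen a biomarker panel for mediators of age's phenotype effect
#'
#' End-to-end per-biomarker screen: preprocess the panel, fit the delta
#' phenotype and score subjects, fit the covariate-adjusted base model for
#' the total age effect, then fit one mediation model per biomarker and
#' derive the indirect effect, Sobel test, percent mediated, gate
#' decisions and taxonomy class.  Age and all covariates are standardized
#' internally, so reported coefficients are per-SD.  Per-biomarker fit
#' failures are recorded with `failed = TRUE`, never dropped.
#'
#' @param cohort cohort data frame (generator schema).
#' @param biomarkers biomarker columns; default all `biomarker_*`.
#' @param config a [screen_config()].
#' @param delta_model optionally, a pre-fit [fit_delta()] object to score
#'   with (otherwise fit on `cohort`).
#' @return data frame of class `"mediation_screen"`, sorted by class then
#'   descending |percent mediated|; attributes carry the base-model fit,
#'   the delta fit and the preprocessing report.
#' @export
run_screen <- function(cohort, biomarkers = NULL, config = screen_config(),
                       delta_model = NULL) {
  if (is.null(biomarkers))
    biomarkers <- grep("^biomarker_", names(cohort), value = TRUE)
  prep_report <- NULL
  if (isTRUE(config$preprocess) && length(biomarkers)) {
    pp <- preprocess_cohort(cohort, columns = biomarkers,
                            outlier_cutoff = config$outlier_cutoff,
                            skew_threshold = config$skew_threshold)
    cohort <- pp$cohort
    prep_report <- pp$report
  }
  if (is.null(delta_model)) delta_model <- fit_delta(cohort)
  scores <- predict(delta_model, cohort)
  dat <- cohort
  dat$deq_v2 <- scores$delta
  dat$gprime_v2 <- scores$gprime
  dat$age <- scale_num(dat$age)
  for (v in config$covariates) dat[[v]] <- scale_num(dat[[v]])

  base_spec <- build_base_model(config$covariates)
  base_fit <- sem_fit(base_spec, dat, estimator = config$estimator)
  total_age <- coef(base_fit)[["total_age"]]

  rows <- lapply(biomarkers, function(bm) {
    fit <- tryCatch({
      spec <- build_mediation_model(bm, config$covariates)
      sem_fit(spec, dat, estimator = config$estimator)
    }, error = function(e) e)
    if (inherits(fit, "error"))
      return(screen_row(bm, failed = TRUE, message = conditionMessage(fit)))
    tab <- parameter_table(fit)
    rownames(tab) <- tab$parameter
    a <- tab["path_a", ]; b <- tab["path_b", ]; cc <- tab["path_c", ]
    eff <- mediation_effect(a$estimate, cc$estimate, b$estimate,
                            cc$se, b$se)
    cls <- classify_protein(cc$p, b$p, config$alpha)
    idx <- fit_indices(fit)
    screen_row(bm, failed = !fit$converged,
               path_a = a$estimate, se_a = a$se, p_a = a$p,
               path_b = b$estimate, se_b = b$se, p_b = b$p,
               path_c = cc$estimate, se_c = cc$se, p_c = cc$p,
               indirect = eff$indirect, sobel_z = eff$sobel_z,
               p_indirect = eff$p_indirect,
               percent_mediated = if (cls == 1L) eff$percent_mediated else NA_real_,
               percent_raw = eff$percent_mediated,
               prop_signed = eff$prop_signed,
               direction = eff$direction %||% NA_character_,
               class = cls, chisq = fit$chisq, df = fit$df,
               cmin_df = idx$cmin_df, cfi = idx$cfi, rmsea = idx$rmsea,
               converged = fit$converged,
               message = if (fit$converged) "" else "non-convergence")
  })
  out <- if (length(rows)) do.call(rbind, rows) else screen_row("")[0, ]
  if (nrow(out)) {
    ord <- order(out$class, -abs(ifelse(is.na(out$percent_mediated), -Inf,
                                        out$percent_mediated)),
                 -abs(ifelse(is.na(out$sobel_z), 0, out$sobel_z)))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("mediation_screen", "data.frame"),
            base_fit = base_fit, total_age_effect = total_age,
            delta_model = delta_model, prep_report = prep_report,
            config = config)
}

scale_num <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

screen_row <- function(biomarker, failed = FALSE, path_a = NA_real_,
                       se_a = NA_real_, p_a = NA_real_, path_b = NA_real_,
                       se_b = NA_real_, p_b = NA_real_, path_c = NA_real_,
                       se_c = NA_real_, p_c = NA_real_, indirect = NA_real_,
                       sobel_z = NA_real_, p_indirect = NA_real_,
                       percent_mediated = NA_real_, percent_raw = NA_real_,
                       prop_signed = NA_real_,
                       direction = NA_character_, class = NA_integer_,
                       chisq = NA_real_, df = NA_integer_,
                       cmin_df = NA_real_, cfi = NA_real_, rmsea = NA_real_,
                       converged = NA, message = "") {
  data.frame(biomarker = biomarker, path_a = path_a, se_a = se_a, p_a = p_a,
             path_b = path_b, se_b = se_b, p_b = p_b, path_c = path_c,
             se_c = se_c, p_c = p_c, indirect = indirect, sobel_z = sobel_z,
             p_indirect = p_indirect, percent_mediated = percent_mediated,
             percent_raw = percent_raw,
             prop_signed = prop_signed, direction = direction, class = class,
             chisq = chisq, df = df, cmin_df = cmin_df, cfi = cfi,
             rmsea = rmsea, converged = converged, failed = failed,
             message = message, stringsAsFactors = FALSE)
}

#' @export
print.mediation_screen <- function(x, ...) {
  if (!all(c("class", "failed", "percent_mediated") %in% names(x)))
    return(NextMethod())
  cat(sprintf("Mediation screen: %d biomarkers; class counts %s; total age effect %.3f\n",
              nrow(x), paste(sprintf("%d:%d", 1:4, tabulate(x$class, 4)),
                             collapse = " "),
              attr(x, "total_age_effect")))
  cls1 <- x[x$class == 1L & !x$failed, , drop = FALSE]
  if (nrow(cls1)) {
    cat("Class-1 mediators (percent of total age effect mediated):\n")
    print(cls1[, c("biomarker", "path_a", "sobel_z", "p_indirect",
                   "percent_mediated", "direction")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write the screen's class tables to CSV
#'
#' Emits four class tables plus a mediation-effects table (biomarker,
#' adjusted direct age path, Sobel z and p, percent mediated).
#'
#' @param screen a [run_screen()] result.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_screen_tables <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (k in 1:4) {
    f <- file.path(dir, sprintf("class%d.csv", k))
    utils::write.csv(screen[screen$class == k & !screen$failed, , drop = FALSE],
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }
  eff <- screen[screen$class == 1L & !screen$failed,
                c("biomarker", "path_a", "p_a", "sobel_z", "p_indirect",
                  "percent_mediated", "direction"), drop = FALSE]
  f <- file.path(dir, "mediation_effects.csv")
  utils::write.csv(eff, f, row.names = FALSE)
  fails <- screen[screen$failed, , drop = FALSE]
  ff <- file.path(dir, "failed_fits.csv")
  utils::write.csv(fails, ff, row.names = FALSE)
  invisible(c(paths, f, ff))
}
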