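# Synthetic-cohort generator: draws subjects with the exact latent
# structure the downstream analysis assumes (bifactor delta/g' measurement,
# age -> biomarker -> delta mediation, batch effects, skewed biomarker
# scales, outliers, missingness) and returns the generating truth.

#' Names of the five phenotype indicators
#'
#' Logical Memory II, Visual Reproduction I, Controlled Oral Word
#' Association, Digit Span, and summed instrumental activities of daily
#' living (reverse-scored so that higher always means better function).
#' @return character vector of column names.
#' @export
delta_indicators <- function() c("lm2", "vr1", "cowa", "dst", "iadl")

#' Names of the model covariates
#' @return character vector: APOE e4 carrier status, education years,
#'   ethnicity, gender, depressive symptoms (GDS), homocysteine, HbA1c.
#' @export
covariate_names <- function() c("apoe", "educ", "ethnicity", "gender",
                                "gds", "hcy", "hgba1c")

indicator_scale <- function() {
  data.frame(indicator = delta_indicators(),
             mean = c(8.05, 7.88, 8.41, 8.89, 10.48),
             sd = c(4.30, 3.68, 3.49, 3.01, 4.52))
}

#' Configuration of the synthetic-cohort generator
#'
#' All structural coefficients are on the standardized (unit-variance)
#' scale of the latent generating model.  Defaults define the package's
#' reference study conditions; the methods vignette documents the
#' rationale for each.  When `path_c_vec`/`path_b_vec` are not supplied
#' they are built from a four-class biomarker layout: `n_true_mediators`
#' class-1 biomarkers (both age- and delta-related; 70% attenuating with
#' `c = 0.35, b = -0.12`, 30% accentuating with `c = -0.35, b = -0.12`),
#' then age-only (class 2), delta-only (class 3) and null (class 4)
#' biomarkers in roughly the proportions 40:18:22 of the remainder.
#'
#' @param n_subjects number of subjects.
#' @param n_biomarkers number of serum biomarker columns.
#' @param n_true_mediators number of class-1 (true mediator) biomarkers;
#'   defaults to a fifth of the panel.
#' @param loading_delta loadings of the five indicators on delta.
#' @param loading_gprime loadings on g' (the IADL entry must be 0).
#' @param path_a direct (unmediated) age -> delta coefficient.
#' @param path_c_vec per-biomarker age -> biomarker coefficients.
#' @param path_b_vec per-biomarker biomarker -> delta coefficients.
#' @param path_gprime_age weak age -> g' coefficient.
#' @param covariate_effects named vector of covariate -> delta effects
#'   (standardized per-SD scale).
#' @param batch_count number of assay batches.
#' @param batch_sd SD of the per-batch additive shift on the (log) scale.
#' @param skew_flag logical per-biomarker: report on a lognormal scale.
#' @param missing_rate expected fraction of missing indicator/biomarker
#'   cells, in `[0, 1)`.
#' @param missing_mechanism `"mcar"` or `"mar_age"`.
#' @param outlier_rate fraction of biomarker cells replaced by gross
#'   outliers (5-8 SD), in `[0, 1)`.
#' @param age_mean,age_sd age distribution (years).
#' @param dx_thresholds standard-normal cut points on delta separating
#'   AD / MCI / NC (defaults: tertiles).
#' @param seed RNG seed recorded with the cohort.
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 3000L, n_biomarkers = 100L,
                         n_true_mediators = NULL,
                         loading_delta = c(0.75, 0.45, 0.65, 0.35, 0.80),
                         loading_gprime = c(0.40, 0.65, 0.45, 0.70, 0),
                         path_a = -0.12,
                         path_c_vec = NULL, path_b_vec = NULL,
                         path_gprime_age = -0.11,
                         covariate_effects = c(apoe = -0.15, educ = 0.12,
                                               ethnicity = -0.05, gender = 0.03,
                                               gds = -0.12, hcy = -0.05,
                                               hgba1c = -0.05),
                         batch_count = 5L, batch_sd = 0.30,
                         skew_flag = NULL,
                         missing_rate = 0.05,
                         missing_mechanism = c("mcar", "mar_age"),
                         outlier_rate = 0.005,
                         age_mean = 71, age_sd = 9.5,
                         dx_thresholds = stats::qnorm(c(1/3, 2/3)),
                         seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  K <- as.integer(n_biomarkers)
  # default: one fifth of the panel are true mediators (20 on the 100-panel)
  if (is.null(n_true_mediators)) n_true_mediators <- round(0.2 * K)
  if (n_true_mediators > K)
    stop_("n_true_mediators (%d) exceeds n_biomarkers (%d)", n_true_mediators, K)
  if (missing_rate < 0 || missing_rate >= 1) stop_("missing_rate must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop_("outlier_rate must be in [0, 1)")
  if (length(loading_delta) != 5L || length(loading_gprime) != 5L)
    stop_("indicator loading vectors must have length 5")
  if (loading_gprime[5] != 0) stop_("IADL must not load on g'")
  if (!all(is.finite(c(loading_delta, loading_gprime, path_a, path_gprime_age))))
    stop_("loadings and paths must be finite")

  if (is.null(path_c_vec) || is.null(path_b_vec)) {
    layout <- default_biomarker_layout(K, as.integer(n_true_mediators))
    path_c_vec <- path_c_vec %||% layout$c
    path_b_vec <- path_b_vec %||% layout$b
  }
  if (length(path_c_vec) != K || length(path_b_vec) != K)
    stop_("path_c_vec and path_b_vec must have length n_biomarkers")
  if (is.null(skew_flag)) skew_flag <- (seq_len(K) %% 2L) == 1L
  if (length(skew_flag) == 1L) skew_flag <- rep(skew_flag, K)
  if (length(skew_flag) != K) stop_("skew_flag must have length n_biomarkers")

  covs <- covariate_names()
  eff <- stats::setNames(rep(0, length(covs)), covs)
  eff[names(covariate_effects)] <- covariate_effects

  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_biomarkers = K,
    n_true_mediators = as.integer(n_true_mediators),
    loading_delta = loading_delta, loading_gprime = loading_gprime,
    path_a = path_a, path_c_vec = path_c_vec, path_b_vec = path_b_vec,
    path_gprime_age = path_gprime_age, covariate_effects = eff,
    batch_count = as.integer(batch_count), batch_sd = batch_sd,
    skew_flag = as.logical(skew_flag), missing_rate = missing_rate,
    missing_mechanism = missing_mechanism, outlier_rate = outlier_rate,
    age_mean = age_mean, age_sd = age_sd, dx_thresholds = dx_thresholds,
    seed = as.integer(seed)), class = "synth_config")
  check_config_variances(cfg)
  cfg
}

default_biomarker_layout <- function(K, n_med) {
  cvec <- numeric(K); bvec <- numeric(K)
  if (n_med > 0) {
    n_att <- ceiling(0.7 * n_med)
    cvec[seq_len(n_med)] <- c(rep(0.35, n_att), rep(-0.35, n_med - n_att))
    bvec[seq_len(n_med)] <- -0.12
  }
  rest <- K - n_med
  if (rest > 0) {
    n2 <- round(rest * 40 / 80); n3 <- round(rest * 18 / 80)
    idx <- n_med + seq_len(rest)
    if (n2 > 0) cvec[idx[seq_len(n2)]] <- 0.35
    if (n3 > 0) bvec[idx[n2 + seq_len(n3)]] <- rep_len(c(-0.10, 0.10), n3)
  }
  list(c = cvec, b = bvec)
}

# Positive-variance checks; errors name the offending variable.
check_config_variances <- function(cfg) {
  theta <- 1 - cfg$loading_delta^2 - cfg$loading_gprime^2
  bad <- which(theta <= 0)
  if (length(bad))
    stop_("non-positive unique variance for indicator %s",
          delta_indicators()[bad[1]])
  bad <- which(1 - cfg$path_c_vec^2 <= 0)
  if (length(bad))
    stop_("non-positive residual variance for biomarker_%d", bad[1])
  if (delta_disturbance(cfg) <= 0)
    stop_("non-positive disturbance variance for delta (systematic variance >= 1)")
  if (1 - cfg$path_gprime_age^2 <= 0)
    stop_("non-positive disturbance variance for gprime")
  invisible(cfg)
}

# Disturbance variance of delta implied by the standardized generating
# equations (biomarkers correlate pairwise through age: cov = c_j c_k).
delta_disturbance <- function(cfg) {
  a <- cfg$path_a; b <- cfg$path_b_vec; cc <- cfg$path_c_vec
  sbc <- sum(b * cc)
  sys <- a^2 + sum(b^2) + 2 * a * sbc + (sbc^2 - sum((b * cc)^2)) +
    sum(cfg$covariate_effects^2)
  1 - sys
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a subject-level table following the generating equations of the
#' standardized latent model: age and covariates are exogenous; each
#' biomarker is `c_k * age_std` plus noise (plus a batch shift, and
#' exponentiated when flagged skewed); delta is the sum of its direct age
#' path, the biomarker paths, covariate effects and a disturbance scaled
#' to unit total variance; g' is near-independent of age; the five
#' indicators load on delta (IADL on delta only) and g'; diagnosis labels
#' come from thresholding delta and CDR sum-of-boxes is a noisy monotone
#' transform of delta.  Outliers and missingness are injected last.
#'
#' @param config a [synth_config()].
#' @return list with `cohort` (data frame) and `truth` (class
#'   `"synth_truth"`: generating paths, per-biomarker indirect effect and
#'   percent mediated, class labels 1-4, and per-subject latent scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  check_config_variances(config)
  cfg <- config
  n <- cfg$n_subjects; K <- cfg$n_biomarkers
  with_seed(cfg$seed, {
    age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
    age_std <- (age - cfg$age_mean) / cfg$age_sd

    # covariates: raw marginals echo the cohort demographics; standardized
    # copies (theoretical moments) carry the effects on delta
    raw <- list(
      apoe = stats::rbinom(n, 1, 0.39),
      educ = stats::rnorm(n, 13.24, 4.25),
      ethnicity = stats::rbinom(n, 1, 0.36),
      gender = stats::rbinom(n, 1, 0.39),
      gds = pmax(stats::rnorm(n, 5.6, 5.25), 0),
      hcy = stats::rnorm(n), hgba1c = stats::rnorm(n))
    mom <- list(apoe = c(0.39, sqrt(0.39 * 0.61)), educ = c(13.24, 4.25),
                ethnicity = c(0.36, sqrt(0.36 * 0.64)),
                gender = c(0.39, sqrt(0.39 * 0.61)), gds = c(5.6, 5.25),
                hcy = c(0, 1), hgba1c = c(0, 1))
    zcov <- sapply(covariate_names(), function(v)
      (raw[[v]] - mom[[v]][1]) / mom[[v]][2])

    m_std <- sapply(seq_len(K), function(k)
      cfg$path_c_vec[k] * age_std +
        sqrt(1 - cfg$path_c_vec[k]^2) * stats::rnorm(n))

    psi <- delta_disturbance(cfg)
    delta <- cfg$path_a * age_std + drop(m_std %*% cfg$path_b_vec) +
      drop(zcov %*% cfg$covariate_effects) + sqrt(psi) * stats::rnorm(n)
    gprime <- cfg$path_gprime_age * age_std +
      sqrt(1 - cfg$path_gprime_age^2) * stats::rnorm(n)

    sc <- indicator_scale()
    theta <- 1 - cfg$loading_delta^2 - cfg$loading_gprime^2
    ind <- sapply(1:5, function(j)
      sc$mean[j] + sc$sd[j] * (cfg$loading_delta[j] * delta +
        cfg$loading_gprime[j] * gprime + sqrt(theta[j]) * stats::rnorm(n)))
    colnames(ind) <- delta_indicators()

    batch <- sample.int(cfg$batch_count, n, replace = TRUE)
    shifts <- matrix(stats::rnorm(cfg$batch_count * K, sd = cfg$batch_sd),
                     cfg$batch_count, K)
    bio <- m_std + shifts[batch, , drop = FALSE]
    for (k in which(cfg$skew_flag)) bio[, k] <- exp(bio[, k])
    colnames(bio) <- paste0("biomarker_", seq_len(K))

    dx <- cut(delta, c(-Inf, cfg$dx_thresholds, Inf),
              labels = c("AD", "MCI", "NC"))
    cdr <- pmin(pmax(2.4 - 2.2 * delta + stats::rnorm(n, sd = 1.5), 0), 18)
    cdr <- round(cdr * 2) / 2

    cohort <- data.frame(subject_id = seq_len(n), age = age,
                         zcov_raw_placeholder = NA)
    cohort$zcov_raw_placeholder <- NULL
    for (v in covariate_names()) cohort[[v]] <- raw[[v]]
    cohort <- cbind(cohort, as.data.frame(ind), as.data.frame(bio))
    cohort$batch <- batch
    cohort$dx <- as.character(dx)
    cohort$cdr <- cdr

    if (cfg$outlier_rate > 0) {
      for (k in seq_len(K)) {
        col <- paste0("biomarker_", k)
        hit <- which(stats::runif(n) < cfg$outlier_rate)
        if (length(hit)) {
          m0 <- mean(cohort[[col]]); s0 <- stats::sd(cohort[[col]])
          cohort[[col]][hit] <- m0 + sample(c(-1, 1), length(hit), TRUE) *
            stats::runif(length(hit), 5, 8) * s0
        }
      }
    }
    if (cfg$missing_rate > 0)
      cohort <- inject_missingness(cohort, cfg$missing_rate,
                                   cfg$missing_mechanism,
                                   seed = NULL)  # inside the seeded stream

    indirect <- cfg$path_c_vec * cfg$path_b_vec
    denom <- abs(indirect) + abs(cfg$path_a)
    percent <- ifelse(denom > 0, 100 * abs(indirect) / denom, NA_real_)
    class <- ifelse(cfg$path_c_vec != 0 & cfg$path_b_vec != 0, 1L,
             ifelse(cfg$path_c_vec != 0, 2L,
             ifelse(cfg$path_b_vec != 0, 3L, 4L)))
    truth <- structure(list(
      config = cfg, path_a = cfg$path_a, path_c = cfg$path_c_vec,
      path_b = cfg$path_b_vec, indirect = indirect,
      percent_mediated = percent, class = class,
      biomarker = colnames(bio), delta = delta, gprime = gprime,
      seed = cfg$seed), class = "synth_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Inject missingness into indicator and biomarker cells
#'
#' Masks cells completely at random (`"mcar"`) or with an age-dependent
#' rate (`"mar_age"`: above-median-age subjects are masked at 1.5x the
#' rate, below-median at 0.5x, preserving the expected overall rate).
#' `age` and `dx` are never masked.  The input is not modified.
#'
#' @param table cohort data frame.
#' @param rate expected fraction of masked cells, in `[0, 1)`.
#' @param mechanism `"mcar"` or `"mar_age"`.
#' @param seed optional seed (`NULL` uses the current RNG stream).
#' @param columns columns eligible for masking; defaults to the indicator
#'   and `biomarker_*` columns present.
#' @return a new data frame with masked cells.
#' @export
inject_missingness <- function(table, rate, mechanism = c("mcar", "mar_age"),
                               seed = NULL, columns = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate >= 1) stop_("rate must be < 1")
  if (rate < 0) stop_("rate must be >= 0")
  if (rate == 0) return(table)
  if (is.null(columns))
    columns <- intersect(c(delta_indicators(),
                           grep("^biomarker_", names(table), value = TRUE)),
                         names(table))
  columns <- setdiff(columns, c("age", "dx"))
  n <- nrow(table)
  p_row <- rep(rate, n)
  if (mechanism == "mar_age") {
    if (is.null(table$age)) stop_("mar_age mechanism requires an age column")
    above <- table$age > stats::median(table$age)
    hi <- min(1.5 * rate, 0.95)
    p_row <- ifelse(above, hi, 2 * rate - hi)
    p_row <- pmax(p_row, 0)
  }
  with_seed(seed, {
    for (col in columns) {
      mask <- stats::runif(n) < p_row
      table[[col]][mask] <- NA
    }
    table
  })
}

#' Write / read a cohort and its ground truth
#'
#' The cohort is written as one CSV row per subject (indicator columns,
#' covariate columns, `biomarker_<k>`, `batch`, `dx`, `cdr`); the truth
#' object goes to a JSON sidecar.  The generating seed is recorded in both.
#'
#' @param cohort,truth as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "cohort.csv")
  tpath <- file.path(dir, "truth.json")
  cohort$generator_seed <- truth$seed
  utils::write.csv(cohort, cpath, row.names = FALSE)
  tr <- truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(unclass(tr), tpath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(cohort = cpath, truth = tpath))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  seed <- cohort$generator_seed[1]
  cohort$generator_seed <- NULL
  tpath <- file.path(dir, "truth.json")
  truth <- if (file.exists(tpath)) jsonlite::fromJSON(tpath) else NULL
  list(cohort = cohort, truth = truth, seed = seed)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: n = %d, %d biomarkers (%d true mediators), seed = %d\n",
              x$n_subjects, x$n_biomarkers, x$n_true_mediators, x$seed))
  cat(sprintf("  direct age path a = %.3f; missing %.1f%%, outliers %.2f%%, %d batches\n",
              x$path_a, 100 * x$missing_rate, 100 * x$outlier_rate, x$batch_count))
  invisible(x)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d biomarkers; class counts: %s\n",
              length(x$class),
              paste(sprintf("%d:%d", 1:4, tabulate(x$class, 4)), collapse = " ")))
  cat(sprintf("  true percent mediated (class 1): %s\n",
              paste(round(unique(x$percent_mediated[x$class == 1]), 1), collapse = ", ")))
  invisible(x)
}
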