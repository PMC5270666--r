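# Biomarker conditioning chain: single-pass outlier trimming, optional log
# transform for highly skewed columns, z-standardization, batch
# residualization, re-standardization.

#' Trim gross outliers from a biomarker column
#'
#' Single pass: z-scores are computed once from the non-missing mean and SD
#' of the input, and entries with `|z| > cutoff` are set to missing.  The
#' pass is not iterated.
#'
#' @param values numeric vector, possibly with missing entries.
#' @param cutoff SD multiple beyond which a value is an outlier (default 3.0).
#' @return the trimmed vector, with attribute `n_removed`.
#' @export
remove_outliers <- function(values, cutoff = 3.0) {
  ok <- !is.na(values)
  if (sum(ok) == 0L) stop_("all values missing")
  if (sum(ok) < 3L) stop_("need at least 3 non-missing values")
  m <- mean(values[ok]); s <- stats::sd(values[ok])
  if (is.na(s) || s == 0) {
    out <- values
    attr(out, "n_removed") <- 0L
    return(out)
  }
  z <- (values - m) / s
  drop_idx <- which(ok & abs(z) > cutoff)
  values[drop_idx] <- NA
  attr(values, "n_removed") <- length(drop_idx)
  values
}

#' Normalize a biomarker column
#'
#' Applies a natural-log transform when the sample skewness exceeds
#' `skew_threshold` in absolute value (non-positive values are first
#' shifted by `1 - min` and the shift recorded), then z-standardizes the
#' non-missing entries to mean 0 and unit variance.
#'
#' @param values numeric vector (outliers already removed).
#' @param skew_threshold |skewness| above which the log branch triggers
#'   (default 1.0).
#' @return standardized vector with attributes `log_applied`, `shift`,
#'   `skew_before`, `skew_after`.
#' @export
normalize_biomarker <- function(values, skew_threshold = 1.0) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop_("need at least 3 non-missing values")
  g1 <- sample_skewness(values)
  log_applied <- FALSE
  shift <- 0
  out <- values
  if (is.finite(g1) && abs(g1) > skew_threshold) {
    mn <- min(values, na.rm = TRUE)
    if (mn <= 0) shift <- 1 - mn
    out <- log(values + shift)
    log_applied <- TRUE
  }
  m <- mean(out, na.rm = TRUE); s <- stats::sd(out, na.rm = TRUE)
  if (is.na(s) || s == 0) stop_("zero variance after transform")
  out <- (out - m) / s
  attr(out, "log_applied") <- log_applied
  attr(out, "shift") <- shift
  attr(out, "skew_before") <- g1
  attr(out, "skew_after") <- sample_skewness(out)
  out
}

#' Residualize a variable on a regressor matrix
#'
#' Ordinary least-squares residuals computed on complete cases; missing
#' targets stay missing.  Used to adjust biomarkers for assay-batch dummy
#' variables.  Constant regressors are dropped (residual = centered
#' target); genuinely collinear regressors are an error naming the
#' columns.
#'
#' @param target numeric vector.
#' @param regressors numeric matrix or data frame (dummies etc.).
#' @return residual vector with the target's missingness pattern;
#'   attribute `r_squared` records the variance explained.
#' @export
residualize <- function(target, regressors) {
  X <- as.matrix(regressors)
  storage.mode(X) <- "double"
  if (nrow(X) != length(target)) stop_("regressor rows != target length")
  keep_col <- apply(X, 2, function(c) stats::sd(c, na.rm = TRUE) > 0)
  X <- X[, keep_col, drop = FALSE]
  ok <- !is.na(target) & stats::complete.cases(X)
  out <- rep(NA_real_, length(target))
  y <- target[ok]
  if (!ncol(X)) {
    out[ok] <- y - mean(y)
    attr(out, "r_squared") <- 0
    return(out)
  }
  Xc <- cbind(1, X[ok, , drop = FALSE])
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(Xc))] - 1]
    stop_("rank-deficient regressors; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  res <- qr.resid(qr_x, y)
  out[ok] <- res
  v0 <- stats::var(y)
  attr(out, "r_squared") <- if (v0 > 0) 1 - stats::var(res) / v0 else 0
  out
}

#' Run the full biomarker preprocessing chain on a cohort
#'
#' For every `biomarker_*` column (or the columns named): trim outliers
#' beyond `outlier_cutoff` SD (single pass), log-transform if skewness
#' exceeds `skew_threshold`, standardize, residualize on batch dummies,
#' and re-standardize.  The input cohort is not modified.
#'
#' @param cohort cohort data frame (with a `batch` column if batch
#'   adjustment is wanted).
#' @param columns biomarker columns; default all `biomarker_*`.
#' @param outlier_cutoff,skew_threshold chain thresholds.
#' @param batch_adjust residualize on batch dummies (default `TRUE` when a
#'   `batch` column exists).
#' @return list with `cohort` (processed copy) and `report` (one row per
#'   column: `column`, `n_outliers`, `log_applied`, `batch_r2`).
#' @export
preprocess_cohort <- function(cohort, columns = NULL, outlier_cutoff = 3.0,
                              skew_threshold = 1.0,
                              batch_adjust = !is.null(cohort$batch)) {
  if (is.null(columns))
    columns <- grep("^biomarker_", names(cohort), value = TRUE)
  batch_dummies <- NULL
  if (batch_adjust) {
    if (is.null(cohort$batch)) stop_("batch_adjust = TRUE but no batch column")
    b <- factor(cohort$batch)
    if (nlevels(b) > 1L)
      batch_dummies <- stats::model.matrix(~ b)[, -1, drop = FALSE]
  }
  report <- data.frame(column = columns, n_outliers = NA_integer_,
                       log_applied = NA, batch_r2 = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    col <- columns[i]
    v <- remove_outliers(cohort[[col]], cutoff = outlier_cutoff)
    report$n_outliers[i] <- attr(v, "n_removed")
    v <- tryCatch(normalize_biomarker(as.numeric(v), skew_threshold),
                  error = function(e) stop_("column %s: %s", col, conditionMessage(e)))
    report$log_applied[i] <- attr(v, "log_applied")
    if (!is.null(batch_dummies)) {
      r <- residualize(as.numeric(v), batch_dummies)
      report$batch_r2[i] <- attr(r, "r_squared")
      v <- r
    } else report$batch_r2[i] <- 0
    # re-standardize so every biomarker enters the models on the same scale
    v <- as.numeric(v)
    cohort[[col]] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  list(cohort = cohort, report = report)
}
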