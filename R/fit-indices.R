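#' SEM fit indices
#'
#' Computes the usual absolute and incremental fit indices from a fitted
#' model and the independence (null) model on the same data:
#' `CMIN/DF = chi^2 / df`,
#' `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_0 - df_0, chi2_M - df_M, 0)`
#' (clipped to `[0, 1]`), and
#' `RMSEA = sqrt(max(chi2_M - df_M, 0) / (df_M (N - 1)))`.
#' When the model is saturated (`df = 0`), CFI and RMSEA are reported as
#' `NA` sentinels.
#'
#' @param model a [sem_fit()] result.
#' @param null_model optional independence-model fit (variances and means
#'   free, covariances zero) on the same data; computed automatically from
#'   the model's stored sample moments when omitted.
#' @return list with `chisq`, `df`, `pvalue`, `cmin_df`, `cfi`, `rmsea`,
#'   `null_chisq`, `null_df`.
#' @export
fit_indices <- function(model, null_model = NULL) {
  if (is.null(null_model)) null_model <- independence_fit(model)
  chisq <- model$chisq; df <- model$df
  chisq0 <- null_model$chisq; df0 <- null_model$df
  pvalue <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  if (df <= 0) {
    return(list(chisq = chisq, df = df, pvalue = pvalue,
                cmin_df = NA_real_, cfi = NA_real_, rmsea = NA_real_,
                null_chisq = chisq0, null_df = df0))
  }
  num <- max(chisq - df, 0)
  den <- max(chisq0 - df0, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (model$N - 1)))
  list(chisq = chisq, df = df, pvalue = pvalue,
       cmin_df = chisq / df, cfi = cfi, rmsea = rmsea,
       null_chisq = chisq0, null_df = df0)
}

# Independence model on the same data/moments as `model`.
independence_fit <- function(model) {
  p <- ncol(model$S)
  if (model$estimator == "fiml") {
    # chi^2_0 = 2 (ll_saturated - ll_independence); the independence
    # log-likelihood is separable per variable and stored by the engine.
    chisq0 <- model$null_chisq_fiml
    if (is.null(chisq0))
      stop_("independence model unavailable; pass null_model explicitly")
    df0 <- p * (p + 1) / 2 - p
    return(list(chisq = chisq0, df = df0))
  }
  S <- model$S
  F0 <- ml_discrepancy(S, diag(diag(S), p))
  list(chisq = (model$N - 1) * F0, df = p * (p + 1) / 2 - p)
}

#' Chi-square difference test for nested models
#'
#' @param constrained fit of the more restricted model.
#' @param unconstrained fit of the nesting model (same data).
#' @return list with `delta_chisq`, `delta_df`, `pvalue`.
#' @export
chi_square_difference <- function(constrained, unconstrained) {
  d_df <- constrained$df - unconstrained$df
  if (d_df < 0) stop_("models are not nested: delta df = %d", d_df)
  d_chisq <- constrained$chisq - unconstrained$chisq
  if (d_chisq < -1e-6)
    stop_("constrained chi-square below unconstrained beyond tolerance (%.3g)", d_chisq)
  d_chisq <- max(d_chisq, 0)
  if (d_df == 0) {
    # identical models (e.g. zero constraints): no test, p = 1
    if (d_chisq > 1e-6) stop_("models are not nested: delta df = 0 with delta chi-square > 0")
    return(list(delta_chisq = 0, delta_df = 0L, pvalue = 1))
  }
  list(delta_chisq = d_chisq, delta_df = d_df,
       pvalue = stats::pchisq(d_chisq, d_df, lower.tail = FALSE))
}
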