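# The latent dementia phenotype: bifactor delta/g' specification, factor
# scoring, Grice determinacy, and validation against severity and
# diagnosis.

#' Build the bifactor delta/g' specification
#'
#' All five indicators load on latent delta; the four cognitive indicators
#' additionally load on latent g'; the IADL (functional) indicator loads on
#' delta only, which is what ties delta to disability.  Both latent
#' variances are fixed to 1 and the factors are orthogonal (covariance
#' fixed to 0), so delta is the disability-sharing fraction of general
#' cognitive performance and g' is its residual.
#'
#' @param indicator_names exactly five indicator column names.
#' @param iadl which of them is the functional-status indicator.
#' @return a [sem_spec()] with 14 free parameters (5 delta loadings, 4 g'
#'   loadings, 5 residual variances); covariance-structure df = 1.
#' @export
build_deq_spec <- function(indicator_names = delta_indicators(),
                           iadl = "iadl") {
  indicator_names <- as.character(indicator_names)
  if (length(indicator_names) != 5L)
    stop_("exactly 5 indicator names required, got %d", length(indicator_names))
  if (!iadl %in% indicator_names)
    stop_("IADL indicator '%s' not among indicator names", iadl)
  cog <- setdiff(indicator_names, iadl)
  paths <- rbind(
    data.frame(from = "delta", to = indicator_names),
    data.frame(from = "gprime", to = cog))
  covs <- data.frame(
    v1 = c("delta", "gprime", "delta"),
    v2 = c("delta", "gprime", "gprime"),
    free = FALSE, value = c(1, 1, 0))
  sem_spec(observed = indicator_names, latent = c("delta", "gprime"),
           paths = paths, covariances = covs)
}

#' Fit the delta phenotype model
#'
#' Standardizes the indicators on the fitting sample, fits the bifactor
#' specification from [build_deq_spec()], and attaches regression-method
#' factor-score weights and Grice determinacies.
#'
#' @param data data frame containing the indicator columns.
#' @param indicators indicator names (see [delta_indicators()]).
#' @param iadl the functional-status indicator name.
#' @param estimator `"ml"` (complete cases) or `"fiml"`.
#' @param ... passed to [sem_fit()].
#' @return object of class `"delta_fit"`: the underlying [sem_fit()]
#'   (`$fit`), weights `$weights`, `$determinacy`, and the indicator
#'   centering/scaling used.
#' @export
fit_delta <- function(data, indicators = delta_indicators(), iadl = "iadl",
                      estimator = "ml", ...) {
  spec <- build_deq_spec(indicators, iadl)
  X <- data[indicators]
  cc <- stats::complete.cases(X)
  center <- vapply(X[cc, ], mean, 0)
  scale <- vapply(X[cc, ], stats::sd, 0)
  if (any(scale == 0)) stop_("constant indicator column")
  Xs <- as.data.frame(sweep(sweep(as.matrix(X), 2, center), 2, scale, `/`))
  fit <- sem_fit(spec, Xs, estimator = estimator, ...)
  W <- factor_score_weights(fit)
  attr(W, "center") <- center
  attr(W, "scale") <- scale
  structure(list(fit = fit, spec = spec, weights = W,
                 determinacy = factor_determinacy(fit),
                 indicators = indicators, center = center, scale = scale),
            class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat("Latent dementia phenotype fit (bifactor delta/g')\n")
  print(x$fit)
  cat(sprintf("  Grice determinacy: delta = %.3f, g' = %.3f\n",
              x$determinacy["delta"], x$determinacy["gprime"]))
  invisible(x)
}

#' @export
coef.delta_fit <- function(object, ...) coef(object$fit)

#' @export
predict.delta_fit <- function(object, newdata, ...) {
  composite_scores(object$weights, newdata, ...)
}

# Lambda (observed x latent) and Phi (latent covariance) at the estimates.
measurement_matrices <- function(fitted) {
  spec <- fitted$spec
  if (!length(spec$latent)) stop_("model has no latent variables")
  mats <- spec_matrices(spec, fitted$coefficients)
  k <- length(spec$vars)
  B <- solve(diag(k) - mats$A)
  C <- B %*% mats$S %*% t(B)
  obs <- seq_along(spec$observed)
  lat <- length(spec$observed) + seq_along(spec$latent)
  Lambda <- mats$A[obs, lat, drop = FALSE]
  Phi <- C[lat, lat, drop = FALSE]
  dimnames(Lambda) <- list(spec$observed, spec$latent)
  dimnames(Phi) <- list(spec$latent, spec$latent)
  list(Lambda = Lambda, Phi = Phi,
       Sigma = C[obs, obs, drop = FALSE])
}

#' Regression-method factor-score weights
#'
#' `W = Sigma^-1 Lambda Phi` over the indicators, deterministic given the
#' estimates.
#'
#' @param fitted a converged [sem_fit()] with latent variables.
#' @return weight matrix (indicators x factors).
#' @export
factor_score_weights <- function(fitted) {
  if (!fitted$converged) stop_("factor scores require a converged fit")
  mm <- measurement_matrices(fitted)
  Sinv <- tryCatch(solve(mm$Sigma), error = function(e)
    stop_("implied covariance is singular"))
  W <- Sinv %*% mm$Lambda %*% mm$Phi
  dimnames(W) <- list(rownames(mm$Lambda), colnames(mm$Lambda))
  W
}

#' Composite factor scores
#'
#' Applies factor-score weights to (standardized) observed indicators.
#' Rows with any missing indicator are scored missing (complete-case
#' scoring, which keeps the composites deterministic).  By default the g'
#' composite is orthogonalized against the delta composite - the empirical
#' realization of "g' is delta's residual in g" - which makes the two
#' score columns exactly uncorrelated and removes the delta contamination
#' that regression scoring of orthogonal factors otherwise introduces.
#'
#' @param W weight matrix from [factor_score_weights()] (with optional
#'   `center`/`scale` attributes recording the fitting sample's scale).
#' @param observed_table data frame containing the indicator columns.
#' @param orthogonalize_gprime residualize the `gprime` score on the
#'   `delta` score (default `TRUE` when both factors are present).
#' @return data frame of per-subject scores, one column per factor.
#' @export
composite_scores <- function(W, observed_table,
                             orthogonalize_gprime = TRUE) {
  ind <- rownames(W)
  miss <- setdiff(ind, names(observed_table))
  if (length(miss)) stop_("unknown indicator column(s): %s",
                          paste(miss, collapse = ", "))
  X <- as.matrix(observed_table[ind])
  storage.mode(X) <- "double"
  center <- attr(W, "center"); scale <- attr(W, "scale")
  if (!is.null(center)) X <- sweep(X, 2, center[ind])
  if (!is.null(scale)) X <- sweep(X, 2, scale[ind], `/`)
  cc <- stats::complete.cases(X)
  scores <- matrix(NA_real_, nrow(X), ncol(W),
                   dimnames = list(NULL, colnames(W)))
  scores[cc, ] <- X[cc, , drop = FALSE] %*% W
  scores <- as.data.frame(scores)
  if (orthogonalize_gprime && all(c("delta", "gprime") %in% names(scores))) {
    d <- scores$delta[cc]; g <- scores$gprime[cc]
    beta <- stats::cov(g, d) / stats::var(d)
    scores$gprime[cc] <- g - mean(g) - beta * (d - mean(d))
  }
  scores
}

#' Grice factor-score determinacy
#'
#' For factor j, `rho_j = (W' Lambda Phi)_jj / sqrt((W' Sigma W)_jj *
#' Phi_jj)`: the correlation between the estimated factor score and the
#' factor itself.  Values near 1 mean the composite is a faithful stand-in
#' for the latent variable.
#'
#' @param fitted a converged [sem_fit()] with latent variables.
#' @return named vector of determinacy coefficients in `[0, 1]`.
#' @export
factor_determinacy <- function(fitted) {
  W <- factor_score_weights(fitted)
  mm <- measurement_matrices(fitted)
  num <- diag(t(W) %*% mm$Lambda %*% mm$Phi)
  den <- sqrt(diag(t(W) %*% mm$Sigma %*% W) * diag(mm$Phi))
  rho <- ifelse(den > 0, num / den, 0)
  names(rho) <- colnames(mm$Lambda)
  pmin(pmax(rho, 0), 1)
}

#' AUC for discriminating a positive class by a composite score
#'
#' Area under the ROC curve by the Mann-Whitney identity (ties counted
#' one-half), with a Hanley-McNeil 95% confidence interval.  The AUC is
#' reported for the convention that the positive class takes *lower*
#' scores (dementia cases perform worse), i.e. it is
#' `P(score_case < score_control) + 0.5 P(tie)`.
#'
#' @param scores numeric scores (missing entries dropped with their labels).
#' @param labels class labels.
#' @param positive label of the positive (case) class.
#' @param negative label of the control class; defaults to all others.
#' @param direction `"less"` (default: cases score lower) or `"greater"`.
#' @return list with `auc`, `ci` (length 2), `se`, `n_case`, `n_control`.
#' @export
auc_roc <- function(scores, labels, positive = "AD", negative = NULL,
                    direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (!is.null(negative)) {
    keep <- labels %in% c(positive, negative)
    scores <- scores[keep]; labels <- labels[keep]
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  case <- labels == positive
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L) stop_("both classes must be non-empty")
  r <- rank(scores)
  # P(score_case > score_control) + 0.5 ties, then flip for "less"
  auc_gt <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- if (direction == "less") 1 - auc_gt else auc_gt
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  list(auc = auc, ci = ci, se = se, n_case = n1, n_control = n0)
}

#' Criterion validation against dementia severity
#'
#' Pearson correlation of the phenotype composite with CDR sum of boxes.
#' Higher composites mean better performance, so on well-behaved data the
#' correlation with severity is negative.
#'
#' @param scores phenotype composite scores.
#' @param cdr CDR sum-of-boxes values.
#' @return list with `r`, `p`, `n`.
#' @export
validate_vs_severity <- function(scores, cdr) {
  ok <- !is.na(scores) & !is.na(cdr)
  if (sum(ok) < 3L) stop_("need at least 3 complete pairs")
  ct <- stats::cor.test(scores[ok], cdr[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
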