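# Full-information maximum likelihood for incomplete multivariate-normal
# data: casewise likelihood accumulated over missingness patterns.

# Group rows of X (matrix over observed vars) by missingness pattern.
missing_patterns <- function(X) {
  obs_mask <- !is.na(X)
  if (any(rowSums(obs_mask) == 0L))
    stop_("rows with no observed variables are not admissible under FIML")
  key <- apply(obs_mask, 1, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(X)), key)
  lapply(idx, function(rows) {
    o <- which(obs_mask[rows[1], ])
    list(cols = o, X = X[rows, o, drop = FALSE], n = length(rows))
  })
}

pattern_loglik <- function(patterns, Sigma, mu, varnames = NULL) {
  ll <- 0
  for (p in patterns) {
    o <- p$cols
    So <- Sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(R)) {
      nm <- if (!is.null(varnames)) paste(varnames[o], collapse = ",") else
        paste(o, collapse = ",")
      stop_("implied sub-covariance singular for pattern {%s}", nm)
    }
    Xc <- sweep(p$X, 2, mu[o], `-`)
    Q <- backsolve(R, t(Xc), transpose = TRUE)
    ll <- ll - 0.5 * (p$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(R)))) +
                        sum(Q^2))
  }
  ll
}

#' Full-information log-likelihood of a model on incomplete data
#'
#' Sums, over the data's missingness patterns, the multivariate-normal
#' log-likelihood of each pattern's observed sub-vector under the implied
#' mean and covariance marginalized to that pattern.
#'
#' @param spec a [sem_spec()]; if it declares no mean structure the implied
#'   means are taken as zero.
#' @param params named parameter vector.
#' @param data data frame with (possibly) missing entries; every row must
#'   observe at least one model variable.
#' @return scalar log-likelihood.
#' @export
fiml_loglik <- function(spec, params, data) {
  obs <- spec$observed
  X <- as.matrix(data[obs]); storage.mode(X) <- "double"
  mom <- implied_moments(spec, params)
  mu <- mom$mu %||% rep(0, length(obs))
  pattern_loglik(missing_patterns(X), mom$Sigma, mu, obs)
}

# Saturated multivariate-normal fit to incomplete data by EM.
# Returns mu, Sigma (ML, divisor N) and the maximized log-likelihood.
mvn_em <- function(X, max_iter = 500L, tol = 1e-9) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (!anyNA(X)) {
    mu <- colMeans(X)
    Sigma <- cov_ml(X)
    patterns <- missing_patterns(X)
    return(list(mu = mu, Sigma = Sigma,
                loglik = pattern_loglik(patterns, Sigma, mu)))
  }
  patterns <- missing_patterns(X)
  mu <- vapply(seq_len(p), function(j) mean(X[, j], na.rm = TRUE), 0)
  v <- vapply(seq_len(p), function(j) stats::var(X[, j], na.rm = TRUE), 0)
  Sigma <- diag(pmax(v, 1e-6), p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (pt in patterns) {
      o <- pt$cols; m <- setdiff(seq_len(p), o)
      Xo <- pt$X
      if (!length(m)) {
        T1 <- T1; T1[o] <- T1[o] + colSums(Xo)
        T2[o, o] <- T2[o, o] + crossprod(Xo)
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      K <- solve(Soo, Sigma[o, m, drop = FALSE])        # |o| x |m|
      Xm_hat <- sweep(sweep(Xo, 2, mu[o], `-`) %*% K, 2, mu[m], `+`)
      Cmm <- Sigma[m, m, drop = FALSE] - Sigma[m, o, drop = FALSE] %*% K
      T1[o] <- T1[o] + colSums(Xo)
      T1[m] <- T1[m] + colSums(Xm_hat)
      cross <- crossprod(Xo, Xm_hat)
      T2[o, o] <- T2[o, o] + crossprod(Xo)
      T2[o, m] <- T2[o, m] + cross
      T2[m, o] <- T2[m, o] + t(cross)
      T2[m, m] <- T2[m, m] + crossprod(Xm_hat) + pt$n * Cmm
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- pattern_loglik(patterns, Sigma, mu)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll)
}

# Independence-model log-likelihood on incomplete data (free means and
# variances, zero covariances): separable per variable.
independence_loglik <- function(X) {
  sum(vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; x <- x[!is.na(x)]
    m <- mean(x); s2 <- mean((x - m)^2)
    -0.5 * length(x) * (log(2 * pi * s2) + 1)
  }, 0))
}

# FIML estimation engine, called from sem_fit(estimator = "fiml").
fit_fiml_engine <- function(spec, data, start, se, restarts, gtol) {
  obs <- spec$observed
  miss <- setdiff(obs, names(data))
  if (length(miss)) stop_("data lacks column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(data[obs]); storage.mode(X) <- "double"
  keep <- rowSums(!is.na(X)) > 0L
  X <- X[keep, , drop = FALSE]
  all_missing <- obs[colSums(!is.na(X)) == 0L]
  if (length(all_missing))
    stop_("variable(s) with no observed values under FIML: %s",
          paste(all_missing, collapse = ", "))
  N <- nrow(X)

  if (is.null(spec$means)) {
    spec <- sem_spec(spec$observed, spec$latent, spec$paths,
                     spec$covariances, auto_var = FALSE,
                     means = data.frame(var = obs, free = TRUE,
                                        value = NA_real_, label = NA_character_))
  }
  labs <- free_labels(spec)
  nfree <- length(labs)
  if (N <= nfree) stop_("N = %d too small for %d free parameters", N, nfree)

  patterns <- missing_patterns(X)
  neg_ll <- function(theta) {
    params <- stats::setNames(theta, labs)
    mom <- tryCatch(implied_moments(spec, params), error = function(e) NULL)
    if (is.null(mom)) return(1e10)
    ll <- tryCatch(pattern_loglik(patterns, mom$Sigma, mom$mu, obs),
                   error = function(e) NULL)
    if (is.null(ll) || !is.finite(ll)) return(1e10)
    -ll
  }
  gr <- function(theta) numeric_gradient(neg_ll, theta)

  cc <- X[stats::complete.cases(X), , drop = FALSE]
  S0 <- if (nrow(cc) > ncol(X) + 2) cov_ml(cc) else {
    v <- vapply(seq_len(ncol(X)), function(j) stats::var(X[, j], na.rm = TRUE), 0)
    diag(pmax(v, 1e-6), ncol(X), dimnames = list(obs, obs))
  }
  dimnames(S0) <- list(obs, obs)
  mns <- vapply(seq_len(ncol(X)), function(j) mean(X[, j], na.rm = TRUE), 0)
  names(mns) <- obs
  theta0 <- start %||% start_values(spec, S0, means = mns)
  theta0 <- theta0[labs]

  lower <- variance_bounds(spec, S0)
  res <- optimize_with_restarts(neg_ll, gr, theta0, restarts, gtol,
                                lower = lower[labs])

  sat <- mvn_em(X)
  ll_model <- -res$value
  chisq <- max(2 * (sat$loglik - ll_model), 0)
  p <- length(obs)
  df <- p * (p + 1) / 2 + p - nfree
  out <- build_fit(spec, res, se = se, N = N, estimator = "fiml",
                   S = sat$Sigma, means = sat$mu, F_min = NULL,
                   chisq = chisq, df = df, info_scale = 1, fn = neg_ll,
                   logLik = ll_model, ll_sat = sat$loglik,
                   n_patterns = length(patterns))
  out$null_chisq_fiml <- max(2 * (sat$loglik - independence_loglik(X)), 0)
  out
}
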