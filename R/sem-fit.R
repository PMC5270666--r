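#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The classical ML fitting function
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, which is zero iff
#' `S == Sigma` and positive otherwise.
#'
#' @param S sample covariance matrix (positive definite).
#' @param Sigma model-implied covariance matrix (positive definite).
#' @param p dimension; defaults to `ncol(S)`.
#' @return scalar discrepancy, `>= 0`.
#' @export
ml_discrepancy <- function(S, Sigma, p = ncol(S)) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  if (!all(dim(S) == dim(Sigma))) stop_("S and Sigma differ in dimension")
  R <- tryCatch(chol(Sigma), error = function(e)
    stop_("Sigma is not positive definite"))
  ld_Sigma <- 2 * sum(log(diag(R)))
  ld_S <- tryCatch(log_det_chol(S), error = function(e)
    stop_("S is not positive definite"))
  tr <- sum(diag(chol2inv(R) %*% S))
  max(ld_Sigma + tr - ld_S - p, 0)
}

# Analytic gradient of F_ML with respect to the free parameters.
# dF = tr[W dSigma], W = Sigma^-1 (Sigma - S) Sigma^-1;
# for RAM matrices: G_A = 2 B' Wf C,  G_S = B' Wf B (off-diagonals doubled),
# with B = (I-A)^-1, C = B S_full B', Wf = W padded to the full registry.
ml_gradient <- function(spec, theta, S) {
  params <- stats::setNames(theta, free_labels(spec))
  mom <- implied_moments(spec, params)
  Sigma <- mom$Sigma
  Sinv <- chol2inv(chol(Sigma))
  W <- Sinv - Sinv %*% S %*% Sinv
  k <- length(spec$vars)
  obs <- seq_along(spec$observed)
  Wf <- matrix(0, k, k)
  Wf[obs, obs] <- W
  B <- mom$B
  Cfull <- B %*% mom$mats$S %*% t(B)
  GA <- 2 * t(B) %*% Wf %*% Cfull
  GS <- t(B) %*% Wf %*% B
  grad_from_matrices(spec, GA, GS)
}

grad_from_matrices <- function(spec, GA, GS) {
  vars <- spec$vars
  labs <- free_labels(spec)
  g <- stats::setNames(numeric(length(labs)), labs)
  pt <- spec$paths[spec$paths$free, , drop = FALSE]
  if (nrow(pt)) {
    vals <- GA[cbind(match(pt$to, vars), match(pt$from, vars))]
    for (r in seq_len(nrow(pt))) g[pt$label[r]] <- g[pt$label[r]] + vals[r]
  }
  ct <- spec$covariances[spec$covariances$free, , drop = FALSE]
  if (nrow(ct)) {
    i <- match(ct$v1, vars); j <- match(ct$v2, vars)
    vals <- ifelse(i == j, GS[cbind(i, j)], 2 * GS[cbind(i, j)])
    for (r in seq_len(nrow(ct))) g[ct$label[r]] <- g[ct$label[r]] + vals[r]
  }
  g
}

# Start values: OLS for observed-variable regressions, modest positive
# loadings, half the sample variance for residuals, sample covariances for
# exogenous blocks.  Deterministic.
start_values <- function(spec, S, means = NULL) {
  vars <- spec$vars
  labs <- free_labels(spec)
  theta <- stats::setNames(rep(NA_real_, length(labs)), labs)
  obs <- spec$observed
  sv <- function(v) if (v %in% obs) S[v, v] else 1

  pt <- spec$paths
  endo <- unique(pt$to)
  for (y in endo) {
    rows <- which(pt$to == y & pt$free)
    if (!length(rows)) next
    parents <- pt$from[pt$to == y]
    obs_par <- intersect(parents, obs)
    beta <- NULL
    if (y %in% obs && length(obs_par)) {
      beta <- tryCatch(
        drop(solve(S[obs_par, obs_par, drop = FALSE], S[obs_par, y])),
        error = function(e) NULL)
      if (!is.null(beta)) names(beta) <- obs_par
    }
    for (r in rows) {
      from <- pt$from[r]
      val <- if (!is.null(beta) && from %in% names(beta)) beta[[from]] else {
        # loading start: first-declared latent gets the larger share so that
        # multi-factor (e.g. bifactor) starts are not symmetric
        tier <- match(from, spec$latent)
        mag <- if (is.na(tier)) 0.4 else c(0.7, 0.35, 0.25)[min(tier, 3)]
        mag * sqrt(max(sv(if (pt$to[r] %in% obs) pt$to[r] else from), 1e-6))
      }
      if (is.na(theta[pt$label[r]])) theta[pt$label[r]] <- val
    }
  }
  ct <- spec$covariances
  for (r in which(ct$free)) {
    lab <- ct$label[r]
    if (!is.na(theta[lab])) next
    v1 <- ct$v1[r]; v2 <- ct$v2[r]
    if (v1 == v2) {
      has_parent <- v1 %in% pt$to
      theta[lab] <- if (has_parent) 0.5 * sv(v1) else sv(v1)
      if (!(v1 %in% obs)) theta[lab] <- if (has_parent) 0.5 else 1
    } else {
      theta[lab] <- if (v1 %in% obs && v2 %in% obs) S[v1, v2] else 0
    }
  }
  if (!is.null(spec$means)) {
    mt <- spec$means
    for (r in which(mt$free)) {
      lab <- mt$label[r]
      if (is.na(theta[lab]))
        theta[lab] <- if (!is.null(means) && mt$var[r] %in% names(means))
          means[[mt$var[r]]] else 0
    }
  }
  theta[is.na(theta)] <- 0.1
  theta
}

#' Fit a structural equation model
#'
#' Estimates the free parameters of a [sem_spec()] by minimizing the ML
#' discrepancy between the sample and implied covariance matrices
#' (`estimator = "ml"`, complete cases) or by maximizing the
#' full-information likelihood over missingness patterns
#' (`estimator = "fiml"`, which also estimates a mean structure).
#' Optimization is quasi-Newton (BFGS with analytic gradients under ML)
#' followed by Newton polishing steps; on non-convergence up to
#' `restarts` deterministically jittered restarts are attempted and the
#' result is flagged, never silently accepted.
#'
#' The test statistic uses the `chi^2 = (N - 1) * F_min` convention (with
#' the sample covariance computed with divisor `N`); standard errors come
#' from the inverse observed information (numeric Hessian).  Negative
#' estimated residual variances (Heywood cases) are reported and recorded
#' in `$warnings`.
#'
#' @param spec a [sem_spec()].
#' @param data data frame containing the observed variables.
#' @param estimator `"ml"` (complete cases) or `"fiml"`.
#' @param sample_cov optionally, a covariance matrix in place of `data`
#'   (ML only); `sample_n` must then give the sample size.
#' @param sample_n sample size accompanying `sample_cov`.
#' @param start optional named start vector.
#' @param se compute standard errors (default `TRUE`).
#' @param restarts maximum jittered restarts on non-convergence.
#' @param gtol gradient-norm convergence tolerance.
#' @return An object of class `"sem_fit"`: coefficients, standard errors,
#'   `chisq`/`df`/`pvalue`, `F_min` or `logLik`, convergence flag and
#'   gradient norm, plus the sample moments used.
#' @export
sem_fit <- function(spec, data = NULL, estimator = c("ml", "fiml"),
                    sample_cov = NULL, sample_n = NULL, start = NULL,
                    se = TRUE, restarts = 5L, gtol = 1e-5) {
  estimator <- match.arg(estimator)
  if (estimator == "fiml") return(fit_fiml_engine(spec, data, start, se, restarts, gtol))
  obs <- spec$observed
  if (!is.null(data)) {
    miss <- setdiff(obs, names(data))
    if (length(miss)) stop_("data lacks column(s): %s", paste(miss, collapse = ", "))
    X <- as.matrix(data[obs])
    storage.mode(X) <- "double"
    X <- X[stats::complete.cases(X), , drop = FALSE]
    N <- nrow(X)
    S <- cov_ml(X)
  } else {
    if (is.null(sample_cov) || is.null(sample_n))
      stop_("either data or sample_cov + sample_n must be supplied")
    S <- as.matrix(sample_cov)[obs, obs]
    N <- sample_n
  }
  nfree <- length(free_labels(spec))
  if (N <= nfree) stop_("N = %d too small for %d free parameters", N, nfree)

  fn <- function(theta) {
    params <- stats::setNames(theta, free_labels(spec))
    Sigma <- tryCatch(implied_covariance(spec, params), error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ld <- 2 * sum(log(diag(R)))
    ld + sum(chol2inv(R) * S) - log_det_chol(S) - length(obs)
  }
  gr <- function(theta) ml_gradient(spec, theta, S)

  theta0 <- start %||% start_values(spec, S)
  theta0 <- theta0[free_labels(spec)]
  res <- optimize_with_restarts(fn, gr, theta0, restarts, gtol,
                                lower = variance_bounds(spec, S))

  p <- length(obs)
  F_min <- max(res$value, 0)
  df <- p * (p + 1) / 2 - nfree
  chisq <- max((N - 1) * F_min, 0)
  out <- build_fit(spec, res, se = se, N = N, estimator = "ml",
                   S = S, means = NULL, F_min = F_min,
                   chisq = chisq, df = df,
                   info_scale = (N - 1) / 2, fn = fn, gr = gr)
  out
}

# Lower bounds for the optimizer: observed-variable variance parameters are
# kept above -0.05 * S_vv (mild Heywood estimates remain reportable, the
# unbounded bifactor-collapse ridge is excluded); all else unbounded.
variance_bounds <- function(spec, S) {
  labs <- free_labels(spec)
  lower <- stats::setNames(rep(-Inf, length(labs)), labs)
  ct <- spec$covariances
  rows <- which(ct$free & ct$v1 == ct$v2 & ct$v1 %in% spec$observed)
  for (r in rows) {
    b <- -0.05 * S[ct$v1[r], ct$v1[r]]
    lower[ct$label[r]] <- max(lower[ct$label[r]], b, na.rm = FALSE)
    if (!is.finite(lower[ct$label[r]])) lower[ct$label[r]] <- b
  }
  lower
}

optimize_with_restarts <- function(fn, gr, theta0, restarts, gtol,
                                   lower = rep(-Inf, length(theta0))) {
  jitters <- c(0, 0.2, -0.25, 0.45, -0.5, 0.7)  # deterministic restart schedule
  alt <- rep_len(c(1, -0.6, 0.8, -1, 0.5), length(theta0))
  lower <- unname(lower)
  best <- NULL
  for (r in seq_len(min(restarts + 1L, length(jitters)))) {
    th <- theta0 * (1 + jitters[r] * alt) + jitters[r] * 0.05 * alt
    th <- pmax(th, lower + 0.01 * is.finite(lower))
    if (fn(th) >= 1e10) next
    opt <- tryCatch(
      stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 2000, factr = 10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    cand <- newton_polish(fn, gr, opt$par, gtol, lower)
    if (is.null(best) || cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) < 1e-10 && cand$gnorm < best$gnorm))
      best <- cand
    if (best$converged) break
  }
  if (is.null(best)) stop_("optimization could not start: infeasible start values")
  best$at_bound <- is.finite(lower) & best$par <= lower + 1e-8
  best
}

# Up to 8 damped Newton steps using a finite-difference Jacobian of the
# gradient, restricted to coordinates away from their bounds; declares
# convergence when the projected gradient norm is below
# gtol * max(1, |F| + 1).
newton_polish <- function(fn, gr, theta, gtol, lower = rep(-Inf, length(theta))) {
  proj_gnorm <- function(theta, g) {
    at <- is.finite(lower) & theta <= lower + 1e-8 & g > 0
    if (all(at)) 0 else max(abs(g[!at]))
  }
  f <- fn(theta); g <- gr(theta)
  for (it in 1:8) {
    if (proj_gnorm(theta, g) < gtol * max(1, abs(f) + 1)) break
    act <- is.finite(lower) & theta <= lower + 1e-8 & g > 0
    idx <- which(!act)
    gr_sub <- function(t_sub) { tt <- theta; tt[idx] <- t_sub; gr(tt)[idx] }
    H <- jacobian_fd(gr_sub, theta[idx])
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H + diag(1e-8, length(idx)), g[idx]),
                     error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1, 0.01)) {
      cand <- theta
      cand[idx] <- cand[idx] - damp * step
      cand <- pmax(cand, lower)
      fc <- fn(cand)
      if (fc < f + 1e-12) { theta <- cand; f <- fc; g <- gr(theta); ok <- TRUE; break }
    }
    if (!ok) break
  }
  gnorm <- proj_gnorm(theta, g)
  list(par = theta, value = f, gnorm = gnorm,
       converged = gnorm < gtol * max(1, abs(f) + 1))
}

jacobian_fd <- function(gr, theta, eps = 1e-6) {
  m <- length(theta)
  J <- matrix(0, m, m)
  for (i in seq_len(m)) {
    h <- eps * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  J
}

numeric_gradient <- function(fn, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    h <- eps * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    g[i] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  g
}

# Shared post-processing: SEs, Heywood screen, object assembly.
build_fit <- function(spec, res, se, N, estimator, S, means, F_min,
                      chisq, df, info_scale, fn, gr = NULL, logLik = NULL,
                      ll_sat = NULL, n_patterns = NULL) {
  labs <- free_labels(spec)
  est <- stats::setNames(res$par, labs)
  warnings <- character()
  vt <- spec$covariances[spec$covariances$free &
                           spec$covariances$v1 == spec$covariances$v2, ]
  neg <- vt$label[est[vt$label] < 0]
  if (length(neg))
    warnings <- c(warnings, sprintf(
      "Heywood case: negative variance estimate for %s", paste(neg, collapse = ", ")))
  if (any(res$at_bound %||% FALSE))
    warnings <- c(warnings, sprintf(
      "estimate(s) at variance lower bound: %s",
      paste(labs[res$at_bound], collapse = ", ")))

  se_vec <- rep(NA_real_, length(labs)); names(se_vec) <- labs
  vc <- NULL
  if (se) {
    H <- tryCatch(
      if (!is.null(gr)) jacobian_fd(gr, res$par) else stats::optimHess(res$par, fn),
      error = function(e) NULL)
    if (!is.null(H)) {
      info <- info_scale * (H + t(H)) / 2
      vc <- tryCatch(solve(info), error = function(e) NULL)
      if (is.null(vc)) {
        vc <- tryCatch(solve(info + diag(1e-8, nrow(info))), error = function(e) NULL)
        if (!is.null(vc)) warnings <- c(warnings, "information matrix near-singular; SEs ridge-stabilized")
      }
      if (!is.null(vc)) {
        d <- diag(vc)
        se_vec[d > 0] <- sqrt(d[d > 0])
        dimnames(vc) <- list(labs, labs)
      }
    }
  }
  structure(list(
    spec = spec, estimator = estimator, coefficients = est, se = se_vec,
    vcov = vc, N = N, F_min = F_min, logLik = logLik, ll_saturated = ll_sat,
    chisq = chisq, df = df,
    pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    converged = res$converged, gradient_norm = res$gnorm,
    S = S, sample_means = means, n_patterns = n_patterns,
    warnings = warnings), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("SEM fit (%s), N = %d, %sconverged\n", toupper(x$estimator),
              x$N, if (x$converged) "" else "NOT "))
  cat(sprintf("  chi-square = %.3f, df = %d%s\n", x$chisq, x$df,
              if (!is.na(x$pvalue)) sprintf(", p = %.4g", x$pvalue) else ""))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  tab <- parameter_table(object)
  out <- list(fit = object, table = tab, indices = tryCatch(
    fit_indices(object), error = function(e) NULL))
  class(out) <- "summary.sem_fit"
  out
}

#' @export
print.summary.sem_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$indices))
    cat(sprintf("  CMIN/DF = %.3f, CFI = %.3f, RMSEA = %.3f\n",
                x$indices$cmin_df, x$indices$cfi, x$indices$rmsea))
  cat("\nParameters:\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' @param fitted a [sem_fit()] result.
#' @return data frame with columns `parameter`, `estimate`, `se`, `z`, `p`.
#' @export
parameter_table <- function(fitted) {
  est <- fitted$coefficients
  se <- fitted$se[names(est)]
  z <- est / se
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))), stringsAsFactors = FALSE)
}

#' Export fitted parameters to CSV
#' @param fitted a [sem_fit()] result.
#' @param path output CSV path.
#' @return invisibly, the exported table.
#' @export
export_parameters <- function(fitted, path) {
  tab <- parameter_table(fitted)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @export
coef.sem_fit <- function(object, ...) object$coefficients

#' @export
vcov.sem_fit <- function(object, ...) object$vcov

#' @export
logLik.sem_fit <- function(object, ...) {
  ll <- object$logLik
  if (is.null(ll)) {
    # complete-data multivariate-normal log-likelihood at the ML solution
    mom <- implied_moments(object$spec, object$coefficients)
    p <- length(object$spec$observed)
    R <- chol(mom$Sigma)
    ll <- -0.5 * object$N * (p * log(2 * pi) + 2 * sum(log(diag(R))) +
                               sum(chol2inv(R) * object$S))
  }
  structure(ll, df = length(object$coefficients), class = "logLik")
}

#' @export
fitted.sem_fit <- function(object, ...) {
  implied_covariance(object$spec, object$coefficients)
}

#' @export
residuals.sem_fit <- function(object, ...) {
  object$S - fitted(object)
}

#' @export
simulate.sem_fit <- function(object, nsim = 1, seed = NULL, n = object$N, ...) {
  mom <- implied_moments(object$spec, object$coefficients)
  mu <- mom$mu %||% object$sample_means %||% rep(0, length(object$spec$observed))
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      Z <- matrix(stats::rnorm(n * nrow(mom$Sigma)), n)
      X <- Z %*% chol(mom$Sigma)
      X <- sweep(X, 2, mu, `+`)
      colnames(X) <- object$spec$observed
      as.data.frame(X)
    })
  })
}

#' @export
plot.sem_fit <- function(x, ...) {
  R <- residuals(x)
  d <- sqrt(diag(x$S))
  Rc <- R / tcrossprod(d)
  graphics::image(seq_len(ncol(Rc)), seq_len(ncol(Rc)), t(Rc[rev(seq_len(nrow(Rc))), ]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Residual correlations (sample - implied)", ...)
  graphics::axis(1, seq_len(ncol(Rc)), colnames(x$S), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(Rc)), rev(colnames(x$S)), las = 2, cex.axis = 0.7)
  invisible(x)
}
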