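# Split-half generalizability: random halves, simultaneous two-group
# fitting with equality constraints on named paths, and the chi-square
# degradation test.

#' Random split of a cohort into two halves
#'
#' Disjoint, exhaustive halves whose sizes differ by at most one; seeded
#' and reproducible.
#'
#' @param cohort data frame.
#' @param seed RNG seed.
#' @return list with `half_A`, `half_B`.
#' @export
random_split <- function(cohort, seed = 1L) {
  n <- nrow(cohort)
  if (n < 4L) stop_("need at least 4 rows to split")
  with_seed(seed, {
    idx <- sample.int(n)
    nA <- ceiling(n / 2)
    list(half_A = cohort[sort(idx[seq_len(nA)]), , drop = FALSE],
         half_B = cohort[sort(idx[(nA + 1):n]), , drop = FALSE])
  })
}

# Relabel a spec's free parameters with a group prefix, except those in
# `shared` (which remain equality-constrained across groups).
prefix_spec <- function(spec, prefix, shared) {
  relab <- function(df) {
    if (is.null(df)) return(NULL)
    free <- df$free & !(df$label %in% shared)
    df$label[free] <- paste0(prefix, df$label[free])
    df
  }
  sem_spec(spec$observed, spec$latent, relab(spec$paths),
           relab(spec$covariances), auto_var = FALSE, means = relab(spec$means))
}

#' Simultaneous multi-group ML fit
#'
#' Fits the same specification in each group, minimizing
#' `sum_g (N_g - 1) F_g`; parameters whose labels appear in `constrain`
#' are shared across groups, all others are group-specific.  The joint
#' chi-square is `sum_g (N_g - 1) F_g` at the optimum.
#'
#' @param spec a [sem_spec()].
#' @param data_list list of data frames, one per group.
#' @param constrain labels of parameters equated across groups.
#' @param se compute standard errors.
#' @param gtol gradient tolerance.
#' @return object of class `"sem_fit"` (multi-group flavour): shared
#'   parameters keep their labels, group-specific ones carry a `g<i>.`
#'   prefix.
#' @export
sem_fit_groups <- function(spec, data_list, constrain = character(),
                           se = TRUE, gtol = 1e-5) {
  G <- length(data_list)
  stopifnot(G >= 2L)
  bad <- setdiff(constrain, free_labels(spec))
  if (length(bad)) stop_("constraint on unknown parameter(s): %s",
                         paste(bad, collapse = ", "))
  obs <- spec$observed
  specs <- lapply(seq_len(G), function(g)
    prefix_spec(spec, sprintf("g%d.", g), constrain))
  Ss <- list(); Ns <- numeric(G)
  for (g in seq_len(G)) {
    X <- as.matrix(data_list[[g]][obs]); storage.mode(X) <- "double"
    X <- X[stats::complete.cases(X), , drop = FALSE]
    Ns[g] <- nrow(X)
    Ss[[g]] <- cov_ml(X)
  }
  labs <- unique(unlist(lapply(specs, free_labels)))
  fn <- function(theta) {
    params <- stats::setNames(theta, labs)
    tot <- 0
    for (g in seq_len(G)) {
      Sigma <- tryCatch(implied_covariance(specs[[g]], params),
                        error = function(e) NULL)
      if (is.null(Sigma)) return(1e10)
      R <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      tot <- tot + (Ns[g] - 1) *
        (2 * sum(log(diag(R))) + sum(chol2inv(R) * Ss[[g]]) -
           log_det_chol(Ss[[g]]) - length(obs))
    }
    tot
  }
  gr <- function(theta) {
    g_out <- stats::setNames(numeric(length(labs)), labs)
    for (g in seq_len(G)) {
      gl <- free_labels(specs[[g]])
      gg <- ml_gradient(specs[[g]], stats::setNames(theta, labs)[gl], Ss[[g]])
      g_out[gl] <- g_out[gl] + (Ns[g] - 1) * gg
    }
    unname(g_out)
  }
  theta0 <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (g in seq_len(G)) {
    st <- start_values(specs[[g]], Ss[[g]])
    fill <- is.na(theta0[names(st)])
    theta0[names(st)][fill] <- st[fill]
  }
  lower <- stats::setNames(rep(-Inf, length(labs)), labs)
  for (g in seq_len(G)) {
    lb <- variance_bounds(specs[[g]], Ss[[g]])
    lower[names(lb)] <- pmax(lower[names(lb)], lb)
  }
  res <- optimize_with_restarts(fn, gr, unname(theta0), gtol = gtol,
                                restarts = 5L, lower = unname(lower[labs]))
  names(res$par) <- labs
  p <- length(obs)
  df <- G * p * (p + 1) / 2 - length(labs)
  chisq <- max(res$value, 0)
  sev <- rep(NA_real_, length(labs)); names(sev) <- labs
  vc <- NULL
  if (se) {
    H <- tryCatch(jacobian_fd(gr, unname(res$par)), error = function(e) NULL)
    if (!is.null(H)) {
      # information for the joint objective sum (N_g - 1) F_g is H / 2
      vc <- tryCatch(solve((H + t(H)) / 4), error = function(e) NULL)
      if (!is.null(vc)) {
        d <- diag(vc)
        sev[d > 0] <- sqrt(d[d > 0])
        dimnames(vc) <- list(labs, labs)
      }
    }
  }
  structure(list(
    spec = spec, estimator = "ml", coefficients = res$par, se = sev,
    vcov = vc, N = sum(Ns), F_min = res$value, logLik = NULL,
    chisq = chisq, df = df,
    pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    converged = res$converged, gradient_norm = res$gnorm,
    S = Ss, sample_means = NULL,
    groups = list(specs = specs, Ns = Ns, labels = labs,
                  constrained = constrain),
    warnings = character()), class = "sem_fit")
}

#' Constrained vs unconstrained two-group comparison
#'
#' Fits the spec simultaneously in the two halves twice - once with the
#' named paths equated across halves, once without - and tests the fit
#' degradation by [chi_square_difference()].  When the constrained model
#' carries the mediation path labels (`path_a`, `path_b`, `path_c`), the
#' mediation effect is recomputed from the constrained estimates.
#'
#' @param spec a [sem_spec()].
#' @param half_A,half_B data frames (see [random_split()]).
#' @param paths_to_constrain labels of the paths to equate.
#' @return list: `delta_chisq`, `delta_df`, `pvalue`,
#'   `constrained`/`unconstrained` fits, a per-path `estimates` table
#'   (estimate in each half and under the constraint), and `mediation`
#'   (recomputed from constrained estimates when applicable).
#' @export
constrained_comparison <- function(spec, half_A, half_B,
                                   paths_to_constrain) {
  halves <- list(half_A, half_B)
  unc <- sem_fit_groups(spec, halves, constrain = character(), se = TRUE)
  if (!length(paths_to_constrain)) {
    return(list(delta_chisq = 0, delta_df = 0, pvalue = 1,
                constrained = unc, unconstrained = unc,
                estimates = NULL, mediation = NULL))
  }
  con <- sem_fit_groups(spec, halves, constrain = paths_to_constrain,
                        se = TRUE)
  dtest <- chi_square_difference(con, unc)
  est <- data.frame(
    path = paths_to_constrain,
    estimate_A = unname(coef(unc)[paste0("g1.", paths_to_constrain)]),
    estimate_B = unname(coef(unc)[paste0("g2.", paths_to_constrain)]),
    constrained_estimate = unname(coef(con)[paths_to_constrain]),
    stringsAsFactors = FALSE)
  med <- NULL
  needed <- c("path_a", "path_b", "path_c")
  if (all(needed %in% paths_to_constrain)) {
    cf <- coef(con); sev <- con$se
    med <- mediation_effect(cf[["path_a"]], cf[["path_c"]], cf[["path_b"]],
                            sev[["path_c"]], sev[["path_b"]])
  }
  c(dtest, list(constrained = con, unconstrained = unc,
                estimates = est, mediation = med))
}
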