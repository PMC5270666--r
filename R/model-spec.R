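#' Define a structural equation model
#'
#' Builds a model specification in the reticular-action (RAM) form used by
#' the estimation engine: a matrix of directed paths `A` (loadings and
#' structural regressions), a symmetric matrix `S` of variances and
#' covariances (latent disturbances and observed residuals), and an optional
#' mean structure.  The implied covariance over the observed registry is
#' `F (I - A)^-1 S (I - A)^-T F'`.
#'
#' Free parameters are identified by label; entries sharing a label are
#' constrained equal (this is how cross-group equality constraints are
#' expressed).  Every latent variable must carry a scale constraint: either
#' its variance fixed (typically to 1) or one of its loadings fixed.
#'
#' @param observed character vector of observed-variable names.
#' @param latent character vector of latent-variable names (may be empty).
#' @param paths data frame with columns `from`, `to` and optionally `free`
#'   (default `TRUE`), `value` (fixed value, or start value for free
#'   parameters) and `label`.  A path `from -> to` is a loading when `from`
#'   is latent and a regression otherwise.
#' @param covariances data frame with columns `v1`, `v2` and optionally
#'   `free`, `value`, `label`, declaring (co)variance elements of `S`.
#'   Variances are rows with `v1 == v2`.
#' @param auto_var add a free variance for every variable that has none
#'   declared (default `TRUE`).
#' @param means optional data frame with columns `var` and optionally
#'   `free`, `value`, `label`; when omitted, a saturated mean structure is
#'   generated automatically if the model is fit by FIML.
#'
#' @return An object of class `"sem_spec"`.
#' @seealso [sem_fit()], [implied_covariance()], [spec_to_json()]
#' @export
sem_spec <- function(observed, latent = character(), paths = NULL,
                     covariances = NULL, auto_var = TRUE, means = NULL) {
  observed <- as.character(observed)
  latent <- as.character(latent)
  if (anyDuplicated(c(observed, latent)))
    stop_("duplicated variable names in spec")
  vars <- c(observed, latent)

  if (is.null(paths))
    paths <- data.frame(from = character(), to = character())
  paths <- normalize_entries(paths, c("from", "to"), vars)
  if (anyDuplicated(paths[c("from", "to")]))
    stop_("duplicate path declarations")
  if (any(paths$from == paths$to)) stop_("self-loop path declared")

  if (is.null(covariances))
    covariances <- data.frame(v1 = character(), v2 = character())
  covariances <- normalize_entries(covariances, c("v1", "v2"), vars)
  # canonical order of each pair so (x,y) and (y,x) collide
  swap <- match(covariances$v1, vars) > match(covariances$v2, vars)
  tmp <- covariances$v1[swap]
  covariances$v1[swap] <- covariances$v2[swap]
  covariances$v2[swap] <- tmp
  if (anyDuplicated(covariances[c("v1", "v2")]))
    stop_("duplicate (co)variance declarations")

  if (auto_var) {
    have <- covariances$v1[covariances$v1 == covariances$v2]
    need <- setdiff(vars, have)
    if (length(need))
      covariances <- rbind(covariances, data.frame(
        v1 = need, v2 = need, free = TRUE, value = NA_real_,
        label = NA_character_, stringsAsFactors = FALSE))
  }

  if (!is.null(means)) {
    means <- normalize_entries(means, "var", vars)
    if (anyDuplicated(means$var)) stop_("duplicate mean declarations")
  }

  # default labels
  paths$label <- ifelse(is.na(paths$label),
                        paste0(paths$to, "~", paths$from), paths$label)
  covariances$label <- ifelse(
    is.na(covariances$label),
    paste0(covariances$v1, "~~", covariances$v2), covariances$label)
  if (!is.null(means))
    means$label <- ifelse(is.na(means$label),
                          paste0(means$var, "~1"), means$label)

  spec <- structure(list(
    observed = observed, latent = latent, vars = vars,
    paths = paths, covariances = covariances, means = means),
    class = "sem_spec")
  validate_spec(spec)
  spec
}

normalize_entries <- function(df, key_cols, vars) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (k in key_cols) {
    df[[k]] <- as.character(df[[k]])
    bad <- setdiff(df[[k]], vars)
    if (length(bad)) stop_("unknown variable(s) in spec: %s",
                           paste(bad, collapse = ", "))
  }
  if (is.null(df$free)) df$free <- rep(TRUE, nrow(df))
  if (is.null(df$value)) df$value <- rep(NA_real_, nrow(df))
  if (is.null(df$label)) df$label <- rep(NA_character_, nrow(df))
  df$free <- as.logical(df$free)
  df$value <- as.numeric(df$value)
  df$label <- as.character(df$label)
  if (any(!df$free & is.na(df$value)))
    stop_("fixed entries must carry a value")
  df[c(key_cols, "free", "value", "label")]
}

validate_spec <- function(spec) {
  # scale constraint for every latent: fixed variance or a fixed loading
  for (lv in spec$latent) {
    v <- spec$covariances
    fixed_var <- any(v$v1 == lv & v$v2 == lv & !v$free)
    fixed_load <- any(spec$paths$from == lv & !spec$paths$free)
    if (!fixed_var && !fixed_load)
      stop_("latent '%s' has no scale constraint (fix its variance or a loading)", lv)
  }
  p <- length(spec$observed)
  n_free <- length(free_labels(spec))
  n_mom <- p * (p + 1) / 2 + if (!is.null(spec$means)) p else 0
  if (n_free > n_mom)
    stop_("model not identified: %d free parameters exceed %d distinct moments",
          n_free, n_mom)
  invisible(spec)
}

#' Free-parameter labels of a specification
#'
#' Unique labels of the free parameters, in declaration order; entries
#' sharing a label are a single (equality-constrained) parameter.
#'
#' @param spec a [sem_spec()].
#' @return character vector of labels.
#' @export
free_labels <- function(spec) {
  labs <- c(spec$paths$label[spec$paths$free],
            spec$covariances$label[spec$covariances$free],
            if (!is.null(spec$means)) spec$means$label[spec$means$free])
  unique(labs)
}

# Assemble A, S (and m) matrices from a named parameter vector.
spec_matrices <- function(spec, params) {
  vars <- spec$vars
  k <- length(vars)
  A <- matrix(0, k, k, dimnames = list(vars, vars))
  S <- matrix(0, k, k, dimnames = list(vars, vars))
  pt <- spec$paths
  val <- ifelse(pt$free, unname(params[pt$label]), pt$value)
  A[cbind(match(pt$to, vars), match(pt$from, vars))] <- val
  ct <- spec$covariances
  val <- ifelse(ct$free, unname(params[ct$label]), ct$value)
  i <- match(ct$v1, vars); j <- match(ct$v2, vars)
  S[cbind(i, j)] <- val
  S[cbind(j, i)] <- val
  m <- NULL
  if (!is.null(spec$means)) {
    m <- numeric(k); names(m) <- vars
    mt <- spec$means
    m[mt$var] <- ifelse(mt$free, unname(params[mt$label]), mt$value)
  }
  list(A = A, S = S, m = m)
}

#' Model-implied covariance matrix
#'
#' Assembles the covariance matrix over the observed variables implied by a
#' model specification and a parameter vector, via
#' `Sigma = F (I - A)^-1 S (I - A)^-T F'`.  On recursive models this equals
#' the classical path-tracing expansion exactly.
#'
#' @param spec a [sem_spec()].
#' @param params named numeric vector covering every free parameter label.
#' @return symmetric covariance matrix over `spec$observed`.
#' @export
implied_covariance <- function(spec, params) {
  mom <- implied_moments(spec, params)
  mom$Sigma
}

# Sigma (observed) and optionally mu; also returns B = (I-A)^-1 for gradients
implied_moments <- function(spec, params) {
  check_params(spec, params)
  mats <- spec_matrices(spec, params)
  k <- length(spec$vars)
  B <- tryCatch(solve(diag(k) - mats$A), error = function(e)
    stop_("implied covariance undefined: (I - A) is singular"))
  C <- B %*% mats$S %*% t(B)
  obs <- seq_along(spec$observed)
  Sigma <- C[obs, obs, drop = FALSE]
  Sigma <- (Sigma + t(Sigma)) / 2
  if (any(!is.finite(Sigma))) stop_("implied covariance has non-finite entries")
  mu <- if (!is.null(mats$m)) drop(B %*% mats$m)[obs] else NULL
  list(Sigma = Sigma, mu = mu, B = B, mats = mats)
}

check_params <- function(spec, params) {
  labs <- free_labels(spec)
  missing <- setdiff(labs, names(params))
  if (length(missing))
    stop_("missing parameter value(s): %s", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("SEM specification\n")
  cat("  observed:", length(x$observed), paste0("(", paste(utils::head(x$observed, 8), collapse = ", "),
      if (length(x$observed) > 8) ", ..." else "", ")"), "\n")
  if (length(x$latent)) cat("  latent:  ", paste(x$latent, collapse = ", "), "\n")
  cat("  free parameters:", length(free_labels(x)), "\n")
  p <- length(x$observed)
  df <- p * (p + 1) / 2 - length(free_labels(x))
  cat("  df (covariance structure):", df, "\n")
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' `spec_to_json()` writes the full registry, free/fixed map and labels to a
#' JSON string (or file); `spec_from_json()` restores an identical spec.
#'
#' @param spec a [sem_spec()].
#' @param path optional file path; when given, JSON is written there.
#' @return `spec_to_json()`: JSON string (invisibly if written to a file);
#'   `spec_from_json()`: a [sem_spec()].
#' @export
spec_to_json <- function(spec, path = NULL) {
  payload <- list(observed = spec$observed, latent = spec$latent,
                  paths = spec$paths, covariances = spec$covariances,
                  means = spec$means)
  js <- jsonlite::toJSON(payload, dataframe = "columns", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname spec_to_json
#' @param json JSON string or path to a JSON file produced by `spec_to_json()`.
#' @export
spec_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  payload <- jsonlite::fromJSON(json)
  as_df <- function(x) if (is.null(x) || length(x$label) == 0L && length(x) == 0L) NULL else
    as.data.frame(x, stringsAsFactors = FALSE)
  sem_spec(observed = payload$observed,
           latent = payload$latent %||% character(),
           paths = as_df(payload$paths),
           covariances = as_df(payload$covariances),
           auto_var = FALSE,
           means = as_df(payload$means))
}
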