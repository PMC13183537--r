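#' GEE specification
#'
#' Marginal-model settings for the segmented fits: the clustering column,
#' the working correlation structure, and convergence controls. Standard
#' errors are always robust (sandwich) so inference is valid even when the
#' exchangeable working correlation is misspecified.
#'
#' @param cluster column identifying the cluster (patient).
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol convergence tolerance on coefficients.
#' @param maxit maximum coefficient/correlation alternations.
#' @return A `gee_spec` list.
#' @export
gee_spec <- function(cluster = "patient_id",
                     corstr = c("exchangeable", "independence"),
                     tol = 1e-8, maxit = 100) {
  structure(list(cluster = cluster, corstr = match.arg(corstr),
                 tol = tol, maxit = maxit),
            class = "gee_spec")
}

#' Hinge (broken-stick) basis
#'
#' Two basis columns encoding a continuity-constrained slope change at `K`:
#' `below = (fsh - K) * [fsh < K]` and `above = (fsh - K) * [fsh >= K]`.
#' Their sum is `fsh - K` everywhere and both vanish at `fsh = K`, so a
#' linear model on them is automatically continuous at the breakpoint.
#'
#' @param fsh exposure values.
#' @param K breakpoint (finite scalar).
#' @return A two-column matrix `cbind(below, above)`.
#' @export
hinge_design <- function(fsh, K) {
  stopifnot(is.numeric(K), length(K) == 1, is.finite(K))
  d <- fsh - K
  cbind(below = d * (d < 0), above = d * (d >= 0))
}

# Build the complete-case fitting frame once per cohort so repeated fits
# (grid candidates, bootstrap replicates, CV folds) reuse the same design.
# Returns rows sorted by cluster with an integer cluster-size vector.
.prepare_gee_data <- function(cohort, covariates, spec,
                              outcome = "oocytes", exposure = "fsh_day7") {
  stopifnot(inherits(cohort, "fsh_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort: nothing to fit")
  need <- c(spec$cluster, outcome, exposure, covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(cohort)[need]
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete cases for the requested model")
  ord <- order(df[[spec$cluster]])
  df <- df[ord, , drop = FALSE]
  cl <- df[[spec$cluster]]
  csize <- as.integer(rle(as.character(cl))$lengths)
  Z <- if (length(covariates)) {
    mf <- df[covariates]
    for (v in names(mf)) {
      if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
      if (is.factor(mf[[v]])) mf[[v]] <- droplevels(mf[[v]])
    }
    model.matrix(~ ., data = mf)
  } else matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  list(y = df[[outcome]], fsh = df[[exposure]], Z = Z, csize = csize,
       cluster = cl, n = nrow(df), n_clusters = length(csize),
       n_dropped = sum(!cc), rows = which(cc)[ord], covariates = covariates)
}

# low-level engine wrapper with collinearity diagnostics
.gee_engine <- function(X, y, csize, spec) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(structure(class = c("collinearity_error", "error", "condition"),
                   list(message = paste0("rank-deficient design; aliased: ",
                                         paste(aliased, collapse = ", ")),
                        call = NULL)))
  }
  fit <- .gee_fit_cpp(X, y, csize, spec$corstr == "exchangeable",
                      spec$tol, spec$maxit)
  if (!fit$converged)
    stop(structure(class = c("gee_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "GEE did not converge in %d iterations (last alpha=%.4f)",
                     fit$iterations, fit$alpha), call = NULL)))
  fit$beta <- drop(fit$beta)
  names(fit$beta) <- colnames(X)
  dimnames(fit$vbeta) <- list(colnames(X), colnames(X))
  fit
}

#' Fit the continuity-constrained two-piece-wise GEE model
#'
#' Solves the Gaussian-family GEE estimating equations for the mean
#' `beta0 + beta1 (FSH - K)[FSH < K] + beta2 (FSH - K)[FSH >= K] + Z gamma`
#' at a fixed breakpoint `K`, with exchangeable (or independence) working
#' correlation estimated by moments from standardized residuals, and robust
#' sandwich covariance. The Gaussian log quasi-likelihood
#' `QL = -RSS / (2 phi)` is returned for model comparison.
#'
#' @param cohort an `fsh_cohort`.
#' @param K breakpoint, strictly inside the observed exposure range.
#' @param covariates character vector of adjustment columns (may be empty).
#' @param spec a [gee_spec()].
#' @param outcome,exposure column names.
#' @return A `segmented_fit`: coefficient table (estimate, robust SE, 95% CI,
#'   p), `K`, `quasi_likelihood`, `rss`, dispersion `phi`, working `alpha`,
#'   counts, and the fitting frame bookkeeping.
#' @export
fit_segmented_gee <- function(cohort, K, covariates = character(),
                              spec = gee_spec(), outcome = "oocytes",
                              exposure = "fsh_day7") {
  prep <- .prepare_gee_data(cohort, covariates, spec, outcome, exposure)
  rng <- range(prep$fsh)
  if (K <= rng[1] || K >= rng[2])
    stop("K must lie strictly inside the observed exposure range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (prep$n_clusters < 2) stop("need at least 2 clusters for a GEE fit")
  .fit_segmented_prepared(prep, K, spec)
}

.fit_segmented_prepared <- function(prep, K, spec) {
  H <- hinge_design(prep$fsh, K)
  X <- cbind(prep$Z, fsh_below = H[, 1], fsh_above = H[, 2])
  fit <- .gee_engine(X, prep$y, prep$csize, spec)
  se <- sqrt(diag(fit$vbeta))
  z <- qnorm(0.975)
  tab <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                    robust_se = unname(se),
                    ci_low = unname(fit$beta - z * se),
                    ci_high = unname(fit$beta + z * se),
                    p_value = unname(2 * pnorm(-abs(fit$beta / se))),
                    row.names = NULL)
  structure(list(
    K = K,
    beta0 = unname(fit$beta["(Intercept)"]),
    beta1 = unname(fit$beta["fsh_below"]),
    beta2 = unname(fit$beta["fsh_above"]),
    gamma = fit$beta[setdiff(names(fit$beta),
                             c("(Intercept)", "fsh_below", "fsh_above"))],
    coefficients = tab, vbeta = fit$vbeta,
    quasi_likelihood = -fit$rss / (2 * fit$phi),
    rss = fit$rss, phi = fit$phi, alpha = fit$alpha,
    n_obs = prep$n, n_clusters = prep$n_clusters,
    n_dropped = prep$n_dropped, spec = spec, covariates = prep$covariates,
    converged = fit$converged, iterations = fit$iterations),
    class = "segmented_fit")
}

# linear (single-slope) GEE on the same frame; used as the nested reference
.fit_linear_prepared <- function(prep, spec) {
  X <- cbind(prep$Z, fsh = prep$fsh)
  fit <- .gee_engine(X, prep$y, prep$csize, spec)
  list(beta = fit$beta, vbeta = fit$vbeta, rss = fit$rss, phi = fit$phi,
       alpha = fit$alpha, quasi_likelihood = -fit$rss / (2 * fit$phi))
}

#' Predicted marginal mean of a segmented fit
#'
#' @param object a `segmented_fit`.
#' @param newdata data frame with exposure and covariate columns.
#' @param covariates,exposure column names used at fit time.
#' @param ... unused.
#' @return Numeric vector of fitted means.
#' @export
predict.segmented_fit <- function(object, newdata, covariates = NULL,
                                  exposure = "fsh_day7", ...) {
  covariates <- covariates %||% object$covariates
  Z <- if (length(covariates)) model.matrix(~ ., data = newdata[covariates])
       else matrix(1, nrow(newdata), 1, dimnames = list(NULL, "(Intercept)"))
  H <- hinge_design(newdata[[exposure]], object$K)
  X <- cbind(Z, fsh_below = H[, 1], fsh_above = H[, 2])
  est <- object$coefficients$estimate
  names(est) <- object$coefficients$term
  drop(X[, names(est), drop = FALSE] %*% est)
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Two-piece-wise GEE fit (breakpoint K = %.4g)\n", x$K))
  cat(sprintf("  slope below K : %8.4f\n", x$beta1))
  cat(sprintf("  slope >= K    : %8.4f\n", x$beta2))
  cat(sprintf("  n = %d cycles, %d patients; working alpha = %.3f, phi = %.3f\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi))
  cat(sprintf("  quasi-likelihood = %.3f\n", x$quasi_likelihood))
  invisible(x)
}
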