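#' Smoothing-spline nonlinearity screen
#'
#' Fits a covariate-adjusted penalized spline partial effect of the exposure
#' (generalized additive model), evaluates it with a pointwise 95% band on a
#' fixed grid, and compares it with the nested linear fit to produce an
#' approximate nonlinearity p-value. A clearly nonlinear dose--response
#' gates the threshold modeling stage.
#'
#' @name gam_screen
NULL

#' Spline configuration
#'
#' @param k basis dimension of the cubic regression spline (about 10 knots
#'   at exposure quantiles).
#' @param method smoothing-parameter selection: `"GCV.Cp"` (generalized
#'   cross-validation, default) or `"REML"`.
#' @param grid_n evaluation-grid size.
#' @param grid_trim percentile trim of the grid (default 1st--99th; curve
#'   tails beyond are unstable).
#' @param min_n minimum complete cases for a fit.
#' @return A `spline_config` list.
#' @export
spline_config <- function(k = 10, method = c("GCV.Cp", "REML"),
                          grid_n = 200, grid_trim = c(0.01, 0.99),
                          min_n = 50) {
  structure(list(k = k, method = match.arg(method), grid_n = grid_n,
                 grid_trim = grid_trim, min_n = min_n),
            class = "spline_config")
}

#' Fit the adjusted smooth dose--response curve
#'
#' Penalized cubic regression spline on the exposure with linear covariate
#' adjustment, fitted by [mgcv::gam()]. The nonlinearity p-value comes from
#' an F-type comparison of the spline fit against the nested linear fit,
#' with the smooth's effective degrees of freedom as numerator df; it is
#' approximate and documented as such.
#'
#' @param cohort an `fsh_cohort`.
#' @param exposure,outcome column names.
#' @param covariates adjustment columns.
#' @param config a [spline_config()].
#' @return A `smooth_fit`: evaluation `grid` (exposure, partial effect `fit`,
#'   `lo`, `hi`), `edf`, `p_nonlinear`, `n_used`, and the underlying `gam`.
#' @export
fit_smooth <- function(cohort, exposure = "fsh_day7", outcome = "oocytes",
                       covariates = character(), config = spline_config()) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  cols <- c(outcome, exposure, covariates)
  df <- as.data.frame(cohort)[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < config$min_n)
    stop("need at least ", config$min_n, " complete cases (have ",
         nrow(df), ")")
  nx <- length(unique(df[[exposure]]))
  if (nx < 10) stop("exposure has fewer than 10 distinct values")
  if (nx < config$k)
    stop(structure(class = c("basis_error", "error", "condition"),
                   list(message = sprintf(
                     "fewer distinct exposure values (%d) than basis size (%d)",
                     nx, config$k), call = NULL)))
  for (v in names(df)) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  rhs <- c(sprintf("s(%s, bs = \"cr\", k = %d)", exposure, config$k),
           covariates)
  fml <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  g <- mgcv::gam(fml, data = df, method = config$method)

  # nested linear fit on the same rows
  fml_lin <- as.formula(paste(outcome, "~",
                              paste(c(exposure, covariates), collapse = " + ")))
  l <- lm(fml_lin, data = df)
  edf <- sum(g$edf[g$smooth[[1]]$first.para:g$smooth[[1]]$last.para]) + 1
  rss_g <- sum(residuals(g)^2)
  rss_l <- sum(residuals(l)^2)
  df1 <- max(edf - 1, 1e-8)
  df2 <- g$df.residual
  Fv <- max(0, (rss_l - rss_g) / df1) / (rss_g / df2)
  p_nl <- pf(Fv, df1, df2, lower.tail = FALSE)

  qs <- quantile(df[[exposure]], config$grid_trim, names = FALSE, type = 7)
  grid_x <- seq(qs[1], qs[2], length.out = config$grid_n)
  nd <- df[rep(1, config$grid_n), , drop = FALSE]
  nd[[exposure]] <- grid_x
  pr <- predict(g, newdata = nd, type = "terms", se.fit = TRUE)
  sterm <- grep(paste0("^s\\(", exposure), colnames(pr$fit), value = TRUE)[1]
  fit_v <- pr$fit[, sterm]
  se_v <- pr$se.fit[, sterm]
  grid <- data.frame(exposure = grid_x, fit = fit_v,
                     lo = fit_v - 1.96 * se_v, hi = fit_v + 1.96 * se_v)
  structure(list(grid = grid, edf = edf, p_nonlinear = p_nl,
                 F_statistic = Fv, n_used = nrow(df),
                 covariates = covariates, exposure = exposure,
                 outcome = outcome, gam = g, config = config),
            class = "smooth_fit")
}

#' Stratified smooth curves
#'
#' Independent [fit_smooth()] per stratum on a shared evaluation grid
#' (spanning the pooled trimmed exposure range), enabling overlay plots.
#' Strata below `min_n` complete cases are skipped with a warning.
#'
#' @param cohort an `fsh_cohort`.
#' @param stratum column defining the strata.
#' @param exposure,outcome,covariates,config as in [fit_smooth()].
#' @return Named list of `smooth_fit`s (skipped strata are absent).
#' @export
stratified_smooths <- function(cohort, stratum, exposure = "fsh_day7",
                               outcome = "oocytes",
                               covariates = character(),
                               config = spline_config()) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  s <- cohort[[stratum]]
  if (is.null(s)) stop("stratum column '", stratum, "' absent")
  s <- as.factor(s)
  pooled <- cohort[[exposure]][!is.na(cohort[[exposure]])]
  qs <- quantile(pooled, config$grid_trim, names = FALSE, type = 7)
  out <- list()
  for (lev in levels(s)) {
    sub <- cohort[!is.na(s) & s == lev, , drop = FALSE]
    class(sub) <- c("fsh_cohort", "data.frame")
    fit <- tryCatch(fit_smooth(sub, exposure, outcome, covariates, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("stratum '", lev, "' skipped: ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    # re-evaluate on the shared grid
    grid_x <- seq(max(qs[1], min(sub[[exposure]], na.rm = TRUE)),
                  min(qs[2], max(sub[[exposure]], na.rm = TRUE)),
                  length.out = config$grid_n)
    df <- as.data.frame(sub)[c(outcome, exposure, covariates)]
    df <- df[complete.cases(df), , drop = FALSE]
    nd <- df[rep(1, length(grid_x)), , drop = FALSE]
    nd[[exposure]] <- grid_x
    pr <- predict(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
    sterm <- grep(paste0("^s\\(", exposure), colnames(pr$fit), value = TRUE)[1]
    fit$grid <- data.frame(exposure = grid_x, fit = pr$fit[, sterm],
                           lo = pr$fit[, sterm] - 1.96 * pr$se.fit[, sterm],
                           hi = pr$fit[, sterm] + 1.96 * pr$se.fit[, sterm])
    out[[lev]] <- fit
  }
  out
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("Adjusted smooth fit: edf = %.2f, nonlinearity p = %.3g (n = %d)\n",
              x$edf, x$p_nonlinear, x$n_used))
  invisible(x)
}

#' Plot a smooth dose--response fit
#'
#' Draws the partial-effect curve (red) with its 95% band (blue), the usual
#' presentation of an adjusted dose--response smooth. Requires ggplot2.
#'
#' @param x a `smooth_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.smooth_fit <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(x$grid, ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "red",
                       linewidth = 0.9) +
    ggplot2::labs(x = x$exposure,
                  y = sprintf("partial effect on %s", x$outcome)) +
    ggplot2::theme_minimal()
}
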