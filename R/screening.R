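#' Tertile descriptives and linear screening
#'
#' Machinery for the descriptive tertile table with group tests, the
#' univariate linear screen, the multivariable-adjusted model, and the
#' ordinal trend test across tertiles.
#'
#' @name screening_stats
NULL

#' Baseline characteristics by group
#'
#' One row per cohort variable: continuous variables are summarized as
#' mean +/- SD per group and compared by one-way ANOVA, or by the
#' Kruskal-Wallis H test when skewed (|skewness| > `skew_threshold`);
#' categorical variables are summarized as n (%) and compared by the
#' chi-square test on the contingency table.
#'
#' @param cohort an `fsh_cohort` with tertiles assigned (see
#'   [assign_tertiles()]), or any grouping factor via `group`.
#' @param group name of the grouping column (default `"tertile"`).
#' @param variables columns to summarize; defaults to all schema variables
#'   except identifiers and the grouping column.
#' @param skew_threshold |skewness| above which the Kruskal-Wallis test is
#'   used instead of ANOVA.
#' @return A data frame of `GroupComparisonRow`s: variable, per-group
#'   summary, test, statistic, p_value.
#' @export
baseline_table <- function(cohort, group = "tertile", variables = NULL,
                           skew_threshold = 1) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  g <- cohort[[group]]
  if (is.null(g)) stop("grouping column '", group, "' absent; assign tertiles first")
  g <- droplevels(as.factor(g))
  counts <- table(g)
  if (any(counts == 0) || nlevels(g) < 2) {
    empty <- names(counts)[counts == 0]
    stop("group(s) with zero records: ",
         paste(if (length(empty)) empty else "(need >= 2 groups)",
               collapse = ", "))
  }
  if (is.null(variables))
    variables <- setdiff(intersect(names(.cohort_schema()), names(cohort)),
                         c("patient_id", "cycle_index", group, "canceled",
                           "first_cycle"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(g)
    xv <- x[keep]; gv <- droplevels(g[keep])
    if (is.factor(x) || length(unique(xv)) <= 2) {
      tab <- table(factor(xv), gv)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      summ <- paste(vapply(levels(gv), function(l) {
        ns <- table(factor(xv)[gv == l])
        if (length(ns) == 2 && all(rownames(tab) %in% c("0", "1")))
          sprintf("%d (%.1f%%)", ns["1"], 100 * ns["1"] / sum(ns))
        else paste(sprintf("%s=%d", names(ns), ns), collapse = ";")
      }, character(1)), collapse = " | ")
      data.frame(variable = v, summary = summ, test = "chi_square",
                 statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value))
    } else {
      skewed <- abs(sample_skewness(xv)) > skew_threshold
      summ <- paste(vapply(levels(gv), function(l)
        sprintf("%.2f ± %.2f", mean(xv[gv == l]), sd(xv[gv == l])),
        character(1)), collapse = " | ")
      if (skewed) {
        kt <- kruskal.test(xv, gv)
        data.frame(variable = v, summary = summ, test = "kruskal_wallis",
                   statistic = unname(kt$statistic),
                   p_value = unname(kt$p.value))
      } else {
        ft <- summary(aov(xv ~ gv))[[1]]
        data.frame(variable = v, summary = summ, test = "anova",
                   statistic = ft[["F value"]][1],
                   p_value = ft[["Pr(>F)"]][1])
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one linear-effect row from an lm fit, t-based 95% CI
.effect_row <- function(fit, term, exposure, n_used, adjusted_for) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) return(NULL)
  est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  dfr <- fit$df.residual
  tq <- qt(0.975, dfr)
  data.frame(exposure = exposure, term = term, beta = est,
             ci_low = est - tq * se, ci_high = est + tq * se,
             p_value = sm[term, "Pr(>|t|)"], n_used = n_used,
             adjusted_for = paste(adjusted_for, collapse = ","),
             row.names = NULL)
}

#' Univariate linear screen
#'
#' Simple linear regression of the outcome on each exposure in turn, with
#' classical normal-theory (t-based) 95% CIs. Categorical exposures are
#' expanded against a reference level (default: the most frequent category)
#' and yield one row per non-reference level.
#'
#' @param cohort an `fsh_cohort`.
#' @param outcome outcome column (default `"oocytes"`).
#' @param exposures character vector of exposure columns.
#' @param reference optional named list `exposure -> reference level`.
#' @return A data frame of `LinearEffect` rows.
#' @export
univariate_effects <- function(cohort, outcome = "oocytes",
                               exposures, reference = list()) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  out <- lapply(exposures, function(v) {
    df <- data.frame(y = cohort[[outcome]], x = cohort[[v]])
    df <- df[complete.cases(df), , drop = FALSE]
    if (is.factor(df$x) || is.character(df$x)) {
      df$x <- droplevels(as.factor(df$x))
      ref <- reference[[v]] %||% names(which.max(table(df$x)))
      df$x <- stats::relevel(df$x, ref = ref)
      fit <- lm(y ~ x, data = df)
      lv <- setdiff(levels(df$x), ref)
      do.call(rbind, lapply(lv, function(l)
        .effect_row(fit, paste0("x", l), v, nrow(df), character(0))))
    } else {
      if (length(unique(df$x)) < 2) {
        warning("constant exposure '", v, "': skipped", call. = FALSE)
        return(NULL)
      }
      fit <- lm(y ~ x, data = df)
      .effect_row(fit, "x", v, nrow(df), character(0))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multivariable-adjusted exposure effect
#'
#' Linear model of the outcome on the exposure plus covariates on complete
#' cases; returns the exposure's partial effect with t-based 95% CI and the
#' number of rows used. A rank-deficient design aborts, naming the aliased
#' columns.
#'
#' @param cohort an `fsh_cohort`.
#' @param exposure exposure column.
#' @param outcome outcome column.
#' @param covariates adjustment columns (empty = crude model, identical to
#'   [univariate_effects()] for that exposure).
#' @return A one-row `LinearEffect` data frame (attribute `"fit"` holds the
#'   `lm` object).
#' @export
adjusted_effect <- function(cohort, exposure, outcome = "oocytes",
                            covariates = character()) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  cols <- c(outcome, exposure, covariates)
  df <- as.data.frame(cohort)[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(covariates) + 2)
    stop("too few complete cases (", nrow(df), ") for the adjusted model")
  for (v in names(df)) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  fml <- as.formula(paste0("`", outcome, "` ~ ",
                           paste0("`", c(exposure, covariates), "`",
                                  collapse = " + ")))
  fit <- lm(fml, data = df)
  al <- is.na(coef(fit))
  if (any(al))
    stop(structure(class = c("collinearity_error", "error", "condition"),
                   list(message = paste0("collinear design; aliased: ",
                                         paste(names(coef(fit))[al],
                                               collapse = ", ")),
                        call = NULL)))
  nm <- gsub("`", "", names(coef(fit)))
  term <- names(coef(fit))[match(exposure, nm)]
  if (is.na(term))
    term <- names(coef(fit))[startsWith(nm, exposure)][1]
  row <- .effect_row(fit, term, exposure, nrow(df), covariates)
  attr(row, "fit") <- fit
  row
}

#' Tertile trend test
#'
#' Enters the tertile as an ordinal score (low = 1, medium = 2, high = 3) in
#' the covariate-adjusted linear model and returns the score coefficient's
#' p-value.
#'
#' @param cohort an `fsh_cohort` with tertiles assigned.
#' @param outcome outcome column.
#' @param covariates adjustment columns.
#' @param group tertile column name.
#' @return The trend p-value, with attributes `beta` and `n_used`.
#' @export
trend_test <- function(cohort, outcome = "oocytes",
                       covariates = character(), group = "tertile") {
  stopifnot(inherits(cohort, "fsh_cohort"))
  g <- cohort[[group]]
  if (is.null(g)) stop("tertiles not assigned")
  if (length(unique(na.omit(g))) < 3)
    stop("fewer than 3 groups represented")
  work <- cohort
  work$.score <- as.numeric(factor(g, levels = .cohort_vocab$tertile))
  class(work) <- c("fsh_cohort", "data.frame")
  row <- adjusted_effect(work, ".score", outcome, covariates)
  structure(row$p_value, beta = row$beta, n_used = row$n_used)
}
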