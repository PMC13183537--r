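#' Subgroup, interaction and sensitivity analyses
#'
#' Stratified adjusted exposure effects with product-term interaction tests,
#' and the two sensitivity designs: first-cycle-only and a
#' gonadotropin-type-restricted rerun of the full threshold pipeline.
#'
#' @name subgroup_sensitivity
NULL

#' Default stratum definitions
#'
#' Age at 35 years; AMH at 1.2 and 5 ng/mL; BMI at 18.5 kg/m2; the binary
#' POR and PCOS flags.
#'
#' @return Named list of definitions for [stratified_effects()]: each is
#'   either `list(breaks = ...)` for a numeric cut or `list(levels = TRUE)`
#'   for a categorical/flag variable.
#' @export
default_strata <- function() {
  list(age = list(breaks = 35),
       amh = list(breaks = c(1.2, 5)),
       bmi = list(breaks = 18.5),
       por = list(levels = TRUE),
       pcos = list(levels = TRUE))
}

# cut a stratifying variable into labelled, exhaustive strata
.make_strata <- function(x, def, varname) {
  if (!is.null(def$breaks)) {
    br <- sort(def$breaks)
    labs <- character(length(br) + 1)
    labs[1] <- sprintf("< %g", br[1])
    if (length(br) > 1)
      for (j in seq_len(length(br) - 1))
        labs[j + 1] <- sprintf("%g-%g", br[j], br[j + 1])
    labs[length(labs)] <- sprintf(">= %g", br[length(br)])
    cut(x, breaks = c(-Inf, br, Inf), right = FALSE, labels = labs)
  } else {
    factor(x)
  }
}

#' Stratified exposure effects with interaction tests
#'
#' Within each stratum, the covariate-adjusted linear exposure effect is
#' estimated with the stratifying variable removed from the adjustment list.
#' The interaction p-value comes from a pooled adjusted model with
#' exposure-by-stratum product terms, tested jointly (F test against the
#' no-product-term model).
#'
#' @param cohort an `fsh_cohort`.
#' @param strata named list of stratum definitions (see [default_strata()]).
#' @param exposure,outcome column names.
#' @param covariates full adjustment list (the stratifying variable and, for
#'   AMH-derived flags, nothing else is removed automatically beyond it).
#' @param min_n strata below this size are skipped with a warning.
#' @return A `subgroup_result` list: per-variable tables of per-stratum
#'   `LinearEffect`s with `p_interaction` and stratum sizes.
#' @export
stratified_effects <- function(cohort, strata = default_strata(),
                               exposure = "fsh_day7", outcome = "oocytes",
                               covariates = character(), min_n = 30) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  out <- list()
  for (v in names(strata)) {
    if (is.null(cohort[[v]]))
      stop("stratifying variable '", v, "' absent from cohort")
    adj <- setdiff(covariates, v)
    sv <- .make_strata(cohort[[v]], strata[[v]], v)
    cols <- unique(c(outcome, exposure, adj))
    df <- as.data.frame(cohort)[cols]
    keep <- complete.cases(df) & !is.na(sv)
    df <- df[keep, , drop = FALSE]
    svk <- droplevels(sv[keep])
    for (cn in names(df)) {
      if (is.character(df[[cn]])) df[[cn]] <- factor(df[[cn]])
      if (is.factor(df[[cn]])) df[[cn]] <- droplevels(df[[cn]])
    }

    rows <- lapply(levels(svk), function(lev) {
      sub <- df[svk == lev, , drop = FALSE]
      if (nrow(sub) < min_n) {
        warning("stratum ", v, " = '", lev, "' skipped (n = ", nrow(sub),
                ")", call. = FALSE)
        return(NULL)
      }
      sub_cohort <- sub
      class(sub_cohort) <- c("fsh_cohort", "data.frame")
      eff <- adjusted_effect(sub_cohort, exposure, outcome, adj)
      data.frame(variable = v, stratum = lev, n = nrow(sub),
                 beta = eff$beta, ci_low = eff$ci_low,
                 ci_high = eff$ci_high, p_value = eff$p_value)
    })
    tab <- do.call(rbind, rows)

    # pooled interaction test (joint Wald/F across product terms)
    p_int <- NA_real_
    if (nlevels(svk) >= 2) {
      pooled <- df
      pooled$.stratum <- svk
      rhs0 <- paste(c(sprintf("`%s`", exposure), ".stratum",
                      sprintf("`%s`", adj)), collapse = " + ")
      f0 <- as.formula(paste0("`", outcome, "` ~ ", rhs0))
      f1 <- as.formula(paste0("`", outcome, "` ~ ", rhs0,
                              " + `", exposure, "`:.stratum"))
      m0 <- lm(f0, data = pooled)
      m1 <- lm(f1, data = pooled)
      p_int <- stats::anova(m0, m1)[2, "Pr(>F)"]
    }
    out[[v]] <- list(variable = v, table = tab, p_interaction = p_int,
                     n_total = nrow(df))
  }
  structure(out, class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  for (v in names(x)) {
    cat(sprintf("%s (p interaction = %.3g)\n", v, x[[v]]$p_interaction))
    print(x[[v]]$table, row.names = FALSE)
  }
  invisible(x)
}

# shared threshold pipeline used by the sensitivity designs
.threshold_pipeline <- function(cohort, covariates, spec, config,
                                B, seed, folds = NULL,
                                outcome = "oocytes", exposure = "fsh_day7") {
  search <- recursive_threshold_search(cohort, covariates, spec, config,
                                       outcome, exposure)
  ci <- if (!is.null(B) && B > 0)
    bootstrap_breakpoint_ci(cohort, covariates, spec, config, B = B,
                            seed = seed, outcome = outcome,
                            exposure = exposure) else NULL
  qlr <- qlr_threshold_test(cohort, search$fit, covariates, spec,
                            outcome, exposure)
  cv <- if (!is.null(folds))
    cross_validate_threshold(cohort, covariates, spec, config,
                             folds = folds, seed = seed,
                             outcome = outcome, exposure = exposure) else NULL
  search$ci <- ci
  search$qlr <- qlr
  search$cv <- cv
  search
}

#' Sensitivity analysis: first cycle per patient only
#'
#' Restricts the cohort to one (the first) cycle per patient — clustering
#' becomes trivial — and reruns exclusions, tertiles, screening and the full
#' threshold pipeline (search, bootstrap CI, QLR test).
#'
#' @param cohort an `fsh_cohort` (pre-exclusion).
#' @param covariates adjustment columns.
#' @param policy an [exclusion_policy()].
#' @param spec,config,B,seed as in the threshold functions.
#' @return A report list (`ok`, `n_cycles`, `K`, `fit`, `ci`, `qlr`, ...) or,
#'   on failure, a structured record with `ok = FALSE` and the error message.
#' @export
sensitivity_first_cycle <- function(cohort, covariates = character(),
                                    policy = exclusion_policy(),
                                    spec = gee_spec(),
                                    config = search_config(),
                                    B = 200, seed = 1L) {
  tryCatch({
    sub <- first_cycle_subset(cohort)
    sub <- apply_exclusions(sub, policy)
    if (nrow(sub) == 0) stop("no eligible first cycles")
    sub <- assign_tertiles(sub)
    res <- .threshold_pipeline(sub, covariates, spec, config, B, seed)
    list(ok = TRUE, design = "first_cycle_only", n_cycles = nrow(sub),
         n_patients = length(unique(sub$patient_id)),
         K = res$K_opt, fit = res$fit, ci = res$ci, qlr = res$qlr,
         exclusions = attr(sub, "exclusion_report"), search = res)
  }, error = function(e) {
    list(ok = FALSE, design = "first_cycle_only",
         error = conditionMessage(e))
  })
}

#' Sensitivity analysis: restrict to one gonadotropin type
#'
#' Restricts the cohort to the named gonadotropin type and reruns the full
#' threshold pipeline, reporting K, segment slopes, bootstrap CI and QLR p.
#'
#' @param cohort an `fsh_cohort`.
#' @param type `"recombinant"` or `"urinary"`.
#' @param covariates,policy,spec,config,B,seed as in
#'   [sensitivity_first_cycle()].
#' @return A report list as in [sensitivity_first_cycle()].
#' @export
sensitivity_gonadotropin_subset <- function(cohort, type,
                                            covariates = character(),
                                            policy = NULL,
                                            spec = gee_spec(),
                                            config = search_config(),
                                            B = 200, seed = 1L) {
  if (!type %in% .cohort_vocab$gonadotropin_type)
    stop("unknown gonadotropin type '", type, "'; valid: ",
         paste(.cohort_vocab$gonadotropin_type, collapse = ", "))
  tryCatch({
    if (is.null(policy))
      policy <- exclusion_policy(gonadotropin_type = type)
    else policy$gonadotropin_type <- type
    sub <- apply_exclusions(cohort, policy)
    if (nrow(sub) == 0) stop("empty subset after restricting to ", type)
    sub <- assign_tertiles(sub)
    res <- .threshold_pipeline(sub, covariates, spec, config, B, seed)
    list(ok = TRUE, design = paste0("gonadotropin_", type),
         n_cycles = nrow(sub),
         n_patients = length(unique(sub$patient_id)),
         K = res$K_opt, fit = res$fit, ci = res$ci, qlr = res$qlr,
         exclusions = attr(sub, "exclusion_report"), search = res)
  }, error = function(e) {
    list(ok = FALSE, design = paste0("gonadotropin_", type),
         error = conditionMessage(e))
  })
}
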