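#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis in the study's order: exclusions,
#' tertile descriptives, univariate screen, adjusted model with trend test,
#' smoothing-spline nonlinearity screen, threshold analysis (breakpoint
#' search, bootstrap CI, QLR test, grouped cross-validation), subgroup
#' analyses, and sensitivity designs, producing a reproducible report
#' bundle.
#'
#' @name cli_pipeline
NULL

#' Default adjustment covariates
#'
#' The multivariable adjustment set: age, infertility duration, BMI, AMH,
#' Day-1 FSH, AFC, PCOS, POR, infertility-factor category, and initial and
#' total gonadotropin dose.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age", "infertility_duration", "bmi", "amh", "fsh_day1", "afc",
    "pcos", "por", "infertility_factor", "initial_dose", "total_dose")
}

#' Run configuration
#'
#' Bundles every analysis choice into one object so a run is fully
#' determined by `config + seed`. The `input` is either a cohort CSV path or
#' a [simulation_config()].
#'
#' @param input file path or `simulation_config`.
#' @param policy an [exclusion_policy()].
#' @param covariates adjustment columns.
#' @param search a [search_config()].
#' @param spline a [spline_config()].
#' @param gee a [gee_spec()].
#' @param bootstrap_B bootstrap replicates (0 disables the breakpoint CI).
#' @param cv_folds cross-validation folds (0 disables CV).
#' @param strata subgroup definitions (see [default_strata()]); `NULL`
#'   disables subgroup analysis.
#' @param sensitivity character subset of
#'   `c("first_cycle", "recombinant", "urinary")`.
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @param outdir output directory for the bundle files, or `NULL` to skip
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(input = default_study_config(),
                       policy = exclusion_policy(),
                       covariates = default_covariates(),
                       search = search_config(),
                       spline = spline_config(),
                       gee = gee_spec(),
                       bootstrap_B = 1000,
                       cv_folds = 10,
                       strata = default_strata(),
                       sensitivity = "first_cycle",
                       seed = 1L,
                       outdir = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(input = input, policy = policy, covariates = covariates,
                 search = search, spline = spline, gee = gee,
                 bootstrap_B = bootstrap_B, cv_folds = cv_folds,
                 strata = strata, sensitivity = sensitivity,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' The study-settings profile
#'
#' The committed profile of the original design choices: grid 5--95 at step
#' 5, refinement +/- 4 percentile points at step 1, 1000 bootstrap
#' replicates, 10-fold cross-validation.
#'
#' @param ... overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
study_profile <- function(...) {
  run_config(search = search_config(5, 95, 5, 4, 1),
             bootstrap_B = 1000, cv_folds = 10, ...)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis
#'
#' Executes every stage on the configured input and returns (and, when
#' `outdir` is set, writes) the report bundle: exclusion report, tertile
#' descriptives, univariate screen, adjusted model with trend test, smooth
#' curve, threshold analysis (K, slopes, bootstrap CI, QLR p), CV summary,
#' subgroup table, sensitivity reports, and a manifest recording the config
#' hash, seed and versions. Stage failures are caught and recorded in
#' `bundle$failures`; completed artifacts are still returned.
#'
#' @param config a [run_config()].
#' @return The report bundle (list), invisibly when written to disk.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  bundle <- list(failures = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      bundle$failures[[name]] <<- conditionMessage(res)
      message("stage '", name, "' failed: ", conditionMessage(res))
      NULL
    } else res
  }

  cohort <- stage("input", {
    if (inherits(config$input, "simulation_config"))
      simulate_cohort(config$input, seed = seed)
    else read_cohort(config$input)
  })
  if (is.null(cohort)) return(bundle)
  message(sprintf("input: %d cycles, %d patients", nrow(cohort),
                  length(unique(cohort$patient_id))))

  eligible <- stage("exclusions", apply_exclusions(cohort, config$policy))
  if (is.null(eligible) || nrow(eligible) == 0) return(bundle)
  bundle$exclusion_report <- attr(eligible, "exclusion_report")
  message(sprintf("eligible: %d cycles (excluded %d)", nrow(eligible),
                  nrow(cohort) - nrow(eligible)))

  eligible <- stage("tertiles", assign_tertiles(eligible)) %||% eligible
  bundle$baseline <- stage("baseline_table", baseline_table(eligible))
  bundle$univariate <- stage("univariate_screen",
    univariate_effects(eligible, exposures = c("fsh_day7",
                                               config$covariates)))
  bundle$adjusted <- stage("adjusted_model",
    adjusted_effect(eligible, "fsh_day7", covariates = config$covariates))
  bundle$trend_p <- stage("trend_test",
    as.numeric(trend_test(eligible, covariates = config$covariates)))
  bundle$smooth <- stage("gam_screen",
    fit_smooth(eligible, covariates = config$covariates,
               config = config$spline))

  thr <- stage("threshold", .threshold_pipeline(
    eligible, config$covariates, config$gee, config$search,
    B = config$bootstrap_B, seed = seed,
    folds = if (config$cv_folds >= 2) config$cv_folds else NULL))
  if (!is.null(thr)) {
    bundle$threshold <- thr
    bundle$table4 <- data.frame(
      quantity = c("breakpoint_K", "slope_below", "slope_above"),
      estimate = c(thr$K_opt, thr$fit$beta1, thr$fit$beta2),
      ci_low = c(if (is.null(thr$ci)) NA else thr$ci[1],
                 thr$fit$coefficients$ci_low[match(
                   c("fsh_below", "fsh_above"), thr$fit$coefficients$term)]),
      ci_high = c(if (is.null(thr$ci)) NA else thr$ci[2],
                  thr$fit$coefficients$ci_high[match(
                    c("fsh_below", "fsh_above"), thr$fit$coefficients$term)]))
    bundle$qlr_p <- as.numeric(thr$qlr)
    bundle$cv <- thr$cv
    message(sprintf("threshold: K = %.3f, slopes %.3f / %.3f, QLR p = %.3g",
                    thr$K_opt, thr$fit$beta1, thr$fit$beta2,
                    as.numeric(thr$qlr)))
  }

  if (!is.null(config$strata))
    bundle$subgroups <- stage("subgroups",
      stratified_effects(eligible, config$strata,
                         covariates = config$covariates))

  if ("first_cycle" %in% config$sensitivity)
    bundle$sensitivity_first_cycle <- stage("sensitivity_first_cycle",
      sensitivity_first_cycle(cohort, config$covariates, config$policy,
                              config$gee, config$search,
                              B = min(config$bootstrap_B, 200), seed = seed))
  for (gt in intersect(config$sensitivity, c("recombinant", "urinary")))
    bundle[[paste0("sensitivity_", gt)]] <- stage(
      paste0("sensitivity_", gt),
      sensitivity_gonadotropin_subset(cohort, gt, config$covariates,
                                      config$policy, config$gee,
                                      config$search,
                                      B = min(config$bootstrap_B, 200),
                                      seed = seed))

  bundle$manifest <- list(
    config_hash = .config_hash(config[setdiff(names(config), "outdir")]),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fshthreshold")),
    timestamp = NA_character_)

  if (!is.null(config$outdir)) {
    .write_bundle(bundle, config$outdir)
    return(invisible(bundle))
  }
  bundle
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(outdir, f), auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)
  if (!is.null(bundle$exclusion_report))
    wj(bundle$exclusion_report, "exclusion_report.json")
  if (!is.null(bundle$baseline))
    write.csv(bundle$baseline, file.path(outdir, "baseline_table.csv"),
              row.names = FALSE)
  if (!is.null(bundle$univariate))
    write.csv(bundle$univariate, file.path(outdir, "univariate_screen.csv"),
              row.names = FALSE)
  if (!is.null(bundle$adjusted))
    write.csv(bundle$adjusted, file.path(outdir, "adjusted_model.csv"),
              row.names = FALSE)
  if (!is.null(bundle$smooth))
    write.csv(bundle$smooth$grid, file.path(outdir, "smooth_curve.csv"),
              row.names = FALSE)
  if (!is.null(bundle$threshold)) {
    thr <- bundle$threshold
    write.csv(rbind(cbind(thr$stage1, stage = 1),
                    cbind(thr$stage2, stage = 2)),
              file.path(outdir, "ql_profile.csv"), row.names = FALSE)
    wj(list(K = thr$K_opt,
            ci = if (is.null(thr$ci)) NULL else as.numeric(thr$ci),
            qlr_p = as.numeric(thr$qlr),
            coefficients = thr$fit$coefficients,
            alpha = thr$fit$alpha, phi = thr$fit$phi,
            n_obs = thr$fit$n_obs, n_clusters = thr$fit$n_clusters),
       "threshold_fit.json")
    if (!is.null(thr$cv))
      write.csv(thr$cv$folds, file.path(outdir, "cv_folds.csv"),
                row.names = FALSE)
  }
  if (!is.null(bundle$subgroups)) {
    tabs <- do.call(rbind, lapply(bundle$subgroups, function(s)
      cbind(s$table, p_interaction = s$p_interaction)))
    write.csv(tabs, file.path(outdir, "subgroups.csv"), row.names = FALSE)
  }
  for (nm in grep("^sensitivity_", names(bundle), value = TRUE)) {
    rep_ <- bundle[[nm]]
    wj(list(ok = rep_$ok, design = rep_$design, n_cycles = rep_$n_cycles,
            K = rep_$K,
            ci = if (is.null(rep_$ci)) NULL else as.numeric(rep_$ci),
            qlr_p = if (is.null(rep_$qlr)) NULL else as.numeric(rep_$qlr),
            error = rep_$error),
       paste0(nm, ".json"))
  }
  wj(bundle$manifest, "manifest.json")
  wj(bundle$failures, "failures.json")
  invisible(outdir)
}
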