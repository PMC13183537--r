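# manual two-stratum generator with configurable slopes
make_strata_cohort <- function(n, slope0, slope1, seed, noise_sd = 2) {
  set.seed(seed)
  x <- rlnorm(n, log(12), 0.35)
  g <- rbinom(n, 1, 0.5)
  y <- 15 + ifelse(g == 1, slope1, slope0) * x + rnorm(n, 0, noise_sd)
  co <- make_cohort(n, fsh = x, oocytes = y, pcos = 0L,
                    age = rnorm(n, 33, 4))
  co$pcos <- g
  co
}

test_that("opposite stratum slopes at the reported magnitudes are detected", {
  co <- make_strata_cohort(2000, slope0 = -0.04, slope1 = 1.01, seed = 311)
  res <- stratified_effects(co, strata = list(pcos = list(levels = TRUE)),
                            covariates = c("age", "pcos"))
  expect_lt(res$pcos$p_interaction, 0.001)
  tab <- res$pcos$table
  expect_equal(tab$beta[tab$stratum == "1"], 1.01, tolerance = 0.1)
  expect_equal(tab$beta[tab$stratum == "0"], -0.04, tolerance = 0.1)
})

test_that("the interaction test is calibrated when strata share one slope", {
  ps <- vapply(1:60, function(i) {
    co <- make_strata_cohort(400, slope0 = 0.3, slope1 = 0.3,
                             seed = 5000 + i)
    res <- stratified_effects(co, strata = list(pcos = list(levels = TRUE)),
                              covariates = c("age", "pcos"))
    res$pcos$p_interaction
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("strata are exhaustive and counts reconcile with the eligible cohort", {
  cfg <- default_study_config(n_patients = 800, seed = 313)
  co <- simulate_cohort(cfg, seed = 313)
  res <- stratified_effects(co, strata = default_strata(),
                            covariates = c("age", "amh", "bmi", "pcos", "por"))
  for (v in names(res)) {
    expect_equal(sum(res[[v]]$table$n), res[[v]]$n_total, info = v)
  }
  # numeric cuts are labelled as closed-below intervals
  expect_setequal(res$age$table$stratum, c("< 35", ">= 35"))
  expect_setequal(res$amh$table$stratum, c("< 1.2", "1.2-5", ">= 5"))
})

test_that("a tiny stratum is skipped while the rest are reported", {
  co <- make_strata_cohort(300, 0.3, 0.3, seed = 317)
  co$pcos[co$pcos == 1] <- 0L
  co$pcos[1:5] <- 1L
  expect_warning(
    res <- stratified_effects(co, strata = list(pcos = list(levels = TRUE)),
                              covariates = character()),
    "skipped")
  expect_equal(res$pcos$table$stratum, "0")
})

test_that("an absent stratifying variable is a definition error", {
  co <- make_cohort(50)
  expect_error(stratified_effects(co, strata = list(nope = list(levels = TRUE))),
               "absent")
})

test_that("the first-cycle sensitivity design is idempotent on one-cycle cohorts", {
  cfg <- default_study_config(n_patients = 900, seed = 331,
                                  second_cycle_prob = 0)
  co <- simulate_cohort(cfg, seed = 331)
  covs <- c("age", "amh")
  rep_ <- sensitivity_first_cycle(co, covs, B = 0, seed = 2)
  expect_true(rep_$ok)
  expect_equal(rep_$n_cycles, nrow(co))
  main <- recursive_threshold_search(co, covs)
  expect_equal(rep_$K, main$K_opt)
})

test_that("a cohort too small for the search yields a structured failure", {
  cfg <- default_study_config(n_patients = 25, seed = 337)
  co <- simulate_cohort(cfg, seed = 337)
  rep_ <- sensitivity_first_cycle(co, c("age"), B = 0, seed = 2)
  expect_false(rep_$ok)
  expect_type(rep_$error, "character")
})

test_that("the gonadotropin-subset design restricts, reruns, and validates its input", {
  cfg <- default_study_config(n_patients = 1200, seed = 341,
                                  urinary_prob = 0.5)
  co <- simulate_cohort(cfg, seed = 341)
  expect_error(sensitivity_gonadotropin_subset(co, "equine"), "unknown")
  rep_ <- sensitivity_gonadotropin_subset(co, "urinary", c("age", "amh"),
                                          B = 0, seed = 2)
  expect_true(rep_$ok)
  expect_lt(rep_$n_cycles, nrow(co))
  expect_true(is.numeric(rep_$K))
  # an empty subset fails structurally, not with an uncaught error
  cfg2 <- default_study_config(n_patients = 200, seed = 343)
  co2 <- simulate_cohort(cfg2, seed = 343)  # all recombinant
  rep2 <- sensitivity_gonadotropin_subset(co2, "urinary", c("age"),
                                          B = 0, seed = 2)
  expect_false(rep2$ok)
})

test_that("subset analyses recover distinct breakpoints per gonadotropin type", {
  cfg_r <- default_study_config(n_patients = 2000, seed = 347,
                                    true_K = 9.13)
  cfg_u <- default_study_config(n_patients = 2000, seed = 349,
                                    true_K = 10.45)
  co_r <- simulate_cohort(cfg_r, seed = 347)
  co_u <- simulate_cohort(cfg_u, seed = 349)
  co_u$gonadotropin_type <- factor("urinary",
                                   levels = levels(co_u$gonadotropin_type))
  co_u$patient_id <- paste0("U", co_u$patient_id)
  both <- rbind(as.data.frame(co_r), as.data.frame(co_u))
  co <- as_cohort(both)
  covs <- names(cfg_r$gamma)
  rr <- sensitivity_gonadotropin_subset(co, "recombinant", covs, B = 0, seed = 2)
  ru <- sensitivity_gonadotropin_subset(co, "urinary", covs, B = 0, seed = 2)
  expect_true(rr$ok && ru$ok)
  expect_lt(abs(rr$K - 9.13), 0.8)
  expect_lt(abs(ru$K - 10.45), 0.8)
})
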