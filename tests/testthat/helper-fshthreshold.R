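# Shared fixture builders. Everything is generated in code: no data files.

# minimal hand-built cohort (singleton clusters unless cycles given)
make_cohort <- function(n = 10, fsh = NULL, oocytes = NULL, canceled = 0L,
                        gonadotropin = "recombinant", cycles = NULL, ...) {
  if (!is.null(cycles)) n <- sum(cycles)
  df <- data.frame(
    patient_id = if (is.null(cycles)) sprintf("P%03d", seq_len(n))
                 else rep(sprintf("P%03d", seq_along(cycles)), cycles),
    fsh_day7 = fsh %||% seq(5, 20, length.out = n),
    oocytes = oocytes %||% rep(8, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(cycles))
    df$cycle_index <- unlist(lapply(cycles, seq_len))
  df$canceled <- rep_len(canceled, nrow(df))
  df$gonadotropin_type <- rep_len(gonadotropin, nrow(df))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], nrow(df))
  as_cohort(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent least-squares oracle: solve the normal equations directly
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# brute-force chi-square statistic from a contingency table
chisq_bruteforce <- function(tab) {
  tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / tot
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# noiseless study-scale cohort with the true breakpoint placed exactly on the
# search grid (the 40th exposure percentile), so recovery must be exact
noiseless_grid_cohort <- function(n_patients = 1500, seed = 77,
                                  pct = 0.40, ...) {
  cfg0 <- default_study_config(n_patients = n_patients, seed = seed,
                                   sigma = 0, ...)
  probe <- simulate_cohort(cfg0, seed = seed)
  K_grid <- unname(quantile(probe$fsh_day7, pct, type = 7))
  cfg <- default_study_config(n_patients = n_patients, seed = seed,
                                  sigma = 0, ...)
  cfg$true_K <- K_grid
  co <- simulate_cohort(cfg, seed = seed)
  stopifnot(identical(co$fsh_day7, probe$fsh_day7))
  list(cohort = co, config = cfg, K = K_grid)
}
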