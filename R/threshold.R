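#' Breakpoint search configuration
#'
#' Controls the two-stage recursive quasi-likelihood search: a global screen
#' over exposure percentiles `grid_start`..`grid_stop` in steps of
#' `grid_step`, then a refinement of `refine_halfwidth` percentile points
#' around the stage-1 winner at `refine_step`-point steps, clamped to the
#' global bounds. Candidates leaving fewer than `min_segment` observations on
#' either side of the breakpoint are skipped (and logged).
#'
#' @param grid_start,grid_stop,grid_step stage-1 percentiles (default 5..95
#'   by 5).
#' @param refine_halfwidth,refine_step stage-2 window half-width and step in
#'   percentile points (default +/- 4 by 1).
#' @param min_segment minimum observations per side; default
#'   `max(20, 2 * n_parameters)`.
#' @return A `search_config` list.
#' @export
search_config <- function(grid_start = 5, grid_stop = 95, grid_step = 5,
                          refine_halfwidth = 4, refine_step = 1,
                          min_segment = NULL) {
  stopifnot(grid_start >= 1, grid_stop <= 99, grid_start < grid_stop,
            grid_step >= 1, refine_halfwidth >= 0, refine_step >= 1)
  structure(list(grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step, refine_halfwidth = refine_halfwidth,
                 refine_step = refine_step, min_segment = min_segment),
            class = "search_config")
}

# Resampled / subset designs can lose a rare factor level entirely, leaving
# an all-constant dummy column; drop such columns (never the intercept) so
# the replicate fit stays full rank.
.drop_constant_cols <- function(Z) {
  if (ncol(Z) <= 1) return(Z)
  keep <- c(TRUE, vapply(2:ncol(Z), function(j) {
    x <- Z[, j]
    any(x != x[1])
  }, logical(1)))
  Z[, keep, drop = FALSE]
}

# Evaluate QL at exposure-percentile candidates with the working alpha and
# dispersion phi held at their linear-model values, so candidate comparison
# is monotone in weighted RSS (one WLS solve per candidate).
.eval_candidates <- function(prep, pcts, alpha, phi, min_segment) {
  Ks <- quantile(prep$fsh, pcts / 100, type = 7, names = FALSE)
  n_below <- vapply(Ks, function(k) sum(prep$fsh < k), integer(1))
  n_above <- prep$n - n_below
  ok <- n_below >= min_segment & n_above >= min_segment
  ql <- rep(NA_real_, length(Ks))
  if (any(ok)) {
    rss <- .hinge_rss_profile_cpp(prep$Z, prep$fsh, prep$y, prep$csize,
                                  Ks[ok], alpha)
    ql[ok] <- -rss / (2 * phi)
  }
  data.frame(percentile = pcts, K = Ks, quasi_likelihood = ql,
             skipped = !ok | is.na(ql))
}

# core search on a prepared frame; returns trace + K_opt (no final refit)
.search_K <- function(prep, spec, config) {
  lin <- .fit_linear_prepared(prep, spec)
  min_seg <- config$min_segment %||% max(20, 2 * (ncol(prep$Z) + 2))
  p1 <- seq(config$grid_start, config$grid_stop, by = config$grid_step)
  s1 <- .eval_candidates(prep, p1, lin$alpha, lin$phi, min_seg)
  if (all(s1$skipped))
    stop(structure(class = c("search_error", "error", "condition"),
                   list(message = "all stage-1 candidates skipped (min_segment)",
                        call = NULL)))
  best1 <- which(!s1$skipped)[order(-s1$quasi_likelihood[!s1$skipped],
                                    s1$K[!s1$skipped])][1]
  pstar <- s1$percentile[best1]
  p2 <- seq(max(config$grid_start, pstar - config$refine_halfwidth),
            min(config$grid_stop, pstar + config$refine_halfwidth),
            by = config$refine_step)
  s2 <- .eval_candidates(prep, p2, lin$alpha, lin$phi, min_seg)
  all_cand <- rbind(cbind(s1, stage = 1L), cbind(s2, stage = 2L))
  live <- all_cand[!all_cand$skipped, , drop = FALSE]
  pick <- live[order(-live$quasi_likelihood, live$K), ][1, ]
  list(K_opt = pick$K, stage1 = s1, stage2 = s2,
       alpha = lin$alpha, phi = lin$phi, linear = lin, min_segment = min_seg)
}

#' Recursive quasi-likelihood breakpoint search
#'
#' Stage 1 screens the 5th--95th exposure percentiles at 5-point intervals;
#' stage 2 re-searches +/- 4 percentile points around the stage-1 winner at
#' 1-point steps, clamped to the global bounds. The optimal breakpoint
#' maximizes the Gaussian quasi-likelihood over every evaluated candidate
#' (ties broken toward the smallest K). While profiling, the working
#' correlation and dispersion are held at their linear-model estimates; the
#' returned fit re-estimates the full GEE at the optimum.
#'
#' @param cohort an `fsh_cohort`.
#' @param covariates adjustment columns.
#' @param spec a [gee_spec()].
#' @param config a [search_config()].
#' @param outcome,exposure column names.
#' @return A `threshold_search` object: `K_opt`, the full candidate traces
#'   (`stage1`, `stage2`), the refitted `segmented_fit` (`fit`), and slots
#'   for the bootstrap CI (`ci`), threshold-test p (`qlr`) and CV summary
#'   (`cv`) filled by the respective functions.
#' @export
recursive_threshold_search <- function(cohort, covariates = character(),
                                       spec = gee_spec(),
                                       config = search_config(),
                                       outcome = "oocytes",
                                       exposure = "fsh_day7") {
  prep <- .prepare_gee_data(cohort, covariates, spec, outcome, exposure)
  res <- .search_K(prep, spec, config)
  fit <- .fit_segmented_prepared(prep, res$K_opt, spec)
  structure(list(K_opt = res$K_opt, stage1 = res$stage1, stage2 = res$stage2,
                 fit = fit, profile_alpha = res$alpha,
                 profile_phi = res$phi, min_segment = res$min_segment,
                 linear_rss = res$linear$rss,
                 covariates = covariates, spec = spec, config = config,
                 outcome = outcome, exposure = exposure,
                 ci = NULL, qlr = NULL, cv = NULL),
            class = "threshold_search")
}

#' Cluster-bootstrap percentile CI for the breakpoint
#'
#' Resamples patients (clusters) with replacement to the original cluster
#' count, reruns the recursive search in each replicate, and returns the
#' 2.5th and 97.5th percentiles of the replicate breakpoints. Resampling
#' clusters, not cycles, preserves the within-patient correlation.
#'
#' @param cohort an `fsh_cohort`.
#' @param covariates,spec,config,outcome,exposure as in
#'   [recursive_threshold_search()].
#' @param B number of bootstrap replicates (>= 100 for reporting).
#' @param seed integer seed (mandatory for reproducibility).
#' @return Numeric `c(low, high)` with attributes `"K_boot"` (the replicate
#'   estimates) and `"n_failed"`.
#' @export
bootstrap_breakpoint_ci <- function(cohort, covariates = character(),
                                    spec = gee_spec(),
                                    config = search_config(),
                                    B = 1000, seed = 1L,
                                    outcome = "oocytes",
                                    exposure = "fsh_day7") {
  stopifnot(B >= 1)
  if (B < 100)
    warning("B < 100 bootstrap replicates is below reporting grade",
            call. = FALSE)
  prep <- .prepare_gee_data(cohort, covariates, spec, outcome, exposure)
  k <- prep$n_clusters
  ends <- cumsum(prep$csize)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rowlist <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  Ks <- rep(NA_real_, B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      pick <- sample.int(k, k, replace = TRUE)
      idx <- unlist(rowlist[pick], use.names = FALSE)
      prep_b <- list(y = prep$y[idx], fsh = prep$fsh[idx],
                     Z = .drop_constant_cols(prep$Z[idx, , drop = FALSE]),
                     csize = prep$csize[pick], n = length(idx),
                     n_clusters = k)
      Ks[b] <- tryCatch(.search_K(prep_b, spec, config)$K_opt,
                        error = function(e) NA_real_)
    }
  })
  n_failed <- sum(is.na(Ks))
  if (n_failed > 0.2 * B)
    stop(structure(class = c("bootstrap_error", "error", "condition"),
                   list(message = sprintf(
                     "%d of %d bootstrap searches failed", n_failed, B),
                     call = NULL)))
  ci <- quantile(Ks, c(0.025, 0.975), na.rm = TRUE, names = FALSE, type = 7)
  structure(ci, K_boot = Ks, n_failed = n_failed, B = B)
}

#' Quasi-likelihood ratio test of the threshold effect
#'
#' Compares the two-piece-wise segmented GEE model with the nested
#' single-slope linear model on the same complete-case rows:
#' `statistic = 2 * (QL_segmented - QL_linear)` with both quasi-likelihoods
#' computed at the linear model's dispersion, referred to a chi-square with
#' 1 df (the added slope parameter). Because the breakpoint is estimated
#' from the same data, the reference distribution is anti-conservative; the
#' returned p carries that note in its attributes.
#'
#' @param cohort an `fsh_cohort`.
#' @param fit a `segmented_fit` obtained on this cohort.
#' @param covariates,spec,outcome,exposure as used for `fit`.
#' @return The p-value, with attributes `statistic`, `df`, and `note`.
#' @export
qlr_threshold_test <- function(cohort, fit, covariates = character(),
                               spec = gee_spec(), outcome = "oocytes",
                               exposure = "fsh_day7") {
  stopifnot(inherits(fit, "segmented_fit"))
  prep <- .prepare_gee_data(cohort, covariates, spec, outcome, exposure)
  if (prep$n != fit$n_obs)
    stop(structure(class = c("model_comparison_error", "error", "condition"),
                   list(message = sprintf(
                     "row sets differ: segmented fit used %d rows, linear model has %d",
                     fit$n_obs, prep$n), call = NULL)))
  lin <- .fit_linear_prepared(prep, spec)
  stat <- max(0, (lin$rss - fit$rss) / lin$phi)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(p, statistic = stat, df = 1,
            note = paste("chi-square(1) reference is approximate and",
                         "anti-conservative because K is estimated"))
}

#' Grouped 10-fold cross-validation of the threshold model
#'
#' Folds partition patients (clusters), never cycles, so no patient appears
#' in both training and test data. Per fold, the breakpoint search and both
#' the segmented and the linear GEE fits run on the training clusters; mean
#' squared prediction error is computed on the held-out cycles.
#'
#' @param cohort an `fsh_cohort`.
#' @param covariates,spec,config,outcome,exposure as in
#'   [recursive_threshold_search()].
#' @param folds number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @return A `threshold_cv` object: per-fold table (`fold`, `K`, `n_test`,
#'   `mse_segmented`, `mse_linear`) and pooled errors.
#' @export
cross_validate_threshold <- function(cohort, covariates = character(),
                                     spec = gee_spec(),
                                     config = search_config(),
                                     folds = 10, seed = 1L,
                                     outcome = "oocytes",
                                     exposure = "fsh_day7") {
  stopifnot(folds >= 2)
  prep <- .prepare_gee_data(cohort, covariates, spec, outcome, exposure)
  k <- prep$n_clusters
  if (k < folds) stop("fewer clusters than folds")
  fold_of_cluster <- with_seed(seed,
    sample(rep_len(seq_len(folds), k)))
  ends <- cumsum(prep$csize)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rowlist <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_cl <- which(fold_of_cluster == f)
    train_cl <- which(fold_of_cluster != f)
    test_idx <- unlist(rowlist[test_cl], use.names = FALSE)
    train_idx <- unlist(rowlist[train_cl], use.names = FALSE)
    if (!length(test_idx))
      stop(structure(class = c("fold_error", "error", "condition"),
                     list(message = sprintf("fold %d has no test cycles", f),
                          call = NULL)))
    Ztr <- prep$Z[train_idx, , drop = FALSE]
    keep_cols <- colnames(.drop_constant_cols(Ztr))
    prep_tr <- list(y = prep$y[train_idx], fsh = prep$fsh[train_idx],
                    Z = Ztr[, keep_cols, drop = FALSE],
                    csize = prep$csize[train_cl], n = length(train_idx),
                    n_clusters = length(train_cl),
                    covariates = prep$covariates)
    res <- .search_K(prep_tr, spec, config)
    seg <- .fit_segmented_prepared(prep_tr, res$K_opt, spec)
    lin <- .fit_linear_prepared(prep_tr, spec)
    # predictions on held-out cycles
    H <- hinge_design(prep$fsh[test_idx], res$K_opt)
    Zte <- prep$Z[test_idx, keep_cols, drop = FALSE]
    Xs <- cbind(Zte, H)
    est <- seg$coefficients$estimate
    mu_seg <- drop(Xs %*% est)
    Xl <- cbind(Zte, prep$fsh[test_idx])
    mu_lin <- drop(Xl %*% lin$beta)
    yt <- prep$y[test_idx]
    per_fold[[f]] <- data.frame(
      fold = f, K = res$K_opt, n_test = length(test_idx),
      mse_segmented = mean((yt - mu_seg)^2),
      mse_linear = mean((yt - mu_lin)^2))
  }
  tab <- do.call(rbind, per_fold)
  w <- tab$n_test / sum(tab$n_test)
  structure(list(folds = tab,
                 pooled_mse_segmented = sum(w * tab$mse_segmented),
                 pooled_mse_linear = sum(w * tab$mse_linear),
                 n_folds = folds, seed = seed),
            class = "threshold_cv")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("Recursive threshold search: K_opt = %.4g (%d + %d candidates)\n",
              x$K_opt, nrow(x$stage1), nrow(x$stage2)))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI: [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  if (!is.null(x$qlr))
    cat(sprintf("  QLR threshold test p = %.3g\n", as.numeric(x$qlr)))
  print(x$fit)
  invisible(x)
}

#' @export
print.threshold_cv <- function(x, ...) {
  cat(sprintf("%d-fold grouped CV: pooled MSE segmented = %.3f, linear = %.3f\n",
              x$n_folds, x$pooled_mse_segmented, x$pooled_mse_linear))
  invisible(x)
}
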