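test_that("chi-square on reference PCOS-by-tertile counts matches a brute-force computation", {
  # 1112 / 132 / 13 PCOS cases in three tertiles of 3323 cycles each
  counts <- c(1112, 132, 13)
  pcos <- unlist(lapply(counts, function(k) rep(c(1L, 0L), c(k, 3323 - k))))
  tert <- rep(c("low", "medium", "high"), each = 3323)
  co <- make_cohort(3 * 3323, fsh = rep(c(8, 13, 19), each = 3323),
                    pcos = 0L)
  co$pcos <- pcos
  co$tertile <- factor(tert, levels = c("low", "medium", "high"))
  tab <- baseline_table(co, variables = "pcos")
  oracle <- chisq_bruteforce(table(pcos, tert))
  expect_equal(tab$statistic, oracle, tolerance = 1e-6)
  expect_equal(tab$test, "chi_square")
  expect_lt(tab$p_value, 1e-10)
})

test_that("identical column proportions give chi-square statistic 0, p 1", {
  co <- make_cohort(60, pcos = rep(c(1, 0), 30))
  co$tertile <- factor(rep(c("low", "medium", "high"), each = 20),
                       levels = c("low", "medium", "high"))
  tab <- baseline_table(co, variables = "pcos")
  expect_equal(tab$statistic, 0, tolerance = 1e-12)
  expect_equal(tab$p_value, 1, tolerance = 1e-12)
})

test_that("test selection follows the skewness policy", {
  set.seed(2)
  co <- make_cohort(600, age = rnorm(600, 33, 4), amh = rlnorm(600, 0.5, 1))
  co <- assign_tertiles(co)
  tab <- baseline_table(co, variables = c("age", "amh"))
  expect_equal(tab$test[tab$variable == "age"], "anova")
  expect_equal(tab$test[tab$variable == "amh"], "kruskal_wallis")
})

test_that("a group with zero records is refused", {
  co <- make_cohort(10)
  co$tertile <- factor(rep("low", 10), levels = c("low", "medium", "high"))
  expect_error(baseline_table(co), "group")
})

test_that("ANOVA on two groups equals the squared pooled t statistic", {
  set.seed(5)
  x <- c(rnorm(40, 10), rnorm(40, 11))
  g <- factor(rep(c("a", "b"), each = 40))
  F_aov <- summary(aov(x ~ g))[[1]][["F value"]][1]
  t_stat <- t.test(x ~ g, var.equal = TRUE)$statistic
  expect_equal(F_aov, unname(t_stat^2), tolerance = 1e-10)
})

test_that("a perfect linear relationship gives the exact slope with zero-width CI", {
  co <- make_cohort(5, fsh = 1:5, oocytes = 2 * (1:5))
  eff <- univariate_effects(co, exposures = "fsh_day7")
  expect_equal(eff$beta, 2, tolerance = 1e-12)
  expect_equal(eff$ci_high - eff$ci_low, 0, tolerance = 1e-9)
})

test_that("univariate slopes agree with the normal-equations oracle on random data", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    x <- rnorm(n, 12, 2)
    y <- rnorm(n, 1 + 0.7 * x)
    co <- make_cohort(n, fsh = x, oocytes = y)
    eff <- univariate_effects(co, exposures = "fsh_day7")
    b <- ols_oracle(cbind(1, x), y)
    expect_equal(eff$beta, b[2], tolerance = 1e-10)
  }
})

test_that("the univariate slope recovers a simulated effect within sampling bounds", {
  set.seed(3)
  n <- 10000
  x <- rnorm(n, 10, 2)
  y <- 13 - 0.5 * x + rnorm(n)
  eff <- univariate_effects(make_cohort(n, fsh = x, oocytes = y),
                            exposures = "fsh_day7")
  expect_gt(eff$beta, -0.53)
  expect_lt(eff$beta, -0.47)
})

test_that("categorical exposures expand against the stated reference level", {
  set.seed(8)
  lv <- c("tubal", "male", "ovulatory")
  f <- factor(sample(lv, 300, TRUE, prob = c(0.7, 0.2, 0.1)), levels = lv)
  y <- c(tubal = 5, male = 6, ovulatory = 9)[as.character(f)] + rnorm(300)
  co <- make_cohort(300, oocytes = y)
  co$infertility_factor <- f
  eff <- univariate_effects(co, exposures = "infertility_factor")
  expect_equal(nrow(eff), 2)  # most frequent level (tubal) is the reference
  expect_false(any(grepl("tubal", eff$term)))
  ov <- eff$beta[grepl("ovulatory", eff$term)]
  expect_equal(ov, 4, tolerance = 0.5)
})

test_that("constant exposures are skipped with a warning, others unaffected", {
  co <- make_cohort(20, age = 30)
  expect_warning(eff <- univariate_effects(co, exposures = c("age", "fsh_day7")),
                 "constant")
  expect_equal(eff$exposure, "fsh_day7")
})

test_that("adjusted_effect with no covariates reduces to the univariate fit", {
  set.seed(13)
  co <- make_cohort(100, fsh = rnorm(100, 12, 3),
                    oocytes = rnorm(100, 9, 2))
  a <- adjusted_effect(co, "fsh_day7")
  u <- univariate_effects(co, exposures = "fsh_day7")
  expect_equal(a$beta, u$beta, tolerance = 1e-12)
  expect_equal(a$p_value, u$p_value, tolerance = 1e-12)
})

test_that("adjustment recovers a direct effect masked by confounding", {
  set.seed(17)
  reps <- 30
  crude <- adj <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 800
    z <- rnorm(n)                      # confounder
    x <- 10 + 1.5 * z + rnorm(n)       # exposure depends on z
    y <- 15 + 0.3 * x + 2.5 * z + rnorm(n)
    co <- make_cohort(n, fsh = x, oocytes = y, amh = z)
    crude[i] <- univariate_effects(co, exposures = "fsh_day7")$beta
    adj[i] <- adjusted_effect(co, "fsh_day7", covariates = "amh")$beta
  }
  expect_lt(abs(mean(adj) - 0.3), 0.03)
  expect_gt(abs(mean(crude) - 0.3), 0.5)
})

test_that("a duplicated covariate column raises a collinearity error", {
  set.seed(19)
  co <- make_cohort(50, fsh = rnorm(50, 12), oocytes = rnorm(50, 9),
                    age = rnorm(50, 33))
  co$age2 <- co$age
  expect_error(adjusted_effect(co, "fsh_day7", covariates = c("age", "age2")),
               class = "collinearity_error")
})

test_that("CI excludes zero exactly when p < 0.05 (normal-theory duality)", {
  set.seed(23)
  for (i in 1:25) {
    n <- 60
    x <- rnorm(n, 12, 2)
    y <- rnorm(n, 8 + 0.2 * (x - 12))
    eff <- univariate_effects(make_cohort(n, fsh = x, oocytes = y),
                              exposures = "fsh_day7")
    excludes <- eff$ci_low > 0 || eff$ci_high < 0
    expect_equal(excludes, eff$p_value < 0.05)
    expect_true(eff$ci_low <= eff$beta && eff$beta <= eff$ci_high)
  }
})

test_that("the trend test is powerful under a strong ordered separation", {
  set.seed(29)
  n <- 3000
  fsh <- runif(n, 5, 20)
  co <- make_cohort(n, fsh = fsh, oocytes = 0)
  co <- assign_tertiles(co)
  co$oocytes <- c(low = 5, medium = 9, high = 13)[as.character(co$tertile)] +
    rnorm(n)
  expect_lt(as.numeric(trend_test(co)), 1e-6)
})

test_that("the trend test is calibrated under the null and label-exchangeable", {
  set.seed(31)
  p_null <- replicate(60, {
    n <- 300
    co <- make_cohort(n, fsh = runif(n, 5, 20), oocytes = rnorm(n, 9))
    co <- assign_tertiles(co)
    as.numeric(trend_test(co))
  })
  expect_gte(mean(p_null < 0.05), 0)
  expect_lte(mean(p_null < 0.05), 0.15)
  # permuting group labels leaves the null behavior unchanged
  set.seed(32)
  co <- assign_tertiles(make_cohort(300, fsh = runif(300, 5, 20),
                                    oocytes = rnorm(300, 9)))
  co2 <- co
  co2$tertile <- sample(co2$tertile)
  expect_gt(as.numeric(trend_test(co2)), 1e-4)
})

test_that("fewer than 3 represented groups abort the trend test", {
  co <- make_cohort(10)
  co$tertile <- factor(rep(c("low", "high"), 5),
                       levels = c("low", "medium", "high"))
  expect_error(trend_test(co), "3 groups")
})
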