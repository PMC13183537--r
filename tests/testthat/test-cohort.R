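test_that("a well-formed delimited file parses into typed records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,fsh_day7,oocytes,age",
               "A,8.2,10,31", "B,12.5,7,35", "C,16.1,4,38"), f)
  co <- read_cohort(f)
  expect_s3_class(co, "fsh_cohort")
  expect_equal(nrow(co), 3)
  expect_equal(length(unique(co$patient_id)), 3)
  expect_type(co$fsh_day7, "double")
  expect_equal(co$oocytes, c(10, 7, 4))
})

test_that("header aliases and case are resolved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,Day7_FSH,Oocyte_Count", "A,8.2,10"), f)
  co <- read_cohort(f)
  expect_named(co, c("patient_id", "fsh_day7", "oocytes", "cycle_index"),
               ignore.order = TRUE)
})

test_that("blank exposure cells become missing values, retained for later exclusion", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,fsh_day7,oocytes", "A,8.2,10", "B,,7"), f)
  co <- read_cohort(f)
  expect_equal(nrow(co), 2)
  expect_true(is.na(co$fsh_day7[2]))
})

test_that("strict mode aborts naming the offending row and field", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,fsh_day7,oocytes", "A,8.2,10", "B,9.1,-1"), f)
  expect_error(read_cohort(f, strict = TRUE),
               "row 2, field 'oocytes'", class = "cohort_schema_error")
  expect_warning(co <- read_cohort(f), "oocytes")
  expect_true(is.na(co$oocytes[2]))
})

test_that("missing mandatory columns and empty files are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age", "A,31"), f)
  expect_error(read_cohort(f), "fsh_day7", class = "cohort_schema_error")
  f2 <- withr::local_tempfile(fileext = ".csv")
  file.create(f2)
  expect_error(read_cohort(f2), class = "cohort_empty_error")
})

test_that("exclusion counts mirror the flow chart and sum to rows removed", {
  co <- make_cohort(10, canceled = c(1, 1, rep(0, 8)),
                    fsh = c(rep(9, 9), NA))
  out <- apply_exclusions(co)
  rep_ <- attr(out, "exclusion_report")
  expect_equal(nrow(out), 7)
  expect_equal(rep_$canceled, 2)
  expect_equal(rep_$missing_day7, 1)
  expect_equal(rep_$input_n - rep_$output_n, rep_$canceled + rep_$missing_day7)
})

test_that("gonadotropin-type restriction keeps only the named type", {
  co <- make_cohort(6, gonadotropin = c("recombinant", "urinary"))
  out <- apply_exclusions(co, exclusion_policy(gonadotropin_type = "recombinant"))
  expect_true(all(out$gonadotropin_type == "recombinant"))
  expect_equal(nrow(out), 3)
})

test_that("excluding every record yields an empty cohort with a warning", {
  co <- make_cohort(4, canceled = 1L)
  expect_warning(out <- apply_exclusions(co), "all records excluded")
  expect_equal(nrow(out), 0)
  expect_error(recursive_threshold_search(out), "empty")
})

test_that("tertiles of 1..9 split symmetrically", {
  co <- make_cohort(9, fsh = as.numeric(1:9))
  co <- assign_tertiles(co)
  expect_equal(as.character(co$tertile),
               rep(c("low", "medium", "high"), each = 3))
})

test_that("tertile group sizes match a sort-and-slice oracle on continuous draws", {
  set.seed(101)
  x <- rlnorm(3000, 2.5, 0.4)
  co <- make_cohort(3000, fsh = x)
  co <- assign_tertiles(co)
  expect_true(all(abs(table(co$tertile) - 1000) <= 1))
})

test_that("ties at a cut land in one group and labels ignore record order", {
  x <- c(rep(5, 40), rep(10, 30), rep(20, 30))
  co <- assign_tertiles(make_cohort(100, fsh = x))
  # all tied 10s share a label
  expect_equal(length(unique(co$tertile[x == 10])), 1L)
  perm <- sample(100)
  co2 <- assign_tertiles(make_cohort(100, fsh = x[perm]))
  expect_equal(as.character(co2$tertile), as.character(co$tertile)[perm])
})

test_that("tertile labels are invariant to strictly monotone transformation", {
  set.seed(7)
  x <- rlnorm(300, 2.4, 0.5)
  a <- assign_tertiles(make_cohort(300, fsh = x))
  b <- assign_tertiles(make_cohort(300, fsh = exp(x / 10)))
  expect_equal(as.character(a$tertile), as.character(b$tertile))
})

test_that("fewer than 3 distinct values cannot form tertiles", {
  expect_error(assign_tertiles(make_cohort(6, fsh = rep(c(5, 9), 3))),
               class = "tertile_error")
})

test_that("first-cycle subset keeps exactly one minimal-index cycle per patient", {
  co <- make_cohort(cycles = c(2, 1))
  out <- first_cycle_subset(co)
  expect_equal(nrow(out), 2)
  expect_true(all(out$cycle_index == 1))
  # idempotent on an already one-cycle cohort
  expect_equal(nrow(first_cycle_subset(out)), 2)
  # count equals distinct patients on a simulated mixed cohort
  cfg <- default_study_config(n_patients = 1000, seed = 5)
  sim <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(first_cycle_subset(sim)), 1000)
})

test_that("duplicate (patient, cycle) pairs are ambiguous", {
  df <- data.frame(patient_id = c("A", "A"), cycle_index = c(1, 1),
                   fsh_day7 = c(8, 9), oocytes = c(5, 6))
  expect_error(first_cycle_subset(as_cohort(df)),
               class = "cycle_ambiguity_error")
})

test_that("write/read round trip is lossless, including missing cells", {
  cfg <- default_study_config(n_patients = 60, seed = 9,
                                  round_and_clip = TRUE)
  co <- simulate_cohort(cfg, seed = 9)
  co$amh[c(3, 10)] <- NA
  co <- assign_tertiles(co)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  for (col in names(co)) {
    expect_equal(unname(back[[col]]), unname(co[[col]]),
                 info = col, tolerance = 0)
  }
  expect_true(all(is.na(back$amh[c(3, 10)])))
})

test_that("full double precision survives the round trip bit-for-bit", {
  co <- make_cohort(5, fsh = c(pi, exp(1), sqrt(2), 1/3, 9.13),
                    oocytes = c(1.1, 2.2, 3.3, 0, 57) / 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_identical(back$fsh_day7, co$fsh_day7)
  expect_identical(back$oocytes, co$oocytes)
})

test_that("an empty cohort writes a header-only file", {
  co <- make_cohort(2)[integer(0), ]
  class(co) <- c("fsh_cohort", "data.frame")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_equal(length(readLines(f)), 1L)
})
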