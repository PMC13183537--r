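#' Cycle-level cohort data structures and I/O
#'
#' A cohort is one row per IVF cycle: a patient (cluster) identifier, the
#' Day-7 serum FSH exposure (mIU/mL), the oocyte-yield outcome, and the
#' adjustment covariates used throughout the pipeline. `fsh_cohort` objects
#' are plain data frames carrying a validated schema plus derived columns
#' (`tertile`, `first_cycle`) once assigned.
#'
#' @name cohort
NULL

# schema: column -> storage type
# num = double, int = integer, flag = 0/1, cat = closed vocabulary, id = char
.cohort_schema <- function() {
  list(
    patient_id = "id", cycle_index = "int",
    fsh_day7 = "num", fsh_day1 = "num", oocytes = "num",
    age = "num", infertility_duration = "num", bmi = "num",
    amh = "num", afc = "int", pcos = "flag", por = "flag",
    infertility_factor = "cat", initial_dose = "num", total_dose = "num",
    gonadotropin_type = "cat", canceled = "flag",
    tertile = "cat", first_cycle = "flag"
  )
}

.cohort_vocab <- list(
  infertility_factor = c("tubal", "endometriosis", "ovulatory", "male",
                         "unexplained", "immune", "other"),
  gonadotropin_type = c("recombinant", "urinary"),
  tertile = c("low", "medium", "high")
)

.mandatory_cols <- c("patient_id", "fsh_day7", "oocytes")

# header aliases (lower-cased, punctuation collapsed to "_")
.cohort_aliases <- c(
  id = "patient_id", patient = "patient_id", subject_id = "patient_id",
  cycle = "cycle_index", cycle_number = "cycle_index",
  day7_fsh = "fsh_day7", fsh7 = "fsh_day7", serum_fsh_day7 = "fsh_day7",
  day1_fsh = "fsh_day1", fsh1 = "fsh_day1", baseline_fsh = "fsh_day1",
  oocyte_count = "oocytes", n_oocytes = "oocytes",
  oocytes_retrieved = "oocytes",
  duration = "infertility_duration",
  duration_of_infertility = "infertility_duration",
  antral_follicle_count = "afc",
  cancelled = "canceled"
)

.norm_header <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

.schema_error <- function(msg) {
  stop(structure(class = c("cohort_schema_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Construct / validate a cohort
#'
#' Coerces a data frame to the cohort schema and validates its invariants:
#' non-negative oocyte counts, strictly positive Day-7 FSH where present,
#' cycle indices of at least 1, and categorical values drawn from the closed
#' vocabularies. In strict mode any violation aborts with the offending row
#' and field; otherwise offending cells are set to missing with a warning.
#'
#' @param df data frame with (a subset of) the schema columns.
#' @param strict abort on any schema violation instead of repairing to `NA`.
#' @return An `fsh_cohort` data frame with typed columns.
#' @export
as_cohort <- function(df, strict = FALSE) {
  stopifnot(is.data.frame(df))
  schema <- .cohort_schema()
  names(df) <- .resolve_headers(names(df))
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols))
    .schema_error(paste0("missing mandatory column(s): ",
                         paste(missing_cols, collapse = ", ")))
  out <- df[intersect(names(schema), names(df))]
  extra <- setdiff(names(df), names(schema))
  if (length(extra) && strict)
    .schema_error(paste0("unknown column(s): ", paste(extra, collapse = ", ")))
  for (col in names(out))
    out[[col]] <- .coerce_column(out[[col]], col, schema[[col]], strict)
  out <- .check_invariants(out, strict)
  if (is.null(out$cycle_index)) out$cycle_index <- rep(1L, nrow(out))
  class(out) <- c("fsh_cohort", "data.frame")
  attr(out, "schema_version") <- "1.0"
  out
}

.resolve_headers <- function(nm) {
  nm <- .norm_header(nm)
  hit <- nm %in% names(.cohort_aliases)
  nm[hit] <- unname(.cohort_aliases[nm[hit]])
  nm
}

.coerce_column <- function(x, col, type, strict) {
  if (type == "id") return(as.character(x))
  if (type == "cat") {
    x <- trimws(tolower(as.character(x)))
    x[x == ""] <- NA_character_
    bad <- which(!is.na(x) & !(x %in% .cohort_vocab[[col]]))
    if (length(bad)) {
      if (strict)
        .schema_error(sprintf(
          "row %d, field '%s': value '%s' not in {%s}", bad[1], col,
          x[bad[1]], paste(.cohort_vocab[[col]], collapse = ", ")))
      warning(sprintf("%d value(s) of '%s' outside vocabulary set to NA",
                      length(bad), col), call. = FALSE)
      x[bad] <- NA_character_
    }
    return(factor(x, levels = .cohort_vocab[[col]]))
  }
  # numeric-like types
  if (is.character(x) || is.factor(x)) {
    xc <- trimws(as.character(x))
    xc[xc == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(xc))
    bad <- which(!is.na(xc) & is.na(num))
    if (length(bad)) {
      if (strict)
        .schema_error(sprintf("row %d, field '%s': unparseable value '%s'",
                              bad[1], col, xc[bad[1]]))
      warning(sprintf("%d unparseable value(s) in '%s' set to NA",
                      length(bad), col), call. = FALSE)
    }
    x <- num
  } else x <- as.numeric(x)
  if (type %in% c("int", "flag")) {
    xi <- suppressWarnings(as.integer(round(x)))
    x <- xi
  }
  x
}

.check_invariants <- function(df, strict) {
  fail <- function(rows, col, what) {
    if (!length(rows)) return(df[[col]])
    if (strict)
      .schema_error(sprintf("row %d, field '%s': %s", rows[1], col, what))
    warning(sprintf("%d row(s) violate '%s' (%s); set to NA",
                    length(rows), col, what), call. = FALSE)
    df[[col]][rows] <<- NA
    df[[col]]
  }
  if (!is.null(df$oocytes))
    df$oocytes <- fail(which(!is.na(df$oocytes) & df$oocytes < 0),
                       "oocytes", "must be >= 0")
  if (!is.null(df$fsh_day7))
    df$fsh_day7 <- fail(which(!is.na(df$fsh_day7) & df$fsh_day7 <= 0),
                        "fsh_day7", "must be > 0")
  if (!is.null(df$cycle_index))
    df$cycle_index <- fail(which(!is.na(df$cycle_index) & df$cycle_index < 1),
                           "cycle_index", "must be >= 1")
  for (col in c("pcos", "por", "canceled", "first_cycle")) {
    if (!is.null(df[[col]]))
      df[[col]] <- fail(which(!is.na(df[[col]]) & !(df[[col]] %in% 0:1)),
                        col, "must be 0/1")
  }
  invisible(df)
}

#' Read a cohort from a delimited file
#'
#' Comma-delimited UTF-8 with a header row; missing values are empty cells.
#' Header names are matched case-insensitively against the schema with a
#' small alias table (`day7_fsh`, `oocyte_count`, ...).
#'
#' @param path file path.
#' @param strict abort on any schema violation (see [as_cohort()]).
#' @return An `fsh_cohort`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    stop(structure(class = c("cohort_empty_error", "error", "condition"),
                   list(message = paste0("empty input file: ", path),
                        call = NULL)))
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  if (nrow(df) == 0 && ncol(df) == 0)
    stop(structure(class = c("cohort_empty_error", "error", "condition"),
                   list(message = paste0("empty input file: ", path),
                        call = NULL)))
  as_cohort(df, strict = strict)
}

#' Write a cohort to a delimited file
#'
#' Serializes with full double precision (`%.17g`) so that
#' `read_cohort(write_cohort(x))` reproduces every finite numeric value
#' exactly; missing values become empty cells.
#'
#' @param cohort an `fsh_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    x <- out[[col]]
    if (is.double(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- ""
      out[[col]] <- s
    } else if (is.factor(x)) {
      s <- as.character(x)
      s[is.na(s)] <- ""
      out[[col]] <- s
    } else {
      s <- as.character(x)
      s[is.na(x)] <- ""
      out[[col]] <- s
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write cohort to: ", path)
  invisible(path)
}

#' Exclusion policy for cohort eligibility
#'
#' Default policy mirrors the study design: drop canceled cycles, drop cycles
#' without a Day-7 FSH measurement, and optionally restrict to one
#' gonadotropin type.
#'
#' @param drop_canceled drop cycles flagged `canceled == 1`.
#' @param drop_missing_day7 drop cycles with missing `fsh_day7`.
#' @param gonadotropin_type `NULL`, `"recombinant"` or `"urinary"`.
#' @return A policy list used by [apply_exclusions()].
#' @export
exclusion_policy <- function(drop_canceled = TRUE, drop_missing_day7 = TRUE,
                             gonadotropin_type = NULL) {
  if (!is.null(gonadotropin_type) &&
      !gonadotropin_type %in% .cohort_vocab$gonadotropin_type)
    stop("unknown gonadotropin_type '", gonadotropin_type,
         "'; valid: ", paste(.cohort_vocab$gonadotropin_type, collapse = ", "))
  structure(list(drop_canceled = drop_canceled,
                 drop_missing_day7 = drop_missing_day7,
                 gonadotropin_type = gonadotropin_type),
            class = "exclusion_policy")
}

#' Apply eligibility exclusions
#'
#' Filters the cohort per the policy, sequentially, and attaches a
#' per-criterion count report (attribute `"exclusion_report"`) whose counts
#' sum to the number of removed rows — the flow-chart view of the screening.
#'
#' @param cohort an `fsh_cohort`.
#' @param policy an [exclusion_policy()].
#' @return The eligible `fsh_cohort`, with an exclusion report attribute.
#' @export
apply_exclusions <- function(cohort, policy = exclusion_policy()) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  if (!inherits(policy, "exclusion_policy"))
    stop("policy must be built with exclusion_policy()")
  report <- list(input_n = nrow(cohort))
  keep <- cohort
  if (isTRUE(policy$drop_canceled)) {
    drop <- !is.na(keep$canceled %||% rep(0L, nrow(keep))) &
      (keep$canceled %||% rep(0L, nrow(keep))) == 1L
    report$canceled <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }
  if (isTRUE(policy$drop_missing_day7)) {
    drop <- is.na(keep$fsh_day7)
    report$missing_day7 <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }
  if (!is.null(policy$gonadotropin_type)) {
    if (is.null(keep$gonadotropin_type))
      stop("policy restricts gonadotropin_type but the column is absent")
    drop <- is.na(keep$gonadotropin_type) |
      keep$gonadotropin_type != policy$gonadotropin_type
    report$gonadotropin_type <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }
  report$output_n <- nrow(keep)
  if (nrow(keep) == 0)
    warning("all records excluded; downstream fitting will refuse an empty cohort",
            call. = FALSE)
  rownames(keep) <- NULL
  class(keep) <- c("fsh_cohort", "data.frame")
  attr(keep, "schema_version") <- attr(cohort, "schema_version")
  attr(keep, "exclusion_report") <- report
  keep
}

#' Exposure tertiles
#'
#' Labels each record `low` / `medium` / `high` by the 1/3 and 2/3 sample
#' quantiles (type 7, linear interpolation) of `variable`. Records exactly at
#' a cut belong to the lower group (closed lower intervals), so heavy ties at
#' a cut land in one group and the labelling is invariant to record order and
#' to strictly monotone transformations of the variable.
#'
#' @param cohort an `fsh_cohort`.
#' @param variable numeric column to split on (default the exposure).
#' @return The cohort with a `tertile` factor column.
#' @export
assign_tertiles <- function(cohort, variable = "fsh_day7") {
  stopifnot(inherits(cohort, "fsh_cohort"))
  x <- cohort[[variable]]
  if (is.null(x) || !is.numeric(x))
    stop("'", variable, "' must be a numeric cohort column")
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 3)
    stop(structure(class = c("tertile_error", "error", "condition"),
                   list(message = "need at least 3 distinct values to form tertiles",
                        call = NULL)))
  cuts <- quantile(obs, c(1, 2) / 3, type = 7, names = FALSE)
  lab <- rep(NA_character_, nrow(cohort))
  lab[!is.na(x) & x <= cuts[1]] <- "low"
  lab[!is.na(x) & x > cuts[1] & x <= cuts[2]] <- "medium"
  lab[!is.na(x) & x > cuts[2]] <- "high"
  cohort$tertile <- factor(lab, levels = .cohort_vocab$tertile)
  attr(cohort, "tertile_cuts") <- cuts
  cohort
}

#' Restrict to each patient's first cycle
#'
#' Keeps exactly one record per `patient_id`: the one with the minimal
#' `cycle_index`. Duplicate (patient, cycle) pairs are ambiguous and abort.
#'
#' @param cohort an `fsh_cohort`.
#' @return An `fsh_cohort` with one row per patient, `first_cycle = 1`.
#' @export
first_cycle_subset <- function(cohort) {
  stopifnot(inherits(cohort, "fsh_cohort"))
  ci <- cohort$cycle_index
  if (is.null(ci) || all(is.na(ci)))
    stop("cycle_index is required to identify first cycles")
  key <- paste(cohort$patient_id, ci, sep = "\r")
  if (anyDuplicated(key))
    stop(structure(class = c("cycle_ambiguity_error", "error", "condition"),
                   list(message = "duplicate (patient_id, cycle_index) pairs",
                        call = NULL)))
  ord <- order(cohort$patient_id, ci)
  firsts <- ord[!duplicated(cohort$patient_id[ord])]
  out <- cohort[sort(firsts), , drop = FALSE]
  out$first_cycle <- rep(1L, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("fsh_cohort", "data.frame")
  attr(out, "schema_version") <- attr(cohort, "schema_version")
  out
}

#' @export
print.fsh_cohort <- function(x, ...) {
  cat(sprintf("<fsh_cohort> %d cycles, %d patients\n", nrow(x),
              length(unique(x$patient_id))))
  rep_ <- attr(x, "exclusion_report")
  if (!is.null(rep_))
    cat("  exclusions:",
        paste(sprintf("%s=%s", names(rep_), unlist(rep_)), collapse = ", "),
        "\n")
  NextMethod()
}
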