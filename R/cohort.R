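#' Canonical cohort schema
#'
#' Column names of the participant-level cohort table. The six analysis
#' variables (age, gait speed over height, grip strength over BMI, one-legged
#' stance, lean appendicular mass %, fat %) are derived from the eight raw
#' profile inputs; binary condition flags are carried alongside and never
#' enter the map.
#'
#' @return Character vector of canonical column names.
#' @export
cohort_schema <- function() {
  c("id", "sex", raw_profile_inputs(), condition_codes(),
    "educ_years", "num_comorbid", "complete_tests")
}

#' @rdname cohort_schema
#' @export
raw_profile_inputs <- function() {
  c("age", "gait_speed", "height", "grip_strength", "bmi",
    "balance", "lam_pct", "fat_pct")
}

#' @rdname cohort_schema
#' @export
condition_codes <- function() {
  c("CI", "ADLD", "IADLD", "DEPR", "FF", "FELL", "MI", "CHF", "CVA", "COPD",
    "ARTH", "PUD", "LIVER", "DIAB", "HEMI", "CKD", "CANCER", "AIDS", "PVD",
    "HTN", "OSTEO")
}

# maximum one-legged stance duration: the protocol stops the test at 45 s
BALANCE_CAP <- 45

new_cohort_table <- function(df, provenance = "unknown") {
  structure(df,
            provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants (%s)\n",
              nrow(x), attr(x, "provenance")))
  NextMethod()
}

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("woman", "women", "female", "f", "w")] <- "woman"
  out[key %in% c("man", "men", "male", "m")] <- "man"
  out
}

validate_cohort <- function(df) {
  if (anyDuplicated(df$id))
    stop("duplicate participant ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!is.na(df$sex) & !df$sex %in% c("woman", "man")))
    stop("sex must be 'woman' or 'man'")
  bad_bal <- !is.na(df$balance) & (df$balance < 0 | df$balance > BALANCE_CAP)
  if (any(bad_bal))
    stop("balance outside [0, ", BALANCE_CAP, "] for id(s): ",
         paste(df$id[bad_bal], collapse = ", "))
  for (v in c("lam_pct", "fat_pct")) {
    bad <- !is.na(df[[v]]) & (df[[v]] <= 0 | df[[v]] >= 100)
    if (any(bad))
      stop(v, " outside (0, 100) for id(s): ", paste(df$id[bad], collapse = ", "))
  }
  for (v in c("gait_speed", "height", "grip_strength", "bmi")) {
    bad <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(bad))
      stop(v, " must be positive; offending id(s): ",
           paste(df$id[bad], collapse = ", "))
  }
  invisible(df)
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated, UTF-8, headered participant table into the
#' canonical schema. `schema` maps canonical field names to the file's
#' column names, so a deposited database can be ingested whatever its
#' headers are. Unparseable numeric cells become missing; missingness is
#' preserved, never imputed. When the file has no `complete_tests` column
#' the flag is derived as "all eight raw profile inputs non-missing", since
#' test completion is defined behaviorally.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector or list mapping canonical
#'   names (see [cohort_schema()]) to column names in the file; canonical
#'   names absent from the mapping are looked up verbatim.
#' @param provenance Free-text source tag stored on the result.
#' @return A `cohort_table` (data frame) with one record per data row.
#' @export
load_cohort <- function(path, schema = NULL, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (nrow(df) == 0) stop("empty cohort file: ", path)
  schema <- as.list(schema)
  col_of <- function(canon) {
    nm <- if (!is.null(schema[[canon]])) schema[[canon]] else canon
    if (nm %in% names(df)) df[[nm]] else NULL
  }
  mandatory <- c("id", "sex", raw_profile_inputs())
  missing_cols <- mandatory[vapply(mandatory, function(v) is.null(col_of(v)), TRUE)]
  if (length(missing_cols))
    stop("schema error: mandatory column(s) not found: ",
         paste(missing_cols, collapse = ", "))

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(id = as.character(col_of("id")),
                    sex = normalize_sex(col_of("sex")),
                    stringsAsFactors = FALSE)
  for (v in raw_profile_inputs()) out[[v]] <- num(col_of(v))
  for (cc in condition_codes()) {
    x <- col_of(cc)
    out[[cc]] <- if (is.null(x)) NA_integer_ else as.integer(num(x) != 0)
  }
  ed <- col_of("educ_years")
  out$educ_years <- if (is.null(ed)) NA_real_ else num(ed)
  nc <- col_of("num_comorbid")
  out$num_comorbid <- if (is.null(nc)) NA_integer_ else as.integer(num(nc))
  ct <- col_of("complete_tests")
  out$complete_tests <- if (is.null(ct)) {
    stats::complete.cases(out[raw_profile_inputs()])
  } else {
    as.logical(num(ct) != 0)
  }
  validate_cohort(out)
  new_cohort_table(out, provenance = provenance)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the study eligibility filter
#'
#' Retains records with `age >= min_age`, `complete_tests = TRUE`, and no
#' missing value among the raw inputs of the six profile variables. Order is
#' preserved and an exclusion log (id + first failing reason) is attached as
#' the `"exclusions"` attribute (see [exclusion_log()]). Condition flags may
#' remain partially missing: they are not map inputs, and downstream
#' statistics drop them pairwise.
#'
#' @param cohort A `cohort_table`.
#' @param min_age Minimum age in years (default 60).
#' @return Filtered `cohort_table` with an `exclusions` attribute.
#' @export
apply_eligibility <- function(cohort, min_age = 60) {
  stopifnot(min_age >= 0)
  df <- as.data.frame(cohort)
  incomplete <- !df$complete_tests | !stats::complete.cases(df[raw_profile_inputs()])
  too_young <- is.na(df$age) | df$age < min_age
  reason <- ifelse(too_young, "age_below_minimum",
                   ifelse(incomplete, "incomplete_tests", NA_character_))
  keep <- is.na(reason)
  excl <- data.frame(id = df$id[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  out <- new_cohort_table(df[keep, , drop = FALSE],
                          provenance = attr(cohort, "provenance"))
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' @rdname apply_eligibility
#' @export
exclusion_log <- function(cohort) {
  ex <- attr(cohort, "exclusions")
  if (is.null(ex)) data.frame(id = character(), reason = character()) else ex
}
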