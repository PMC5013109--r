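# Cohort schema, CSV input/output, eligibility exclusions, COPD derivation.

parse_boolean <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[v %in% c("0", "false", "no", "f", "n")] <- FALSE
  out[v == "" | v == "na"] <- NA
  as.logical(out)
}

parse_positive_numeric <- function(x) {
  v <- trimws(as.character(x))
  v[v == "" | tolower(v) == "na"] <- NA
  num <- suppressWarnings(as.numeric(v))
  num[!is.na(num) & num <= 0] <- NA  # invariant: strictly positive when present
  num
}

parse_enum <- function(x, levels, case_map = identity) {
  v <- case_map(trimws(as.character(x)))
  v[!(v %in% levels)] <- NA
  v
}

#' Read a patient-level cohort table from CSV
#'
#' Expects the canonical columns `patient_id, age, heart_rate, systolic_bp,
#' creatinine, diuretic_in_hospital, cardiac_arrest, st_deviation,
#' elevated_markers, oad_indicator, smoking, diagnosis, diabetes,
#' admission_year, died_6m` (a `schema` mapping can rename file columns onto
#' these). Empty strings are missing; booleans accept `0/1`, `true/false`,
#' `yes/no` case-insensitively; unparseable or non-positive numeric values
#' become missing rather than failing the read. Row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the column names used in the file, e.g.
#'   `c(died_6m = "dead180")`. Unmapped columns are looked up by their
#'   canonical name.
#' @return A `data.frame` (one row per admission) with validated types.
#' @seealso [write_cohort()], [apply_exclusions()]
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path)

  file_names <- stats::setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), COHORT_COLUMNS)
    if (length(bad)) stop("schema maps unknown column(s): ",
                          paste(bad, collapse = ", "))
    file_names[names(schema)] <- schema
  }
  missing_cols <- file_names[!(file_names %in% names(raw))]
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  col <- function(nm) raw[[file_names[[nm]]]]
  id <- trimws(col("patient_id"))
  id[id == ""] <- NA_character_

  out <- data.frame(
    patient_id = id,
    age = parse_positive_numeric(col("age")),
    heart_rate = parse_positive_numeric(col("heart_rate")),
    systolic_bp = parse_positive_numeric(col("systolic_bp")),
    creatinine = parse_positive_numeric(col("creatinine")),
    diuretic_in_hospital = parse_boolean(col("diuretic_in_hospital")),
    cardiac_arrest = parse_boolean(col("cardiac_arrest")),
    st_deviation = parse_boolean(col("st_deviation")),
    elevated_markers = parse_boolean(col("elevated_markers")),
    oad_indicator = parse_boolean(col("oad_indicator")),
    smoking = parse_enum(col("smoking"), SMOKING_LEVELS, tolower),
    diagnosis = parse_enum(col("diagnosis"), DIAGNOSIS_LEVELS, toupper),
    diabetes = parse_boolean(col("diabetes")),
    admission_year = {
      y <- suppressWarnings(as.integer(trimws(col("admission_year"))))
      y
    },
    died_6m = parse_boolean(col("died_6m")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values are written as empty strings
#' and logical columns as `true`/`false`, so `read_cohort(write_cohort(x))`
#' reproduces `x` field by field.
#'
#' @param cohort A cohort `data.frame` as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort[, COHORT_COLUMNS, drop = FALSE]
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.logical(v)) v <- ifelse(is.na(v), "", ifelse(v, "true", "false"))
    v <- as.character(v)
    v[is.na(v)] <- ""
    out[[nm]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the eligibility exclusions to a cohort
#'
#' Records are dropped, in this fixed order, if they lack (1) a patient
#' identifier, (2) the obstructive-airway-disease indicator, (3) smoking
#' history, or (4) 6-month vital status; each record is counted under the
#' first reason that applies. Missing numeric score inputs do *not* exclude a
#' record here — downstream steps are complete-case per analysis and report
#' their own drop counts.
#'
#' @param cohort A cohort `data.frame`.
#' @return A list with `cohort` (retained rows) and `log`, an
#'   `exclusion_log` with per-reason counts reconciling to the input size.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("cohort is empty")

  reason <- rep(NA_character_, nrow(cohort))
  miss_id <- is.na(cohort$patient_id) | cohort$patient_id == ""
  reason[miss_id] <- "missing_id"
  m <- is.na(reason) & is.na(cohort$oad_indicator)
  reason[m] <- "missing_oad"
  m <- is.na(reason) & is.na(cohort$smoking)
  reason[m] <- "missing_smoking"
  m <- is.na(reason) & is.na(cohort$died_6m)
  reason[m] <- "missing_vital_status"

  keep <- is.na(reason)
  log <- structure(
    list(
      n_input = nrow(cohort),
      n_retained = sum(keep),
      missing_id = sum(reason == "missing_id", na.rm = TRUE),
      missing_oad = sum(reason == "missing_oad", na.rm = TRUE),
      missing_smoking = sum(reason == "missing_smoking", na.rm = TRUE),
      missing_vital_status = sum(reason == "missing_vital_status", na.rm = TRUE)
    ),
    class = "exclusion_log"
  )
  if (log$n_retained == 0L) warning("all records excluded; empty cohort returned")
  list(cohort = cohort[keep, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Eligibility exclusions\n")
  cat(sprintf("  records in:            %d\n", x$n_input))
  cat(sprintf("  missing identifier:    %d\n", x$missing_id))
  cat(sprintf("  missing OAD indicator: %d\n", x$missing_oad))
  cat(sprintf("  missing smoking:       %d\n", x$missing_smoking))
  cat(sprintf("  missing vital status:  %d\n", x$missing_vital_status))
  cat(sprintf("  records retained:      %d\n", x$n_retained))
  invisible(x)
}

#' Derive the COPD flag from airway-disease indicator and smoking history
#'
#' A patient is flagged as having chronic obstructive pulmonary disease when
#' the obstructive-airway-disease indicator is positive *and* the patient is
#' an ex- or current smoker. Both inputs must be non-missing (run
#' [apply_exclusions()] first).
#'
#' @param oad_indicator Logical vector (or a cohort `data.frame`, in which
#'   case `smoking` is taken from it too).
#' @param smoking Character vector with values `never`, `ex` or `current`.
#' @return Logical vector, `TRUE` where the COPD rule is met.
#' @export
#' @examples
#' identify_copd(c(TRUE, TRUE, FALSE), c("current", "never", "current"))
identify_copd <- function(oad_indicator, smoking) {
  if (is.data.frame(oad_indicator)) {
    smoking <- oad_indicator$smoking
    oad_indicator <- oad_indicator$oad_indicator
  }
  if (anyNA(oad_indicator) || anyNA(smoking)) {
    stop("oad_indicator and smoking must be non-missing; apply exclusions first")
  }
  if (!all(smoking %in% SMOKING_LEVELS)) stop("invalid smoking category")
  oad_indicator & smoking %in% c("ex", "current")
}
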