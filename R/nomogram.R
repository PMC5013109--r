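# Table-driven nomogram scoring: covariate values -> points -> total score
# -> predicted 6-month death probability -> risk band.

#' Construct a nomogram object
#'
#' A nomogram maps each score input to points — continuous variables through
#' a step function over breakpoint intervals (`points[i]` applies from
#' `breakpoints[i]` up to the next breakpoint; values below the first
#' breakpoint clamp to the first interval, values at or above the last take
#' the last), boolean variables through a fixed point value when true — and
#' maps the total score to predicted risk by linear interpolation between
#' ordered `(score, risk)` anchors, clamped to the terminal risks outside the
#' anchor range.
#'
#' @param variables Named list; each element either
#'   `list(type = "continuous", breakpoints =, points =)` with strictly
#'   increasing breakpoints, or `list(type = "binary", points =)`.
#' @param score_to_risk Data frame (or list) with `score` strictly increasing
#'   and `risk` non-decreasing in `[0, 1]`, at least two anchors.
#' @param name,source Metadata strings carried along for provenance.
#' @return A `nomogram` object.
#' @export
nomogram <- function(variables, score_to_risk, name = "unnamed",
                     source = NA_character_) {
  stopifnot(is.list(variables), length(variables) > 0, !is.null(names(variables)))
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (!v$type %in% c("continuous", "binary")) {
      stop("variable '", nm, "': type must be 'continuous' or 'binary'")
    }
    if (v$type == "continuous") {
      if (length(v$breakpoints) != length(v$points)) {
        stop("variable '", nm, "': breakpoints and points differ in length")
      }
      if (any(diff(v$breakpoints) <= 0)) {
        stop("variable '", nm, "': breakpoints must be strictly increasing")
      }
    } else if (length(v$points) != 1L) {
      stop("variable '", nm, "': binary variables take a single point value")
    }
  }
  curve <- as.data.frame(score_to_risk)
  stopifnot(all(c("score", "risk") %in% names(curve)))
  if (nrow(curve) < 2L) stop("score_to_risk needs at least two anchors")
  if (any(diff(curve$score) <= 0)) stop("score_to_risk scores must be strictly increasing")
  if (any(diff(curve$risk) < 0)) stop("score_to_risk risks must be non-decreasing")
  if (any(curve$risk < 0 | curve$risk > 1)) stop("risks must lie in [0, 1]")
  structure(list(variables = variables, score_to_risk = curve,
                 name = name, source = source),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat("Nomogram:", x$name, "\n")
  if (!is.na(x$source)) cat("Source:", x$source, "\n")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    if (v$type == "binary") {
      cat(sprintf("  %-22s binary, %g points if true\n", nm, v$points))
    } else {
      cat(sprintf("  %-22s %d intervals, points %g..%g\n", nm,
                  length(v$points), min(v$points), max(v$points)))
    }
  }
  cat(sprintf("  score-to-risk: %d anchors, scores %g..%g, risks %.3f..%.3f\n",
              nrow(x$score_to_risk), min(x$score_to_risk$score),
              max(x$score_to_risk$score), min(x$score_to_risk$risk),
              max(x$score_to_risk$risk)))
  invisible(x)
}

#' Read a nomogram from a JSON or YAML config file
#'
#' The file holds per-variable entries (`breakpoints`/`points` for
#' continuous, `points` for binary), a `score_to_risk` anchor list, and
#' optional `name`/`source` metadata.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [nomogram()] object.
#' @export
read_nomogram <- function(path) {
  if (!file.exists(path)) stop("nomogram file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported nomogram format: .", ext)
  vars <- lapply(raw$variables, function(v) {
    v$points <- as.numeric(unlist(v$points))
    if (!is.null(v$breakpoints)) v$breakpoints <- as.numeric(unlist(v$breakpoints))
    v
  })
  curve <- raw$score_to_risk
  if (!is.data.frame(curve)) {
    curve <- data.frame(score = as.numeric(unlist(curve$score)),
                        risk = as.numeric(unlist(curve$risk)))
  }
  nomogram(vars, curve,
           name = if (is.null(raw$name)) "unnamed" else raw$name,
           source = if (is.null(raw$source)) NA_character_ else raw$source)
}

#' The default 6-month mortality nomogram shipped with the package
#'
#' A synthetic GRACE-style table (realistic point structure, monotone
#' score-to-risk curve) shipped for demonstration; it is *not* a verified
#' transcription of any published nomogram, and all correctness guarantees in
#' the package are established against small purpose-built nomograms, not
#' this table. Replace it with [read_nomogram()] on your own transcription
#' for substantive use.
#'
#' @return A [nomogram()] object.
#' @export
default_nomogram <- function() {
  read_nomogram(system.file("extdata", "nomogram_6m_synthetic.json",
                            package = "graceval", mustWork = TRUE))
}

#' Points contributed by one variable
#'
#' @param variable Variable name present in the nomogram.
#' @param value Numeric value (continuous) or logical (binary); vectorised.
#' @param nomogram A [nomogram()].
#' @param interpolate Score continuous variables by linear interpolation
#'   between breakpoints instead of the default step function (published
#'   nomograms tabulate ranges, so the step function is the default).
#' @return Numeric vector of points.
#' @export
#' @examples
#' ng <- nomogram(
#'   list(age = list(type = "continuous", breakpoints = c(40, 60, 80),
#'                   points = c(0, 10, 20))),
#'   data.frame(score = c(0, 20), risk = c(0.01, 0.2)))
#' points_for_variable("age", 65, ng)
points_for_variable <- function(variable, value, nomogram, interpolate = FALSE) {
  v <- nomogram$variables[[variable]]
  if (is.null(v)) stop("unknown nomogram variable: ", variable)
  if (anyNA(value)) stop("missing value for nomogram variable: ", variable)
  if (v$type == "binary") {
    ifelse(as.logical(value), v$points, 0)
  } else if (interpolate && length(v$breakpoints) > 1L) {
    stats::approx(v$breakpoints, v$points, xout = value, rule = 2,
                  ties = "ordered")$y
  } else {
    idx <- findInterval(value, v$breakpoints)
    idx[idx == 0L] <- 1L  # clamp below-range values to the first interval
    v$points[idx]
  }
}

#' Total nomogram score for each record
#'
#' Sums the per-variable points over the eight score inputs
#' (`age, heart_rate, systolic_bp, creatinine` continuous;
#' `diuretic_in_hospital, cardiac_arrest, st_deviation, elevated_markers`
#' boolean, with in-hospital diuretic use standing in for heart failure).
#' Records missing any input score as `NA`; the caller counts and drops them.
#'
#' @param cohort Cohort `data.frame` (or a single-record list).
#' @param nomogram A [nomogram()].
#' @param interpolate Passed to [points_for_variable()].
#' @return Numeric vector of total scores (`NA` where unscoreable).
#' @export
grace_score <- function(cohort, nomogram, interpolate = FALSE) {
  cohort <- as.data.frame(cohort)
  needed <- names(nomogram$variables)
  missing_vars <- setdiff(needed, names(cohort))
  if (length(missing_vars)) stop("cohort lacks nomogram variable(s): ",
                                 paste(missing_vars, collapse = ", "))
  complete <- !Reduce(`|`, lapply(needed, function(nm) is.na(cohort[[nm]])))
  score <- rep(NA_real_, nrow(cohort))
  if (any(complete)) {
    total <- 0
    for (nm in needed) {
      total <- total + points_for_variable(nm, cohort[[nm]][complete], nomogram,
                                           interpolate = interpolate)
    }
    score[complete] <- total
  }
  score
}

#' Convert a total score to predicted 6-month death probability
#'
#' Linear interpolation between the nomogram's score-to-risk anchors,
#' clamped to the terminal risks outside the anchor range.
#'
#' @param score Numeric vector of total scores.
#' @param nomogram A [nomogram()].
#' @return Probabilities in `[0, 1]` (`NA` passed through).
#' @export
score_to_risk <- function(score, nomogram) {
  curve <- nomogram$score_to_risk
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  if (any(ok)) {
    out[ok] <- stats::approx(curve$score, curve$risk, xout = score[ok],
                             rule = 2, ties = "ordered")$y
  }
  out
}

#' Risk-band thresholds
#'
#' The conventional treatment-guidance bands for predicted 6-month death:
#' low below 3%, moderate from 3% to 6% inclusive, high above 6%. Exact
#' boundary membership is a convention, so the thresholds are visible
#' configuration rather than hard-coded.
#'
#' @param low_upper Upper edge of the low band (default 0.03).
#' @param moderate_upper Upper edge of the moderate band (default 0.06).
#' @return A `risk_bands` object.
#' @export
risk_bands <- function(low_upper = 0.03, moderate_upper = 0.06) {
  if (!(0 < low_upper && low_upper < moderate_upper && moderate_upper < 1)) {
    stop("require 0 < low_upper < moderate_upper < 1")
  }
  structure(list(low_upper = low_upper, moderate_upper = moderate_upper),
            class = "risk_bands")
}

BAND_LEVELS <- c("low", "moderate", "high")

#' Assign predicted risks to bands
#'
#' `low` if risk < `low_upper`; `moderate` if `low_upper` <= risk <=
#' `moderate_upper`; `high` above.
#'
#' @param risk Probabilities in `[0, 1]` (`NA` passed through).
#' @param bands A [risk_bands()].
#' @return Ordered factor with levels `low < moderate < high`.
#' @export
stratify_risk <- function(risk, bands = risk_bands()) {
  ok <- !is.na(risk)
  if (any(risk[ok] < 0 | risk[ok] > 1)) stop("risk must lie in [0, 1]")
  out <- rep(NA_character_, length(risk))
  out[ok] <- ifelse(risk[ok] < bands$low_upper, "low",
                    ifelse(risk[ok] <= bands$moderate_upper, "moderate", "high"))
  factor(out, levels = BAND_LEVELS, ordered = TRUE)
}

#' Score a cohort and attach predicted risks and bands
#'
#' @param cohort Cohort `data.frame`.
#' @param nomogram A [nomogram()].
#' @param bands A [risk_bands()].
#' @return List with `predictions` (data frame: `patient_id`, `score`,
#'   `risk`, `band`, plus the retained row index `row`) and `n_dropped`,
#'   the number of records missing a score input.
#' @export
predict_cohort <- function(cohort, nomogram, bands = risk_bands()) {
  score <- grace_score(cohort, nomogram)
  keep <- !is.na(score)
  if (!any(keep)) stop("no scoreable records: every record is missing a score input")
  risk <- score_to_risk(score[keep], nomogram)
  predictions <- data.frame(
    patient_id = cohort$patient_id[keep],
    score = score[keep],
    risk = risk,
    band = stratify_risk(risk, bands),
    row = which(keep),
    stringsAsFactors = FALSE
  )
  list(predictions = predictions, n_dropped = sum(!keep))
}
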