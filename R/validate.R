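# End-to-end subgroup validation of a nomogram risk score: the central
# fitting function and the methods on its result.

MODEL_NAMES <- c("grace", "grace_x_f", "minap", "minap_smoking", "minap_copd")

MODEL_LABELS <- c(
  grace = "Normal score (nomogram)",
  grace_x_f = "Normal score x f for group",
  minap = "Registry-refit score",
  minap_smoking = "Registry-refit + smoking",
  minap_copd = "Registry-refit + COPD"
)

#' Validate and recalibrate a risk score for a patient subgroup
#'
#' Runs the full assessment on a cohort: eligibility exclusions; nomogram
#' scoring; the decile-adjusted Mantel-Haenszel risk ratio comparing observed
#' 6-month mortality between the subgroup (COPD by default) and the rest,
#' conditional on predicted risk; three model respecifications fitted by
#' logistic regression (the eight score inputs, plus smoking, plus the COPD
#' indicator); multiplicative recalibration of the subgroup's nomogram risks
#' by the estimated (or supplied) risk ratio; and, per model, the
#' C-statistic, Hosmer-Lemeshow test, paired C-statistic comparisons
#' (modified nomogram vs nomogram; augmented refits vs base refit), the
#' continuous NRI for adding COPD, risk-band reclassification tables for the
#' subgroup, and deaths-by-decile stratification profiles.
#'
#' All model-based quantities are computed on the records with complete
#' score inputs (the same complete-case set for every model, so paired
#' comparisons are valid); the drop count is reported.
#'
#' @param data Cohort `data.frame` (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param nomogram A [nomogram()] (default: the shipped synthetic table).
#' @param bands A [risk_bands()].
#' @param group Subgroup definition: `"copd"` (derived by [identify_copd()])
#'   or the name of a logical cohort column (e.g. `"diabetes"`).
#' @param multiplier Recalibration factor for the subgroup's nomogram risks;
#'   `NULL` (default) estimates it from the data as the decile-adjusted
#'   Mantel-Haenszel RR under the nomogram model.
#' @param bootstrap_reps Bootstrap replicates for internal validation of the
#'   refit models (0 = skip).
#' @param stratify_by Optional column (`"diagnosis"` or `"admission_year"`)
#'   on which to rerun the whole analysis per stratum.
#' @param seed Optional integer seed (used by the bootstrap).
#' @param keep_predictions Keep the per-record prediction table in the
#'   result (needed by `simulate`; default `TRUE`).
#' @return A `grace_validation` object; see [print.grace_validation()],
#'   [summary.grace_validation()], [coef.grace_validation()],
#'   [predict.grace_validation()], [plot.grace_validation()].
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n = 4000, seed = 7))
#' fit <- grace_validate(cohort, bootstrap_reps = 0)
#' fit
grace_validate <- function(data, nomogram = default_nomogram(),
                           bands = risk_bands(), group = "copd",
                           multiplier = NULL, bootstrap_reps = 0L,
                           stratify_by = NULL, seed = NULL,
                           keep_predictions = TRUE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)

  excl <- apply_exclusions(data)
  cohort <- excl$cohort
  if (nrow(cohort) == 0L) stop("no records left after exclusions")

  group_flag_all <- if (identical(group, "copd")) {
    identify_copd(cohort)
  } else {
    g <- as.logical(cohort[[group]])
    if (anyNA(g)) stop("subgroup column '", group, "' has missing values")
    g
  }
  if (all(group_flag_all) || !any(group_flag_all)) {
    stop("subgroup column '", group, "' is constant")
  }

  # complete-case set for the score inputs; identical for the nomogram and
  # every refit (smoking/OAD are complete after exclusions), so all paired
  # comparisons share the same records
  scored <- predict_cohort(cohort, nomogram, bands)
  rows <- scored$predictions$row
  n_dropped <- scored$n_dropped
  grp <- group_flag_all[rows]
  died <- cohort$died_6m[rows]

  risks <- list(grace = scored$predictions$risk)

  # base-model adjusted RR doubles as the estimated recalibration multiplier
  mh_grace <- estimate_multiplier(risks$grace, died, grp)
  mult_exact <- mh_grace$rr
  mult_used <- if (is.null(multiplier)) mult_exact else multiplier
  risks$grace_x_f <- recalibrate(risks$grace, grp, mult_used)

  # registry respecifications (shared complete-case rows by construction)
  fits <- list()
  designs <- list(
    minap = build_design(cohort, "grace"),
    minap_smoking = build_design(cohort, "grace+smoking"),
    minap_copd = build_design(cohort, "grace+copd")
  )
  for (nm in names(designs)) {
    stopifnot(identical(designs[[nm]]$rows, rows))  # same complete-case set
    fits[[nm]] <- fit_logistic(designs[[nm]])
    risks[[nm]] <- predict_prob(fits[[nm]], designs[[nm]]$x)
  }

  models <- list()
  for (nm in MODEL_NAMES) {
    dec <- assign_deciles(risks[[nm]])
    models[[nm]] <- list(
      name = nm, label = MODEL_LABELS[[nm]], n_used = length(rows),
      mh = if (nm == "grace") mh_grace else
        mh_pooled_rr(stratum_tables(dec, grp, died)),
      c_statistic = c_statistic(risks[[nm]], died),
      hl = hosmer_lemeshow(risks[[nm]], died)
    )
  }

  comparisons <- list(
    grace_x_f_vs_grace = compare_c_statistics(risks$grace_x_f, risks$grace, died),
    minap_smoking_vs_minap = compare_c_statistics(risks$minap_smoking,
                                                  risks$minap, died),
    minap_copd_vs_minap = compare_c_statistics(risks$minap_copd, risks$minap, died)
  )
  nri <- continuous_nri(risks$minap, risks$minap_copd, died)

  tables <- list(
    by_decile = observed_vs_predicted_by_decile(risks$grace, died, grp),
    by_band = lapply(risks[c("grace", "grace_x_f", "minap", "minap_copd")],
                     function(r) observed_by_band(r, died, grp, bands)),
    reclass_multiplier = reclassification_matrix(
      stratify_risk(risks$grace, bands)[grp],
      stratify_risk(risks$grace_x_f, bands)[grp]),
    reclass_refit = reclassification_matrix(
      stratify_risk(risks$minap, bands)[grp],
      stratify_risk(risks$minap_copd, bands)[grp])
  )

  dbd <- sapply(risks[c("grace", "grace_x_f", "minap_copd")],
                function(r) deaths_by_decile(r, died, grp))
  rownames(dbd) <- paste0("decile_", 1:10)

  boot <- NULL
  if (bootstrap_reps > 0L) {
    boot <- lapply(designs, bootstrap_fit, reps = bootstrap_reps)
  }

  strata_reports <- NULL
  if (!is.null(stratify_by)) {
    levels <- sort(unique(cohort[[stratify_by]]))
    strata_reports <- lapply(levels, function(lv) {
      grace_validate(cohort[cohort[[stratify_by]] == lv, , drop = FALSE],
                     nomogram = nomogram, bands = bands, group = group,
                     multiplier = multiplier, bootstrap_reps = 0L,
                     keep_predictions = FALSE)
    })
    names(strata_reports) <- as.character(levels)
  }

  predictions <- NULL
  if (keep_predictions) {
    predictions <- data.frame(
      patient_id = cohort$patient_id[rows],
      group = grp, died_6m = died,
      as.data.frame(risks), stringsAsFactors = FALSE
    )
  }

  structure(
    list(call = cl, n_input = excl$log$n_input, exclusion_log = excl$log,
         n_analysed = length(rows), n_dropped_incomplete = n_dropped,
         group = group, n_group = sum(grp), bands = bands,
         multiplier = list(estimate = mh_grace, exact = mult_exact,
                           rounded = round(mult_exact, 1), used = mult_used),
         nomogram = nomogram,
         models = models, comparisons = comparisons, nri = nri,
         tables = tables, deaths_by_decile = dbd,
         fits = fits, bootstrap = boot, strata = strata_reports,
         seed = seed, predictions = predictions),
    class = "grace_validation"
  )
}

fmt_p <- function(p) if (p < 0.001) "<0.001" else sprintf("%.3f", p)
fmt_hl_p <- function(p) if (p > 0.999) ">0.999" else sprintf("%.3f", p)

#' @export
print.grace_validation <- function(x, digits = 3, ...) {
  cat("Subgroup validation of a 6-month mortality risk score\n")
  cat(sprintf("  records analysed: %d (of %d input; %d excluded, %d incomplete)\n",
              x$n_analysed, x$n_input,
              x$n_input - x$exclusion_log$n_retained, x$n_dropped_incomplete))
  cat(sprintf("  subgroup: %s (n = %d, %.1f%%)\n\n", x$group, x$n_group,
              100 * x$n_group / x$n_analysed))

  comp_p <- c(grace = NA, grace_x_f = x$comparisons$grace_x_f_vs_grace$p,
              minap = NA, minap_smoking = x$comparisons$minap_smoking_vs_minap$p,
              minap_copd = x$comparisons$minap_copd_vs_minap$p)
  cat(sprintf("  %-28s %-22s %-18s %s\n", "Model", "M-H RR (95% CI)",
              "C-statistic", "H-L p"))
  for (nm in MODEL_NAMES) {
    m <- x$models[[nm]]
    cstat <- sprintf("%.4f", m$c_statistic)
    if (!is.na(comp_p[[nm]])) cstat <- sprintf("%s (p=%s)", cstat,
                                               fmt_p(comp_p[[nm]]))
    cat(sprintf("  %-28s %-22s %-18s %s\n", m$label,
                sprintf("%.2f (%.2f to %.2f)", m$mh$rr, m$mh$ci_low,
                        m$mh$ci_high),
                cstat, fmt_hl_p(m$hl$p)))
  }
  cat(sprintf("\n  recalibration multiplier: %.4f (rounded %.1f; used %.4f)\n",
              x$multiplier$exact, x$multiplier$rounded, x$multiplier$used))
  cat(sprintf("  continuous NRI, +COPD vs base refit: %.3f (p %s)\n",
              x$nri$nri, fmt_p(x$nri$p)))
  invisible(x)
}

#' Detailed summary of a subgroup validation
#'
#' Adds the exclusion log, the observed-vs-predicted decile table, observed
#' mortality by risk band per model version, and the subgroup's risk-band
#' reclassification matrices to the headline results.
#'
#' @param object A `grace_validation`.
#' @param ... Unused.
#' @return `object`, invisibly, after printing.
#' @export
summary.grace_validation <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$exclusion_log)
  cat("\nObserved vs predicted mortality by decile (nomogram model):\n")
  tab <- object$tables$by_decile
  tab[-1] <- round(100 * tab[-1], 1)  # percentages; n stays a count
  tab$n <- object$tables$by_decile$n
  print(tab, row.names = FALSE)
  cat("\nObserved mortality (%) by risk band and model version:\n")
  for (nm in names(object$tables$by_band)) {
    b <- object$tables$by_band[[nm]]
    cat(sprintf("  %s:\n", MODEL_LABELS[[nm]]))
    b$observed_non_group <- round(100 * b$observed_non_group, 1)
    b$observed_group <- round(100 * b$observed_group, 1)
    print(b, row.names = FALSE)
  }
  cat("\nSubgroup reclassification, nomogram -> nomogram x f:\n")
  print(object$tables$reclass_multiplier)
  cat("\nSubgroup reclassification, base refit -> refit + COPD:\n")
  print(object$tables$reclass_refit)
  if (!is.null(object$bootstrap)) {
    cat("\nBootstrap internal validation (refit models):\n")
    for (nm in names(object$bootstrap)) {
      cat(sprintf("  %s:\n", nm))
      print(object$bootstrap[[nm]])
    }
  }
  invisible(object)
}

#' Coefficients of the registry-refit logistic models
#'
#' @param object A `grace_validation`.
#' @param ... Unused.
#' @return Matrix of coefficients, one column per refit model (`NA` where a
#'   term is absent from a model).
#' @export
coef.grace_validation <- function(object, ...) {
  terms <- unique(unlist(lapply(object$fits, function(f) names(f$coefficients))))
  out <- sapply(object$fits, function(f) f$coefficients[terms])
  rownames(out) <- terms
  out
}

#' Predicted 6-month death risk for new records
#'
#' @param object A `grace_validation`.
#' @param newdata Cohort `data.frame`.
#' @param model Which model's predictions to return.
#' @param ... Unused.
#' @return Numeric vector aligned with `newdata` rows (`NA` where a record
#'   is missing a needed input). For `"grace_x_f"` the stored multiplier is
#'   applied to subgroup members.
#' @export
predict.grace_validation <- function(object, newdata,
                                     model = c("minap_copd", "grace",
                                               "grace_x_f", "minap",
                                               "minap_smoking"), ...) {
  model <- match.arg(model)
  nomogram <- object$nomogram
  out <- rep(NA_real_, nrow(newdata))
  if (model %in% c("grace", "grace_x_f")) {
    risk <- score_to_risk(grace_score(newdata, nomogram), nomogram)
    if (model == "grace_x_f") {
      grp <- if (identical(object$group, "copd")) identify_copd(newdata)
             else as.logical(newdata[[object$group]])
      risk <- recalibrate(risk, grp, object$multiplier$used)
    }
    return(risk)
  }
  spec <- switch(model, minap = "grace", minap_smoking = "grace+smoking",
                 minap_copd = "grace+copd")
  des <- build_design_matrix(newdata, spec)
  out[des$rows] <- predict_prob(object$fits[[model]], des$x)
  out
}

#' Simulate 6-month outcomes from a validated model
#'
#' Draws Bernoulli outcomes from the per-record predicted risks stored in
#' the validation object (requires `keep_predictions = TRUE`).
#'
#' @param object A `grace_validation`.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param model Which model's risks to simulate from.
#' @param ... Unused.
#' @return `data.frame` with `nsim` logical columns, one row per analysed
#'   record.
#' @export
simulate.grace_validation <- function(object, nsim = 1, seed = NULL,
                                      model = "minap_copd", ...) {
  if (is.null(object$predictions)) {
    stop("per-record predictions were not kept; rerun with keep_predictions = TRUE")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- object$predictions[[model]]
  out <- as.data.frame(
    replicate(nsim, stats::runif(length(p)) < p),
    stringsAsFactors = FALSE
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a subgroup validation
#'
#' `which = "stratification"` draws the share of the subgroup's deaths per
#' decile of predicted risk for the nomogram model, the multiplicatively
#' recalibrated model and the refit including COPD (a steeper profile means
#' better risk stratification). `which = "calibration"` draws observed
#' against mean predicted mortality by decile for subgroup and non-subgroup
#' records under the nomogram model.
#'
#' @param x A `grace_validation`.
#' @param which `"stratification"` or `"calibration"`.
#' @param ... Passed to `matplot`/`plot`.
#' @return `x`, invisibly.
#' @export
plot.grace_validation <- function(x, which = c("stratification", "calibration"),
                                  ...) {
  which <- match.arg(which)
  if (which == "stratification") {
    graphics::matplot(1:10, 100 * x$deaths_by_decile, type = "b", pch = 16,
                      lty = 1, col = c("grey40", "firebrick", "steelblue"),
                      xlab = "Decile of predicted risk",
                      ylab = "% of subgroup deaths", ...)
    graphics::legend("topleft", bty = "n",
                     legend = MODEL_LABELS[c("grace", "grace_x_f", "minap_copd")],
                     col = c("grey40", "firebrick", "steelblue"),
                     lty = 1, pch = 16)
  } else {
    tab <- x$tables$by_decile
    rng <- range(100 * unlist(tab[c("mean_predicted", "observed_non_group",
                                    "observed_group")]), na.rm = TRUE)
    graphics::plot(100 * tab$mean_predicted, 100 * tab$observed_non_group,
                   type = "b", pch = 16, col = "grey40", xlim = rng, ylim = rng,
                   xlab = "Mean predicted mortality (%)",
                   ylab = "Observed mortality (%)", ...)
    graphics::lines(100 * tab$mean_predicted, 100 * tab$observed_group,
                    type = "b", pch = 17, col = "firebrick")
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", bty = "n", pch = c(16, 17),
                     col = c("grey40", "firebrick"),
                     legend = c("non-subgroup", "subgroup"))
  }
  invisible(x)
}

#' Decile-adjusted risk ratio for an alternative subgroup
#'
#' Applies the same machinery as the main analysis — nomogram predictions,
#' pooled deciles, Mantel-Haenszel pooled RR — to any binary subgroup column
#' (e.g. diabetes), for comparison with the primary subgroup's excess risk.
#'
#' @param data Cohort `data.frame`.
#' @param group `"copd"` or the name of a logical cohort column.
#' @param nomogram A [nomogram()].
#' @param bands A [risk_bands()].
#' @return An [mh_pooled_rr()] result.
#' @export
subgroup_comparison <- function(data, group, nomogram = default_nomogram(),
                                bands = risk_bands()) {
  excl <- apply_exclusions(data)
  cohort <- excl$cohort
  grp_all <- if (identical(group, "copd")) identify_copd(cohort)
             else as.logical(cohort[[group]])
  if (anyNA(grp_all)) stop("subgroup column '", group, "' has missing values")
  if (all(grp_all) || !any(grp_all)) stop("subgroup column '", group,
                                          "' is constant")
  scored <- predict_cohort(cohort, nomogram, bands)
  rows <- scored$predictions$row
  estimate_multiplier(scored$predictions$risk, cohort$died_6m[rows],
                      grp_all[rows])
}
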