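# Registry-derived logistic respecification of the risk model: design
# construction, maximum-likelihood fit, prediction, bootstrap validation.

#' Build a regression design for a model respecification
#'
#' Continuous score inputs enter linearly after standardisation with the
#' fixed reference constants of [grace_standardisation()] (creatinine on the
#' log scale); boolean inputs enter as 0/1. `grace+smoking` adds two
#' indicators (ex, current; never is the reference); `grace+copd` adds the
#' derived COPD indicator. Records missing any needed variable are dropped
#' and counted.
#'
#' @param cohort Cohort `data.frame` (exclusions already applied).
#' @param spec One of `"grace"`, `"grace+smoking"`, `"grace+copd"`.
#' @return List: `x` (named design matrix, no intercept column), `y`
#'   (0/1 outcome), `n_dropped`, `rows` (retained row indices), `spec`.
#' @export
build_design <- function(cohort, spec = c("grace", "grace+smoking", "grace+copd")) {
  spec <- match.arg(spec)
  m <- build_design_matrix(cohort, spec, require_outcome = TRUE)
  y <- as.numeric(cohort$died_6m[m$rows])
  if (length(unique(y)) < 2L) stop("degenerate outcome: died_6m is constant")
  list(x = m$x, y = y, n_dropped = nrow(cohort) - length(m$rows),
       rows = m$rows, spec = spec)
}

# predictor matrix + retained rows; no outcome handling
build_design_matrix <- function(cohort, spec, require_outcome = FALSE) {
  std <- grace_standardisation()
  needed <- GRACE_VARS
  if (require_outcome) needed <- c(needed, "died_6m")
  if (spec == "grace+smoking") needed <- c(needed, "smoking")
  if (spec == "grace+copd") needed <- c(needed, "oad_indicator", "smoking")
  complete <- !Reduce(`|`, lapply(needed, function(nm) is.na(cohort[[nm]])))
  rows <- which(complete)
  if (length(rows) == 0L) stop("no complete records for model spec '", spec, "'")
  d <- cohort[rows, , drop = FALSE]

  x <- cbind(
    age = (d$age - std$age[["center"]]) / std$age[["scale"]],
    heart_rate = (d$heart_rate - std$heart_rate[["center"]]) / std$heart_rate[["scale"]],
    systolic_bp = (d$systolic_bp - std$systolic_bp[["center"]]) / std$systolic_bp[["scale"]],
    creatinine = (log(d$creatinine) - std$log_creatinine[["center"]]) /
      std$log_creatinine[["scale"]],
    diuretic_in_hospital = as.numeric(d$diuretic_in_hospital),
    cardiac_arrest = as.numeric(d$cardiac_arrest),
    st_deviation = as.numeric(d$st_deviation),
    elevated_markers = as.numeric(d$elevated_markers)
  )
  if (spec == "grace+smoking") {
    x <- cbind(x,
               smoking_ex = as.numeric(d$smoking == "ex"),
               smoking_current = as.numeric(d$smoking == "current"))
  }
  if (spec == "grace+copd") {
    x <- cbind(x, copd = as.numeric(identify_copd(d)))
  }
  list(x = x, rows = rows)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares (via `stats::glm`), with explicit
#' flags for non-convergence, rank deficiency, and separation (any
#' standardised-scale coefficient exceeding 15 in magnitude, the point at
#' which fitted probabilities saturate).
#'
#' @param design A design list from [build_design()], or a numeric matrix
#'   (then `y` must be given).
#' @param y 0/1 outcome vector when `design` is a matrix.
#' @param tol Convergence tolerance on the deviance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A `logistic_fit`: `coefficients` (intercept first), `se`,
#'   `loglik`, `n`, `converged`, `spec`.
#' @export
fit_logistic <- function(design, y = NULL, tol = 1e-8, max_iter = 100L) {
  if (is.list(design) && !is.data.frame(design)) {
    x <- design$x; y <- design$y; spec <- design$spec
  } else {
    x <- as.matrix(design); spec <- NA_character_
  }
  stopifnot(length(y) == nrow(x))
  if (nrow(x) <= ncol(x) + 1L) stop("need more records than model terms")

  df <- data.frame(.y = y, x, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol, maxit = max_iter))
  )
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("rank error: singular design (aliased terms: ",
                        paste(names(beta)[is.na(beta)], collapse = ", "), ")")
  if (length(beta) > 1L && max(abs(beta[-1])) > 15) {
    stop("separation error: diverging coefficient(s) ",
         paste(names(beta[-1])[abs(beta[-1]) > 15], collapse = ", "))
  }
  names(beta)[1] <- "intercept"
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(beta)
  structure(
    list(coefficients = beta, se = se,
         loglik = as.numeric(stats::logLik(fit)),
         n = nrow(x), converged = fit$converged, spec = spec),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("Logistic regression fit")
  if (!is.na(x$spec)) cat(" (", x$spec, ")", sep = "")
  cat("\n")
  tab <- cbind(estimate = x$coefficients, se = x$se,
               z = x$coefficients / x$se)
  print(round(tab, digits))
  cat(sprintf("n = %d, log-likelihood = %.2f, converged = %s\n",
              x$n, x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Predicted death probability from a logistic fit
#'
#' Inverse-logit of the linear predictor for each design row.
#'
#' @param fit A `logistic_fit`.
#' @param x Design matrix with the fit's named columns (no intercept column).
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(fit, x) {
  if (!fit$converged) stop("fit did not converge; refusing to predict")
  x <- as.matrix(x)
  terms <- names(fit$coefficients)[-1]
  if (length(terms) == 0L) return(stats::plogis(rep(fit$coefficients[[1]],
                                                    nrow(x))))
  missing_terms <- setdiff(terms, colnames(x))
  if (length(missing_terms)) stop("design lacks term(s): ",
                                  paste(missing_terms, collapse = ", "))
  lp <- fit$coefficients[[1]] + drop(x[, terms, drop = FALSE] %*%
                                       fit$coefficients[-1])
  stats::plogis(lp)
}

#' Bootstrap internal validation of a logistic fit
#'
#' Resamples whole records with replacement, refits per replicate, and
#' summarises the replicate coefficients. Replicates that fail to converge
#' (or separate) are counted and skipped.
#'
#' @param design A design list from [build_design()].
#' @param reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @return A `bootstrap_summary`: `estimates` (reps x terms matrix of
#'   successful replicates), `mean`, `sd`, `ci_low`/`ci_high` (percentile
#'   2.5/97.5%), `n_failed`, `reps`.
#' @export
bootstrap_fit <- function(design, reps = 100L, seed = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(design$y)
  draws <- vector("list", reps)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_r <- tryCatch(
      fit_logistic(list(x = design$x[idx, , drop = FALSE],
                        y = design$y[idx], spec = design$spec)),
      error = function(e) NULL
    )
    if (is.null(fit_r) || !fit_r$converged) {
      n_failed <- n_failed + 1L
    } else {
      draws[[r]] <- fit_r$coefficients
    }
  }
  est <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(est) || nrow(est) == 0L) stop("all bootstrap replicates failed")
  structure(
    list(estimates = est,
         mean = colMeans(est),
         sd = apply(est, 2, stats::sd),
         ci_low = apply(est, 2, stats::quantile, probs = 0.025),
         ci_high = apply(est, 2, stats::quantile, probs = 0.975),
         n_failed = n_failed, reps = reps),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap summary over %d replicates (%d failed)\n",
              x$reps, x$n_failed))
  print(round(cbind(mean = x$mean, sd = x$sd,
                    `2.5%` = x$ci_low, `97.5%` = x$ci_high), digits))
  invisible(x)
}
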