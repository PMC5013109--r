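# Synthetic registry-like cohort generator: group-conditional covariate
# marginals plus a logistic 6-month mortality model with a COPD excess-risk
# offset, so the whole validation pipeline is testable without patient data.

lognormal_params <- function(mean, sd) {
  # moment-match a log-normal to a natural-scale mean and SD
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a large UK acute-coronary-syndrome registry population:
#' COPD prevalence 12.2%; group-conditional age-band mix, heart rate
#' (80.2 +/- 21.9 vs 87.2 +/- 23.7 beats/min), systolic blood pressure,
#' log-normal creatinine, in-hospital diuretic use (22.0% vs 32.5%), ST
#' deviation, elevated cardiac markers and smoking mix (COPD patients are
#' never never-smokers, by construction of the COPD rule). The 6-month death
#' indicator is drawn from a logistic model on standardised covariates (see
#' [grace_standardisation()]) with an additional COPD log-odds offset
#' `copd_log_odds_offset` (default 0.5) and a smaller diabetes offset. The
#' intercept default (-3.23) is tuned so overall mortality is about 12%.
#' Cardiac-arrest prevalence (5%) is a documented placeholder: registry
#' tables rarely report it.
#'
#' @param n Cohort size.
#' @param copd_prevalence Probability a record is COPD (default 0.122).
#' @param copd_log_odds_offset Additional log-odds of death for COPD
#'   records (default 0.5).
#' @param diabetes_log_odds_offset Additional log-odds of death for diabetic
#'   records (default 0.13, a deliberately smaller comparator effect).
#' @param outcome_coefficients Named numeric vector: `intercept` plus one
#'   log-odds coefficient per standardised score input.
#' @param missingness Named numeric vector of per-column missingness rates
#'   (default: none).
#' @param seed Optional integer seed stored in the config; used by
#'   [generate_cohort()] when set.
#' @param ... Overrides for any other config entry (see the returned list).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 10000,
                             copd_prevalence = 0.122,
                             copd_log_odds_offset = 0.5,
                             diabetes_log_odds_offset = 0.13,
                             outcome_coefficients = NULL,
                             missingness = NULL,
                             seed = NULL,
                             ...) {
  cfg <- list(
    n = as.integer(n),
    copd_prevalence = copd_prevalence,
    # age bands (years): lower edges 18,55,65,75,85; upper cap 95
    age_band_breaks = c(18, 55, 65, 75, 85, 95),
    age_band_probs = list(
      non_copd = c(0.188, 0.218, 0.240, 0.238, 0.115),
      copd     = c(0.112, 0.185, 0.296, 0.307, 0.100)
    ),
    heart_rate = list(non_copd = c(mean = 80.2, sd = 21.9),
                      copd     = c(mean = 87.2, sd = 23.7)),
    systolic_bp = list(non_copd = c(mean = 139.9, sd = 28.6),
                       copd     = c(mean = 138.2, sd = 29.0)),
    creatinine = list(non_copd = c(mean = 101.0, sd = 56.6),
                      copd     = c(mean = 103.4, sd = 58.3)),
    diuretic_rate = c(non_copd = 0.220, copd = 0.325),
    cardiac_arrest_rate = c(non_copd = 0.05, copd = 0.05),
    st_deviation_rate = c(non_copd = 0.607, copd = 0.553),
    elevated_markers_rate = c(non_copd = 0.918, copd = 0.922),
    diabetes_rate = c(non_copd = 0.22, copd = 0.22),
    smoking_probs = list(
      non_copd = c(never = 0.336, ex = 0.358, current = 0.306),
      copd     = c(never = 0, ex = 0.598, current = 0.402)
    ),
    # OAD indicator without an ever-smoking history (asthma-like) among
    # non-COPD never-smokers; keeps the COPD rule non-degenerate
    oad_rate_never_smokers = 0.05,
    diagnosis_probs = list(
      non_copd = c(STEMI = 0.326, NSTEMI = 0.434, UA = 0.240),
      copd     = c(STEMI = 0.255, NSTEMI = 0.497, UA = 0.248)
    ),
    admission_years = 2003:2013,
    outcome_coefficients = c(
      intercept = -3.23,
      age = 1.00, heart_rate = 0.35, systolic_bp = -0.35, creatinine = 0.30,
      diuretic_in_hospital = 0.80, cardiac_arrest = 1.00,
      st_deviation = 0.45, elevated_markers = 0.35
    ),
    copd_log_odds_offset = copd_log_odds_offset,
    diabetes_log_odds_offset = diabetes_log_odds_offset,
    standardisation = grace_standardisation(),
    missingness = missingness,
    seed = seed
  )
  if (!is.null(outcome_coefficients)) {
    cfg$outcome_coefficients[names(outcome_coefficients)] <- outcome_coefficients
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown generator config entries: ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 1) stop("config error: n must be >= 1")
  probs <- c(
    cfg$copd_prevalence, cfg$diuretic_rate, cfg$cardiac_arrest_rate,
    cfg$st_deviation_rate, cfg$elevated_markers_rate, cfg$diabetes_rate,
    cfg$oad_rate_never_smokers,
    unlist(cfg$age_band_probs), unlist(cfg$smoking_probs),
    unlist(cfg$diagnosis_probs), cfg$missingness
  )
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must lie in [0, 1]")
  if (cfg$smoking_probs$copd[["never"]] != 0) {
    stop("config error: COPD smoking distribution must put zero mass on 'never'")
  }
  invisible(cfg)
}

#' Serialise and restore a generator configuration
#'
#' Round-trips a [generator_config()] through a JSON or YAML file so cohort
#' simulations can be pinned down and shared.
#'
#' @param config A [generator_config()].
#' @param path Destination (`.json`, `.yaml` or `.yml`).
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns the restored `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  # serialised arrays carry no names, so named vectors are stored as maps
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  out <- keep_names(unclass(config))
  if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(out, path)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext)
  cfg <- generator_config()  # defaults, then overwrite with stored entries
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    entry <- raw[[nm]]
    if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]]))) {
      # restore named sub-structures (per-group parameter sets)
      entry <- lapply(entry, unlist)
    } else if (is.numeric(cfg[[nm]])) {
      entry <- unlist(entry)  # JSON/YAML maps keep their names
      if (is.integer(cfg[[nm]])) entry <- as.integer(entry)
    }
    cfg[[nm]] <- entry
  }
  cfg$n <- as.integer(cfg$n)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

draw_truncated_normal <- function(n, mean, sd) {
  # strictly positive physiological values; rejection is cheap here
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic acute-coronary-syndrome cohort
#'
#' Draws covariates from the group-conditional distributions in `config`,
#' enforces joint consistency between the airway-disease indicator, smoking
#' and the COPD rule of [identify_copd()], and draws the 6-month death
#' indicator from the configured logistic model. Reproducible given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A cohort `data.frame` with the canonical columns.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n = 500, seed = 1))
#' mean(identify_copd(cohort))
generate_cohort <- function(config) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n

  copd <- stats::runif(n) < config$copd_prevalence
  grp <- ifelse(copd, "copd", "non_copd")

  band <- integer(n)
  band[!copd] <- sample.int(5L, sum(!copd), replace = TRUE,
                            prob = config$age_band_probs$non_copd)
  band[copd] <- sample.int(5L, sum(copd), replace = TRUE,
                           prob = config$age_band_probs$copd)
  brk <- config$age_band_breaks
  age <- stats::runif(n, brk[band], brk[band + 1L])

  draw_norm_by_group <- function(field) {
    out <- numeric(n)
    for (g in c("non_copd", "copd")) {
      idx <- grp == g
      p <- config[[field]][[g]]
      out[idx] <- draw_truncated_normal(sum(idx), p[["mean"]], p[["sd"]])
    }
    out
  }
  heart_rate <- draw_norm_by_group("heart_rate")
  systolic_bp <- draw_norm_by_group("systolic_bp")

  creat <- numeric(n)
  for (g in c("non_copd", "copd")) {
    idx <- grp == g
    p <- config$creatinine[[g]]
    lp <- lognormal_params(p[["mean"]], p[["sd"]])
    creat[idx] <- stats::rlnorm(sum(idx), lp[["meanlog"]], lp[["sdlog"]])
  }

  draw_rate_by_group <- function(field) {
    r <- config[[field]]
    stats::runif(n) < ifelse(copd, r[["copd"]], r[["non_copd"]])
  }
  diuretic <- draw_rate_by_group("diuretic_rate")
  arrest <- draw_rate_by_group("cardiac_arrest_rate")
  st_dev <- draw_rate_by_group("st_deviation_rate")
  markers <- draw_rate_by_group("elevated_markers_rate")
  diabetes <- draw_rate_by_group("diabetes_rate")

  smoking <- character(n)
  for (g in c("non_copd", "copd")) {
    idx <- grp == g
    p <- config$smoking_probs[[g]]
    smoking[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
  }
  # COPD implies OAD; otherwise OAD may occur only in never-smokers
  # (an ever-smoker with OAD would be classified COPD by the rule)
  oad <- copd
  never_non <- !copd & smoking == "never"
  oad[never_non] <- stats::runif(sum(never_non)) < config$oad_rate_never_smokers

  diagnosis <- character(n)
  for (g in c("non_copd", "copd")) {
    idx <- grp == g
    p <- config$diagnosis_probs[[g]]
    diagnosis[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
  }

  cohort <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    age = age, heart_rate = heart_rate, systolic_bp = systolic_bp,
    creatinine = creat,
    diuretic_in_hospital = diuretic, cardiac_arrest = arrest,
    st_deviation = st_dev, elevated_markers = markers,
    oad_indicator = oad, smoking = smoking, diagnosis = diagnosis,
    diabetes = diabetes,
    admission_year = sample(config$admission_years, n, replace = TRUE),
    died_6m = NA,
    stringsAsFactors = FALSE
  )
  p <- implied_outcome_probability(cohort, config)
  cohort$died_6m <- stats::runif(n) < p

  if (!is.null(config$missingness) && any(config$missingness > 0)) {
    cohort <- inject_missingness(cohort, config$missingness)
  }
  cohort
}

#' Per-record outcome probability under the generator's logistic model
#'
#' Inverse-logit of `intercept + sum(coef * standardised covariate) +
#' copd_offset * COPD + diabetes_offset * diabetes`, with COPD derived by the
#' [identify_copd()] rule. This is the generator's own truth, used to check
#' that empirical death rates match the model.
#'
#' @param cohort Cohort `data.frame` with complete covariates.
#' @param config A [generator_config()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
implied_outcome_probability <- function(cohort, config) {
  std <- config$standardisation
  b <- config$outcome_coefficients
  copd <- identify_copd(cohort)
  lp <- b[["intercept"]] +
    b[["age"]] * (cohort$age - std$age[["center"]]) / std$age[["scale"]] +
    b[["heart_rate"]] * (cohort$heart_rate - std$heart_rate[["center"]]) /
      std$heart_rate[["scale"]] +
    b[["systolic_bp"]] * (cohort$systolic_bp - std$systolic_bp[["center"]]) /
      std$systolic_bp[["scale"]] +
    b[["creatinine"]] * (log(cohort$creatinine) - std$log_creatinine[["center"]]) /
      std$log_creatinine[["scale"]] +
    b[["diuretic_in_hospital"]] * cohort$diuretic_in_hospital +
    b[["cardiac_arrest"]] * cohort$cardiac_arrest +
    b[["st_deviation"]] * cohort$st_deviation +
    b[["elevated_markers"]] * cohort$elevated_markers +
    config$copd_log_odds_offset * copd +
    config$diabetes_log_odds_offset * cohort$diabetes
  stats::plogis(lp)
}

#' Set cohort cells missing completely at random
#'
#' Each targeted cell is independently set missing with its column's rate.
#'
#' @param cohort Cohort `data.frame`.
#' @param rates Named numeric vector of per-column missingness probabilities.
#' @param seed Optional integer seed for reproducibility.
#' @return The cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rates, seed = NULL) {
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  bad <- setdiff(names(rates), COHORT_COLUMNS)
  if (length(bad)) stop("unknown column(s) in missingness rates: ",
                        paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(rates)) {
    if (rates[[nm]] <= 0) next
    hit <- stats::runif(nrow(cohort)) < rates[[nm]]
    cohort[[nm]][hit] <- NA
  }
  cohort
}
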