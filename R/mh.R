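# Decile stratification of predicted risk and the Mantel-Haenszel pooled
# risk ratio comparing observed death risk between groups conditional on
# predicted risk, plus the observed-vs-predicted summary tables.

quantile_groups <- function(x, g) {
  # rank-based equal-count bins; ties broken by stable input order so
  # bin sizes differ by at most 1 regardless of duplication
  n <- length(x)
  ord <- order(x)            # stable for ties (radix)
  bin <- floor((seq_len(n) - 1L) * g / n) + 1L
  out <- integer(n)
  out[ord] <- bin
  out
}

#' Assign predictions to deciles of predicted risk
#'
#' Rank-based equal-count bins over the pooled predictions (both comparison
#' groups together, so strata are common to both). Ties are broken by stable
#' input order; bin sizes differ by at most one.
#'
#' @param risks Numeric vector of predicted risks (length >= 10).
#' @return Integer vector of decile labels 1-10.
#' @export
assign_deciles <- function(risks) {
  if (length(risks) < 10L) stop("need at least 10 observations to form deciles")
  if (anyNA(risks)) stop("risks must be non-missing")
  quantile_groups(risks, 10L)
}

#' Per-stratum 2x2 death counts for the Mantel-Haenszel estimator
#'
#' @param deciles Integer stratum labels.
#' @param group_flag Logical: membership of the exposed group (e.g. COPD).
#' @param outcomes Logical: death by 6 months.
#' @return Data frame with one row per non-empty stratum: `stratum`, `a`
#'   (deaths, exposed), `n1` (exposed total), `b` (deaths, unexposed),
#'   `n0` (unexposed total), `N`.
#' @export
stratum_tables <- function(deciles, group_flag, outcomes) {
  stopifnot(length(deciles) == length(group_flag),
            length(deciles) == length(outcomes))
  if (anyNA(group_flag) || anyNA(outcomes)) stop("inputs must be non-missing")
  levels <- sort(unique(deciles))
  rows <- lapply(levels, function(k) {
    in_k <- deciles == k
    data.frame(
      stratum = k,
      a = sum(outcomes[in_k] & group_flag[in_k]),
      n1 = sum(group_flag[in_k]),
      b = sum(outcomes[in_k] & !group_flag[in_k]),
      n0 = sum(!group_flag[in_k])
    )
  })
  out <- do.call(rbind, rows)
  out$N <- out$n1 + out$n0
  out
}

#' Mantel-Haenszel pooled risk ratio across strata
#'
#' RR = \[sum_k a_k n0_k / N_k\] / \[sum_k b_k n1_k / N_k\], with a 95% CI
#' from the Greenland-Robins variance of log RR. Strata where either group
#' is empty contribute nothing and are dropped (their count is reported).
#'
#' @param strata Data frame as returned by [stratum_tables()].
#' @return An `mh_result`: `rr`, `ci_low`, `ci_high`, `se_log_rr`,
#'   `n_strata_used`, `n_strata_dropped`.
#' @export
#' @examples
#' s <- data.frame(a = c(8, 30), n1 = c(40, 60), b = c(10, 5), n0 = c(100, 50))
#' s$N <- s$n1 + s$n0
#' mh_pooled_rr(s)
mh_pooled_rr <- function(strata) {
  stopifnot(all(c("a", "n1", "b", "n0") %in% names(strata)))
  for (nm in intersect(c("a", "n1", "b", "n0", "N"), names(strata))) {
    strata[[nm]] <- as.numeric(strata[[nm]])  # avoid integer overflow in products
  }
  if (is.null(strata$N)) strata$N <- strata$n1 + strata$n0
  if (any(strata$a > strata$n1 | strata$b > strata$n0 |
          strata$a < 0 | strata$b < 0)) {
    stop("invalid stratum counts")
  }
  usable <- strata$n1 > 0 & strata$n0 > 0
  n_dropped <- sum(!usable)
  strata <- strata[usable, , drop = FALSE]
  if (nrow(strata) == 0L) stop("no usable strata: every stratum has an empty group")

  num <- sum(strata$a * strata$n0 / strata$N)
  den <- sum(strata$b * strata$n1 / strata$N)
  if (den == 0) stop("undefined risk ratio: no deaths among the unexposed in any stratum")
  rr <- num / den

  if (num > 0) {
    # Greenland-Robins variance of log RR
    v <- sum((strata$a + strata$b) * strata$n1 * strata$n0 / strata$N^2 -
               strata$a * strata$b / strata$N) / (num * den)
    se <- sqrt(v)
    z <- stats::qnorm(0.975)
    ci <- rr * exp(c(-z, z) * se)
  } else {
    se <- NA_real_  # no exposed deaths: RR is 0, log-scale CI undefined
    ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(rr = rr, ci_low = ci[1], ci_high = ci[2],
         se_log_rr = se, n_strata_used = nrow(strata),
         n_strata_dropped = n_dropped),
    class = "mh_result"
  )
}

#' @export
print.mh_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mantel-Haenszel pooled RR: %.*f (95%% CI %.*f to %.*f)\n",
              digits, x$rr, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  strata used: %d  dropped (empty group): %d\n",
              x$n_strata_used, x$n_strata_dropped))
  invisible(x)
}

#' Observed vs predicted mortality by decile of predicted risk
#'
#' @param risks Predicted risks (pooled groups).
#' @param outcomes Logical death indicator.
#' @param group_flag Logical subgroup membership.
#' @return Data frame per decile: `decile`, `n`, `mean_predicted`,
#'   `observed_non_group`, `observed_group` (proportions; `NA`, not 0, where
#'   a group is empty in a decile).
#' @export
observed_vs_predicted_by_decile <- function(risks, outcomes, group_flag) {
  stopifnot(length(risks) == length(outcomes),
            length(risks) == length(group_flag))
  dec <- assign_deciles(risks)
  rows <- lapply(sort(unique(dec)), function(k) {
    in_k <- dec == k
    grp <- group_flag[in_k]
    dth <- outcomes[in_k]
    data.frame(
      decile = k,
      n = sum(in_k),
      mean_predicted = mean(risks[in_k]),
      observed_non_group = if (any(!grp)) mean(dth[!grp]) else NA_real_,
      observed_group = if (any(grp)) mean(dth[grp]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Observed mortality by risk band and group
#'
#' @param risks Predicted risks.
#' @param outcomes Logical death indicator.
#' @param group_flag Logical subgroup membership.
#' @param bands A [risk_bands()].
#' @return Data frame per band: `band`, `n_non_group`, `observed_non_group`,
#'   `n_group`, `observed_group` (`NA`, not 0, for empty cells).
#' @export
observed_by_band <- function(risks, outcomes, group_flag, bands = risk_bands()) {
  band <- stratify_risk(risks, bands)
  rows <- lapply(BAND_LEVELS, function(b) {
    in_b <- band == b
    grp <- group_flag[in_b]
    dth <- outcomes[in_b]
    data.frame(
      band = b,
      n_non_group = sum(!grp),
      observed_non_group = if (any(!grp)) mean(dth[!grp]) else NA_real_,
      n_group = sum(grp),
      observed_group = if (any(grp)) mean(dth[grp]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out$band <- factor(out$band, levels = BAND_LEVELS, ordered = TRUE)
  out
}
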