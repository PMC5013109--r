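# Multiplicative subgroup recalibration, multiplier estimation,
# reclassification tables, and deaths-by-decile stratification.

#' Multiplicatively recalibrate a subgroup's predicted risks
#'
#' Group members' risks are multiplied by `factor` and capped at 1 (the cap
#' keeps the operation total; clinically relevant risks sit far below it);
#' non-members are returned unchanged to the bit.
#'
#' @param risk Predicted risks in `[0, 1]`.
#' @param group_flag Logical: records whose risk is rescaled.
#' @param factor Positive multiplier (e.g. the subgroup's adjusted risk
#'   ratio, 1.3).
#' @param cap_at_one Cap rescaled risks at 1 (default `TRUE`).
#' @return Numeric vector of recalibrated risks.
#' @export
#' @examples
#' recalibrate(c(0.025, 0.9), c(TRUE, TRUE), factor = 1.3)
recalibrate <- function(risk, group_flag, factor, cap_at_one = TRUE) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("config error: factor must be a single positive number")
  }
  stopifnot(length(risk) == length(group_flag))
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) stop("risk must lie in [0, 1]")
  out <- risk
  out[group_flag] <- risk[group_flag] * factor
  if (cap_at_one) out <- pmin(out, 1)
  out
}

#' Estimate the subgroup recalibration multiplier from the data
#'
#' The multiplier is the decile-adjusted Mantel-Haenszel pooled risk ratio
#' of observed death comparing group with non-group members, conditional on
#' the supplied predictions ([assign_deciles()] on the pooled risks, then
#' [mh_pooled_rr()]).
#'
#' @param risk Predicted risks under the model being recalibrated.
#' @param outcomes Logical death indicator.
#' @param group_flag Logical subgroup membership.
#' @return The [mh_pooled_rr()] result; its `rr` element is the multiplier.
#' @export
estimate_multiplier <- function(risk, outcomes, group_flag) {
  dec <- assign_deciles(risk)
  mh_pooled_rr(stratum_tables(dec, group_flag, outcomes))
}

#' Cross-tabulate risk bands before and after a model modification
#'
#' @param bands_before,bands_after Factors (or characters) with levels
#'   `low`, `moderate`, `high`.
#' @return A `reclass_matrix`: `counts` (3x3, rows = before), `row_pct`
#'   (row percentages; `NaN` rows with no members print as empty).
#' @export
reclassification_matrix <- function(bands_before, bands_after) {
  stopifnot(length(bands_before) == length(bands_after))
  b <- factor(as.character(bands_before), levels = BAND_LEVELS)
  a <- factor(as.character(bands_after), levels = BAND_LEVELS)
  if (anyNA(b) || anyNA(a)) stop("bands must be low/moderate/high, non-missing")
  counts <- table(before = b, after = a)
  row_pct <- 100 * prop.table(counts, margin = 1)
  structure(list(counts = unclass(counts), row_pct = unclass(row_pct),
                 n = length(b)),
            class = "reclass_matrix")
}

#' @export
print.reclass_matrix <- function(x, ...) {
  cat("Risk-band reclassification (rows: before, columns: after)\n")
  cnt <- x$counts
  pct <- x$row_pct
  out <- matrix("", 3, 3, dimnames = dimnames(cnt))
  for (i in 1:3) for (j in 1:3) {
    out[i, j] <- if (sum(cnt[i, ]) == 0) sprintf("%d", cnt[i, j])
    else sprintf("%d (%.1f%%)", cnt[i, j], pct[i, j])
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Share of a group's deaths falling in each decile of predicted risk
#'
#' Deciles are assigned on the pooled predictions; within the group, the
#' proportion of its deaths occurring in each decile is returned (the
#' risk-stratification profile: a well-stratifying model concentrates
#' deaths in the top deciles).
#'
#' @param risk Predicted risks (all records).
#' @param outcomes Logical death indicator.
#' @param group_flag Logical subgroup membership.
#' @return Numeric vector of length 10, non-negative, summing to 1.
#' @export
deaths_by_decile <- function(risk, outcomes, group_flag) {
  stopifnot(length(risk) == length(outcomes),
            length(risk) == length(group_flag))
  dec <- assign_deciles(risk)
  deaths <- outcomes & group_flag
  total <- sum(deaths)
  if (total == 0L) stop("undefined proportions: the group has no deaths")
  counts <- vapply(1:10, function(k) sum(deaths[dec == k]), numeric(1))
  counts / total
}
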