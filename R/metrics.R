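# Discrimination and calibration metrics: C-statistic (Mann-Whitney
# construction), DeLong paired comparison, Hosmer-Lemeshow goodness of fit,
# continuous net reclassification improvement.

check_outcomes <- function(outcomes) {
  outcomes <- as.logical(outcomes)
  if (anyNA(outcomes)) stop("outcomes must be non-missing")
  if (all(outcomes) || !any(outcomes)) {
    stop("degenerate outcomes: need at least one event and one non-event")
  }
  outcomes
}

#' Concordance (C) statistic
#'
#' Probability that a randomly chosen event carries a higher predicted risk
#' than a randomly chosen non-event, ties counted one half (the Mann-Whitney
#' construction), computed from midranks in O(n log n).
#'
#' @param predictions Numeric predicted risks.
#' @param outcomes Logical (or 0/1) event indicator.
#' @return C-statistic in `[0, 1]`.
#' @export
#' @examples
#' c_statistic(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
c_statistic <- function(predictions, outcomes) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  if (anyNA(predictions)) stop("predictions must be non-missing")
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  r <- rank(predictions, ties.method = "average")
  (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 per event, V01 per non-event, computed
# from midranks (fast equivalent of averaging the 0/0.5/1 kernel).
delong_components <- function(predictions, outcomes) {
  x <- predictions[outcomes]
  y <- predictions[!outcomes]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two paired C-statistics (DeLong test)
#'
#' Asymptotic two-sided test for the difference between the C-statistics of
#' two prediction sets evaluated on the same records, using DeLong's
#' structural-component covariance for paired curves.
#'
#' @param pred_a,pred_b Predicted risks from the two models (same records).
#' @param outcomes Logical event indicator.
#' @return List: `c_a`, `c_b`, `difference` (a minus b), `z`, `p`.
#' @export
compare_c_statistics <- function(pred_a, pred_b, outcomes) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(pred_a) == length(outcomes),
            length(pred_b) == length(outcomes))
  da <- delong_components(pred_a, outcomes)
  db <- delong_components(pred_b, outcomes)
  m <- length(da$v10); n <- length(da$v01)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- da$auc - db$auc
  if (var_diff <= 0) {
    # identical (or rank-identical) predictions: no variance in the contrast
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(c_a = da$auc, c_b = db$auc, difference = diff, z = z, p = p)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Records are grouped into `g` equal-count groups of predicted risk; the
#' statistic is `sum_g (O_g - E_g)^2 / (n_g * pibar_g * (1 - pibar_g))`
#' with `E_g = n_g * pibar_g` and `pibar_g` the mean prediction in group
#' `g`, referred to a chi-square with `g - 2` degrees of freedom (the
#' fitted-model convention, applied to every model here).
#'
#' @param predictions Predicted risks.
#' @param outcomes Logical event indicator.
#' @param g Number of groups (default 10).
#' @return List: `statistic`, `df`, `p`, `table` (per-group observed and
#'   expected counts).
#' @export
hosmer_lemeshow <- function(predictions, outcomes, g = 10L) {
  outcomes <- as.logical(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  if (length(predictions) < g) stop("need at least g observations")
  if (!any(outcomes)) stop("need at least one event")
  grp <- quantile_groups(predictions, g)
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(k) {
    in_k <- grp == k
    data.frame(group = k, n = sum(in_k),
               observed = sum(outcomes[in_k]),
               expected = sum(predictions[in_k]),
               mean_predicted = mean(predictions[in_k]))
  }))
  if (any(tab$mean_predicted <= 0 | tab$mean_predicted >= 1)) {
    stop("degenerate group: a group's mean prediction is 0 or 1; reduce g")
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$n * tab$mean_predicted * (1 - tab$mean_predicted)))
  df <- g - 2L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Continuous net reclassification improvement
#'
#' NRI = \[P(up | event) - P(down | event)\] + \[P(down | non-event) -
#' P(up | non-event)\], where "up"/"down" mean any increase/decrease of the
#' predicted risk from the old to the new model; exact ties count as
#' neither. The z statistic uses the multinomial variance
#' `var = [p_up + p_down - (p_up - p_down)^2]/n` summed over the event and
#' non-event groups.
#'
#' @param pred_old,pred_new Paired predicted risks under the two models.
#' @param outcomes Logical event indicator.
#' @return List: `nri`, `nri_events`, `nri_non_events`, `z`, `p`.
#' @export
#' @examples
#' continuous_nri(c(0.1, 0.2, 0.3, 0.5, 0.5),
#'                c(0.2, 0.3, 0.2, 0.4, 0.6),
#'                c(TRUE, TRUE, TRUE, FALSE, FALSE))
continuous_nri <- function(pred_old, pred_new, outcomes) {
  outcomes <- check_outcomes(outcomes)
  stopifnot(length(pred_old) == length(outcomes),
            length(pred_new) == length(outcomes))
  up <- pred_new > pred_old
  down <- pred_new < pred_old

  prop <- function(keep) {
    c(up = mean(up[keep]), down = mean(down[keep]), n = sum(keep))
  }
  e <- prop(outcomes)
  ne <- prop(!outcomes)
  nri_e <- e[["up"]] - e[["down"]]
  nri_ne <- ne[["down"]] - ne[["up"]]
  nri <- nri_e + nri_ne
  var <- (e[["up"]] + e[["down"]] - nri_e^2) / e[["n"]] +
    (ne[["up"]] + ne[["down"]] - (ne[["up"]] - ne[["down"]])^2) / ne[["n"]]
  if (var <= 0) {
    z <- 0; p <- 1  # nobody moved in either group
  } else {
    z <- nri / sqrt(var)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(nri = nri, nri_events = nri_e, nri_non_events = nri_ne, z = z, p = p)
}
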