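.check_binary_outcome <- function(outcomes) {
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1)))
    stop("outcomes must be 0/1 with no missing values")
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes))
    stop("both outcome classes must be present")
}

# Midrank structural components of the Mann-Whitney AUC.
# V10[i]: placement of case i among controls; V01[j]: of control j
# among cases (ties count 1/2).
.auc_components <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  n1 <- length(cases)
  n0 <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  r1 <- rank(cases, ties.method = "average")
  r0 <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r1) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r0) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney estimator of the AUC — the fraction of case/control
#' pairs in which the case receives the higher score, ties counted one
#' half — with a 95% confidence interval from the DeLong
#' structural-component variance.  Any monotone score can be supplied
#' (probabilities or intercept-free linear predictors; the AUC is
#' invariant to monotone transforms).
#'
#' @param scores Numeric risk scores.
#' @param outcomes 0/1 outcome vector.
#' @param conf_level Confidence level.
#' @return An object of class `auc_result`: list with `auc`, `se`,
#'   `ci` (length 2), `n_events`, `n_nonevents`.
#' @export
#' @examples
#' auc(c(0.8, 0.6, 0.7, 0.2), c(1, 1, 0, 0))
auc <- function(scores, outcomes, conf_level = 0.95) {
  stopifnot(length(scores) == length(outcomes))
  .check_binary_outcome(outcomes)
  cmp <- .auc_components(scores, outcomes)
  v <- stats::var(cmp$v10) / cmp$n1 + stats::var(cmp$v01) / cmp$n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  structure(list(auc = cmp$auc, se = se,
                 ci = c(cmp$auc - z * se, cmp$auc + z * se),
                 n_events = cmp$n1, n_nonevents = cmp$n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f; %.3f), %d events / %d non-events\n",
              x$auc, x$ci[1], x$ci[2], x$n_events, x$n_nonevents))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models evaluated on the same subjects using
#' the structural-component covariance of the paired Mann-Whitney
#' statistics, with a two-sided z-test on the AUC difference.
#'
#' @param scores1,scores2 Paired risk scores for the same subjects.
#' @param outcomes 0/1 outcome vector.
#' @param alpha Significance level used for the `significant` flag.
#' @return An object of class `delong_result`: `auc1`, `auc2`, `diff`,
#'   `cov` (2x2 covariance matrix of the two AUC estimates), `se_diff`,
#'   `z`, `p`, `significant`.
#' @export
delong_compare <- function(scores1, scores2, outcomes, alpha = 0.05) {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(outcomes))
    stop("scores1, scores2 and outcomes must have equal length")
  .check_binary_outcome(outcomes)
  c1 <- .auc_components(scores1, outcomes)
  c2 <- .auc_components(scores2, outcomes)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  covm <- s10 / c1$n1 + s01 / c1$n0
  dimnames(covm) <- list(c("auc1", "auc2"), c("auc1", "auc2"))
  d <- c1$auc - c2$auc
  v <- covm[1, 1] + covm[2, 2] - 2 * covm[1, 2]
  if (d == 0 || v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = c1$auc, auc2 = c2$auc, diff = d, cov = covm,
                 se_diff = sqrt(max(v, 0)), z = z, p = p,
                 significant = p < alpha),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC1 %.3f vs AUC2 %.3f, diff %.3f, z = %.3f, p = %.4g\n",
              x$auc1, x$auc2, x$diff, x$z, x$p))
  invisible(x)
}

#' Net reclassification improvement from reclassification counts
#'
#' Computes the categorical NRI from already-tabulated movement counts:
#' `nri_events = (events up - events down) / n_events`,
#' `nri_nonevents = (non-events down - non-events up) / n_nonevents`,
#' `nri_total` their sum.  A move "up" is into a higher risk category
#' under the new model, which is an improvement for events and a
#' deterioration for non-events.  Component standard errors use the
#' asymptotic multinomial form
#' `se^2 = (up + down)/n^2 - (up - down)^2/n^3`; the total combines the
#' components as independent.
#'
#' @param event_up,event_down Numbers of events moved to a higher /
#'   lower category by the new model.
#' @param n_events Number of events.
#' @param nonevent_up,nonevent_down Same for non-events.
#' @param n_nonevents Number of non-events.
#' @return An object of class `nri_result`.
#' @export
#' @examples
#' nri_from_counts(32, 21, 110, 76, 110, 1291)
nri_from_counts <- function(event_up, event_down, n_events,
                            nonevent_up, nonevent_down, n_nonevents) {
  stopifnot(event_up + event_down <= n_events,
            nonevent_up + nonevent_down <= n_nonevents)
  comp <- function(up, down, n, sign = 1) {
    est <- sign * (up - down) / n
    se <- sqrt(max((up + down) / n^2 - (up - down)^2 / n^3, 0))
    z <- if (se > 0) est / se else 0
    c(est = est, se = se, z = z,
      p = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1)
  }
  ev <- comp(event_up, event_down, n_events)
  ne <- comp(nonevent_down, nonevent_up, n_nonevents)
  tot_est <- ev[["est"]] + ne[["est"]]
  tot_se <- sqrt(ev[["se"]]^2 + ne[["se"]]^2)
  tot_z <- if (tot_se > 0) tot_est / tot_se else 0
  structure(list(
    event_up = event_up, event_down = event_down, n_events = n_events,
    nonevent_up = nonevent_up, nonevent_down = nonevent_down,
    n_nonevents = n_nonevents,
    nri_events = ev[["est"]], se_events = ev[["se"]],
    z_events = ev[["z"]], p_events = ev[["p"]],
    nri_nonevents = ne[["est"]], se_nonevents = ne[["se"]],
    z_nonevents = ne[["z"]], p_nonevents = ne[["p"]],
    nri_total = tot_est, se_total = tot_se, z_total = tot_z,
    p_total = if (tot_se > 0) 2 * stats::pnorm(-abs(tot_z)) else 1),
    class = "nri_result")
}

#' Categorical net reclassification improvement
#'
#' Cross-classifies paired predicted probabilities into ordered risk
#' categories (default bounds 10%, 20%, 30%, 40%, 50%, treated as
#' half-open intervals with a probability of exactly 0.10 in the lowest
#' category) and summarises the net movement: events should move up,
#' non-events down.
#'
#' @param p_new,p_old Paired predicted probabilities in \[0, 1\].
#' @param outcomes 0/1 outcome vector.
#' @param cutpoints Ordered interior category bounds.
#' @return An object of class `nri_result`, see [nri_from_counts()].
#' @export
nri <- function(p_new, p_old, outcomes,
                cutpoints = c(0.10, 0.20, 0.30, 0.40, 0.50)) {
  if (length(p_new) != length(p_old) ||
      length(p_new) != length(outcomes))
    stop("p_new, p_old and outcomes must have equal length")
  .check_binary_outcome(outcomes)
  pr <- c(p_new, p_old)
  if (anyNA(pr) || any(pr < 0 | pr > 1))
    stop("probabilities must lie in [0, 1]")
  breaks <- c(0, cutpoints, 1)
  cat_new <- as.integer(cut(p_new, breaks, include.lowest = TRUE,
                            right = TRUE))
  cat_old <- as.integer(cut(p_old, breaks, include.lowest = TRUE,
                            right = TRUE))
  up <- cat_new > cat_old
  down <- cat_new < cat_old
  ev <- outcomes == 1
  nri_from_counts(sum(up & ev), sum(down & ev), sum(ev),
                  sum(up & !ev), sum(down & !ev), sum(!ev))
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI events     %.4f (p = %.3f)  [%d up / %d down of %d]\n",
    x$nri_events, x$p_events, x$event_up, x$event_down, x$n_events))
  cat(sprintf(
    "NRI non-events %.4f (p = %.3f)  [%d down / %d up of %d]\n",
    x$nri_nonevents, x$p_nonevents, x$nonevent_down, x$nonevent_up,
    x$n_nonevents))
  cat(sprintf("NRI total      %.4f (p = %.3f)\n", x$nri_total, x$p_total))
  invisible(x)
}

#' Hosmer-Lemeshow calibration test
#'
#' Subjects are ranked by predicted probability and split into
#' equal-size groups (quintiles by default); in each group the observed
#' number of events `O_g` is compared with the expected number
#' `E_g = sum of predicted probabilities` via
#' `sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))`, referred to a
#' chi-squared distribution with `groups - 2` degrees of freedom (3 for
#' quintiles).  A statistic above `cutoff` (default 11.5, the 1%
#' critical value for 3 df) flags a significant lack of calibration.
#' Ties in predicted probability are broken by a stable sort on the
#' original subject order so the grouping is deterministic.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param outcomes 0/1 outcome vector.
#' @param groups Number of equal-size risk groups.
#' @param cutoff Lack-of-fit flag threshold on the statistic.
#' @param eps Guard used when a group's expected count is degenerate
#'   (0 or equal to the group size).
#' @return An object of class `hl_result`: `statistic`, `df`, `p`,
#'   `significant_lack_of_fit` and a per-group `table` (`n`, `observed`,
#'   `expected`).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 5,
                            cutoff = 11.5, eps = 1e-8) {
  stopifnot(length(probabilities) == length(outcomes))
  .check_binary_outcome(outcomes)
  n <- length(probabilities)
  if (n < groups) stop("need at least as many subjects as groups")
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  ord <- order(probabilities, seq_len(n))
  bounds <- floor(seq(0, n, length.out = groups + 1))
  g <- rep(seq_len(groups), times = diff(bounds))
  p_s <- probabilities[ord]
  y_s <- outcomes[ord]
  ng <- tabulate(g, groups)
  Og <- vapply(seq_len(groups), function(k) sum(y_s[g == k]), 0)
  Eg <- vapply(seq_len(groups), function(k) sum(p_s[g == k]), 0)
  denom <- Eg * (1 - Eg / ng)
  degenerate <- denom < eps
  if (any(degenerate)) {
    message("Hosmer-Lemeshow: ", sum(degenerate),
            " group(s) with degenerate expected counts; eps guard applied")
    denom[degenerate] <- pmax(denom[degenerate], eps)
  }
  stat <- sum((Og - Eg)^2 / denom)
  df <- groups - 2
  structure(list(
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE),
    significant_lack_of_fit = stat > cutoff, cutoff = cutoff,
    table = data.frame(group = seq_len(groups), n = ng, observed = Og,
                       expected = Eg)),
    class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi-squared %.2f on %d df (p = %.4g)%s\n",
              x$statistic, x$df, x$p,
              if (x$significant_lack_of_fit)
                sprintf("  ** lack of fit (> %.1f)", x$cutoff) else ""))
  invisible(x)
}

#' Predicted incidence
#'
#' The mean predicted probability, as a percentage — compared with the
#' observed incidence to assess calibration-in-the-large.
#'
#' @param probabilities Predicted probabilities.
#' @return Percentage (100 x mean probability).
#' @export
predicted_incidence <- function(probabilities) {
  if (length(probabilities) == 0 || anyNA(probabilities))
    stop("probabilities must be non-empty and non-missing")
  100 * mean(probabilities)
}
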