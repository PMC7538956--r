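#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` over distinct event times, with
#' the usual tie conventions (simultaneous events pooled; censoring at an
#' event time counted after the event). Estimation is delegated to
#' [survival::survfit()].
#'
#' @param records data.frame with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored).
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`
#'   at the distinct observed times.
#' @export
km_curve <- function(records) {
  .check_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = nrow(records)),
            class = "km_curve")
}

.check_survival <- function(records) {
  if (!all(c("time", "event") %in% names(records)))
    .stopf("records need columns time, event")
  if (nrow(records) < 1L) .stopf("need at least one record")
  if (any(!is.finite(records$time)) || any(records$time <= 0))
    .stopf("times must be finite and positive")
  if (!all(records$event %in% c(0, 1)))
    .stopf("event must be 0 (censored) or 1 (event)")
  invisible(records)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d distinct times, %d events\n",
              x$n, length(x$time), sum(x$n_event)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time", ylab = "S(t)", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1),
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the observed-minus-
#' expected events are accumulated with their hypergeometric variance;
#' the statistic `U^2 / V` is referred to a chi-square with 1 df
#' (two-sided p). Delegated to [survival::survdiff()].
#'
#' @param records data.frame with columns `time`, `event`, `group` (exactly
#'   two group labels).
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  .check_survival(records)
  if (!"group" %in% names(records)) .stopf("records need a 'group' column")
  groups <- unique(records$group)
  if (length(groups) != 2L) .stopf("need exactly two groups")
  if (any(table(records$group) == 0L)) .stopf("both groups must be nonempty")
  if (sum(records$event) == 0L) .stopf("no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  list(chi_square = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' `sum (O - E)^2 / E` with `df = (r - 1)(c - 1)`; no continuity
#' correction by default (available via `correct = TRUE` for 2x2 tables).
#'
#' @param table matrix of nonnegative integer counts, at least 2x2, with
#'   no zero row or column margin.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
contingency_chisq <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) .stopf("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    .stopf("table must contain nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .stopf("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties, Pearson correlation on the ranks, and a two-sided
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) .stopf("'x' and 'y' must have equal length")
  if (length(x) < 3L) .stopf("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    .stopf("undefined correlation: constant vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}
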