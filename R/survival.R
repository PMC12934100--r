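#' Kaplan-Meier product-limit estimator
#'
#' Computes \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' event times, with the standard tie convention that subjects censored at
#' an event time remain at risk for the events at that time (events precede
#' censorings).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Data.frame of class \code{"km_curve"} with one row per distinct
#'   event time: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{survival}; attribute \code{"n"} holds the number of subjects.
#'   Zero rows when every subject is censored (the curve stays at 1).
#' @examples
#' km_estimate(c(1, 2), c(1, 1))  # survival 0.5 then 0
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) == 0) stop("at least one subject is required")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), 0)
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    survival = surv, row.names = NULL)
  attr(out, "n") <- length(time)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-sample log-rank test
#'
#' At every distinct event time the observed number of events in the first
#' group is compared with its hypergeometric expectation given the risk
#' sets; the statistic is \eqn{(\sum O - \sum E)^2 / \sum V} with
#' \eqn{V = d (n - d) n_1 n_2 / (n^2 (n - 1))} per time, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels; exactly two non-empty groups.
#' @return List with \code{statistic}, \code{df} (= 1), \code{p},
#'   \code{observed} and \code{expected} (per group, in sorted label order).
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time); event <- as.numeric(event)
  group <- as.character(group)
  if (length(time) != length(event) || length(time) != length(group))
    stop("time, event and group must have the same length")
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  lev <- sort(unique(group))
  if (length(lev) != 2) stop("exactly two groups are required")
  if (sum(group == lev[1]) == 0 || sum(group == lev[2]) == 0)
    stop("both groups must be non-empty")
  if (sum(event) == 0) stop("the log-rank statistic needs at least one event")
  g1 <- group == lev[1]
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = stats::setNames(c(O, sum(event) - O), lev),
       expected = stats::setNames(c(E, sum(event) - E), lev))
}

#' Pearson chi-square test on a response contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expectations from the row and
#' column margins and \eqn{df = (rows-1)(cols-1)}. No continuity correction
#' by default (set \code{correct = TRUE} for the Yates correction on 2x2
#' tables).
#'
#' @param tab Integer matrix of counts (at least 2x2, all margins > 0),
#'   e.g. phenotype groups x response categories.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @examples
#' response_chisq(matrix(c(10, 0, 0, 10), 2))$statistic  # 20
#' @export
response_chisq <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("the table must be at least 2x2")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column margin must be > 0")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Response contingency table from clinical annotations
#'
#' @param group Per-sample group labels (e.g. dormant / proliferative).
#' @param response Per-sample response categories.
#' @return Counts matrix (groups x response categories).
#' @export
response_table <- function(group, response) {
  if (length(group) != length(response))
    stop("group and response must have the same length")
  as.matrix(table(group = as.character(group),
                  response = as.character(response)))
}
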