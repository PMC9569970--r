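#' Median-split group labels
#'
#' Dichotomizes a continuous expression vector at its median: values above
#' the median are `"high"`, values below are `"low"`. Values exactly equal
#' to the median go to `"low"` -- a deterministic tie rule chosen because
#' "above versus below the median" leaves ties undefined. Errors if either
#' group would be empty (e.g. all values identical).
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `high`, same length as `values`.
#' @export
median_split <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    abort("values must be a numeric vector (length >= 2, no NAs)",
          class = "ppptrace_invalid_input")
  }
  med <- median(values)
  grp <- ifelse(values > med, "high", "low")
  if (length(unique(grp)) < 2L) {
    abort("median split impossible: one group would be empty",
          class = "ppptrace_split_impossible")
  }
  factor(grp, levels = c("low", "high"))
}

check_survival_records <- function(time, event, group = NULL) {
  if (length(time) != length(event) || anyNA(time) || anyNA(event)) {
    abort("time and event must be equal-length without NAs",
          class = "ppptrace_invalid_input")
  }
  if (any(time < 0)) {
    abort("times must be non-negative", class = "ppptrace_invalid_input")
  }
  if (!all(event %in% c(0, 1))) {
    abort("event must be 0 (censored) or 1 (death observed)",
          class = "ppptrace_invalid_input")
  }
  if (!is.null(group)) {
    g <- factor(group)
    if (nlevels(g) != 2L || any(table(g) == 0L)) {
      abort("exactly two non-empty groups are required",
            class = "ppptrace_invalid_grouping")
    }
    return(g)
  }
  invisible(NULL)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each distinct event time, the observed number of events in the first
#' group is compared with its hypergeometric expectation given the risk
#' sets; the statistic is \eqn{(\sum O - \sum E)^2 / \sum V}, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @param group Two-level grouping (e.g. from [median_split()]).
#' @return List with `statistic`, `p`, `observed`, `expected` (both for the
#'   first group level), and `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  g <- check_survival_records(time, event, group)
  if (sum(event) < 1) {
    abort("at least one event is required", class = "ppptrace_invalid_input")
  }
  g1 <- levels(g)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p = if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
       observed = O, expected = E,
       n = as.integer(table(g)))
}

#' Kaplan-Meier product-limit curve for one group
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`, `survival`;
#'   survival starts at 1 (time 0 row included) and is non-increasing.
#' @export
km_curve <- function(time, event) {
  check_survival_records(time, event)
  ts <- sort(unique(time))
  surv <- 1
  rows <- list(tibble::tibble(time = 0, n_risk = length(time),
                              n_event = 0L, n_censor = 0L, survival = 1))
  for (t in ts) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    c_ <- sum(time == t & event == 0)
    if (d > 0) surv <- surv * (1 - d / n_risk)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = t, n_risk = n_risk, n_event = as.integer(d),
      n_censor = as.integer(c_), survival = surv)
  }
  dplyr::bind_rows(rows)
}
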