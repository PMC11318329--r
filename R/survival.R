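#' Kaplan-Meier product-limit estimate for one group
#'
#' At each distinct event time t with d deaths among n at risk, the survival
#' estimate multiplies by (1 - d/n); censored individuals leave the risk set
#' after their censoring time. Daily inspection makes event times integer
#' days, so ties within a day are expected.
#'
#' @param records survival data frame with columns `group`, `day`, `event`
#'   (1 = death, 0 = censored).
#' @param group label of the group to estimate; `NULL` uses all records.
#' @return A `km_curve`: data frame `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, carrying the group label as an attribute. `survival` starts
#'   from S(0) = 1 implicitly; rows are the distinct observed times.
#' @export
#' @examples
#' cfg <- default_config(seed = 1)
#' km <- km_estimate(generate_survival(cfg), group = "5")
#' km_survival_at(km, 21)  # 0.90
km_estimate <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  if (!nrow(records)) stop("no records in group", call. = FALSE)
  if (any(!records$event %in% c(0L, 1L))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  if (any(records$day <= 0)) stop("times must be positive", call. = FALSE)
  times <- sort(unique(records$day))
  n_risk <- vapply(times, function(t) sum(records$day >= t), integer(1))
  n_event <- vapply(times, function(t) sum(records$day == t & records$event == 1L),
                    integer(1))
  n_censor <- vapply(times, function(t) sum(records$day == t & records$event == 0L),
                     integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = times, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  attr(out, "group") <- if (is.null(group)) NA_character_ else group
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Read the survival estimate off a curve at a given time
#'
#' @param curve a [km_estimate()] result.
#' @param t time point.
#' @return S(t): 1 before the first observed time, otherwise the estimate at
#'   the last observed time not exceeding `t`.
#' @export
km_survival_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  if (i == 0) 1 else curve$survival[i]
}

#' Kaplan-Meier curves for every group
#'
#' @param records survival data frame (`group`, `day`, `event`).
#' @return Long data frame of all per-group curves with a `group` column,
#'   suitable for `km_curves.csv`.
#' @export
km_curves <- function(records) {
  groups <- unique(records$group)
  do.call(rbind, lapply(groups, function(g) {
    cv <- km_estimate(records, g)
    cbind(group = g, as.data.frame(cv))
  }))
}

#' k-group log-rank test
#'
#' At each distinct event time the observed deaths per group are compared
#' with their conditional expectation `E_gj = d_j * n_gj / N_j` under the
#' hypergeometric model, and the tied-data hypergeometric covariance
#' `V_gg'j = d_j (N_j - d_j) / (N_j - 1) * (n_gj / N_j) (delta_gg' - n_g'j / N_j)`
#' is accumulated. The statistic is the quadratic form of (O - E) over any
#' k-1 groups (the covariance matrix is singular since the sums vanish),
#' referred to a chi-square with k - 1 degrees of freedom; no continuity
#' correction.
#'
#' @param records survival data frame over two or more groups (`group`,
#'   `day`, `event`).
#' @return A `logrank_result` list: `chisq`, `df`, `p_value`, and per-group
#'   `observed`, `expected`, plus the covariance matrix `var`.
#' @export
#' @examples
#' cfg <- default_config(seed = 1)
#' logrank_test(generate_survival(cfg))  # chi-square approximately 8.3, df 2
logrank_test <- function(records) {
  groups <- unique(records$group)
  k <- length(groups)
  if (k < 2) stop("log-rank test needs at least two groups", call. = FALSE)
  if (sum(records$event) == 0) {
    stop("log-rank statistic undefined: no events in any group", call. = FALSE)
  }
  event_times <- sort(unique(records$day[records$event == 1L]))
  O <- E <- stats::setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  for (t in event_times) {
    at_risk <- records$day >= t
    n_g <- vapply(groups, function(g) sum(at_risk & records$group == g), numeric(1))
    N <- sum(n_g)
    d_g <- vapply(groups, function(g)
      sum(records$day == t & records$event == 1L & records$group == g), numeric(1))
    d <- sum(d_g)
    if (N == 0 || d == 0) next
    O <- O + d_g
    E <- E + d * n_g / N
    if (N > 1) {
      p <- n_g / N
      V <- V + d * (N - d) / (N - 1) * (diag(p, nrow = k) - outer(p, p))
    }
  }
  keep <- seq_len(k - 1)
  u <- (O - E)[keep]
  Vk <- V[keep, keep, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(u) %*% solve(Vk, u)),
                    error = function(e) {
                      # singular reduced covariance: generalized inverse
                      s <- svd(Vk)
                      pos <- s$d > max(s$d) * 1e-12
                      ginv <- s$v[, pos, drop = FALSE] %*%
                        (t(s$u[, pos, drop = FALSE]) / s$d[pos])
                      as.numeric(t(u) %*% ginv %*% u)
                    })
  df <- k - 1
  structure(list(
    chisq = chisq,
    df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
    observed = O,
    expected = E,
    var = V
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = x$expected, row.names = NULL))
  invisible(x)
}

#' Per-group mortality percentage from survival records
#'
#' @param records survival data frame.
#' @return Data frame `group`, `n`, `deaths`, `mortality_pct` where the
#'   mortality is `100 x (1 - S(end))` from each group's product-limit
#'   curve (equal to the crude death fraction when censoring happens only at
#'   the end).
#' @export
mortality_summary <- function(records) {
  groups <- unique(records$group)
  do.call(rbind, lapply(groups, function(g) {
    cv <- km_estimate(records, g)
    data.frame(group = g,
               n = sum(records$group == g),
               deaths = sum(records$event[records$group == g]),
               mortality_pct = 100 * (1 - km_survival_at(cv, max(records$day))),
               stringsAsFactors = FALSE)
  }))
}
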