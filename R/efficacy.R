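#' Exponential tumor-growth fit from bioluminescence
#'
#' Log-linear least squares of ln(flux) on time over a window (the
#' treatment period, e.g. days 7-37). The slope is the exponential growth
#' rate; doubling time is ln(2)/rate. A non-positive slope (regression or
#' shrinkage) leaves the doubling time undefined and flagged.
#'
#' @param series A [bli_series].
#' @param window Two-element numeric `c(start, end)` in days; points with
#'   `start <= t <= end` are fitted. Default spans the whole series.
#' @return A list of class `growth_fit` with `rate` (1/day),
#'   `doubling_time` (days), `intercept` (ln flux at t = 0), `r_squared`,
#'   `window`, `n_points` and `flag`.
#' @export
fit_growth <- function(series, window = NULL) {
  stopifnot(inherits(series, "bli_series"))
  t <- series$times; f <- series$flux
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  t <- t[keep]; f <- f[keep]
  if (length(t) < 3) stop("growth fit requires >= 3 points in window",
                          call. = FALSE)
  fit <- stats::lm(log(f) ~ t)
  rate <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (rate <= 1e-12) {
    return(structure(list(animal_id = series$animal_id,
                          group = series$group, rate = rate,
                          doubling_time = NA_real_,
                          intercept = unname(stats::coef(fit)[1]),
                          r_squared = r2, window = window,
                          n_points = length(t),
                          flag = "no growth: doubling time undefined"),
                     class = "growth_fit"))
  }
  structure(list(animal_id = series$animal_id, group = series$group,
                 rate = rate, doubling_time = log(2) / rate,
                 intercept = unname(stats::coef(fit)[1]), r_squared = r2,
                 window = window, n_points = length(t),
                 flag = NA_character_),
            class = "growth_fit")
}

#' Group summary of per-animal growth fits
#'
#' Fits each animal with [fit_growth] and summarises doubling time per
#' group by the geometric mean (doubling times are ratios of a log-scale
#' fit, so the geometric mean is the natural group centre). Animals with an
#' undefined doubling time are counted but excluded from the mean.
#'
#' @param series_list A list of [bli_series].
#' @param window Passed to [fit_growth].
#' @return A data.frame with columns `group`, `doubling_time` (geometric
#'   mean, days), `gsd` (geometric SD), `n`, `n_undefined`.
#' @export
growth_summary <- function(series_list, window = NULL) {
  fits <- lapply(series_list, fit_growth, window = window)
  df <- data.frame(group = vapply(fits, `[[`, "", "group"),
                   dt = vapply(fits, `[[`, numeric(1), "doubling_time"))
  rows <- lapply(split(df, df$group), function(d) {
    ok <- !is.na(d$dt)
    data.frame(group = d$group[1],
               doubling_time = if (any(ok)) exp(mean(log(d$dt[ok])))
                               else NA_real_,
               gsd = if (sum(ok) > 1) exp(stats::sd(log(d$dt[ok])))
                     else NA_real_,
               n = nrow(d), n_undefined = sum(!ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring. The median is the earliest
#' event time at which the survival curve reaches 0.5 or below; it is
#' undefined (NA, flagged) when the curve never does.
#'
#' @param records A [survival_records] data.frame (single group).
#' @return A list of class `km_result` with `time`, `surv`, `n_risk`,
#'   `n_event`, `median` (days or NA) and `flag`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, censored = TRUE)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med,
                 flag = if (is.na(med)) "median undefined: curve stays above 0.5"
                        else NA_character_),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d time point(s), median %s days\n",
              length(x$time),
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square over the pooled event times
#' with the hypergeometric variance, df = groups - 1. Ties are handled by
#' the simultaneous-event convention.
#'
#' @param records A [survival_records] data.frame with >= 2 groups and at
#'   least one event.
#' @return A list of class `logrank_result` with `statistic`, `df`,
#'   `p_value`.
#' @export
logrank <- function(records) {
  g <- unique(records$group)
  if (length(g) < 2) stop("log-rank test requires >= 2 groups", call. = FALSE)
  if (sum(records$event) < 1) stop("log-rank test requires >= 1 event",
                                   call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(g) - 1
  structure(list(statistic = sd$chisq, df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Full efficacy summary: growth kinetics and survival per group
#'
#' @param series_list A list of [bli_series] (may be `NULL`).
#' @param records A [survival_records] data.frame (may be `NULL`).
#' @param window Growth-fit window in days.
#' @return A list with `growth` (from [growth_summary]), `km` (one
#'   `km_result` per group), `median_survival` (named vector) and
#'   `logrank` (when >= 2 groups).
#' @export
efficacy_summary <- function(series_list = NULL, records = NULL,
                             window = NULL) {
  out <- list(growth = NULL, km = NULL, median_survival = NULL,
              logrank = NULL)
  if (!is.null(series_list)) {
    out$growth <- growth_summary(series_list, window = window)
  }
  if (!is.null(records)) {
    by_group <- split(records, records$group)
    out$km <- lapply(by_group, km_estimate)
    out$median_survival <- vapply(out$km, `[[`, numeric(1), "median")
    if (length(by_group) >= 2 && sum(records$event) >= 1) {
      out$logrank <- logrank(records)
    }
  }
  out
}
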