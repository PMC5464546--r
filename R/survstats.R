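# Kaplan-Meier estimation, two-group log-rank testing, group hazard
# ratios, and t-year DMFS readouts.

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with deaths processed before
#' censorings at tied times: the at-risk count at an event time
#' includes samples censored exactly at that time.
#'
#' @param time positive follow-up times (years).
#' @param event 0/1 event indicators.
#' @return An object of class `km_curve`: data.frame of distinct event
#'   times with `n_risk`, `n_event`, `surv`, plus the censoring times
#'   and input size as attributes.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  attr(out, "censor_times") <- sort(time[event == 0])
  attr(out, "n") <- length(time)
  attr(out, "max_time") <- max(time)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Read a survival probability off a Kaplan-Meier curve
#'
#' Evaluates the right-continuous step function at `t`. Beyond the last
#' observed time the last value is returned with attribute
#' `extrapolated = TRUE`.
#'
#' @param curve a [km_curve].
#' @param t time in years (>= 0).
#' @return The survival probability, with an `extrapolated` attribute.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  extra <- t > attr(curve, "max_time")
  if (nrow(curve) == 0 || t < curve$time[1]) {
    s <- 1
  } else {
    s <- curve$surv[max(which(curve$time <= t))]
  }
  structure(s, extrapolated = extra)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each
#' distinct event time, referred to chi-square(1).
#'
#' @param timeA,eventA outcome of group A.
#' @param timeB,eventB outcome of group B.
#' @return A list `(chi2, p, observed_A, expected_A)`; `NA` statistics
#'   when there are no events.
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0 || length(timeB) == 0) {
    stop("both groups must be non-empty")
  }
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(0L, 1L), c(length(timeA), length(timeB)))
  if (sum(event) == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, observed_A = 0,
                expected_A = 0))
  }
  ev_times <- sort(unique(time[event == 1]))
  oa <- ea <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 0L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 0L)
    oa <- oa + d1
    ea <- ea + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) {
    return(list(chi2 = NA_real_, p = NA_real_, observed_A = oa,
                expected_A = ea))
  }
  chi2 <- (oa - ea)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed_A = oa, expected_A = ea)
}

#' Hazard ratio between risk groups
#'
#' Univariate Cox fit on the high-vs-low indicator with a 95% normal
#' confidence interval on the log hazard ratio. Separation (all events
#' in one group before any in the other) yields a flagged `NA` result.
#'
#' @param assignment a `risk_assignment` (columns `sample`, `group`).
#' @param clin a [clinical_table].
#' @param ties Cox tie handling.
#' @return A list `(hr, ci_low, ci_high, beta, se, p, flagged)`.
#' @export
group_hr <- function(assignment, clin, ties = "efron") {
  ok <- !is.na(assignment$group)
  cl <- align_clinical(clin, assignment$sample[ok])
  x <- as.numeric(assignment$group[ok] == "high")
  fit <- cox_fit(x, cl$time, cl$event, ties = ties)
  if (fit$flagged) {
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                beta = NA_real_, se = NA_real_, p = NA_real_,
                flagged = TRUE))
  }
  list(hr = fit$hr, ci_low = exp(fit$beta - 1.96 * fit$se),
       ci_high = exp(fit$beta + 1.96 * fit$se), beta = fit$beta,
       se = fit$se, p = fit$p, flagged = FALSE)
}

#' Compare risk groups: log-rank, hazard ratio, t-year DMFS
#'
#' Bundles the standard readout for a low/high risk split: log-rank
#' chi-square and p-value, Cox hazard ratio (high vs low) with 95% CI,
#' and the Kaplan-Meier DMFS at `t_years` per group.
#'
#' @param assignment a `risk_assignment`.
#' @param clin a [clinical_table].
#' @param t_years horizon for the DMFS readout (default 5).
#' @param ties Cox tie handling.
#' @return A list of class `group_comparison`.
#' @export
group_comparison <- function(assignment, clin, t_years = 5,
                             ties = "efron") {
  ok <- !is.na(assignment$group)
  if (!any(ok)) stop("no assigned samples")
  asg <- assignment[ok, , drop = FALSE]
  cl <- align_clinical(clin, asg$sample)
  lowi <- asg$group == "low"
  n_low <- sum(lowi); n_high <- sum(!lowi)
  if (n_low == 0 || n_high == 0) {
    stop("degenerate split: one risk group is empty")
  }
  lr <- logrank_test(cl$time[lowi], cl$event[lowi],
                     cl$time[!lowi], cl$event[!lowi])
  hr <- group_hr(asg, clin, ties = ties)
  km_low <- km_estimate(cl$time[lowi], cl$event[lowi])
  km_high <- km_estimate(cl$time[!lowi], cl$event[!lowi])
  out <- list(n_low = n_low, n_high = n_high,
              logrank_chi2 = lr$chi2, logrank_p = lr$p,
              hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high,
              hr_p = hr$p, hr_flagged = hr$flagged,
              dmfs_low = as.numeric(survival_at(km_low, t_years)),
              dmfs_high = as.numeric(survival_at(km_high, t_years)),
              t_years = t_years, km_low = km_low, km_high = km_high)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %d low / %d high risk\n",
              x$n_low, x$n_high))
  cat(sprintf("  DMFS at %g years: %.1f%% (low) vs %.1f%% (high)\n",
              x$t_years, 100 * x$dmfs_low, 100 * x$dmfs_high))
  if (!x$hr_flagged) {
    cat(sprintf("  HR (high vs low) = %.3f (95%% CI %.3f-%.3f)\n",
                x$hr, x$ci_low, x$ci_high))
  } else {
    cat("  HR: not estimable (separation)\n")
  }
  cat(sprintf("  log-rank chi2 = %.4f, p = %.4g\n",
              x$logrank_chi2, x$logrank_p))
  invisible(x)
}

#' Export Kaplan-Meier step-function coordinates
#'
#' Writes a plot-ready TSV of the two groups' KM coordinates
#' (time, survival, group) including the initial (0, 1) point.
#'
#' @param comparison a [group_comparison()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_coordinates <- function(comparison, path) {
  coord <- function(km, g) {
    data.frame(time = c(0, km$time), surv = c(1, km$surv), group = g)
  }
  df <- rbind(coord(comparison$km_low, "low"),
              coord(comparison$km_high, "high"))
  df$time <- format_num(df$time)
  df$surv <- format_num(df$surv)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
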