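#' Kaplan-Meier curve for one group
#'
#' Product-limit estimate of the survival function for a single group of a
#' \code{\link{SurvivalTable}}, with right-censoring support. Ties at an
#' event time are handled as simultaneous deaths.
#'
#' @param table a \code{SurvivalTable}.
#' @param group group label to estimate.
#' @return a list of class \code{"KMCurve"} with components
#'   \code{event_times} (ascending distinct death times), \code{survival}
#'   (S(t) just after each event time), \code{at_risk}, \code{n_events},
#'   and \code{group}.
#' @seealso \code{\link{medianSurvival}}, \code{\link{logrankTest}}
#' @export
kmEstimate <- function(table, group) {
  d <- survivalData(table)
  d <- d[d$group == group, , drop = FALSE]
  if (nrow(d) == 0) stop("group '", group, "' not present or empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  keep <- fit$n.event > 0
  out <- list(event_times = fit$time[keep],
              survival = fit$surv[keep],
              at_risk = fit$n.risk[keep],
              n_events = fit$n.event[keep],
              n = nrow(d),
              group = group)
  class(out) <- "KMCurve"
  out
}

#' @export
print.KMCurve <- function(x, ...) {
  cat("Kaplan-Meier curve for group", x$group, "(", x$n, "animals,",
      sum(x$n_events), "deaths )\n")
  med <- medianSurvival(x)
  cat("median survival:", if (is.na(med)) "undefined" else paste(med, "days"),
      "\n")
  invisible(x)
}

#' Step-function coordinates of a KM curve
#'
#' Expands a \code{KMCurve} into plot-ready (time, survival) coordinates
#' starting from S(0) = 1.
#'
#' @param curve a \code{KMCurve}.
#' @return data.frame with columns \code{time}, \code{survival}.
#' @export
kmCoordinates <- function(curve) {
  stopifnot(inherits(curve, "KMCurve"))
  data.frame(time = c(0, curve$event_times),
             survival = c(1, curve$survival))
}

#' Median survival from a KM curve
#'
#' Smallest event time at which the estimated survival drops to 0.5 or
#' below; \code{NA} when the curve never reaches 0.5 (heavy censoring).
#'
#' @param curve a \code{KMCurve} from \code{\link{kmEstimate}}.
#' @return days, or \code{NA_real_} when undefined.
#' @export
medianSurvival <- function(curve) {
  stopifnot(inherits(curve, "KMCurve"))
  hit <- which(curve$survival <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  curve$event_times[hit[1]]
}

#' Percent change between two median lifespans
#'
#' 100 * (treated - control) / control, the convention used when reporting
#' lifespan extension (e.g. a 636 -> 931 day median shift is +46\%).
#'
#' @param treated_median treated-group median lifespan, days.
#' @param control_median control-group median lifespan, days (> 0).
#' @return a list with \code{percent} (raw value), \code{rounded}
#'   (nearest integer), \code{difference} (days) and a printable
#'   \code{label}.
#' @examples
#' percentChange(931, 636)$rounded  # 46
#' @export
percentChange <- function(treated_median, control_median) {
  stopifnot(is.finite(treated_median), is.finite(control_median))
  if (control_median <= 0) stop("control median must be positive")
  pct <- 100 * (treated_median - control_median) / control_median
  list(percent = pct,
       rounded = as.integer(round(pct)),
       difference = treated_median - control_median,
       label = sprintf("%d%%", as.integer(round(pct))))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves with censoring,
#' df = 1, p from the upper chi-square tail.
#'
#' @param table a \code{SurvivalTable}.
#' @param group_a,group_b labels of the two groups to compare.
#' @return list of class \code{"LogRankResult"}: \code{chi2}, \code{df},
#'   \code{p}.
#' @export
logrankTest <- function(table, group_a, group_b) {
  d <- survivalData(table)
  d <- d[d$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% d$group))
    stop("both groups must be present and non-empty")
  for (g in c(group_a, group_b)) {
    if (sum(d$event[d$group == g]) == 0)
      warning("group '", g, "' has zero observed events")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi2 <- unname(sd$chisq)
  out <- list(chi2 = chi2, df = 1L,
              p = pchisq(chi2, df = 1, lower.tail = FALSE))
  class(out) <- "LogRankResult"
  out
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("log-rank test: chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

# order-statistic quantile: value at ceil(q * n) of the sorted sample.
# Determinate under ties; no interpolation.
orderStatQuantile <- function(x, q) {
  sx <- sort(x)
  sx[max(1L, ceiling(q * length(x)))]
}

#' Wang/Allison maximal-lifespan quantile test
#'
#' Compares, between two groups, the proportion of animals still alive at
#' the pooled age at which only (1 - quantile) of all animals remain alive
#' (default: the pooled 90th-percentile lifespan). "Alive beyond" means a
#' lifespan strictly greater than the pooled threshold; the resulting 2x2
#' table is tested with a two-sided Fisher exact test. Censored animals
#' are excluded with a warning, since the comparison concerns realised
#' lifespans.
#'
#' @param table a \code{SurvivalTable}.
#' @param group_a,group_b group labels (a = treated, b = control for the
#'   percent-change direction).
#' @param quantile pooled lifespan quantile defining the threshold age
#'   (default 0.90).
#' @return list of class \code{"MaxLifeResult"}: \code{threshold_age},
#'   \code{counts} (2x2 matrix, rows = groups, cols = beyond/not),
#'   \code{p} (Fisher exact, two-sided), \code{group_q90} (each group's own
#'   quantile lifespan), \code{percent_change_q90}, \code{n_censored_dropped}.
#' @references Wang C, Li Q, Redden DT, Weindruch R, Allison DB (2004)
#'   Statistical methods for testing effects on "maximum lifespan".
#'   Mech Ageing Dev 125:629-632.
#' @export
maxlifeQuantileTest <- function(table, group_a, group_b, quantile = 0.90) {
  stopifnot(quantile > 0, quantile < 1)
  d <- survivalData(table)
  d <- d[d$group %in% c(group_a, group_b), , drop = FALSE]
  n_cens <- sum(d$event == 0L)
  if (n_cens > 0) {
    warning("excluding ", n_cens, " censored animal(s) from the ",
            "maximal-lifespan quantile test")
    d <- d[d$event == 1L, , drop = FALSE]
  }
  if (nrow(d) < 10)
    stop("fewer than 10 pooled uncensored animals: pooled quantile unstable")
  if (!all(c(group_a, group_b) %in% d$group))
    stop("both groups need uncensored animals")
  thr <- orderStatQuantile(d$time, quantile)
  la <- d$time[d$group == group_a]
  lb <- d$time[d$group == group_b]
  counts <- rbind(c(sum(la > thr), sum(la <= thr)),
                  c(sum(lb > thr), sum(lb <= thr)))
  dimnames(counts) <- list(c(group_a, group_b), c("beyond", "not_beyond"))
  p <- fisher.test(counts, alternative = "two.sided")$p.value
  qa <- orderStatQuantile(la, quantile)
  qb <- orderStatQuantile(lb, quantile)
  out <- list(threshold_age = thr,
              counts = counts,
              p = p,
              group_q90 = setNames(c(qa, qb), c(group_a, group_b)),
              percent_change_q90 = 100 * (qa - qb) / qb,
              quantile = quantile,
              n_censored_dropped = n_cens)
  class(out) <- "MaxLifeResult"
  out
}

#' @export
print.MaxLifeResult <- function(x, ...) {
  cat(sprintf("Wang/Allison maximal-lifespan test (pooled q%02.0f threshold = %g days)\n",
              100 * x$quantile, x$threshold_age))
  print(x$counts)
  cat(sprintf("Fisher exact (two-sided) p = %.4g\n", x$p))
  cat(sprintf("group q%02.0f lifespans: %g vs %g days (%+.1f%%)\n",
              100 * x$quantile, x$group_q90[1], x$group_q90[2],
              x$percent_change_q90))
  invisible(x)
}
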