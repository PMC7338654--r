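#' Kaplan-Meier product-limit survival estimate
#'
#' Standard product-limit estimator under right censoring: at each distinct
#' event time the survival probability is multiplied by
#' `1 - d / n_at_risk`; subjects censored at an event time remain in the
#' risk set for the events at that time. An optional horizon (e.g. 1825
#' days for a 5-year analysis) censors later follow-up at the horizon.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 death, 0 censored).
#' @param horizon Optional horizon; times beyond it are censored at it.
#' @return A `km_curve`: data-frame-backed list with `time` (distinct event
#'   times), `surv`, `n_risk`, `n_event`, `n_censor`. With no events the
#'   curve is identically 1.
#' @export
km_estimate <- function(times, events, horizon = NULL) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(times <= 0)) stop("times must be positive")
  events <- as.integer(events != 0)
  if (!is.null(horizon)) {
    events[times > horizon] <- 0L
    times <- pmin(times, horizon)
  }
  ut <- sort(unique(times[events == 1L]))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t0 <- ut[i]
    n_risk[i] <- sum(times >= t0)
    n_event[i] <- sum(times == t0 & events == 1L)
    n_censor[i] <- sum(times == t0 & events == 0L)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(list(time = ut, surv = surv, n_risk = n_risk,
                 n_event = n_event, n_censor = n_censor,
                 n_subjects = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (`S(0) = 1`).
#' @export
km_surv <- function(curve, t) {
  vapply(t, function(x) {
    i <- sum(curve$time <= x)
    if (i == 0L) 1 else curve$surv[i]
  }, 0)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d event time(s); final S = %.4f\n",
              x$n_subjects, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected log-rank chi-square with 1 degree of freedom,
#' using the hypergeometric variance at each distinct event time; the
#' two-sided p-value comes from the chi-square distribution.
#'
#' @param time1,event1 Follow-up and event indicator for group 1.
#' @param time2,event2 Same for group 2.
#' @return List with `statistic`, `p_value`, `observed` and `expected`
#'   event counts in group 1.
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (!length(time1) || !length(time2)) stop("both groups must be non-empty")
  event1 <- as.integer(event1 != 0); event2 <- as.integer(event2 != 0)
  if (sum(event1) + sum(event2) == 0L) stop("log-rank test undefined with zero events")
  times <- c(time1, time2)
  events <- c(event1, event2)
  grp1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  ut <- sort(unique(times[events == 1L]))
  O1 <- E1 <- V <- 0
  for (t0 in ut) {
    at <- times >= t0
    n <- sum(at); n1 <- sum(at & grp1)
    d <- sum(times == t0 & events == 1L)
    d1 <- sum(times == t0 & events == 1L & grp1)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1L) V <- V + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  if (V == 0) return(list(statistic = 0, p_value = 1, observed = O1,
                          expected = E1))
  chi <- (O1 - E1)^2 / V
  list(statistic = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = O1, expected = E1)
}

#' Split a cohort into high/low expression groups for one gene
#'
#' `median`: split at the median, ties going to the low group. `quantile`:
#' split at the `q` quantile. `scan`: evaluate cutoffs at the 0.2-0.8
#' quantiles in steps of 0.05 and keep the cutoff minimizing the log-rank
#' p-value; the number of cutoffs tried is reported so downstream callers
#' can disclose (and correct for) the implied multiple testing.
#'
#' @param cohort Data frame with `time_days`, `event` and one column per
#'   gene.
#' @param gene Gene column to stratify on.
#' @param rule `"scan"`, `"median"` or `"quantile"`.
#' @param q Quantile for `rule = "quantile"`.
#' @param horizon Optional horizon applied before the scan's log-rank
#'   evaluations.
#' @return List with `high`, `low` (logical masks), `cutoff`, `rule`,
#'   `n_cutoffs_tried`, and for the scan rule `p_at_cutoff`.
#' @export
stratify_by_expression <- function(cohort, gene,
                                   rule = c("scan", "median", "quantile"),
                                   q = 0.5, horizon = NULL) {
  rule <- match.arg(rule)
  x <- cohort[[gene]]
  if (is.null(x)) stop("gene not present in cohort: ", gene)
  if (stats::sd(x) == 0) stop("cannot stratify: constant expression")
  time <- cohort$time_days
  event <- cohort$event
  if (!is.null(horizon)) {
    event[time > horizon] <- 0L
    time <- pmin(time, horizon)
  }
  if (rule %in% c("median", "quantile")) {
    cut <- stats::quantile(x, if (rule == "median") 0.5 else q, names = FALSE)
    high <- x > cut
    return(list(high = high, low = !high, cutoff = cut, rule = rule,
                n_cutoffs_tried = 1L, p_at_cutoff = NA_real_))
  }
  cuts <- stats::quantile(x, seq(0.2, 0.8, by = 0.05), names = FALSE)
  best <- NULL
  for (cut in cuts) {
    high <- x > cut
    if (!any(high) || all(high)) next
    if (sum(event) == 0L) next
    p <- logrank_test(time[high], event[high], time[!high], event[!high])$p_value
    if (is.null(best) || p < best$p) best <- list(cut = cut, p = p)
  }
  if (is.null(best)) stop("cannot stratify: no admissible cutoff")
  high <- x > best$cut
  list(high = high, low = !high, cutoff = best$cut, rule = rule,
       n_cutoffs_tried = length(cuts), p_at_cutoff = best$p)
}

#' Screen DE genes for prognostic value by cutoff stratification + log-rank
#'
#' For every differentially expressed gene present in the cohort, the
#' cohort is split by [stratify_by_expression()] and the two arms compared
#' with [logrank_test()] at the given horizon. Because the scan rule picks
#' the minimum p over cutoffs, the output carries both the nominal p-value
#' and a Bonferroni correction over the number of cutoffs tried.
#'
#' @param de_genes [de_test()]-shaped table; rows with direction
#'   `up`/`down` are screened.
#' @param cohort Data frame with `patient_id`, `time_days`, `event`, and
#'   one column per gene.
#' @param rule Stratification rule (default `"scan"`).
#' @param horizon Analysis horizon in days (default 1825 = 5 years).
#' @return Data frame sorted by `p_value`: `gene_id`, `cutoff`, `n_high`,
#'   `n_low`, `p_value`, `p_scan_adjusted`, `n_cutoffs_tried`,
#'   `high_expression_risk` (`higher`/`lower`, from the sign of the
#'   observed-minus-expected events in the high arm).
#' @export
survival_screen <- function(de_genes, cohort, rule = "scan", horizon = 1825) {
  genes <- de_genes$gene_id[de_genes$direction %in% c("up", "down")]
  genes <- intersect(genes, colnames(cohort))
  rows <- list()
  for (g in genes) {
    res <- tryCatch({
      st <- stratify_by_expression(cohort, g, rule = rule, horizon = horizon)
      time <- cohort$time_days; event <- cohort$event
      event[time > horizon] <- 0L
      time <- pmin(time, horizon)
      lr <- logrank_test(time[st$high], event[st$high],
                         time[st$low], event[st$low])
      data.frame(gene_id = g, cutoff = st$cutoff,
                 n_high = sum(st$high), n_low = sum(st$low),
                 p_value = lr$p_value,
                 p_scan_adjusted = min(1, lr$p_value * st$n_cutoffs_tried),
                 n_cutoffs_tried = st$n_cutoffs_tried,
                 high_expression_risk = if (lr$observed >= lr$expected)
                   "higher" else "lower",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("survival_screen: skipping ", g, " (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), cutoff = double(),
                      n_high = integer(), n_low = integer(),
                      p_value = double(), p_scan_adjusted = double(),
                      n_cutoffs_tried = integer(),
                      high_expression_risk = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
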