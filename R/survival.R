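## Kaplan-Meier estimation and multi-group log-rank testing, implemented
## from the product-limit / O-E-V definitions (the `survival` package is
## used only as an independent oracle in the test suite).

#' Kaplan-Meier product-limit estimate
#'
#' Ties follow the standard convention: deaths precede censorings at equal
#' times, so censored subjects at time t are still at risk for the death at
#' t. Greenwood's formula gives the pointwise standard error; the median is
#' the first event time with `S(t) <= 0.5` (NA if never reached).
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = death observed, 0 = censored).
#' @return A list of class `KMCurve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `se` (Greenwood), `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(times < 0)) stop("negative time")
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1")
  ts <- sort(unique(times[events == 1]))
  if (length(ts) == 0L) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), se = numeric(0), median = NA_real_,
                n = length(times))
    class(out) <- "KMCurve"
    return(out)
  }
  n_risk <- vapply(ts, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ts, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, .Machine$double.eps)))
  gw[n_risk == n_event] <- Inf          # S hits 0: variance degenerate
  se <- surv * sqrt(gw)
  se[surv == 0] <- 0
  med <- ts[which(surv <= 0.5 + 1e-12)[1L]]
  out <- list(time = ts, n_risk = as.integer(n_risk),
              n_event = as.integer(n_event), surv = surv, se = se,
              median = if (length(med) && !is.na(med)) med else NA_real_,
              n = length(times))
  class(out) <- "KMCurve"
  out
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("KMCurve: n = %d, %d event time(s), median = %s\n",
              x$n, length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#' @param km A `KMCurve`.
#' @param t Times at which to evaluate the step function.
#' @return `S(t)` values (1 before the first event).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Multi-group log-rank test
#'
#' At each distinct event time with `d` pooled deaths among `n` at risk,
#' group g expects `E_g = d n_g / n` deaths with hypergeometric covariance
#' `V_gh = d (n - d) / (n - 1) * n_g (delta_gh n - n_h) / n^2` (zero when
#' `n = 1`). The statistic is `U' V^- U` over any G-1 coordinates
#' (generalized inverse), chi-square with G-1 df under the null.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (>= 2 non-empty groups).
#' @return A list of class `LogRankResult`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (named per group).
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0)) stop("negative time")
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1")
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  G <- length(glev)
  if (G < 2L) stop("log-rank needs >= 2 groups")
  ts <- sort(unique(times[events == 1]))
  O <- stats::setNames(numeric(G), glev)
  E <- stats::setNames(numeric(G), glev)
  V <- matrix(0, G, G, dimnames = list(glev, glev))
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    ng <- vapply(glev, function(g) sum(at_risk & groups == g), numeric(1))
    dg <- vapply(glev, function(g) sum(times == t & events == 1 & groups == g),
                 numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      # V_gh = d(n-d)/(n-1) * n_g (delta_gh n - n_h) / n^2
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(ng, G) * n - outer(ng, ng)) / n^2
    }
  }
  U <- O - E
  keep <- seq_len(G - 1L)
  Vs <- V[keep, keep, drop = FALSE]
  stat <- drop(t(U[keep]) %*% pseudo_inverse(Vs) %*% U[keep])
  stat <- max(stat, 0)
  df <- G - 1L
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              observed = O, expected = E, variance = V)
  class(out) <- "LogRankResult"
  out
}

## Moore-Penrose pseudo-inverse via SVD (small G, no extra dependency)
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' TMM-stratified overall survival
#'
#' Joins the clinical table with a TMM labeling (exact sample-id match
#' after whitespace trim; unmatched samples are dropped with a message),
#' fits one KM curve per label (per cohort when `by_cohort`), and runs a
#' log-rank test across labels. Labels absent after the join are dropped
#' with a warning and the df reduced accordingly.
#'
#' @param clinical A `ClinicalTable`.
#' @param labels A `TMMLabeling` table.
#' @param by_cohort Also stratify curves by cohort.
#' @return List with `curves` (named `KMCurve` list), `logrank`
#'   (`LogRankResult`), `data` (the joined data.frame).
#' @export
stratified_survival <- function(clinical, labels, by_cohort = FALSE) {
  cl <- clinical
  cl$sample_id <- trimws(cl$sample_id)
  lb <- labels
  lb$sample_id <- trimws(lb$sample_id)
  joined <- merge(cl[, c("sample_id", "os_time", "os_event", "cohort")],
                  lb[, c("sample_id", "label")], by = "sample_id")
  dropped <- nrow(cl) - nrow(joined)
  if (dropped > 0)
    message(dropped, " clinical sample(s) without a TMM label dropped")
  present <- unique(joined$label)
  if (length(present) < 2L)
    stop("fewer than 2 TMM labels present after join")
  absent <- setdiff(TMM_LABELS, present)
  if (length(absent))
    warning("label(s) with zero samples dropped: ",
            paste(absent, collapse = ", "))
  strata <- if (by_cohort) paste(joined$cohort, joined$label, sep = ":")
            else joined$label
  curves <- lapply(split(joined, strata), function(d)
    km_estimate(d$os_time, d$os_event))
  lr <- logrank_test(joined$os_time, joined$os_event, joined$label)
  list(curves = curves, logrank = lr, data = joined)
}

#' Tidy a set of KM curves for TSV output
#' @param curves Named list of `KMCurve` objects.
#' @return Long data.frame (stratum, time, at_risk, events, survival, se).
#' @export
km_tidy <- function(curves) {
  do.call(rbind, lapply(names(curves), function(nm) {
    k <- curves[[nm]]
    if (length(k$time) == 0L)
      return(data.frame(stratum = character(0), time = numeric(0),
                        at_risk = integer(0), events = integer(0),
                        survival = numeric(0), se = numeric(0)))
    data.frame(stratum = nm, time = k$time, at_risk = k$n_risk,
               events = k$n_event, survival = k$surv, se = k$se,
               stringsAsFactors = FALSE)
  }))
}

#' Good/poor outcome split for differential expression
#'
#' The outcome dichotomization used upstream of the DEG comparison. Two
#' strategies are provided, reported side by side by the pipeline:
#' `"median_event"` — poor = deceased with `os_time` below the stratum's
#' median event time, good = alive (censored) with follow-up above that
#' median; `"event"` — poor = deceased, good = alive regardless of time.
#'
#' @param clinical A `ClinicalTable`.
#' @param strategy `"median_event"` or `"event"`.
#' @return Data.frame with `sample_id` and `outcome` in
#'   `{good, poor, NA}` (samples satisfying neither arm get NA).
#' @export
outcome_split <- function(clinical, strategy = c("median_event", "event")) {
  strategy <- match.arg(strategy)
  out <- data.frame(sample_id = clinical$sample_id,
                    outcome = NA_character_, stringsAsFactors = FALSE)
  if (strategy == "event") {
    out$outcome <- ifelse(clinical$os_event == 1, "poor", "good")
    return(out)
  }
  ev_times <- clinical$os_time[clinical$os_event == 1]
  if (length(ev_times) == 0L) return(out)
  med <- stats::median(ev_times)
  out$outcome[clinical$os_event == 1 & clinical$os_time < med] <- "poor"
  out$outcome[clinical$os_event == 0 & clinical$os_time > med] <- "good"
  out
}
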