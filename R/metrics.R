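#' Kaplan-Meier product-limit estimator
#'
#' \eqn{\hat S(t) = \prod_{t_k \le t} (1 - d_k / n_k)} over distinct
#' observed times, as a right-continuous step function with value 1 before
#' the first event. With the indicators flipped it estimates the censoring
#' distribution \eqn{G(t)} used for IPCW weighting.
#'
#' @param durations nonnegative observed times.
#' @param indicators 0/1; 1 marks an observed event at that time.
#' @return object of class `step_function` with fields `times` (distinct
#'   event times) and `values` (the estimate just after each time).
#' @export
km_estimator <- function(durations, indicators) {
  if (!length(durations)) stop("empty input", call. = FALSE)
  stopifnot(length(durations) == length(indicators),
            all(durations >= 0), all(indicators %in% c(0, 1)))
  tk <- sort(unique(durations[indicators == 1]))
  surv <- numeric(length(tk))
  s <- 1
  for (i in seq_along(tk)) {
    n_k <- sum(durations >= tk[i])
    d_k <- sum(durations == tk[i] & indicators == 1)
    s <- s * (1 - d_k / n_k)
    surv[i] <- s
  }
  structure(list(times = tk, values = surv), class = "step_function")
}

#' Evaluate a step function
#'
#' @param sf a `step_function`.
#' @param t numeric times.
#' @param left evaluate the left limit \eqn{f(t^-)} instead of \eqn{f(t)}.
#' @return numeric vector.
#' @export
eval_step <- function(sf, t, left = FALSE) {
  idx <- if (left) findInterval(t, sf$times, left.open = TRUE) else
    findInterval(t, sf$times)
  c(1, sf$values)[idx + 1L]
}

#' Time-dependent concordance index (Antolini)
#'
#' Fraction of comparable pairs ordered concordantly by the predicted
#' survival evaluated at the earlier subject's event time. Pair
#' \eqn{(i, j)} is comparable when \eqn{i} has an event and either
#' \eqn{T_i < T_j}, or \eqn{T_i = T_j} with \eqn{j} censored; it is
#' concordant when \eqn{S_i(T_i) < S_j(T_i)}, and prediction ties score
#' 1/2. Scale-free: invariant to any strictly monotone transformation
#' applied to all survival values at each evaluation time. 1 is perfect
#' discrimination, 0.5 is chance.
#'
#' @param curves list of [survival_curve] on a common grid, or a matrix of
#'   survival values with `times` supplied.
#' @param durations observed times.
#' @param events 0/1 indicators.
#' @param times grid times when `curves` is a matrix.
#' @return list with `ctd` (NA when undefined), `comparable` (pair count),
#'   `defined`.
#' @export
ctd_index <- function(curves, durations, events, times = NULL) {
  S <- curves_to_matrix(curves)
  if (is.null(times)) times <- attr(S, "times")
  n <- length(durations)
  stopifnot(nrow(S) == n, length(events) == n)
  conc <- 0; comp <- 0
  for (i in which(events == 1)) {
    Si <- eval_curve(S, durations[i], times = times)[, 1]
    cmp <- which(durations > durations[i] |
                   (durations == durations[i] & events == 0 &
                      seq_len(n) != i))
    if (!length(cmp)) next
    comp <- comp + length(cmp)
    conc <- conc + sum(Si[i] < Si[cmp]) + 0.5 * sum(Si[i] == Si[cmp])
  }
  if (comp == 0) {
    return(list(ctd = NA_real_, comparable = 0L, defined = FALSE))
  }
  list(ctd = conc / comp, comparable = comp, defined = TRUE)
}

#' IPCW Brier score at a time point
#'
#' Censoring-weighted mean squared error between predicted survival and
#' observed status at `t` (Graf weighting): subjects with an event before
#' or at `t` contribute \eqn{(0 - S_i(t))^2 / G(T_i^-)}, subjects still at
#' risk after `t` contribute \eqn{(1 - S_i(t))^2 / G(t)}, and subjects
#' censored at or before `t` get weight 0. Rows whose required weight has
#' \eqn{G = 0} are excluded (reported via a message).
#'
#' @param curves list of [survival_curve] or a matrix with `times`.
#' @param durations,events observed times and 0/1 indicators.
#' @param t evaluation time.
#' @param censor_dist a `step_function` estimate of the censoring
#'   distribution (from [km_estimator()] on flipped indicators).
#' @param times grid times when `curves` is a matrix.
#' @return the weighted Brier score (denominator: all included subjects).
#' @export
brier_score <- function(curves, durations, events, t, censor_dist,
                        times = NULL) {
  S <- curves_to_matrix(curves)
  if (is.null(times)) times <- attr(S, "times")
  n <- length(durations)
  St <- eval_curve(S, t, times = times)[, 1]
  w <- numeric(n); contrib <- numeric(n)
  dropped <- 0L
  for (i in seq_len(n)) {
    if (durations[i] <= t && events[i] == 1) {
      G <- eval_step(censor_dist, durations[i], left = TRUE)
      if (G <= 0) { dropped <- dropped + 1L; next }
      w[i] <- 1 / G; contrib[i] <- (0 - St[i])^2
    } else if (durations[i] > t) {
      G <- eval_step(censor_dist, t)
      if (G <= 0) { dropped <- dropped + 1L; next }
      w[i] <- 1 / G; contrib[i] <- (1 - St[i])^2
    } # censored at or before t: weight 0
  }
  if (dropped > 0L) {
    message("brier_score: excluded ", dropped, " row(s) with zero ",
            "censoring-survival weight")
  }
  sum(w * contrib) / (n - dropped)
}

#' Integrated Brier score (IBS)
#'
#' Trapezoidal integral of the IPCW Brier score over a time grid, divided
#' by the grid span. The default grid is 100 uniform points over
#' \[0, 90th percentile of observed durations\] — the tail is excluded
#' because the censoring estimate \eqn{G} becomes unstable there.
#'
#' @param curves list of [survival_curve] or a matrix with `times`.
#' @param durations,events observed times and 0/1 indicators.
#' @param grid evaluation times (ascending); a single point degrades to
#'   the pointwise Brier score (with a message).
#' @param times grid times when `curves` is a matrix.
#' @return the integrated Brier score.
#' @export
integrated_brier_score <- function(curves, durations, events, grid = NULL,
                                   times = NULL) {
  if (is.null(grid)) {
    t_max <- as.numeric(stats::quantile(durations, 0.9, type = 1))
    grid <- seq(0, t_max, length.out = 100)
  }
  stopifnot(!is.unsorted(grid))
  G <- km_estimator(durations, 1 - events)
  bs <- vapply(grid, function(t) {
    brier_score(curves, durations, events, t, G, times = times)
  }, numeric(1))
  if (length(grid) == 1L) {
    message("integrated_brier_score: single-point grid, returning the ",
            "pointwise Brier score")
    return(bs)
  }
  span <- max(grid) - min(grid)
  sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
}

#' Summarise per-fold metric reports
#'
#' Mean and sample SD of the time-dependent concordance and integrated
#' Brier score across cross-validation folds.
#'
#' @param folds list of per-fold reports, each with numeric `ctd` and
#'   `ibs`.
#' @return object of class `metric_report`: per-fold values, means, sample
#'   SDs (0 with `single_fold = TRUE` when only one fold is supplied).
#' @export
summarize_folds <- function(folds) {
  stopifnot(length(folds) >= 1)
  ctd <- vapply(folds, function(f) as.numeric(f$ctd), numeric(1))
  ibs <- vapply(folds, function(f) as.numeric(f$ibs), numeric(1))
  single <- length(folds) == 1L
  structure(list(ctd_folds = ctd, ibs_folds = ibs,
                 ctd_mean = mean(ctd, na.rm = TRUE),
                 ctd_sd = if (single) 0 else sd(ctd, na.rm = TRUE),
                 ibs_mean = mean(ibs, na.rm = TRUE),
                 ibs_sd = if (single) 0 else sd(ibs, na.rm = TRUE),
                 n_folds = length(folds), single_fold = single),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Ctd %.3f +/- %.3f | IBS %.3f +/- %.3f (%d folds)\n",
              x$ctd_mean, x$ctd_sd, x$ibs_mean, x$ibs_sd, x$n_folds))
  invisible(x)
}
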