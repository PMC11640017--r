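#' Survival curve on a discrete time grid
#'
#' A right-continuous step function \eqn{S(t) = P(T > t \mid x)} evaluated
#' at ascending interval endpoints, with \eqn{S = 1} before the first point.
#' Values must lie in \eqn{[0, 1]} and be non-increasing.
#'
#' @param times ascending numeric evaluation times (months).
#' @param surv survival probabilities at `times`.
#' @return an object of class `survival_curve`.
#' @export
survival_curve <- function(times, surv) {
  stopifnot(length(times) == length(surv), !is.unsorted(times))
  if (any(surv < -1e-9 | surv > 1 + 1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(surv) > 1e-9)) {
    stop("survival values must be non-increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 surv = pmin(pmax(as.numeric(surv), 0), 1)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve>", length(x$times), "time points; S ranges",
      sprintf("[%.3f, %.3f]\n", min(x$surv), max(x$surv)))
  invisible(x)
}

#' Evaluate survival curves at arbitrary times
#'
#' Step-function evaluation: `S(t)` is the value at the largest grid time
#' `<= t`, and 1 before the first grid time.
#'
#' @param curve a `survival_curve`, or a matrix of survival values (rows =
#'   subjects) with `times` supplied.
#' @param t numeric times.
#' @param times grid times when `curve` is a matrix.
#' @return numeric vector (curve) or matrix (rows = subjects).
#' @export
eval_curve <- function(curve, t, times = NULL) {
  if (inherits(curve, "survival_curve")) {
    idx <- findInterval(t, curve$times)
    return(ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)]))
  }
  stopifnot(is.matrix(curve), !is.null(times))
  idx <- findInterval(t, times)
  out <- matrix(1, nrow(curve), length(t))
  pos <- which(idx > 0)
  if (length(pos)) out[, pos] <- curve[, idx[pos], drop = FALSE]
  out
}

#' Median survival time of a curve
#'
#' First grid time at which the survival probability drops to 0.5 or below.
#'
#' @param curve a `survival_curve`.
#' @return list with `median` (time, or `NA`) and `defined` (FALSE when the
#'   curve never crosses 0.5 on its grid).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  i <- which(curve$surv <= 0.5)
  if (!length(i)) return(list(median = NA_real_, defined = FALSE))
  list(median = curve$times[min(i)], defined = TRUE)
}

# list of survival_curve objects (common grid) -> matrix + times
curves_to_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  stopifnot(length(curves) >= 1)
  times <- curves[[1]]$times
  for (cu in curves) {
    if (length(cu$times) != length(times) || any(cu$times != times)) {
      stop("curves must share a common time grid", call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(curves, `[[`, "surv"))
  attr(m, "times") <- times
  m
}
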