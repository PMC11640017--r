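#' Cox partial-likelihood loss (Breslow ties)
#'
#' Mean negative Cox partial log-likelihood of per-subject risk scores
#' \eqn{g(x)}: for each event \eqn{i},
#' \eqn{-g(x_i) + \log \sum_{j: T_j \ge T_i} e^{g(x_j)}}, averaged over
#' events. Tied event times share the full risk set (Breslow convention).
#' Invariant to adding a constant to all scores.
#'
#' @param scores numeric risk scores, one per subject.
#' @param durations observed times (any positive scale).
#' @param events 0/1 event indicators.
#' @return mean negative partial log-likelihood (0 with a warning when
#'   there are no events).
#' @export
loss_deepsurv <- function(scores, durations, events) {
  stopifnot(length(scores) == length(durations),
            length(events) == length(durations))
  if (sum(events) == 0) {
    warning("no events: Cox partial likelihood undefined, returning 0")
    return(0)
  }
  ord <- order(durations, decreasing = TRUE)
  g <- scores[ord]; tt <- durations[ord]; dd <- events[ord]
  # running logsumexp over subjects with T >= current time
  lse <- numeric(length(g))
  run_max <- -Inf; run_sum <- 0
  for (k in seq_along(g)) {
    if (g[k] > run_max) {
      run_sum <- run_sum * exp(run_max - g[k]) + 1
      run_max <- g[k]
    } else {
      run_sum <- run_sum + exp(g[k] - run_max)
    }
    lse[k] <- run_max + log(run_sum)
  }
  # Breslow: risk set includes all subjects tied with T_i
  last_tie <- cumsum(rle(tt)$lengths)                 # end position per time
  tie_end <- rep(last_tie, rle(tt)$lengths)           # per row
  total <- sum((-g + lse[tie_end])[dd == 1])
  total / sum(dd)
}

# gradient of loss_deepsurv wrt scores (same normalisation)
grad_deepsurv <- function(scores, durations, events) {
  n_ev <- sum(events)
  if (n_ev == 0) return(numeric(length(scores)))
  ord <- order(durations, decreasing = TRUE)
  g <- scores[ord]; tt <- durations[ord]; dd <- events[ord]
  eg <- exp(g - max(g))
  cs <- cumsum(eg)
  last_tie <- cumsum(rle(tt)$lengths)
  tie_end <- rep(last_tie, rle(tt)$lengths)
  S <- cs[tie_end]                                    # risk-set sums
  # for each subject j: sum over events e with T_e >= not.. e risk set
  # containing j (i.e. T_e <= T_j incl. ties) of eg_j / S_e
  w <- ifelse(dd == 1, 1 / S, 0)
  # subjects sorted by decreasing T: event e's risk set = positions 1..tie_end(e)
  # accumulate, for each position j, sum of w_e over events e with
  # tie_end(e) >= j  ==  reverse cumulative sum of w_e scattered at tie_end
  acc <- numeric(length(g))
  ww <- numeric(length(g))
  for (e in which(dd == 1)) ww[tie_end[e]] <- ww[tie_end[e]] + w[e]
  acc <- rev(cumsum(rev(ww)))
  grad_sorted <- (-dd + eg * acc) / n_ev
  out <- numeric(length(scores))
  out[ord] <- grad_sorted
  out
}

#' Discrete logistic-hazard (Nnet-survival) loss
#'
#' Bernoulli negative log-likelihood of per-interval conditional hazards:
#' a subject observed to interval \eqn{T} contributes
#' \eqn{-\sum_{t<T}\log(1-h_t)} plus \eqn{-\log h_T} if the event occurred
#' or \eqn{-\log(1-h_T)} if censored there. Hazards are epsilon-clamped
#' away from 0/1 inside the logs (a message reports how many entries were
#' clamped).
#'
#' @param hazards matrix (subjects x intervals) of hazard probabilities.
#' @param durations integer interval indices in `1:ncol(hazards)`.
#' @param events 0/1 indicators.
#' @param eps clamping epsilon.
#' @return mean negative log-likelihood.
#' @export
loss_logistic_hazard <- function(hazards, durations, events, eps = 1e-7) {
  stopifnot(is.matrix(hazards), length(durations) == nrow(hazards),
            all(durations >= 1), all(durations <= ncol(hazards)))
  if (any(hazards < 0 | hazards > 1)) {
    stop("hazards must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- nrow(hazards)
  need_clamp <- 0L
  total <- 0
  for (i in seq_len(n)) {
    d <- durations[i]
    h <- hazards[i, seq_len(d)]
    y <- c(rep(0, d - 1L), events[i])
    nc <- sum((y == 1 & h < eps) | (y == 0 & h > 1 - eps))
    need_clamp <- need_clamp + nc
    # clamp only the side entering each log so exact terms stay exact
    total <- total - sum(y * log(pmax(h, eps)) +
                           (1 - y) * log(pmax(1 - h, eps)))
  }
  if (need_clamp > 0L) {
    message("loss_logistic_hazard: clamped ", need_clamp,
            " hazard value(s) by epsilon")
  }
  total / n
}

#' DeepHit loss (single event): likelihood / ranking mixture
#'
#' `alpha * L_like + (1 - alpha) * L_rank` where `L_like` is the mean of
#' \eqn{-\log f(T)} for events and \eqn{-\log S(T)} for censored subjects
#' (with \eqn{f} the interval PMF and \eqn{S(k) = 1 - \sum_{t \le k} f_t}
#' including the beyond-horizon remainder), and `L_rank` is the mean over
#' comparable pairs — \eqn{i} an event with \eqn{T_i < T_j} — of
#' \eqn{\exp(-(F_i(T_i) - F_j(T_i))/\sigma)}, \eqn{F} the cumulative
#' incidence. With no comparable pairs the ranking term is 0.
#'
#' @param pmf matrix (subjects x intervals) of interval probabilities with
#'   row sums at most 1; the deficit is the beyond-horizon survival
#'   remainder.
#' @param durations integer interval indices.
#' @param events 0/1 indicators.
#' @param alpha mixture weight in \eqn{[0, 1]}.
#' @param sigma ranking-kernel width (> 0).
#' @param eps clamping epsilon inside logs.
#' @return the mixed loss.
#' @export
loss_deephit <- function(pmf, durations, events, alpha = 0.5, sigma = 1,
                         eps = 1e-7) {
  stopifnot(is.matrix(pmf), length(durations) == nrow(pmf))
  if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (any(pmf < -1e-9) || any(rowSums(pmf) > 1 + 1e-6)) {
    stop("pmf rows must be nonnegative with sum at most 1", call. = FALSE)
  }
  n <- nrow(pmf); K <- ncol(pmf)
  Fm <- t(apply(pmf, 1, cumsum))          # cumulative incidence
  if (K == 1L) Fm <- matrix(Fm, ncol = 1L)
  idx <- cbind(seq_len(n), durations)
  like <- ifelse(events == 1,
                 -log(pmax(pmf[idx], eps)),
                 -log(pmax(1 - Fm[idx], eps)))
  L_like <- mean(like)
  L_rank <- 0
  if (alpha < 1) {
    terms <- c()
    for (i in which(events == 1)) {
      j <- which(durations > durations[i])
      if (!length(j)) next
      terms <- c(terms, exp(-(Fm[i, durations[i]] - Fm[j, durations[i]]) / sigma))
    }
    if (length(terms)) L_rank <- mean(terms)
  }
  alpha * L_like + (1 - alpha) * L_rank
}

#' Cox-Time loss: sampled-risk-set partial likelihood
#'
#' Case–control approximation to a relative-risk loss whose score may
#' depend on time: each event \eqn{i} contributes
#' \eqn{\log\big(1 + \sum_{c} e^{g(T_i, x_c) - g(T_i, x_i)}\big)} over
#' controls \eqn{c} sampled (without replacement) from the risk set at
#' \eqn{T_i}. When the risk set holds no other subject the event
#' contributes 0 (a message reports it); when it holds at most
#' `n_control_samples` subjects the full risk set is used, which makes the
#' loss equal the Breslow partial likelihood.
#'
#' @param score_fn function `(t, X)` returning one score per row of `X`,
#'   evaluated at time `t`.
#' @param covariates feature matrix (subjects x features).
#' @param durations observed times.
#' @param events 0/1 indicators.
#' @param n_control_samples controls per event (>= 1).
#' @param seed integer seed for control sampling.
#' @return mean loss over events (deterministic given the seed).
#' @export
loss_cox_time <- function(score_fn, covariates, durations, events,
                          n_control_samples = 4, seed = 1) {
  stopifnot(n_control_samples >= 1, is.matrix(covariates),
            nrow(covariates) == length(durations))
  ev <- which(events == 1)
  if (!length(ev)) {
    warning("no events: returning 0")
    return(0)
  }
  with_seed(seed, {
    total <- 0
    n_empty <- 0L
    for (i in ev) {
      pool <- which(durations >= durations[i])
      pool <- pool[pool != i]
      if (!length(pool)) {
        n_empty <- n_empty + 1L
        next
      }
      ctrl <- if (length(pool) <= n_control_samples) pool else {
        pool[sample.int(length(pool), n_control_samples)]
      }
      g <- score_fn(durations[i], covariates[c(i, ctrl), , drop = FALSE])
      total <- total + logsumexp(g - g[1])
    }
    if (n_empty > 0L) {
      message("loss_cox_time: ", n_empty,
              " event(s) with empty risk set contributed 0")
    }
    total / length(ev)
  })
}
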