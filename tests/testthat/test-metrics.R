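test_that("product-limit estimator reproduces hand-computed step functions", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$times, c(1, 2, 3))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))
  # all censored: constant 1
  km0 <- km_estimator(c(1, 5, 9), c(0, 0, 0))
  expect_equal(eval_step(km0, c(0, 4, 100)), c(1, 1, 1))
  # censoring distribution via flipped indicators:
  # {(2, event), (3, censored), (5, event)} -> G = 1 before 3, 1/2 after
  G <- km_estimator(c(2, 3, 5), 1 - c(1, 0, 1))
  expect_equal(eval_step(G, c(2, 2.9)), c(1, 1))
  expect_equal(eval_step(G, c(3, 4, 5)), c(0.5, 0.5, 0.5))
  expect_equal(eval_step(G, 3, left = TRUE), 1)
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")
})

test_that("product-limit estimator matches an exhaustive oracle on random inputs", {
  oracle_km <- function(dur, ind, t) {
    s <- 1
    for (x in sort(unique(dur[ind == 1]))) {
      if (x > t) break
      s <- s * (1 - sum(dur == x & ind == 1) / sum(dur >= x))
    }
    s
  }
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:15, 1)
    dur <- sample(1:8, n, TRUE)
    ind <- rbinom(n, 1, 0.6)
    km <- km_estimator(dur, ind)
    for (t in 0:9) {
      expect_equal(eval_step(km, t), oracle_km(dur, ind, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("product-limit estimator agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(8)
  dur <- sample(1:20, 60, TRUE)
  ind <- rbinom(60, 1, 0.5)
  km <- km_estimator(dur, ind)
  sf <- survival::survfit(survival::Surv(dur, ind) ~ 1)
  expect_equal(eval_step(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("time-dependent concordance equals the brute-force pairwise count", {
  times <- 1:8
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    S <- random_curves(n, times)
    dur <- sample(1:8, n, TRUE)
    ev <- rbinom(n, 1, 0.7)
    got <- ctd_index(S, dur, ev, times = times)
    want <- oracle_ctd(S, times, dur, ev)
    if (is.na(want)) expect_false(got$defined)
    else expect_equal(got$ctd, want, tolerance = 1e-12)
  }
  # explicit 4-row instance with one censored subject
  S <- rbind(c(0.9, 0.5, 0.2), c(0.95, 0.8, 0.6), c(0.7, 0.4, 0.3),
             c(0.99, 0.9, 0.85))
  dur <- c(1, 2, 2, 3); ev <- c(1, 1, 0, 1)
  got <- ctd_index(S, dur, ev, times = 1:3)
  expect_equal(got$ctd, oracle_ctd(S, 1:3, dur, ev), tolerance = 1e-12)
  # no comparable pairs -> undefined flag
  und <- ctd_index(S[1:2, ], c(3, 3), c(0, 0), times = 1:3)
  expect_false(und$defined)
})

test_that("concordance endpoints: perfect ordering scores 1, random scores 0.5", {
  times <- 1:10
  n <- 10
  dur <- 1:10; ev <- rep(1, n)
  # lower curve everywhere for earlier failures: perfect discrimination
  S <- outer(order(order(dur)), seq_along(times),
             function(r, t) r / (n + 2) - 0.001 * t)
  expect_equal(ctd_index(S, dur, ev, times = times)$ctd, 1)
  set.seed(5)
  dur2 <- sample(1:10, 20, TRUE); ev2 <- rbinom(20, 1, 0.6); ev2[1] <- 1
  draws <- replicate(300, {
    ctd_index(random_curves(20, times), dur2, ev2, times = times)$ctd
  })
  expect_lt(abs(mean(draws) - 0.5), 0.03)
})

test_that("concordance is invariant to monotone transformations of the predictions", {
  times <- 1:6
  set.seed(23)
  S <- random_curves(9, times)
  dur <- sample(1:6, 9, TRUE); ev <- rbinom(9, 1, 0.8); ev[2] <- 1
  base <- ctd_index(S, dur, ev, times = times)$ctd
  expect_equal(ctd_index(S^3, dur, ev, times = times)$ctd, base)
  expect_equal(ctd_index(plogis(5 * S), dur, ev, times = times)$ctd, base)
})

test_that("concordance equals Harrell's C for crossing-free curves without censoring", {
  times <- 1:12
  set.seed(29)
  risk <- rnorm(10)
  S <- exp(-outer(exp(risk), times) / 12)   # proportional, never cross
  dur <- sample(1:12, 10, TRUE)
  ev <- rep(1, 10)
  harrell <- {
    conc <- 0; comp <- 0
    for (i in 1:10) for (j in 1:10) {
      if (dur[i] < dur[j]) {
        comp <- comp + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
    conc / comp
  }
  expect_equal(ctd_index(S, dur, ev, times = times)$ctd, harrell,
               tolerance = 1e-12)
})

test_that("Brier score reproduces closed-form and hand-enumerated values", {
  times <- 1:5
  dur <- c(2, 3, 5); ev <- c(1, 1, 1)
  # perfect step predictions: S_i(t) = 1{t < T_i}
  S <- outer(dur, times, function(d, t) as.numeric(t < d))
  G <- km_estimator(dur, 1 - ev)
  for (t in times) {
    expect_equal(brier_score(S, dur, ev, t, G, times = times), 0)
  }
  # constant 1/2 prediction, no censoring: 0.25 everywhere
  S5 <- matrix(0.5, 3, 5)
  for (t in times) {
    expect_equal(brier_score(S5, dur, ev, t, G, times = times), 0.25)
  }
  # censored 3-row toy against the fully enumerated weighted sum
  dur2 <- c(2, 3, 5); ev2 <- c(1, 0, 1)
  set.seed(41)
  S2 <- random_curves(3, times)
  G2 <- km_estimator(dur2, 1 - ev2)
  for (t in c(1, 2.5, 4)) {
    expect_equal(brier_score(S2, dur2, ev2, t, G2, times = times),
                 oracle_brier(S2, times, dur2, ev2, t), tolerance = 1e-12)
  }
})

test_that("integrated Brier score integrates the pointwise curve", {
  times <- 1:10
  dur <- sample(1:10, 30, TRUE); ev <- rep(1, 30)
  S_perfect <- outer(dur, times, function(d, t) as.numeric(t < d))
  expect_equal(integrated_brier_score(S_perfect, dur, ev, times = times), 0)
  # constant 1/2 prediction: the integrand is 0.25 wherever the curve is
  # defined (before its first grid time a survival curve is 1 by
  # definition, so the grid starts there)
  S_half <- matrix(0.5, 30, 10)
  expect_equal(integrated_brier_score(S_half, dur, ev,
                                      grid = seq(1, 9, by = 0.5),
                                      times = times), 0.25,
               tolerance = 1e-12)
  # quadrature stability: 100- vs 1000-point uniform grids agree
  set.seed(43)
  ev2 <- rbinom(30, 1, 0.7); ev2[1] <- 1
  Sr <- random_curves(30, times)
  g1 <- seq(0, 8, length.out = 100)
  g2 <- seq(0, 8, length.out = 1000)
  i1 <- integrated_brier_score(Sr, dur, ev2, grid = g1, times = times)
  i2 <- integrated_brier_score(Sr, dur, ev2, grid = g2, times = times)
  expect_lt(abs(i1 - i2), 1e-3)
  expect_message(
    integrated_brier_score(Sr, dur, ev2, grid = 4, times = times),
    "single-point")
})

test_that("fold summaries report means and sample SDs", {
  r <- summarize_folds(list(list(ctd = 0.9, ibs = 0.1),
                            list(ctd = 0.9, ibs = 0.1),
                            list(ctd = 0.9, ibs = 0.1)))
  expect_equal(r$ctd_mean, 0.9)
  expect_equal(r$ctd_sd, 0)
  r2 <- summarize_folds(list(list(ctd = 0.8, ibs = 0.2),
                             list(ctd = 1.0, ibs = 0.3)))
  expect_equal(r2$ctd_mean, 0.9)
  expect_equal(r2$ctd_sd, sd(c(0.8, 1.0)))
  expect_equal(round(r2$ctd_sd, 4), 0.1414)
  r1 <- summarize_folds(list(list(ctd = 0.7, ibs = 0.2)))
  expect_true(r1$single_fold)
  expect_equal(r1$ctd_sd, 0)
})
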