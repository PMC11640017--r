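# Shared fixtures, all built in code.

# Hand-built three-patient cohort with fully known visit histories.
# P1: visits at months 0, 2, 5 (chemo at 2 and 5; AE category 3 at 5),
#     diagnosed month 0, dies at month 8.
# P2: single visit at diagnosis (month 10), censored after 4 months.
# P3: visits at 20, 21, 23, 26 (hormone at 21 and 26), dies at month 30.
toy_cohort <- function() {
  pat <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    diagnosis_month = c(0L, 10L, 20L),
    duration_months = c(8L, 4L, 10L),
    event = c(1L, 0L, 1L),
    age = c(70, 80, 76), race_code = c(1L, 2L, 1L),
    er_status = c(1L, 0L, 1L), pr_status = c(1L, 0L, 0L),
    her2_status = c(0L, 1L, 0L), grade = c(2L, 3L, 4L),
    histology_code = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  vis <- toy_visits(
    list(id = "P1", month = 0L), list(id = "P1", month = 2L, chemo = 1L),
    list(id = "P1", month = 5L, chemo = 1L, ae = 3L),
    list(id = "P2", month = 10L),
    list(id = "P3", month = 20L), list(id = "P3", month = 21L, hormone = 1L),
    list(id = "P3", month = 23L, ae = 1L),
    list(id = "P3", month = 26L, hormone = 1L))
  hazardnet:::new_cohort(pat, vis, time_grid(40))
}

# build a visits data frame from terse per-row specs
toy_visits <- function(...) {
  specs <- list(...)
  rows <- lapply(specs, function(s) {
    r <- data.frame(patient_id = s$id, month = s$month,
                    treat_chemo = s$chemo %||% 0L,
                    treat_bio = s$bio %||% 0L,
                    treat_hormone = s$hormone %||% 0L,
                    stringsAsFactors = FALSE)
    for (k in 1:18) r[[sprintf("ae_%02d", k)]] <- 0L
    if (!is.null(s$ae)) for (k in s$ae) r[[sprintf("ae_%02d", k)]] <- 1L
    r$comorbidity_index <- s$cm %||% 1
    r
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised default calibrated cohort shared across test files
.cohort_cache <- new.env(parent = emptyenv())
calibrated_cohort <- function(n = 2000, seed = 20600) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(generator_config(n_patients = n,
                                                             seed = seed))
  }
  .cohort_cache[[key]]
}

# quick small cohort for model tests
small_cohort <- function(n = 200, seed = 321, ...) {
  generate_cohort(generator_config(n_patients = n, seed = seed, ...))
}

# brute-force Antolini concordance: explicit double loop over pairs
oracle_ctd <- function(S, times, durations, events) {
  n <- length(durations)
  conc <- 0; comp <- 0
  at <- function(i, t) {
    idx <- findInterval(t, times)
    if (idx == 0) 1 else S[i, idx]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events[i] != 1) next
    comparable <- durations[i] < durations[j] ||
      (durations[i] == durations[j] && events[j] == 0)
    if (!comparable) next
    comp <- comp + 1
    si <- at(i, durations[i]); sj <- at(j, durations[i])
    if (si < sj) conc <- conc + 1 else if (si == sj) conc <- conc + 0.5
  }
  if (comp == 0) NA_real_ else conc / comp
}

# brute-force Graf-weighted Brier score: explicit per-subject enumeration
oracle_brier <- function(S, times, durations, events, t) {
  n <- length(durations)
  cens <- durations[events == 0]
  G <- function(u, left = FALSE) {
    # product-limit over censoring times computed from scratch
    tk <- sort(unique(cens))
    val <- 1
    for (x in tk) {
      if ((left && x >= u) || (!left && x > u)) break
      n_k <- sum(durations >= x)
      d_k <- sum(durations == x & events == 0)
      val <- val * (1 - d_k / n_k)
    }
    val
  }
  at <- function(i, u) { idx <- findInterval(u, times)
    if (idx == 0) 1 else S[i, idx] }
  tot <- 0; used <- 0
  for (i in seq_len(n)) {
    if (durations[i] <= t && events[i] == 1) {
      w <- 1 / G(durations[i], left = TRUE)
      tot <- tot + w * (0 - at(i, t))^2; used <- used + 1
    } else if (durations[i] > t) {
      tot <- tot + (1 - at(i, t))^2 / G(t); used <- used + 1
    } else used <- used + 1  # censored before t: weight 0, still counted
  }
  tot / used
}

# random monotone survival-curve matrix on a fixed grid
random_curves <- function(n, times) {
  S <- matrix(runif(n * length(times)), n)
  t(apply(S, 1, function(s) rev(sort(s))))
}
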