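#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates the structure of an elderly stage IV breast-cancer claims cohort
#' on a monthly grid: time-fixed covariates sampled at diagnosis, a visit
#' process with treatment assignment (chemotherapy / biotherapy / hormone
#' therapy), adverse events drawn conditionally on treatment in 18
#' categories, an overdispersed comorbidity index with monthly drift, and
#' death generated from a logistic discrete-time hazard whose linear
#' predictor combines fixed covariates with history summaries. Follow-up is
#' administratively right-censored at the end of the study window.
#'
#' Calibration defaults target a population with age 76.0 (SD 7.5, floor 65
#' for Medicare age eligibility, truncated-normal with the location
#' re-centred so the post-truncation mean hits the target) and a baseline
#' comorbidity index with mean 1.6 and SD 2.6 (negative binomial;
#' SD > mean implies overdispersion).
#'
#' @param n_patients number of patients to simulate.
#' @param age_mean,age_sd target mean and SD of age at diagnosis (years).
#' @param age_floor minimum age (years); sampling is truncated here.
#' @param comorbidity_mean,comorbidity_sd moments of the baseline
#'   comorbidity index (negative-binomial parameterisation).
#' @param horizon_months length of the study window in months; diagnosis
#'   months are uniform over `0:(horizon_months - 1)` and follow-up is
#'   censored at the window end.
#' @param baseline_hazard_per_month discrete monthly death probability at
#'   the reference covariate level.
#' @param coef_fixed named log-hazard-ratios for time-fixed covariates.
#'   Recognised names: `age` (per SD above `age_mean`), `er_status`,
#'   `pr_status`, `her2_status` (per positive status), `grade` (per grade
#'   unit, centred at 2.5).
#' @param coef_timevarying named log-hazard-ratios for history summaries.
#'   Recognised names are those of the history block (see
#'   [extend_covariates()]) plus `cum_ae_total` and `cum_tx_total`;
#'   `comorbidity_latest` acts on the raw (unbucketed) index.
#' @param visit_rate_per_month Bernoulli probability of a claims visit in
#'   any month after diagnosis (the diagnosis month always has a visit).
#' @param treatment_policy list with elements `chemo_base`, `chemo_decay`,
#'   `bio_base`, `hormone_base`, `hormone_ramp`, `background`: chemotherapy
#'   probability decays exponentially with months since diagnosis, hormone
#'   therapy ramps up for receptor-positive patients, biotherapy targets
#'   HER2-positive patients; `background` is the off-target probability.
#' @param ae_prob_given_treatment length-18 vector of per-category adverse
#'   event probabilities in a month with any treatment; months without
#'   treatment use `ae_background_factor` times these.
#' @param ae_background_factor multiplier for AE probabilities in
#'   treatment-free months.
#' @param comorbidity_drift_prob monthly probability of a +1 comorbidity
#'   increment; each adverse event in the month adds
#'   `comorbidity_ae_boost` to that probability.
#' @param comorbidity_ae_boost see above.
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2000,
                             age_mean = 76.0,
                             age_sd = 7.5,
                             age_floor = 65,
                             comorbidity_mean = 1.6,
                             comorbidity_sd = 2.6,
                             horizon_months = 300,
                             baseline_hazard_per_month = 0.012,
                             coef_fixed = c(age = 0.30, er_status = -0.30,
                                            pr_status = -0.15,
                                            her2_status = -0.10,
                                            grade = 0.25),
                             coef_timevarying = c(comorbidity_latest = 0.30,
                                                  cum_ae_total = 0.08,
                                                  cum_chemo = -0.05),
                             visit_rate_per_month = 0.6,
                             treatment_policy = list(chemo_base = 0.45,
                                                     chemo_decay = 24,
                                                     bio_base = 0.30,
                                                     hormone_base = 0.35,
                                                     hormone_ramp = 6,
                                                     background = 0.04),
                             ae_prob_given_treatment = signif(0.12 * exp(-(0:17) / 6), 3),
                             ae_background_factor = 0.15,
                             comorbidity_drift_prob = 0.02,
                             comorbidity_ae_boost = 0.10,
                             seed = 20240101) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0) {
    stop("n_patients must be a single nonnegative integer", call. = FALSE)
  }
  if (horizon_months < 1) stop("horizon_months must be >= 1", call. = FALSE)
  probs <- c(baseline_hazard_per_month, visit_rate_per_month,
             ae_prob_given_treatment, ae_background_factor,
             comorbidity_drift_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(ae_prob_given_treatment) != n_ae_categories()) {
    stop("ae_prob_given_treatment must have length ", n_ae_categories(),
         call. = FALSE)
  }
  if (age_sd <= 0 || comorbidity_sd^2 <= comorbidity_mean) {
    stop("age_sd must be positive and comorbidity SD^2 must exceed the mean ",
         "(overdispersion)", call. = FALSE)
  }
  bad_tv <- setdiff(names(coef_timevarying), allowed_tv_names())
  if (length(bad_tv)) {
    stop("unknown coef_timevarying names: ", paste(bad_tv, collapse = ", "),
         call. = FALSE)
  }
  bad_fx <- setdiff(names(coef_fixed), fixed_effect_names())
  if (length(bad_fx)) {
    stop("unknown coef_fixed names: ", paste(bad_fx, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd, age_floor = age_floor,
    comorbidity_mean = comorbidity_mean, comorbidity_sd = comorbidity_sd,
    horizon_months = as.integer(horizon_months),
    baseline_hazard_per_month = baseline_hazard_per_month,
    coef_fixed = coef_fixed, coef_timevarying = coef_timevarying,
    visit_rate_per_month = visit_rate_per_month,
    treatment_policy = treatment_policy,
    ae_prob_given_treatment = ae_prob_given_treatment,
    ae_background_factor = ae_background_factor,
    comorbidity_drift_prob = comorbidity_drift_prob,
    comorbidity_ae_boost = comorbidity_ae_boost,
    seed = as.integer(seed)
  ), class = "generator_config")
}

n_ae_categories <- function() 18L

fixed_effect_names <- function() {
  c("age", "er_status", "pr_status", "her2_status", "grade")
}

allowed_tv_names <- function() {
  c("cum_chemo", "cum_bio", "cum_hormone", "cum_tx_total", "cum_ae_total",
    sprintf("cum_ae_%02d", seq_len(n_ae_categories())),
    "comorbidity_latest", "months_since_dx", "months_since_tx",
    "ever_treated")
}

# Location parameter of a normal truncated below at `floor` whose
# post-truncation mean equals `target`.
truncnorm_location <- function(target, sd, floor) {
  trunc_mean <- function(mu) {
    a <- (floor - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = target - 6 * sd, upper = target + sd,
                 tol = 1e-10)$root
}

rtruncnorm_floor <- function(n, mu, sd, floor) {
  p0 <- pnorm((floor - mu) / sd)
  mu + sd * qnorm(p0 + runif(n) * (1 - p0))
}

# Transformed fixed-covariate values entering the hazard linear predictor,
# aligned with the names accepted in coef_fixed.
fixed_effect_row <- function(config, fixed) {
  c(age = (fixed[["age"]] - config$age_mean) / config$age_sd,
    er_status = fixed[["er_status"]],
    pr_status = fixed[["pr_status"]],
    her2_status = fixed[["her2_status"]],
    grade = fixed[["grade"]] - 2.5)
}

fixed_linpred <- function(config, fixed) {
  cf <- config$coef_fixed
  if (!length(cf)) return(0)
  vals <- fixed_effect_row(config, fixed)
  sum(cf * vals[names(cf)])
}

tv_linpred <- function(config, summary) {
  ct <- config$coef_timevarying
  if (!length(ct)) return(0)
  sum(ct * summary[names(ct)])
}

# History summary vector maintained by the simulator; raw-valued analogue of
# the encoder's history block.
empty_summary <- function() {
  s <- c(cum_chemo = 0, cum_bio = 0, cum_hormone = 0, cum_tx_total = 0,
         cum_ae_total = 0,
         stats::setNames(numeric(n_ae_categories()),
                         sprintf("cum_ae_%02d", seq_len(n_ae_categories()))),
         comorbidity_latest = 0, months_since_dx = 0, months_since_tx = 0,
         ever_treated = 0)
  s
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates patients month by month from diagnosis: a Bernoulli visit
#' process, state-dependent treatment assignment, adverse events conditional
#' on treatment, a drifting comorbidity index, and death from the logistic
#' discrete hazard
#' \deqn{h(t) = \mathrm{logit}^{-1}\big(\mathrm{logit}(h_0) + \beta_f^\top
#'   x_{fixed} + \beta_v^\top s(t)\big)}
#' where \eqn{s(t)} summarises the visit history up to month \eqn{t}.
#' Patients alive when the study window closes are administratively
#' censored. The true hazard parameters travel with the cohort (field
#' `config`) so downstream fits can be validated against ground truth.
#'
#' @param config a [generator_config()].
#' @return an object of class `cohort`: list with `patients` (one row per
#'   patient: identifiers, diagnosis month, observed duration in months,
#'   event indicator, fixed covariates), `visits` (one row per visit month:
#'   treatment flags, 18 adverse-event flags, comorbidity index), `grid`
#'   (the monthly [time_grid()]), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  H <- config$horizon_months
  K <- n_ae_categories()
  grid <- time_grid(H)
  if (n == 0L) {
    return(new_cohort(empty_patients_df(), empty_visits_df(), grid, config))
  }
  with_seed(config$seed, {
    mu_age <- truncnorm_location(config$age_mean, config$age_sd,
                                 config$age_floor)
    age <- rtruncnorm_floor(n, mu_age, config$age_sd, config$age_floor)
    race_code <- sample.int(4L, n, replace = TRUE,
                            prob = c(0.77, 0.11, 0.07, 0.05))
    er_status <- rbinom(n, 1L, 0.65)
    pr_status <- rbinom(n, 1L, 0.55)
    her2_status <- rbinom(n, 1L, 0.20)
    grade <- sample.int(4L, n, replace = TRUE,
                        prob = c(0.10, 0.35, 0.40, 0.15))
    histology_code <- sample.int(5L, n, replace = TRUE,
                                 prob = c(0.70, 0.12, 0.08, 0.06, 0.04))
    nb_size <- config$comorbidity_mean^2 /
      (config$comorbidity_sd^2 - config$comorbidity_mean)
    cm0 <- rnbinom(n, size = nb_size, mu = config$comorbidity_mean)
    dx_month <- sample.int(H, n, replace = TRUE) - 1L

    pol <- config$treatment_policy
    ae_p <- config$ae_prob_given_treatment

    pat_rows <- vector("list", n)
    vis_rows <- vector("list", n)
    for (i in seq_len(n)) {
      fixed <- c(age = age[i], er_status = er_status[i],
                 pr_status = pr_status[i], her2_status = her2_status[i],
                 grade = grade[i])
      lp_fixed <- fixed_linpred(config, fixed)
      base_logit <- qlogis(config$baseline_hazard_per_month)
      max_follow <- H - dx_month[i]
      s <- empty_summary()
      cm <- cm0[i]
      last_tx <- NA_integer_

      visit_month <- integer(0); visit_tx <- list(); visit_ae <- list()
      visit_cm <- numeric(0)

      record_visit <- function(t) {
        # treatment assignment: chemo front-loaded, hormone maintenance for
        # receptor-positive disease, biotherapy for HER2-positive disease
        p_chemo <- pol$chemo_base * exp(-t / pol$chemo_decay)
        p_bio <- if (her2_status[i] == 1L) pol$bio_base else pol$background
        p_horm <- if (er_status[i] == 1L || pr_status[i] == 1L) {
          pol$hormone_base * (1 - exp(-t / pol$hormone_ramp))
        } else pol$background
        tx <- c(chemo = rbinom(1L, 1L, p_chemo),
                bio = rbinom(1L, 1L, p_bio),
                hormone = rbinom(1L, 1L, p_horm))
        any_tx <- any(tx == 1L)
        pae <- if (any_tx) ae_p else ae_p * config$ae_background_factor
        ae <- rbinom(K, 1L, pae)
        # comorbidity drift, accelerated by adverse events; the diagnosis
        # visit (t = 0) records the sampled baseline index unchanged
        if (t > 0L) {
          p_drift <- min(1, config$comorbidity_drift_prob +
                           config$comorbidity_ae_boost * sum(ae))
          cm <<- cm + rbinom(1L, 1L, p_drift)
        }
        visit_month <<- c(visit_month, dx_month[i] + t)
        visit_tx[[length(visit_tx) + 1L]] <<- tx
        visit_ae[[length(visit_ae) + 1L]] <<- ae
        visit_cm <<- c(visit_cm, cm)
        # fold into history summaries
        s[["cum_chemo"]] <<- s[["cum_chemo"]] + tx[["chemo"]]
        s[["cum_bio"]] <<- s[["cum_bio"]] + tx[["bio"]]
        s[["cum_hormone"]] <<- s[["cum_hormone"]] + tx[["hormone"]]
        s[["cum_tx_total"]] <<- s[["cum_tx_total"]] + sum(tx)
        s[["cum_ae_total"]] <<- s[["cum_ae_total"]] + sum(ae)
        idx <- which(ae == 1L)
        if (length(idx)) {
          nm <- sprintf("cum_ae_%02d", idx)
          s[nm] <<- s[nm] + 1
        }
        s[["comorbidity_latest"]] <<- cm
        if (any_tx) {
          last_tx <<- t
          s[["ever_treated"]] <<- 1
        }
      }

      record_visit(0L)  # diagnosis-month visit always present
      duration <- max_follow
      event <- 0L
      t <- 1L
      while (t <= max_follow) {
        if (runif(1) < config$visit_rate_per_month) record_visit(t)
        s[["months_since_dx"]] <- t
        s[["months_since_tx"]] <- if (is.na(last_tx)) t else t - last_tx
        h <- plogis(base_logit + lp_fixed + tv_linpred(config, s))
        if (runif(1) < h) {
          duration <- t
          event <- 1L
          break
        }
        t <- t + 1L
      }
      # drop any visit recorded past the observed duration (none by
      # construction: visits are drawn before the death check each month)
      pat_rows[[i]] <- data.frame(
        patient_id = sprintf("P%05d", i), diagnosis_month = dx_month[i],
        duration_months = duration, event = event, age = age[i],
        race_code = race_code[i], er_status = er_status[i],
        pr_status = pr_status[i], her2_status = her2_status[i],
        grade = grade[i], histology_code = histology_code[i],
        stringsAsFactors = FALSE)
      tx_m <- do.call(rbind, visit_tx)
      ae_m <- do.call(rbind, visit_ae)
      vis <- data.frame(patient_id = sprintf("P%05d", i),
                        month = visit_month, stringsAsFactors = FALSE)
      vis$treat_chemo <- tx_m[, "chemo"]
      vis$treat_bio <- tx_m[, "bio"]
      vis$treat_hormone <- tx_m[, "hormone"]
      colnames(ae_m) <- sprintf("ae_%02d", seq_len(K))
      vis <- cbind(vis, as.data.frame(ae_m))
      vis$comorbidity_index <- visit_cm
      vis_rows[[i]] <- vis
    }
    patients <- do.call(rbind, pat_rows)
    visits <- do.call(rbind, vis_rows)
    rownames(patients) <- rownames(visits) <- NULL
    new_cohort(patients, visits, grid, config)
  })
}

empty_patients_df <- function() {
  data.frame(patient_id = character(0), diagnosis_month = integer(0),
             duration_months = integer(0), event = integer(0),
             age = numeric(0), race_code = integer(0),
             er_status = integer(0), pr_status = integer(0),
             her2_status = integer(0), grade = integer(0),
             histology_code = integer(0), stringsAsFactors = FALSE)
}

empty_visits_df <- function() {
  d <- data.frame(patient_id = character(0), month = integer(0),
                  treat_chemo = integer(0), treat_bio = integer(0),
                  treat_hormone = integer(0), stringsAsFactors = FALSE)
  for (k in seq_len(n_ae_categories())) d[[sprintf("ae_%02d", k)]] <- integer(0)
  d$comorbidity_index <- numeric(0)
  d
}

new_cohort <- function(patients, visits, grid, config = NULL) {
  structure(list(patients = patients, visits = visits, grid = grid,
                 config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$patients), "patients,", nrow(x$visits),
      "visit entries over", x$grid$n_intervals, "months\n")
  invisible(x)
}

#' Ground-truth survival curve under the generator's hazard
#'
#' Computes \eqn{S(t) = \prod_{s \le t} (1 - h(s))} directly from the
#' generator's own hazard model for a given fixed-covariate profile and a
#' fully specified visit history, for validating fitted models against the
#' data-generating truth.
#'
#' @param config a [generator_config()].
#' @param fixed_covariates named vector with `age`, `er_status`,
#'   `pr_status`, `her2_status`, `grade`.
#' @param treatment_history data frame of visits on the relative monthly
#'   grid: column `month` (0 = diagnosis), treatment flags `treat_chemo`,
#'   `treat_bio`, `treat_hormone`, optional `ae_01`..`ae_18` flags and
#'   `comorbidity_index`. May have zero rows (no visits).
#' @param n_months number of months to evaluate; defaults to the horizon.
#' @return a [survival_curve] over months `1:n_months`.
#' @export
true_survival_curve <- function(config, fixed_covariates, treatment_history,
                                n_months = config$horizon_months) {
  stopifnot(inherits(config, "generator_config"))
  th <- treatment_history
  if (is.null(th)) th <- data.frame(month = integer(0))
  if (nrow(th) && max(th$month) >= config$horizon_months) {
    stop("treatment history extends beyond the study horizon", call. = FALSE)
  }
  if (n_months > config$horizon_months) {
    stop("n_months exceeds the study horizon", call. = FALSE)
  }
  K <- n_ae_categories()
  ae_cols <- sprintf("ae_%02d", seq_len(K))
  base_logit <- qlogis(config$baseline_hazard_per_month)
  lp_fixed <- fixed_linpred(config, fixed_covariates)
  s <- empty_summary()
  last_tx <- NA_integer_
  ingest <- function(row) {
    tx <- c(chemo = row[["treat_chemo"]], bio = row[["treat_bio"]],
            hormone = row[["treat_hormone"]])
    tx[is.na(tx)] <- 0
    ae <- numeric(K)
    present <- intersect(ae_cols, names(row))
    ae[match(present, ae_cols)] <- unlist(row[present])
    s[["cum_chemo"]] <<- s[["cum_chemo"]] + tx[["chemo"]]
    s[["cum_bio"]] <<- s[["cum_bio"]] + tx[["bio"]]
    s[["cum_hormone"]] <<- s[["cum_hormone"]] + tx[["hormone"]]
    s[["cum_tx_total"]] <<- s[["cum_tx_total"]] + sum(tx)
    s[["cum_ae_total"]] <<- s[["cum_ae_total"]] + sum(ae)
    nm <- sprintf("cum_ae_%02d", which(ae == 1))
    if (length(nm)) s[nm] <<- s[nm] + 1
    if (!is.null(row[["comorbidity_index"]]) &&
        !is.na(row[["comorbidity_index"]])) {
      s[["comorbidity_latest"]] <<- row[["comorbidity_index"]]
    }
    if (sum(tx) > 0) {
      last_tx <<- row[["month"]]
      s[["ever_treated"]] <<- 1
    }
  }
  th <- th[order(th$month), , drop = FALSE]
  surv <- numeric(n_months)
  # month loop: ingest visits up to and including month t before the hazard
  vi <- 1L
  cum <- 1
  for (t in seq_len(n_months)) {
    while (vi <= nrow(th) && th$month[vi] <= t) {
      ingest(as.list(th[vi, ]))
      vi <- vi + 1L
    }
    s[["months_since_dx"]] <- t
    s[["months_since_tx"]] <- if (is.na(last_tx)) t else t - last_tx
    h <- plogis(base_logit + lp_fixed + tv_linpred(config, s))
    cum <- cum * (1 - h)
    surv[t] <- cum
  }
  survival_curve(seq_len(n_months), surv)
}

#' Summarise a cohort
#'
#' Patient and visit-entry counts, age and baseline comorbidity moments
#' (mean, SD — the layout of a population-characteristics table), and the
#' observed event fraction. Baseline comorbidity is the index recorded at
#' each patient's first visit.
#'
#' @param cohort a `cohort`.
#' @return a list with `n_patients`, `n_entries`, `age_mean`, `age_sd`,
#'   `comorbidity_mean`, `comorbidity_sd`, `event_fraction`, and
#'   `means_defined` (FALSE for an empty cohort, in which case the moments
#'   are `NA`).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  v <- cohort$visits
  if (nrow(p) == 0L) {
    return(list(n_patients = 0L, n_entries = 0L, age_mean = NA_real_,
                age_sd = NA_real_, comorbidity_mean = NA_real_,
                comorbidity_sd = NA_real_, event_fraction = NA_real_,
                means_defined = FALSE))
  }
  first <- v[order(v$patient_id, v$month), ]
  first <- first[!duplicated(first$patient_id), ]
  cm <- first$comorbidity_index[match(p$patient_id, first$patient_id)]
  list(n_patients = nrow(p), n_entries = nrow(v),
       age_mean = mean(p$age), age_sd = sd(p$age),
       comorbidity_mean = mean(cm, na.rm = TRUE),
       comorbidity_sd = sd(cm, na.rm = TRUE),
       event_fraction = mean(p$event), means_defined = TRUE)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `patients.csv` and `visits.csv` (UTF-8, header
#' row, no missing values) into a directory; `read_cohort()` reads them
#' back. The generator configuration is not serialised.
#'
#' @param cohort a `cohort`.
#' @param dir directory path (created if needed).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param horizon_months study-window length for the reconstructed grid.
#' @export
read_cohort <- function(dir, horizon_months = 300) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  new_cohort(patients, visits, time_grid(horizon_months))
}
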