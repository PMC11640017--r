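#' Patient-level k-fold cross-validation of a survival network
#'
#' Partitions patients (never landmark rows) into `k` folds; for each
#' fold, standardisation is fitted on the training patients' rows only,
#' the model is trained on them, and the time-dependent concordance and
#' integrated Brier score are computed on the held-out patients.
#' Held-out extended-mode patients are represented by one landmark row
#' each (`eval_landmark = "first"` by default, so the prediction uses the
#' history available at the earliest visit and the full residual
#' follow-up; `"last"` and `"all"` are available). Deterministic given
#' `seed`: per-fold model seeds are fanned out with [derive_seed()].
#'
#' @param cohort a `cohort` (cleaned internally; cleaning is idempotent).
#' @param mode `"extended"` or `"fixed_only"` (see [encode_dataset()]).
#' @param family model family (see [hazard_model_config()]).
#' @param config a [hazard_model_config()]; its seed is replaced per fold.
#' @param k number of folds (>= 2).
#' @param seed master seed for fold assignment and per-fold training.
#' @param eval_landmark which landmark row represents a held-out patient.
#' @param landmark_policy passed to [encode_dataset()].
#' @return list with `folds` (per-fold `ctd`, `ibs`, `n_test`), `report`
#'   (a [summarize_folds()] report), and `assignments` (patient -> fold).
#' @export
crossvalidate <- function(cohort, mode, family, config, k = 5, seed = 1,
                          eval_landmark = c("first", "last", "all"),
                          landmark_policy = "per_visit") {
  stopifnot(k >= 2)
  eval_landmark <- match.arg(eval_landmark)
  cohort <- clean_records(cohort)
  pats <- cohort$patients$patient_id
  fold_of <- with_seed(derive_seed(seed, 1L),
                       sample(rep(seq_len(k), length.out = length(pats))))
  names(fold_of) <- pats
  ds <- encode_dataset(cohort, mode = mode,
                       landmark_policy = landmark_policy,
                       standardize = FALSE)
  folds <- list()
  for (f in seq_len(k)) {
    train_rows <- which(fold_of[ds$patient_id] != f)
    test_rows <- which(fold_of[ds$patient_id] == f)
    if (sum(ds$events[train_rows]) == 0 || sum(ds$events[test_rows]) == 0) {
      warning("fold ", f, " has no events; skipped")
      next
    }
    ds_std <- standardize_dataset(ds, train_rows)
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + f)
    model <- fit(subset_dataset(ds_std, train_rows), cfg)
    test <- subset_dataset(ds_std, test_rows)
    if (mode == "extended" && eval_landmark != "all") {
      test <- subset_dataset(test, landmark_row_per_patient(test, eval_landmark))
    }
    curves <- predict_survival(model, test$features, standardized = TRUE)
    S <- curves_to_matrix(curves)
    ct <- ctd_index(S, test$durations, test$events, times = model$cuts)
    ib <- integrated_brier_score(S, test$durations, test$events,
                                 times = model$cuts)
    folds[[length(folds) + 1L]] <- list(ctd = ct$ctd, ibs = ib,
                                        n_test = length(test$durations),
                                        fold = f)
  }
  if (!length(folds)) stop("all folds were skipped", call. = FALSE)
  list(folds = folds, report = summarize_folds(folds),
       assignments = fold_of)
}

#' The published hyperparameter search space
#'
#' Categorical sets for batch size, epochs, dropout, node count, alpha and
#' sigma; an integer range for the number of layers; a continuous
#' (log-uniform) range for the learning rate.
#'
#' @return a named list of domains.
#' @export
default_search_space <- function() {
  list(batch_size = c(32, 64, 128, 256, 512),
       epochs = c(100, 200, 300, 500),
       dropout = c(0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
       n_layers = c(2, 5),
       n_nodes = c(32, 64, 128, 256, 512),
       alpha = c(0.0, 0.001, 0.1, 0.2, 0.5, 0.8, 0.9, 0.99, 1.0),
       sigma = c(0.01, 0.1, 0.25, 0.5, 1.0, 10, 100),
       learning_rate = c(0.0001, 0.1))
}

#' Sample a configuration from a search space
#'
#' Categorical domains are sampled uniformly, the layer count uniformly on
#' its integer range, and the learning rate log-uniformly.
#'
#' @param space a search space as from [default_search_space()].
#' @param family model family.
#' @param seed integer seed.
#' @param overrides named list of fields forced after sampling (e.g. a
#'   desk-scale epoch count); overridden fields bypass the strict
#'   range check.
#' @return a [hazard_model_config()].
#' @export
sample_config <- function(space, family, seed, overrides = list()) {
  if (!length(space)) stop("empty search space", call. = FALSE)
  with_seed(seed, {
    pick <- function(v) v[sample.int(length(v), 1L)]
    args <- list(
      family = family,
      batch_size = pick(space$batch_size),
      epochs = pick(space$epochs),
      dropout = pick(space$dropout),
      n_layers = sample(seq(space$n_layers[1], space$n_layers[2]), 1L),
      n_nodes = pick(space$n_nodes),
      alpha = pick(space$alpha),
      sigma = pick(space$sigma),
      learning_rate = exp(runif(1, log(space$learning_rate[1]),
                                log(space$learning_rate[2]))),
      strict = length(overrides) == 0L)
    args[names(overrides)] <- overrides
    do.call(hazard_model_config, args)
  })
}

#' Hyperparameter search by cross-validated concordance
#'
#' Evaluates `budget` configurations by the cross-validated mean
#' time-dependent concordance and returns the best one together with the
#' full configuration-to-concordance trace. `scheme = "random"` samples
#' the space independently; `scheme = "model_based"` is a simple
#' sequential surrogate: after a random warm-up phase, sampling is
#' restricted to the hyperparameter values seen in the top quartile of the
#' trace so far (the learning-rate range shrinks to the top-quartile
#' span). Ties are broken by first occurrence.
#'
#' @param cohort a `cohort`.
#' @param family model family.
#' @param space search space (see [default_search_space()]).
#' @param budget number of configurations to evaluate (>= 1).
#' @param scheme `"random"` or `"model_based"`.
#' @param seed master seed.
#' @param k folds passed to [crossvalidate()].
#' @param mode covariate mode passed to [crossvalidate()].
#' @param overrides named list forced into every sampled configuration.
#' @return list with `best_config`, `best_ctd`, and `trace` (data frame of
#'   hyperparameters and mean concordance per evaluation).
#' @export
tune <- function(cohort, family, space = default_search_space(), budget = 10,
                 scheme = c("random", "model_based"), seed = 1, k = 5,
                 mode = "extended", overrides = list()) {
  scheme <- match.arg(scheme)
  stopifnot(budget >= 1)
  if (!length(space)) stop("empty search space", call. = FALSE)
  warmup <- if (scheme == "random") budget else min(budget, max(3L, ceiling(budget / 3)))
  trace <- NULL
  configs <- list()
  cur_space <- space
  for (b in seq_len(budget)) {
    if (scheme == "model_based" && b > warmup) {
      top <- trace[order(-trace$ctd), , drop = FALSE]
      top <- top[seq_len(max(1L, ceiling(nrow(top) / 4))), , drop = FALSE]
      cur_space <- space
      for (hp in c("batch_size", "epochs", "dropout", "n_nodes", "alpha",
                   "sigma")) {
        vals <- unique(top[[hp]])
        if (length(vals)) cur_space[[hp]] <- vals
      }
      cur_space$n_layers <- range(top$n_layers)
      cur_space$learning_rate <- range(top$learning_rate)
      if (diff(cur_space$learning_rate) == 0) {
        cur_space$learning_rate <- cur_space$learning_rate * c(0.5, 2)
      }
    }
    cfg <- sample_config(cur_space, family, derive_seed(seed, 200L + b),
                         overrides = overrides)
    cv <- crossvalidate(cohort, mode = mode, family = family, config = cfg,
                        k = k, seed = derive_seed(seed, 300L + b))
    row <- data.frame(eval = b, batch_size = cfg$batch_size,
                      epochs = cfg$epochs, dropout = cfg$dropout,
                      n_layers = cfg$n_layers, n_nodes = cfg$n_nodes,
                      alpha = cfg$alpha, sigma = cfg$sigma,
                      learning_rate = cfg$learning_rate,
                      ctd = cv$report$ctd_mean, ibs = cv$report$ibs_mean)
    trace <- rbind(trace, row)
    configs[[b]] <- cfg
  }
  best <- which.max(trace$ctd)  # first max wins on ties
  list(best_config = configs[[best]], best_ctd = trace$ctd[best],
       trace = trace)
}

#' Compare time-fixed against extended covariate sets
#'
#' Runs patient-level cross-validation for each requested family under
#' both covariate modes and tabulates fold-wise mean +/- SD of the
#' time-dependent concordance and integrated Brier score. A family whose
#' run fails is flagged in the table; the others are still returned.
#'
#' @param cohort a `cohort`.
#' @param families character vector of model families.
#' @param config_per_family named list of [hazard_model_config()] (one per
#'   family), or a single config reused for all.
#' @param k folds.
#' @param seed master seed.
#' @param eval_landmark see [crossvalidate()].
#' @return a `comparison_table` data frame: one row per family with
#'   `ctd_fixed`, `ctd_extended`, `ibs_fixed`, `ibs_extended` mean/SD
#'   columns, per-fold gap SD, fold count, and an `ok`/`error` flag pair.
#' @export
compare_covariate_sets <- function(cohort, families, config_per_family,
                                   k = 5, seed = 1,
                                   eval_landmark = "first") {
  if (inherits(config_per_family, "hazard_model_config")) {
    config_per_family <- stats::setNames(
      rep(list(config_per_family), length(families)), families)
  }
  rows <- list()
  details <- list()
  for (fam in families) {
    cfg <- config_per_family[[fam]]
    cfg$family <- fam
    res <- tryCatch({
      cv_f <- crossvalidate(cohort, mode = "fixed_only", family = fam,
                            config = cfg, k = k,
                            seed = derive_seed(seed, 7L),
                            eval_landmark = eval_landmark)
      cv_e <- crossvalidate(cohort, mode = "extended", family = fam,
                            config = cfg, k = k,
                            seed = derive_seed(seed, 7L),
                            eval_landmark = eval_landmark)
      gap <- vapply(cv_e$folds, `[[`, numeric(1), "ctd") -
        vapply(cv_f$folds, `[[`, numeric(1), "ctd")
      list(ok = TRUE, f = cv_f$report, e = cv_e$report, gap = gap,
           cv_fixed = cv_f, cv_extended = cv_e)
    }, error = function(err) list(ok = FALSE, msg = conditionMessage(err)))
    if (res$ok) {
      rows[[fam]] <- data.frame(
        family = fam,
        ctd_fixed_mean = res$f$ctd_mean, ctd_fixed_sd = res$f$ctd_sd,
        ctd_extended_mean = res$e$ctd_mean, ctd_extended_sd = res$e$ctd_sd,
        ibs_fixed_mean = res$f$ibs_mean, ibs_fixed_sd = res$f$ibs_sd,
        ibs_extended_mean = res$e$ibs_mean, ibs_extended_sd = res$e$ibs_sd,
        ctd_gap_mean = mean(res$gap), ctd_gap_sd = sd(res$gap),
        n_folds = res$f$n_folds, ok = TRUE, error = "",
        stringsAsFactors = FALSE)
      details[[fam]] <- res
    } else {
      rows[[fam]] <- data.frame(
        family = fam, ctd_fixed_mean = NA_real_, ctd_fixed_sd = NA_real_,
        ctd_extended_mean = NA_real_, ctd_extended_sd = NA_real_,
        ibs_fixed_mean = NA_real_, ibs_fixed_sd = NA_real_,
        ibs_extended_mean = NA_real_, ibs_extended_sd = NA_real_,
        ctd_gap_mean = NA_real_, ctd_gap_sd = NA_real_,
        n_folds = 0L, ok = FALSE, error = res$msg,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("comparison_table", "data.frame")
  attr(tab, "details") <- details
  tab
}

#' Per-patient survival curves and median survival
#'
#' Predicts each requested patient's survival curve from their covariates
#' — the extended vector at the latest recorded visit for extended-mode
#' models, or the fixed block alone — and reports the median survival
#' (first grid time with \eqn{S(t) \le 0.5}; flagged undefined when the
#' curve never crosses 0.5).
#'
#' @param model a fitted `hazard_model`.
#' @param cohort the `cohort` the patients live in.
#' @param patient_ids character vector of patient identifiers.
#' @return list with `curves` (named list of [survival_curve]) and
#'   `medians` (data frame: `patient_id`, `median_months`, `defined`).
#' @export
predict_patient_curves <- function(model, cohort, patient_ids) {
  stopifnot(inherits(model, "hazard_model"), inherits(cohort, "cohort"))
  missing_ids <- setdiff(patient_ids, cohort$patients$patient_id)
  if (length(missing_ids)) {
    stop("unknown patient id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  X <- matrix(NA_real_, length(patient_ids), length(model$feature_names),
              dimnames = list(patient_ids, model$feature_names))
  for (i in seq_along(patient_ids)) {
    id <- patient_ids[i]
    vis <- cohort$visits[cohort$visits$patient_id == id, , drop = FALSE]
    asof <- if (nrow(vis)) max(vis$month) else
      cohort$patients$diagnosis_month[match(id, cohort$patients$patient_id)]
    ext <- extend_covariates(cohort, id, asof)
    X[i, ] <- ext$values[model$feature_names]
  }
  curves <- predict_survival(model, X, standardized = FALSE)
  med <- lapply(curves, median_survival)
  list(curves = stats::setNames(curves, patient_ids),
       medians = data.frame(patient_id = patient_ids,
                            median_months = vapply(med, `[[`, numeric(1),
                                                   "median"),
                            defined = vapply(med, `[[`, logical(1),
                                             "defined"),
                            stringsAsFactors = FALSE))
}
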