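# build a model whose network ignores its input and emits fixed outputs,
# for exercising the prediction formulas in isolation
constant_output_model <- function(family, out, cuts, n_features = 2) {
  net <- hazardnet:::mlp_init(n_features, length(out), 1, 4, seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  net$b[[length(net$b)]] <- out
  structure(list(family = family, net = net, cuts = cuts,
                 t_scale = max(cuts),
                 feature_names = paste0("f", seq_len(n_features)),
                 standardization = NULL,
                 config = hazard_model_config(family),
                 training_log = data.frame()),
            class = "hazard_model")
}

test_that("predicted curves follow the discrete product/sum formulas", {
  # logistic hazard (0.1, 0.2) -> S = (0.9, 0.72)
  m <- constant_output_model("logistic_hazard", qlogis(c(0.1, 0.2)), 1:2)
  cu <- predict_survival(m, c(f1 = 0, f2 = 0))
  expect_equal(cu$surv, c(0.9, 0.72), tolerance = 1e-9)
  # hazards all ~0 -> S = 1
  m0 <- constant_output_model("logistic_hazard", c(-40, -40), 1:2)
  expect_equal(predict_survival(m0, c(f1 = 1, f2 = 2))$surv, c(1, 1),
               tolerance = 1e-9)
  # DeepHit PMF concentrated in the first interval -> S = 0 from t >= 1
  md <- constant_output_model("deephit", c(40, 0, 0, 0), 1:3)
  expect_equal(predict_survival(md, c(f1 = 0, f2 = 0))$surv, c(0, 0, 0),
               tolerance = 1e-9)
  # deepsurv with an empty baseline -> S = 1
  ms <- constant_output_model("deepsurv", 0.3, 1:4)
  ms$breslow <- list(times = numeric(0), cumhaz = numeric(0))
  expect_equal(predict_survival(ms, c(f1 = 0, f2 = 0))$surv, rep(1, 4))
  # deepsurv with a known baseline follows exp(-H0 e^g)
  ms$breslow <- list(times = c(1, 3), cumhaz = c(0.2, 0.5))
  expect_equal(predict_survival(ms, c(f1 = 0, f2 = 0))$surv,
               exp(-c(0.2, 0.2, 0.5, 0.5) * exp(0.3)), tolerance = 1e-9)
  # feature-space contract
  expect_error(predict_survival(m, c(a = 1)), "dimension mismatch")
  expect_error(predict_survival(m, c(a = 1, b = 2)), "feature names")
})

test_that("refitting with an identical seed reproduces the model exactly", {
  co <- small_cohort(n = 120, seed = 60)
  ds <- encode_dataset(clean_records(co), mode = "extended")
  cfg <- hazard_model_config("logistic_hazard", epochs = 5,
                             n_intervals = 10, seed = 42)
  m1 <- fit(ds, cfg)
  m2 <- fit(ds, cfg)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$training_log, m2$training_log)
  m3 <- fit(ds, hazard_model_config("logistic_hazard", epochs = 5,
                                    n_intervals = 10, seed = 43))
  expect_false(identical(m1$net$W, m3$net$W))
})

test_that("every family yields monotone curves in [0, 1] and learns signal", {
  co <- small_cohort(n = 150, seed = 61)
  cc <- clean_records(co)
  ds <- encode_dataset(cc, mode = "extended")
  first <- hazardnet:::landmark_row_per_patient(ds, "first")
  test_rows <- first[1:60]
  for (fam in c("deepsurv", "deephit", "logistic_hazard", "cox_time")) {
    m <- fit(ds, hazard_model_config(fam, epochs = 8, n_intervals = 12,
                                     seed = 9))
    curves <- predict_survival(m, ds$features[test_rows, , drop = FALSE],
                               standardized = TRUE)
    for (cu in curves) {
      expect_true(all(cu$surv >= 0 & cu$surv <= 1))
      expect_true(all(diff(cu$surv) <= 1e-9))
    }
    S <- do.call(rbind, lapply(curves, `[[`, "surv"))
    ct <- ctd_index(S, ds$durations[test_rows], ds$events[test_rows],
                    times = m$cuts)
    expect_gt(ct$ctd, 0.55)  # better than chance on training subjects
  }
})

test_that("pure-noise features give chance-level concordance", {
  set.seed(71)
  n <- 150
  co <- small_cohort(n = n, seed = 72)
  ds <- encode_dataset(clean_records(co), mode = "fixed_only",
                       standardize = FALSE)
  # replace every feature by noise, keep outcomes
  ds$features_raw[] <- rnorm(length(ds$features_raw))
  ds <- standardize_dataset(ds)
  m <- fit(ds, hazard_model_config("logistic_hazard", epochs = 10,
                                   n_intervals = 10, seed = 5,
                                   validation_fraction = 0))
  curves <- predict_survival(m, ds$features, standardized = TRUE)
  S <- do.call(rbind, lapply(curves, `[[`, "surv"))
  ct <- ctd_index(S, ds$durations, ds$events, times = m$cuts)
  expect_lt(abs(ct$ctd - 0.5), 0.1)
})

test_that("linear Cox fit recovers coefficient ratios from known generators", {
  # hazard driven by two fixed covariates with log-HRs 0.5 and -0.25:
  # a linear (single-layer equivalent) network score should recover the
  # 2:1 magnitude ratio within simulation tolerance
  co <- generate_cohort(generator_config(
    n_patients = 900, baseline_hazard_per_month = 0.03,
    coef_fixed = c(er_status = -0.5, her2_status = 0.25),
    coef_timevarying = numeric(0), seed = 88))
  ds <- encode_dataset(clean_records(co), mode = "fixed_only",
                       standardize = FALSE)
  # isolate the two informative features so the recovery target is clean
  keep <- c("er_status", "her2_status")
  ds$features_raw <- ds$features_raw[, keep]
  ds$features <- ds$features_raw
  ds$feature_names <- keep
  ds <- standardize_dataset(ds)
  m <- fit(ds, hazard_model_config("deepsurv", epochs = 60,
                                   n_intervals = 20, n_nodes = 8,
                                   dropout = 0.001, seed = 6))
  g <- drop(hazardnet:::mlp_forward(m$net, ds$features)$out)
  er <- ds$features_raw[, "er_status"]
  h2 <- ds$features_raw[, "her2_status"]
  # group contrasts of the fitted score estimate the log-hazard ratios
  # (true values -0.5 and +0.25) up to simulation noise
  er_contrast <- mean(g[er == 1 & h2 == 0]) - mean(g[er == 0 & h2 == 0])
  h2_contrast <- mean(g[er == 0 & h2 == 1]) - mean(g[er == 0 & h2 == 0])
  expect_lt(er_contrast, -0.25)
  expect_gt(er_contrast, -0.9)
  expect_gt(h2_contrast, 0.02)
  expect_lt(h2_contrast, 0.55)
  skip_if_not_installed("survival")
  # independent check that the generated data carry the intended effects
  cox <- survival::coxph(
    survival::Surv(ds$durations, ds$events) ~ er + her2,
    data = data.frame(er = ds$features_raw[, "er_status"],
                      her2 = ds$features_raw[, "her2_status"]))
  expect_lt(coef(cox)[["er"]], -0.15)
  expect_gt(coef(cox)[["er"]], -0.8)
  expect_gt(coef(cox)[["her2"]], 0.05)
  expect_lt(coef(cox)[["her2"]], 0.7)
})

test_that("model checkpoints round-trip through text files", {
  co <- small_cohort(n = 100, seed = 73)
  ds <- encode_dataset(clean_records(co), mode = "fixed_only")
  for (fam in c("deepsurv", "logistic_hazard")) {
    m <- fit(ds, hazard_model_config(fam, epochs = 4, n_intervals = 8,
                                     seed = 2))
    dir <- withr::local_tempdir()
    save_model(m, dir)
    m2 <- load_model(dir)
    cu1 <- predict_survival(m, ds$features[1:5, ], standardized = TRUE)
    cu2 <- predict_survival(m2, ds$features[1:5, ], standardized = TRUE)
    for (i in 1:5) expect_equal(cu1[[i]]$surv, cu2[[i]]$surv,
                                tolerance = 1e-9)
  }
})
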