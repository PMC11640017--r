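test_that("duplicate visit rows collapse to flag unions with the last comorbidity", {
  co <- toy_cohort()
  dup <- co$visits[co$visits$patient_id == "P1" & co$visits$month == 2, ]
  dup$treat_chemo <- 0L; dup$treat_bio <- 1L; dup$comorbidity_index <- 9
  co$visits <- rbind(co$visits, dup)
  cleaned <- clean_records(co)
  rep <- attr(cleaned, "removal_report")
  expect_equal(rep$duplicate_visits, 1)
  row <- cleaned$visits[cleaned$visits$patient_id == "P1" &
                          cleaned$visits$month == 2, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$treat_chemo, 1)   # union of flags
  expect_equal(row$treat_bio, 1)
  expect_equal(row$comorbidity_index, 9)  # last value in input order
})

test_that("cleaning is idempotent and drops exactly the hand-enumerated rows", {
  co <- toy_cohort()
  # five extra rows: 2 out-of-window visits, 1 visit of an invalid patient,
  # 1 exact duplicate, 1 valid new visit
  extra <- toy_visits(list(id = "P1", month = 9L),    # after P1's death at 8
                      list(id = "P2", month = 9L),    # before P2's diagnosis
                      list(id = "P4", month = 1L),    # P4 has bad duration
                      list(id = "P1", month = 0L),    # duplicate
                      list(id = "P3", month = 28L))   # valid
  co$visits <- rbind(co$visits, extra)
  co$patients <- rbind(co$patients, transform(co$patients[1, ],
                                              patient_id = "P4",
                                              duration_months = -2L))
  cleaned <- clean_records(co)
  rep <- attr(cleaned, "removal_report")
  expect_equal(rep$out_of_window_visits, 2)
  expect_equal(rep$invalid_patients, 1)
  expect_equal(rep$duplicate_visits, 1)
  expect_equal(nrow(cleaned$visits), nrow(toy_cohort()$visits) + 1)
  again <- clean_records(cleaned)
  expect_equal(again$visits, cleaned$visits)
  expect_equal(again$patients, cleaned$patients)
  expect_equal(attr(again, "removal_report"),
               list(duplicate_visits = 0L, out_of_window_visits = 0L,
                    invalid_patients = 0L))
})

test_that("bucketing follows the half-open convention and matches a linear scan", {
  b <- c(65, 70, 75, 80, 85)
  expect_equal(bucket_continuous(76, b), 3)   # [75, 80)
  expect_equal(bucket_continuous(80, b), 4)   # boundary goes right
  expect_equal(bucket_continuous(60, b), 0)
  expect_equal(bucket_continuous(99, b), 5)
  expect_error(bucket_continuous(1, numeric(0)), "non-empty")
  expect_error(bucket_continuous(1, c(2, 2, 3)), "strictly ascending")
  set.seed(42)
  x <- runif(1000, 50, 100)
  scan <- vapply(x, function(v) {
    i <- 0L
    for (k in seq_along(b)) if (v >= b[k]) i <- k else break
    i
  }, integer(1))
  expect_equal(bucket_continuous(x, b), scan)
})

test_that("shipped code maps have the published cardinalities", {
  maps <- default_code_maps()
  expect_equal(sort(unique(maps$ae_map$ae_category)), 1:18)
  expect_equal(nrow(maps$drug_map), 141)
  expect_equal(sum(maps$drug_map$drug_class == "chemotherapy"), 82)
  expect_equal(sum(maps$drug_map$drug_class == "biotherapy"), 49)
  expect_equal(sum(maps$drug_map$drug_class == "hormone"), 10)
  broken <- maps
  broken$drug_map <- maps$drug_map[-1, ]
  expect_error(validate_code_maps(broken), "141")
  broken2 <- maps
  broken2$ae_map <- maps$ae_map[maps$ae_map$ae_category != 7, ]
  expect_error(validate_code_maps(broken2), "categories")
})

test_that("history summaries accumulate by hand and never look ahead", {
  co <- toy_cohort()
  # P1: chemo at months 2 and 5, AE category 3 at month 5
  e6 <- extend_covariates(co, "P1", 6)
  expect_equal(unname(e6$values["cum_chemo"]), 2)
  expect_equal(unname(e6$values["cum_ae_03"]), 1)
  expect_equal(unname(e6$values["months_since_tx"]), 1)
  expect_equal(unname(e6$values["months_since_dx"]), 6)
  e4 <- extend_covariates(co, "P1", 4)
  expect_equal(unname(e4$values["cum_chemo"]), 1)
  expect_equal(unname(e4$values["cum_ae_03"]), 0)
  # patient with no visits at all: history block zeros / sentinels
  co2 <- co
  co2$visits <- co2$visits[co2$visits$patient_id != "P2", ]
  e0 <- extend_covariates(co2, "P2", 12)
  hist <- e0$values[e0$history_names]
  expect_equal(unname(hist["cum_chemo"]), 0)
  expect_equal(unname(hist["ever_treated"]), 0)
  expect_equal(unname(hist["months_since_tx"]), 2)  # = months since dx
  # fixed block is untouched by history
  expect_equal(e0$values[e0$fixed_names],
               extend_covariates(co, "P2", 10)$values[e0$fixed_names])
  expect_error(extend_covariates(co, "PX", 5), "unknown patient")
  expect_error(extend_covariates(co, "P2", 3), "precedes")
})

test_that("no-lookahead: perturbing later visits never changes the summary", {
  co <- toy_cohort()
  base <- extend_covariates(co, "P3", 22)$values
  co2 <- co
  late <- co2$visits$patient_id == "P3" & co2$visits$month > 22
  co2$visits$treat_chemo[late] <- 1L
  co2$visits$comorbidity_index[late] <- 50
  expect_identical(extend_covariates(co2, "P3", 22)$values, base)
})

test_that("encoding produces the enumerated landmark rows and matches extend_covariates", {
  co <- toy_cohort()
  dsf <- encode_dataset(co, mode = "fixed_only", standardize = FALSE)
  expect_equal(nrow(dsf$features), 3)
  expect_equal(colnames(dsf$features), hazardnet:::fixed_block_names())
  # landmarks strictly before end of follow-up: P1 3 visits, P2 1, P3 4
  dse <- encode_dataset(co, mode = "extended", standardize = FALSE)
  expect_equal(nrow(dse$features), 8)
  expect_equal(as.vector(table(dse$patient_id)[c("P1", "P2", "P3")]),
               c(3L, 1L, 4L))
  # residual durations at each landmark
  p1 <- dse$landmark_month[dse$patient_id == "P1"]
  expect_equal(dse$durations[dse$patient_id == "P1"], 8 - p1)
  # every encoded row equals the per-query covariate extension
  for (r in seq_len(nrow(dse$features))) {
    ext <- extend_covariates(co, dse$patient_id[r], dse$landmark_month[r])
    expect_equal(unname(dse$features[r, ]), unname(ext$values))
  }
  # last-visit policy keeps exactly one row per patient (the latest)
  dsl <- encode_dataset(co, mode = "extended", landmark_policy = "last_visit",
                        standardize = FALSE)
  expect_equal(nrow(dsl$features), 3)
  expect_equal(sort(dsl$landmark_month), c(5L, 10L, 26L))
})

test_that("first-landmark extended rows agree with fixed-only encoding on the fixed block", {
  co <- small_cohort(n = 60, seed = 7)
  dse <- encode_dataset(clean_records(co), mode = "extended",
                        standardize = FALSE)
  dsf <- encode_dataset(clean_records(co), mode = "fixed_only",
                        standardize = FALSE)
  first <- hazardnet:::landmark_row_per_patient(dse, "first")
  sub <- subset_dataset(dse, first)
  ord <- match(dsf$patient_id, sub$patient_id)
  expect_equal(sub$features[ord, dsf$fixed_names], dsf$features)
  expect_equal(sub$durations[ord], dsf$durations)
})

test_that("standardisation centres and scales on the requested rows only", {
  co <- small_cohort(n = 80, seed = 12)
  ds <- encode_dataset(clean_records(co), mode = "extended",
                       standardize = FALSE)
  fit_rows <- seq_len(floor(nrow(ds$features) / 2))
  ds2 <- standardize_dataset(ds, fit_rows)
  Xf <- ds2$features[fit_rows, ]
  mu <- colMeans(Xf)
  vv <- apply(Xf, 2, sd)
  nondeg <- ds2$standardization$scale != 1 |
    abs(ds2$standardization$center) > 1e-12
  expect_true(all(abs(mu[nondeg]) < 1e-10))
  expect_true(all(abs(vv[vv > 0] - 1) < 1e-10))
  expect_true(all(is.finite(ds2$features)))
})
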