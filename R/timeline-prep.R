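#' Monthly time grid
#'
#' Consecutive, left-closed monthly bins indexed from a labelled origin.
#'
#' @param n_intervals number of monthly intervals (>= 1).
#' @param origin_label label of time zero.
#' @return object of class `time_grid`.
#' @export
time_grid <- function(n_intervals, origin_label = "study start") {
  stopifnot(n_intervals >= 1)
  structure(list(origin_label = origin_label,
                 n_intervals = as.integer(n_intervals),
                 interval_unit = "month"),
            class = "time_grid")
}

#' Code maps for adverse-event and drug categorisation
#'
#' Loads the fixture tables mapping ICD-9 diagnosis codes to the 18
#' adverse-event categories and HCPCS J codes to the three treatment
#' classes (82 chemotherapy, 49 biotherapy, 10 hormone therapy; 141 codes
#' in total). The shipped tables are illustrative synthetic fixtures with
#' the correct cardinalities — the category structure, not the specific
#' code membership, is the contract — and can be replaced by editing the
#' CSVs.
#'
#' @param ae_file,drug_file optional paths overriding the shipped fixtures.
#' @return list with `ae_map` (columns `icd9_code`, `ae_category`, `label`)
#'   and `drug_map` (columns `hcpcs_code`, `drug_class`).
#' @export
default_code_maps <- function(ae_file = NULL, drug_file = NULL) {
  if (is.null(ae_file)) {
    ae_file <- system.file("extdata", "ae_map.csv", package = "hazardnet")
  }
  if (is.null(drug_file)) {
    drug_file <- system.file("extdata", "drug_map.csv", package = "hazardnet")
  }
  maps <- list(ae_map = utils::read.csv(ae_file, stringsAsFactors = FALSE),
               drug_map = utils::read.csv(drug_file, stringsAsFactors = FALSE))
  validate_code_maps(maps)
  maps
}

#' @rdname default_code_maps
#' @param maps a code-map list to validate.
#' @export
validate_code_maps <- function(maps) {
  cats <- sort(unique(maps$ae_map$ae_category))
  if (!identical(as.integer(cats), seq_len(n_ae_categories()))) {
    stop("ae_map must cover exactly the ", n_ae_categories(),
         " adverse-event categories", call. = FALSE)
  }
  if (anyDuplicated(maps$ae_map$icd9_code)) {
    stop("ae_map has duplicate ICD-9 codes", call. = FALSE)
  }
  tab <- table(maps$drug_map$drug_class)
  want <- c(biotherapy = 49L, chemotherapy = 82L, hormone = 10L)
  if (!identical(as.integer(tab[names(want)]), unname(want)) ||
      nrow(maps$drug_map) != 141L) {
    stop("drug_map must contain 141 codes: 82 chemotherapy, 49 biotherapy, ",
         "10 hormone", call. = FALSE)
  }
  if (anyDuplicated(maps$drug_map$hcpcs_code)) {
    stop("drug_map has duplicate HCPCS codes", call. = FALSE)
  }
  invisible(maps)
}

#' Clean a cohort's visit timeline
#'
#' Applies the record-level cleaning rules: duplicate `(patient_id, month)`
#' visit rows are collapsed (flag union; last comorbidity value in input
#' order), visits outside a patient's observation window
#' `[diagnosis, diagnosis + duration]` are dropped, and patients with
#' negative or missing durations are removed together with their visits.
#' Idempotent. A removal report is attached as attribute `removal_report`.
#'
#' @param cohort a `cohort`.
#' @return the cleaned `cohort` with attribute `removal_report` (counts of
#'   `duplicate_visits`, `out_of_window_visits`, `invalid_patients`).
#' @export
clean_records <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  v <- cohort$visits
  bad_pat <- is.na(p$duration_months) | p$duration_months < 0
  n_bad_pat <- sum(bad_pat)
  p <- p[!bad_pat, , drop = FALSE]
  v <- v[v$patient_id %in% p$patient_id, , drop = FALSE]

  n_oow <- 0L
  if (nrow(v)) {
    i <- match(v$patient_id, p$patient_id)
    lo <- p$diagnosis_month[i]
    hi <- p$diagnosis_month[i] + p$duration_months[i]
    keep <- !is.na(v$month) & v$month >= lo & v$month <= hi
    n_oow <- sum(!keep)
    v <- v[keep, , drop = FALSE]
  }

  n_dup <- 0L
  if (nrow(v)) {
    key <- paste(v$patient_id, v$month, sep = "\r")
    n_dup <- nrow(v) - length(unique(key))
    if (n_dup > 0L) {
      flag_cols <- c("treat_chemo", "treat_bio", "treat_hormone",
                     grep("^ae_\\d+$", names(v), value = TRUE))
      summed <- rowsum(as.matrix(v[flag_cols]), key)
      merged <- v[!duplicated(key, fromLast = TRUE), , drop = FALSE]
      mkey <- paste(merged$patient_id, merged$month, sep = "\r")
      merged[flag_cols] <- pmin(summed[mkey, , drop = FALSE], 1L)
      v <- merged
    }
  }
  v <- v[order(v$patient_id, v$month), , drop = FALSE]
  rownames(v) <- NULL
  out <- new_cohort(p, v, cohort$grid, cohort$config)
  attr(out, "removal_report") <- list(duplicate_visits = n_dup,
                                      out_of_window_visits = n_oow,
                                      invalid_patients = n_bad_pat)
  out
}

#' Assign continuous values to half-open buckets
#'
#' Returns, for each value, the index `i` such that the value falls in
#' `[b_i, b_{i+1})`; values below the first boundary map to 0 and values at
#' or above the last boundary map to the last bucket.
#'
#' @param value numeric vector.
#' @param boundaries strictly ascending numeric boundaries.
#' @return integer bucket indices.
#' @export
bucket_continuous <- function(value, boundaries) {
  if (!length(boundaries)) {
    stop("boundaries must be a non-empty ascending vector", call. = FALSE)
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly ascending", call. = FALSE)
  }
  findInterval(value, boundaries)
}

default_age_breaks <- function() c(65, 70, 75, 80, 85, 90)
default_comorbidity_breaks <- function() c(0, 1, 2, 3, 5, 8)

fixed_block_names <- function() {
  c("age_bucket", "race_code", "er_status", "pr_status", "her2_status",
    "grade", "histology_code")
}

history_block_names <- function() {
  c("cum_chemo", "cum_bio", "cum_hormone", "cum_tx_total",
    sprintf("cum_ae_%02d", seq_len(n_ae_categories())), "cum_ae_total",
    "comorbidity_bucket", "months_since_dx", "months_since_tx",
    "ever_treated")
}

fixed_block_row <- function(pat, age_breaks) {
  c(age_bucket = bucket_continuous(pat$age, age_breaks),
    race_code = pat$race_code, er_status = pat$er_status,
    pr_status = pat$pr_status, her2_status = pat$her2_status,
    grade = pat$grade, histology_code = pat$histology_code)
}

# History summaries for one patient at several landmark months (absolute).
# visits must be this patient's rows sorted by month. Vectorised over
# landmarks; used by both extend_covariates and encode_dataset.
history_block_matrix <- function(visits, landmarks, diagnosis_month,
                                 comorbidity_breaks) {
  K <- n_ae_categories()
  nm <- history_block_names()
  out <- matrix(0, length(landmarks), length(nm),
                dimnames = list(NULL, nm))
  vm <- visits$month
  # number of visits with month <= landmark (no lookahead)
  upto <- findInterval(landmarks, vm)
  flag_cols <- c("treat_chemo", "treat_bio", "treat_hormone",
                 sprintf("ae_%02d", seq_len(K)))
  if (nrow(visits)) {
    cs <- apply(as.matrix(visits[flag_cols]), 2, cumsum)
    cs <- rbind(0, cs)  # row r+1 = totals over first r visits
    tot <- cs[upto + 1L, , drop = FALSE]
    out[, "cum_chemo"] <- tot[, "treat_chemo"]
    out[, "cum_bio"] <- tot[, "treat_bio"]
    out[, "cum_hormone"] <- tot[, "treat_hormone"]
    out[, "cum_tx_total"] <- tot[, "treat_chemo"] + tot[, "treat_bio"] +
      tot[, "treat_hormone"]
    ae_tot <- tot[, sprintf("ae_%02d", seq_len(K)), drop = FALSE]
    out[, sprintf("cum_ae_%02d", seq_len(K))] <- ae_tot
    out[, "cum_ae_total"] <- rowSums(ae_tot)
    cm <- ifelse(upto >= 1L, visits$comorbidity_index[pmax(upto, 1L)], 0)
    out[, "comorbidity_bucket"] <- bucket_continuous(cm, comorbidity_breaks)
    any_tx <- visits$treat_chemo + visits$treat_bio + visits$treat_hormone > 0
    tx_months <- vm[any_tx]
    last_tx <- findInterval(landmarks, tx_months)
    msdx <- landmarks - diagnosis_month
    out[, "months_since_tx"] <- ifelse(last_tx >= 1L,
                                       landmarks - tx_months[pmax(last_tx, 1L)],
                                       msdx)
    out[, "ever_treated"] <- as.numeric(last_tx >= 1L)
    out[, "months_since_dx"] <- msdx
  } else {
    out[, "months_since_dx"] <- landmarks - diagnosis_month
    out[, "months_since_tx"] <- landmarks - diagnosis_month
  }
  out
}

#' Extend a patient's covariates with history summaries
#'
#' Fuses the time-fixed block (bucketed age and the other diagnosis-time
#' covariates) with a history block computed strictly from visits at or
#' before `as_of_month` (no lookahead): cumulative counts per treatment
#' class and per adverse-event category (plus their totals), the most
#' recent comorbidity index (bucketed), months since diagnosis, and months
#' since the last treatment. When no treatment (or no visit) has occurred
#' yet, months-since-treatment equals months-since-diagnosis and the
#' `ever_treated` indicator is 0.
#'
#' @param cohort a cleaned `cohort`.
#' @param patient_id patient identifier.
#' @param as_of_month absolute month on the study grid (>= the patient's
#'   diagnosis month).
#' @param age_breaks,comorbidity_breaks bucket boundaries
#'   (see [bucket_continuous()]).
#' @return object of class `extended_covariates`: named numeric `values`,
#'   the name partition (`fixed_names`, `history_names`), `as_of_month`,
#'   `patient_id`.
#' @export
extend_covariates <- function(cohort, patient_id, as_of_month,
                              age_breaks = default_age_breaks(),
                              comorbidity_breaks = default_comorbidity_breaks()) {
  stopifnot(inherits(cohort, "cohort"))
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient: ", patient_id, call. = FALSE)
  pat <- cohort$patients[i, ]
  if (as_of_month < pat$diagnosis_month) {
    stop("as_of_month precedes the diagnosis month", call. = FALSE)
  }
  vis <- cohort$visits[cohort$visits$patient_id == patient_id, , drop = FALSE]
  vis <- vis[order(vis$month), , drop = FALSE]
  hist <- history_block_matrix(vis, as_of_month, pat$diagnosis_month,
                               comorbidity_breaks)[1, ]
  fixed <- fixed_block_row(pat, age_breaks)
  structure(list(values = c(fixed, hist),
                 fixed_names = names(fixed),
                 history_names = names(hist),
                 as_of_month = as_of_month,
                 patient_id = patient_id),
            class = "extended_covariates")
}

#' Encode a cohort as a model-ready dataset
#'
#' Turns a cleaned cohort into a numeric feature matrix with aligned
#' durations (months) and event indicators.
#'
#' * `mode = "fixed_only"`: one row per patient carrying only the
#'   time-fixed block; the duration is the full observed follow-up.
#' * `mode = "extended"`: landmark rows carrying the extended covariate
#'   vector. Under the default `landmark_policy = "per_visit"` a row is
#'   created at every visit month strictly before the end of follow-up and
#'   the duration is re-expressed as residual time from the landmark
#'   (landmarks coinciding with the outcome month would have zero residual
#'   follow-up and are dropped); `"last_visit"` keeps only the latest such
#'   landmark per patient.
#'
#' Standardisation (zero mean, unit variance per feature) is fitted on the
#' rows indicated by `fit_rows` — training rows in a cross-validation
#' setting — and stored with the dataset; zero-variance features get unit
#' scale.
#'
#' @param cohort a cleaned `cohort`.
#' @param mode `"extended"` or `"fixed_only"`.
#' @param landmark_policy `"per_visit"` or `"last_visit"` (extended mode).
#' @param age_breaks,comorbidity_breaks bucket boundaries.
#' @param standardize logical.
#' @param fit_rows row indices on which to fit standardisation (default:
#'   all rows).
#' @return object of class `encoded_dataset`: `features` (standardised
#'   matrix), `features_raw`, `durations` (integer months >= 1), `events`
#'   (0/1), `patient_id` and `landmark_month` per row, `feature_names`,
#'   `fixed_names`, `history_names`, `grid`, `standardization` (per-feature
#'   center/scale or `NULL`).
#' @export
encode_dataset <- function(cohort,
                           mode = c("extended", "fixed_only"),
                           landmark_policy = c("per_visit", "last_visit"),
                           age_breaks = default_age_breaks(),
                           comorbidity_breaks = default_comorbidity_breaks(),
                           standardize = TRUE, fit_rows = NULL) {
  mode <- match.arg(mode)
  landmark_policy <- match.arg(landmark_policy)
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  if (nrow(p) == 0L) stop("cannot encode an empty cohort", call. = FALSE)

  fixed_mat <- t(vapply(seq_len(nrow(p)),
                        function(i) fixed_block_row(p[i, ], age_breaks),
                        numeric(length(fixed_block_names()))))
  colnames(fixed_mat) <- fixed_block_names()

  if (mode == "fixed_only") {
    features <- fixed_mat
    durations <- pmax(p$duration_months, 1L)
    events <- p$event
    pid <- p$patient_id
    landmark <- p$diagnosis_month
    history_names <- character(0)
  } else {
    v <- cohort$visits
    vsplit <- split(v[order(v$patient_id, v$month), , drop = FALSE],
                    factor(v$patient_id[order(v$patient_id, v$month)],
                           levels = p$patient_id))
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      vis <- vsplit[[p$patient_id[i]]]
      if (is.null(vis)) vis <- empty_visits_df()
      end_month <- p$diagnosis_month[i] + p$duration_months[i]
      lms <- unique(vis$month[vis$month < end_month])
      if (!length(lms)) next
      if (landmark_policy == "last_visit") lms <- max(lms)
      hist <- history_block_matrix(vis, lms, p$diagnosis_month[i],
                                   comorbidity_breaks)
      rows[[i]] <- list(
        features = cbind(matrix(fixed_mat[i, ], length(lms),
                                ncol(fixed_mat), byrow = TRUE,
                                dimnames = list(NULL, colnames(fixed_mat))),
                         hist),
        durations = end_month - lms,
        events = rep(p$event[i], length(lms)),
        pid = rep(p$patient_id[i], length(lms)),
        landmark = lms)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("no landmark rows could be formed", call. = FALSE)
    features <- do.call(rbind, lapply(rows, `[[`, "features"))
    durations <- unlist(lapply(rows, `[[`, "durations"), use.names = FALSE)
    events <- unlist(lapply(rows, `[[`, "events"), use.names = FALSE)
    pid <- unlist(lapply(rows, `[[`, "pid"), use.names = FALSE)
    landmark <- unlist(lapply(rows, `[[`, "landmark"), use.names = FALSE)
    history_names <- history_block_names()
  }
  stopifnot(all(is.finite(features)), all(durations >= 1),
            all(events %in% c(0, 1)))
  ds <- structure(list(
    features = features, features_raw = features,
    durations = as.integer(durations), events = as.integer(events),
    patient_id = pid, landmark_month = as.integer(landmark),
    feature_names = colnames(features),
    fixed_names = fixed_block_names(), history_names = history_names,
    grid = cohort$grid, mode = mode, standardization = NULL
  ), class = "encoded_dataset")
  if (standardize) ds <- standardize_dataset(ds, fit_rows) else ds
}

#' Standardise an encoded dataset
#'
#' Fits per-feature center/scale on `fit_rows` (training rows) and applies
#' them to all rows, storing the parameters in the dataset.
#'
#' @param dataset an `encoded_dataset`.
#' @param fit_rows indices of rows used to fit the parameters (default all).
#' @return the dataset with standardised `features` and a
#'   `standardization` data frame (`feature`, `center`, `scale`).
#' @export
standardize_dataset <- function(dataset, fit_rows = NULL) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  X <- dataset$features_raw
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  center <- colMeans(X[fit_rows, , drop = FALSE])
  scale <- apply(X[fit_rows, , drop = FALSE], 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  dataset$features <- sweep(sweep(X, 2, center), 2, scale, "/")
  dataset$standardization <- data.frame(feature = colnames(X),
                                        center = unname(center),
                                        scale = unname(scale),
                                        stringsAsFactors = FALSE)
  dataset
}

#' Subset an encoded dataset by rows
#'
#' @param dataset an `encoded_dataset`.
#' @param rows integer or logical row index.
#' @return the subsetted `encoded_dataset` (standardisation carried over).
#' @export
subset_dataset <- function(dataset, rows) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  for (f in c("durations", "events", "patient_id", "landmark_month")) {
    dataset[[f]] <- dataset[[f]][rows]
  }
  dataset$features <- dataset$features[rows, , drop = FALSE]
  dataset$features_raw <- dataset$features_raw[rows, , drop = FALSE]
  dataset
}

# One row index per patient: earliest or latest landmark.
landmark_row_per_patient <- function(dataset, which = c("first", "last")) {
  which <- match.arg(which)
  ord <- order(dataset$patient_id, dataset$landmark_month)
  if (which == "last") {
    keep <- !duplicated(dataset$patient_id[ord], fromLast = TRUE)
  } else {
    keep <- !duplicated(dataset$patient_id[ord])
  }
  sort(ord[keep])
}

#' Write / read an encoded dataset as delimited text with a JSON sidecar
#'
#' @param dataset an `encoded_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_encoded_dataset()` the directory, invisibly.
#' @export
write_encoded_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- data.frame(patient_id = dataset$patient_id,
                    landmark_month = dataset$landmark_month,
                    duration = dataset$durations, event = dataset$events,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(dataset$features))
  utils::write.csv(tab, file.path(dir, "encoded.csv"), row.names = FALSE)
  meta <- list(feature_names = dataset$feature_names,
               fixed_names = dataset$fixed_names,
               history_names = dataset$history_names,
               mode = dataset$mode,
               n_intervals = dataset$grid$n_intervals,
               standardization = dataset$standardization)
  jsonlite::write_json(meta, file.path(dir, "encoded_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
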