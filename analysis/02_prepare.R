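#!/usr/bin/env Rscript
# Step 2 — clean the timelines and encode model-ready datasets.
#
# Reads the simulated cohort, applies the cleaning rules (duplicate visit
# collapse, out-of-window removal), and writes two encoded datasets: the
# time-fixed representation (one row per patient) and the extended
# representation (per-visit landmark rows with residual durations).

suppressPackageStartupMessages(library(hazardnet))

cohort <- read_cohort(file.path("results", "cohort"))
cleaned <- clean_records(cohort)
rep <- attr(cleaned, "removal_report")
cat(sprintf("cleaning: %d duplicate visits, %d out-of-window visits, %d invalid patients\n",
            rep$duplicate_visits, rep$out_of_window_visits,
            rep$invalid_patients))

for (mode in c("fixed_only", "extended")) {
  ds <- encode_dataset(cleaned, mode = mode)
  out <- file.path("results", paste0("encoded_", mode))
  write_encoded_dataset(ds, out)
  cat(sprintf("%s: %d rows x %d features -> %s\n",
              mode, nrow(ds$features), ncol(ds$features), out))
}
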