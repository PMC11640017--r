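#!/usr/bin/env Rscript
# Step 4 — the central experiment: time-fixed vs extended covariates.
#
# Five-fold patient-level cross-validation of all four model families
# under both covariate representations. The expectation under the
# generator's conditions (history-driven hazard) is a clear concordance
# gain for the extended representation in every family. Writes the
# comparison table and a JSON report under results/.

suppressPackageStartupMessages(library(hazardnet))

seed <- 20620L
cohort <- read_cohort(file.path("results", "cohort"))
families <- c("deepsurv", "deephit", "logistic_hazard", "cox_time")
cfg <- hazard_model_config("deepsurv", epochs = 20, n_intervals = 25,
                           batch_size = 256, n_nodes = 32, n_layers = 2,
                           learning_rate = 0.01, dropout = 0.1, seed = 1)

tab <- compare_covariate_sets(cohort, families, cfg, k = 5, seed = seed)

fmt <- function(m, s) sprintf("%.3f +/- %.3f", m, s)
for (r in seq_len(nrow(tab))) {
  cat(sprintf("%-16s Ctd fixed %s | Ctd extended %s | IBS fixed %s | IBS extended %s\n",
              tab$family[r],
              fmt(tab$ctd_fixed_mean[r], tab$ctd_fixed_sd[r]),
              fmt(tab$ctd_extended_mean[r], tab$ctd_extended_sd[r]),
              fmt(tab$ibs_fixed_mean[r], tab$ibs_fixed_sd[r]),
              fmt(tab$ibs_extended_mean[r], tab$ibs_extended_sd[r])))
}
gain <- tab$ctd_gap_mean > 2 * sqrt(tab$ctd_fixed_sd^2 + tab$ctd_extended_sd^2)
cat("families with a concordance gain beyond fold noise:",
    sum(gain), "of", nrow(tab), "\n")

dir.create("results", showWarnings = FALSE)
utils::write.csv(as.data.frame(tab), file.path("results", "comparison_table.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(step = "compare", seed = seed, k = 5,
                          families = families,
                          table = as.data.frame(tab)),
                     file.path("results", "comparison_report.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/comparison_table.csv\n")
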