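#!/usr/bin/env Rscript
# Stage 1 — simulate the study-shaped cohorts.
#
# Generates per-sex synthetic cohorts from the shipped cluster
# specifications (seven profile centroids per sex with their condition
# prevalences and comorbidity rates) plus the full 620-row study-shaped
# database, and applies the eligibility filter (60+, complete tests).

library(somprofiles)

seed <- 1
dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)

db <- simulate_study_database(seed = seed, path = "results/cohorts/database_synthetic.csv")
elig <- apply_eligibility(db, min_age = 60)
write_cohort(elig, "results/cohorts/eligible.csv")
write.csv(exclusion_log(elig), "results/cohorts/exclusions.csv",
          row.names = FALSE)

message(sprintf("database: %d rows; eligible after the 60+/complete filter: %d",
                nrow(db), nrow(elig)))
message(sprintf("mean age %.1f y; women %.1f%%",
                mean(elig$age), 100 * mean(elig$sex == "woman")))

for (sex in c("woman", "man")) {
  sub <- elig[elig$sex == sex, ]
  write_cohort(sub, sprintf("results/cohorts/%s.csv", sex))
  message(sprintf("%-5s cohort: %d participants", sex, nrow(sub)))
}
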