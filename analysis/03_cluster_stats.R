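#!/usr/bin/env Rscript
# Stage 3 — descriptive sex comparison and the pairwise test cascade.
#
# Reproduces the two inferential surfaces: the women-vs-men descriptive
# table (KS-gated t/Mann-Whitney, chi-square for conditions) and, per sex,
# the cluster-pair comparison matrix for the six analysis variables
# (Shapiro-Wilk gate -> ANOVA/Tukey, Welch/Games-Howell or
# Kruskal-Wallis/Dunn).

library(somprofiles)

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

elig <- load_cohort("results/cohorts/eligible.csv")
sexes <- sex_comparison(elig)
write.csv(sexes, "results/stats/sex_comparison.csv", row.names = FALSE)
message("sex comparison (p < 0.05): ",
        paste(sexes$variable[sexes$p < 0.05], collapse = ", "))

for (sex in c("woman", "man")) {
  cohort <- load_cohort(sprintf("results/cohorts/%s.csv", sex))
  members <- read.csv(sprintf("results/som/%s_members.csv", sex))
  raw <- derive_ratios(cohort)
  stopifnot(identical(as.character(members$id), raw$id))
  cells <- pairwise_matrix(raw, members$cluster, alpha = 0.05)
  write.csv(cells, sprintf("results/stats/%s_comparisons.csv", sex),
            row.names = FALSE)
  writeLines(format_comparison_matrix(cells),
             sprintf("results/stats/%s_comparisons.txt", sex))
  message(sprintf("%s: %d of %d cluster-pair cells significant at 0.05",
                  sex, sum(cells$significant), nrow(cells)))
}
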