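#!/usr/bin/env Rscript
# Stage 2 — per-sex feature derivation, map training and profile clustering.
#
# For each sex: derive the six analysis variables, standardize within sex,
# train the hexagonal map (batch Kohonen, PCA-plane init), cut the codebook
# dendrogram at k = 7 and order the clusters by worsening profile.

library(somprofiles)

seed <- 1
dir.create("results/som", showWarnings = FALSE, recursive = TRUE)

for (sex in c("woman", "man")) {
  cohort <- load_cohort(sprintf("results/cohorts/%s.csv", sex))
  raw <- derive_ratios(cohort)
  fm <- standardize_features(raw)
  dims <- default_lattice_dims(nrow(fm$X), fm$X)
  message(sprintf("%s: n=%d -> %dx%d lattice", sex, nrow(fm$X),
                  dims[1], dims[2]))
  lat <- hex_lattice(dims[1], dims[2])
  tr <- som_train(init_codebook(lat, fm, "pca_plane", seed = seed), fm,
                  som_schedule())
  message(sprintf("  quantization error %.3f -> %.3f; topographic error %.3f",
                  tr$qe_trace[1], tail(tr$qe_trace, 1),
                  topographic_error(tr$codebook, fm)))

  bmu <- find_bmu(tr$codebook, fm)
  part <- cluster_codebook(tr$codebook, k = 7, linkage = "ward")
  part <- assign_members(part, bmu)
  part <- severity_order(part, tr$codebook, fm$worse_direction)
  message(sprintf("  cluster sizes (best -> worst): %s",
                  paste(part$sizes, collapse = " ")))

  prefix <- sprintf("results/som/%s_", sex)
  write_codebook(tr$codebook, paste0(prefix, "codebook.json"))
  write_scaling(fm, paste0(prefix, "scaling.json"))
  write_partition(part, ids = fm$ids,
                  members_path = paste0(prefix, "members.csv"),
                  units_path = paste0(prefix, "units.csv"))
  scan <- silhouette_scan(tr$codebook, ks = 2:10)
  write.csv(scan, paste0(prefix, "silhouette.csv"), row.names = FALSE)
  message(sprintf("  silhouette-preferred k (diagnostic only): %d",
                  scan$k[which.max(scan$mean_silhouette)]))
}
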