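#!/usr/bin/env Rscript
# Stage 5 — map renderings.
#
# Six component-plane heat maps per sex (direction-aware green-yellow-red
# scale, cluster contours overlaid) and the severity-colored cluster map
# with numerals at the cluster centroids.

library(somprofiles)

for (sex in c("woman", "man")) {
  cb <- read_codebook(sprintf("results/som/%s_codebook.json", sex))
  scaling <- read_scaling(sprintf("results/som/%s_scaling.json", sex))
  units <- read.csv(sprintf("results/som/%s_units.csv", sex))
  members <- read.csv(sprintf("results/som/%s_members.csv", sex))
  part <- structure(list(k = max(units$cluster),
                         unit_labels = units$cluster,
                         member_labels = members$cluster,
                         sizes = tabulate(members$cluster, max(units$cluster)),
                         lattice = cb$lattice),
                    class = "profile_partition")
  out <- sprintf("results/maps/%s", sex)
  render_heatmaps(cb, scaling = scaling, partition = part, out_dir = out)
  render_cluster_map(part, out = file.path(out, "cluster_map.png"))
  write.csv(unit_color_table(cb, scaling),
            file.path(out, "unit_colors.csv"), row.names = FALSE)
  message(sex, ": wrote 6 heat maps + cluster map under ", out)
}
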