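#' Hierarchically cluster the codebook units
#'
#' Agglomerative clustering of the unit weight vectors (Euclidean distance;
#' Ward by default, the usual choice for SOM codebooks), with the dendrogram
#' cut to exactly `k` groups. Labels at this stage are arbitrary; see
#' [severity_order()] for the ordered labeling.
#'
#' @param codebook A `som_codebook`.
#' @param k Number of clusters (1..number of units).
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return A `profile_partition`: list with `k`, `unit_labels`, `linkage`,
#'   `merge_heights`, and the `lattice`; member fields filled by
#'   [assign_members()].
#' @export
cluster_codebook <- function(codebook, k, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  m <- nrow(codebook$W)
  if (k < 1 || k > m) stop("k must be in 1..", m)
  hc <- stats::hclust(stats::dist(codebook$W),
                      method = switch(linkage, ward = "ward.D2",
                                      complete = "complete", average = "average"))
  structure(list(k = as.integer(k),
                 unit_labels = as.integer(stats::cutree(hc, k)),
                 member_labels = NULL, sizes = NULL, severity = NULL,
                 linkage = linkage, merge_heights = hc$height,
                 lattice = codebook$lattice),
            class = "profile_partition")
}

#' @export
print.profile_partition <- function(x, ...) {
  cat(sprintf("<profile_partition> k=%d (%s linkage)%s\n", x$k, x$linkage,
              if (is.null(x$member_labels)) ""
              else sprintf(", %d members", length(x$member_labels))))
  if (!is.null(x$sizes)) {
    cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  }
  invisible(x)
}

#' Assign participants to clusters via their best-matching units
#'
#' @param partition A `profile_partition`.
#' @param bmu Result of [find_bmu()] for the participants.
#' @return The partition with `member_labels` and per-cluster `sizes`.
#' @export
assign_members <- function(partition, bmu) {
  partition$member_labels <- partition$unit_labels[bmu$index]
  partition$sizes <- tabulate(partition$member_labels, partition$k)
  partition
}

#' Relabel clusters in order of worsening profile
#'
#' The severity of a cluster is the mean, over its member units and the six
#' variables, of `worse_direction(v) * w_uv` in standardized units; clusters
#' are relabeled 1..k by ascending severity, so label 1 is the best profile
#' and label k the worst. As severity is a composite, individual variables
#' may still be better in a higher-numbered cluster. Ties are broken by
#' assigning the lower label to the larger cluster.
#'
#' @param partition A `profile_partition` (members assigned or not).
#' @param codebook The clustered `som_codebook`.
#' @param direction Named worsening signs (default [worse_direction()]).
#' @return The partition relabeled, with `severity` (ascending over 1..k).
#' @export
severity_order <- function(partition, codebook, direction = worse_direction()) {
  W <- codebook$W
  dirv <- direction[colnames(W)]
  if (anyNA(dirv)) stop("direction must cover all codebook variables")
  unit_badness <- as.vector(W %*% dirv) / ncol(W)
  sev <- vapply(seq_len(partition$k), function(cl)
    mean(unit_badness[partition$unit_labels == cl]), numeric(1))
  sizes <- partition$sizes %||% tabulate(partition$unit_labels, partition$k)
  ord <- order(sev, -sizes)           # ascending severity; ties: larger first
  relabel <- integer(partition$k)
  relabel[ord] <- seq_len(partition$k)
  partition$unit_labels <- relabel[partition$unit_labels]
  if (!is.null(partition$member_labels)) {
    partition$member_labels <- relabel[partition$member_labels]
    partition$sizes <- tabulate(partition$member_labels, partition$k)
  }
  partition$severity <- sev[ord]
  partition
}

#' Which clusters touch on the lattice
#'
#' Two clusters are adjacent iff some unit of one lies at lattice distance 1
#' from some unit of the other. Clusters need not be lattice-contiguous
#' (weights are clustered, not positions); adjacency is reported, not
#' enforced.
#'
#' @param partition A `profile_partition`.
#' @param lattice Optional [hex_lattice()] (defaults to the partition's).
#' @return Symmetric logical k x k matrix with `FALSE` diagonal.
#' @export
cluster_adjacency <- function(partition, lattice = partition$lattice) {
  adj <- lattice_adjacency(lattice)
  k <- partition$k
  out <- matrix(FALSE, k, k)
  lab <- partition$unit_labels
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a < b) {
      out[a, b] <- out[b, a] <- any(adj[lab == a, lab == b, drop = FALSE])
    }
  }
  out
}

#' Silhouette diagnostic over a range of k
#'
#' Mean silhouette width of the codebook partition for each candidate k;
#' a diagnostic only — the headline analysis fixes k.
#'
#' @param codebook A `som_codebook`.
#' @param ks Candidate cluster counts.
#' @param linkage Linkage passed to [cluster_codebook()].
#' @return Data frame (k, mean_silhouette).
#' @export
silhouette_scan <- function(codebook, ks = 2:10, linkage = "ward") {
  d <- stats::dist(codebook$W)
  res <- vapply(ks, function(k) {
    part <- cluster_codebook(codebook, k, linkage)
    mean(cluster::silhouette(part$unit_labels, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}

#' Export a partition to CSV
#'
#' @param partition A `profile_partition` with members assigned.
#' @param ids Participant ids (same order as the BMU assignment).
#' @param members_path,units_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, a list of the written data frames.
#' @export
write_partition <- function(partition, ids = NULL,
                            members_path = NULL, units_path = NULL) {
  units <- data.frame(unit = seq_along(partition$unit_labels),
                      row = partition$lattice$row,
                      col = partition$lattice$col,
                      cluster = partition$unit_labels)
  out <- list(units = units)
  if (!is.null(units_path))
    utils::write.csv(units, units_path, row.names = FALSE)
  if (!is.null(partition$member_labels)) {
    members <- data.frame(id = ids %||% seq_along(partition$member_labels),
                          cluster = partition$member_labels)
    out$members <- members
    if (!is.null(members_path))
      utils::write.csv(members, members_path, row.names = FALSE)
  }
  invisible(out)
}
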