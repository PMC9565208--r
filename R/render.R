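#' Severity-aware chromatic scale
#'
#' Maps per-unit plane values to a green-yellow-red ramp: the best value of
#' a variable (low age/fat, high gait/height, grip/BMI, balance, LAM%) is
#' the green anchor, the worst the red anchor, intermediates pass through
#' yellow; normalization is min-max over the plane. `force_high_green`
#' ignores the worsening direction and always paints the highest value
#' green.
#'
#' @param values Per-unit plane values.
#' @param direction Worsening sign for the variable (+1 higher = worse).
#' @param force_high_green Direction-blind variant.
#' @return Character vector of hex colors (endpoints hit the anchors).
#' @export
profile_color_scale <- function(values, direction = 1, force_high_green = FALSE) {
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("constant plane; using the mid-scale color")
    badness <- rep(0.5, length(values))
  } else {
    badness <- (values - rng[1]) / diff(rng)
    if (force_high_green || direction < 0) badness <- 1 - badness
  }
  ramp <- grDevices::colorRamp(c("green", "yellow", "red"))
  grDevices::rgb(ramp(badness), maxColorValue = 255)
}

#' Fixed severity palette for the cluster map
#'
#' Cluster 1 (best) through 7 (worst): green, blue, purple, yellow, orange,
#' pink, red; additional clusters cycle a darkened copy of the base palette.
#'
#' @param k Number of clusters.
#' @return Character vector of k colors.
#' @export
severity_palette <- function(k) {
  base <- c("green", "blue", "purple", "yellow", "orange", "pink", "red")
  if (k <= length(base)) return(base[seq_len(k)])
  # documented extension: cycle the base palette darkened per cycle
  extra <- rep(base, length.out = k - length(base))
  c(base, vapply(seq_along(extra), function(i)
    grDevices::adjustcolor(extra[i], red.f = 0.6, green.f = 0.6, blue.f = 0.6),
    character(1)))
}

# pointy-top hexagon vertices with flat-to-flat width 1 (so adjacent units
# at plane distance 1 share an edge)
hex_vertices <- function(cx, cy, r = 1 / sqrt(3)) {
  ang <- pi / 180 * (60 * 0:5 + 30)
  data.frame(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

hex_sheet <- function(lattice, fill) {
  do.call(rbind, lapply(seq_len(lattice$n_units), function(u) {
    v <- hex_vertices(lattice$coords[u, 1], lattice$coords[u, 2])
    v$unit <- u
    v$fill <- fill[u]
    v
  }))
}

# boundary segments between lattice-adjacent units in different clusters
cluster_boundaries <- function(lattice, unit_labels, r = 1 / sqrt(3)) {
  adj <- lattice_adjacency(lattice)
  segs <- list()
  for (a in seq_len(lattice$n_units)) {
    nb <- which(adj[a, ] & seq_len(lattice$n_units) > a)
    for (b in nb[unit_labels[nb] != unit_labels[a]]) {
      va <- hex_vertices(lattice$coords[a, 1], lattice$coords[a, 2], r)
      d2b <- (va$x - lattice$coords[b, 1])^2 + (va$y - lattice$coords[b, 2])^2
      shared <- order(d2b)[1:2]          # the two corners nearest the neighbor
      segs[[length(segs) + 1]] <- data.frame(
        x = va$x[shared[1]], y = va$y[shared[1]],
        xend = va$x[shared[2]], yend = va$y[shared[2]])
    }
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

hexmap_plot <- function(sheet, title, boundaries = NULL, labels = NULL) {
  p <- ggplot2::ggplot(sheet) +
    ggplot2::geom_polygon(ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$unit, fill = .data$fill),
                          color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
  if (!is.null(boundaries))
    p <- p + ggplot2::geom_segment(
      data = boundaries,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linewidth = 1, color = "black")
  if (!is.null(labels))
    p <- p + ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 6, fontface = "bold")
  p
}

#' Per-unit color table for headless testing
#'
#' @param codebook A trained `som_codebook`.
#' @param scaling Optional scaling to report raw-unit values.
#' @param force_high_green See [profile_color_scale()].
#' @return Data frame (unit, row, col, variable, value, color).
#' @export
unit_color_table <- function(codebook, scaling = NULL, force_high_green = FALSE) {
  dirs <- worse_direction()
  out <- lapply(colnames(codebook$W), function(v) {
    pl <- component_plane(codebook, v, scaling)
    pl$variable <- v
    pl$color <- profile_color_scale(pl$value, dirs[[v]] %||% 1,
                                    force_high_green)
    pl
  })
  do.call(rbind, out)[, c("unit", "row", "col", "variable", "value", "color")]
}

#' Render one component-plane heat map per variable
#'
#' Hexagon-tiled maps, one per analysis variable, colored by
#' [profile_color_scale()]; cluster contours are overlaid when a partition
#' is supplied. Output is deterministic for fixed inputs.
#'
#' @param codebook Trained `som_codebook`.
#' @param scaling Optional `feature_matrix` scaling for raw-unit values.
#' @param partition Optional `profile_partition` for contour overlay.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` and/or `"svg"`.
#' @param force_high_green See [profile_color_scale()].
#' @param width,height,dpi Device geometry.
#' @return Invisibly, the written file paths.
#' @export
render_heatmaps <- function(codebook, scaling = NULL, partition = NULL,
                            out_dir = ".", format = "png",
                            force_high_green = FALSE,
                            width = 5, height = 5, dpi = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- unit_color_table(codebook, scaling, force_high_green)
  disp <- stats::setNames(analysis_variables(display = TRUE),
                          analysis_variables())
  bnd <- if (!is.null(partition))
    cluster_boundaries(codebook$lattice, partition$unit_labels) else NULL
  paths <- character(0)
  for (v in colnames(codebook$W)) {
    sub <- tab[tab$variable == v, ]
    sheet <- hex_sheet(codebook$lattice, sub$color[order(sub$unit)])
    p <- hexmap_plot(sheet, disp[v] %||% v, boundaries = bnd)
    for (fmt in format) {
      f <- file.path(out_dir, paste0("heatmap_", gsub("[^a-z_]", "", v), ".", fmt))
      ggplot2::ggsave(f, p, width = width, height = height, dpi = dpi)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Render the cluster map
#'
#' Hexagons filled by the fixed severity palette (cluster 1 green through
#' cluster 7 red; additional clusters cycle a darkened palette), with the
#' cluster numeral placed at each cluster's lattice centroid.
#'
#' @param partition A severity-ordered `profile_partition`.
#' @param lattice Optional lattice (defaults to the partition's).
#' @param out Output image path (extension selects the device).
#' @param width,height,dpi Device geometry.
#' @return Invisibly, `out`.
#' @export
render_cluster_map <- function(partition, lattice = partition$lattice,
                               out = "cluster_map.png",
                               width = 5, height = 5, dpi = 150) {
  if (length(partition$unit_labels) != lattice$n_units)
    stop("partition and lattice sizes differ")
  pal <- severity_palette(partition$k)
  fill <- pal[partition$unit_labels]
  sheet <- hex_sheet(lattice, fill)
  labels <- do.call(rbind, lapply(seq_len(partition$k), function(cl) {
    u <- which(partition$unit_labels == cl)
    if (!length(u)) return(NULL)
    ctr <- colMeans(lattice$coords[u, , drop = FALSE])
    at <- u[which.min((lattice$coords[u, 1] - ctr[1])^2 +
                        (lattice$coords[u, 2] - ctr[2])^2)]
    data.frame(x = lattice$coords[at, 1], y = lattice$coords[at, 2],
               label = cl)
  }))
  bnd <- cluster_boundaries(lattice, partition$unit_labels)
  p <- hexmap_plot(sheet, "Profile clusters", boundaries = bnd,
                   labels = labels)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}
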