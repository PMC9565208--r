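#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or `NULL` when generating.
#' @param synthetic A [synthetic_spec()], path to a spec YAML, or `NULL`.
#' @param sex Sex to analyze (`"woman"`/`"man"`); mandatory when `input`
#'   holds both sexes.
#' @param schema Optional column-name mapping for [load_cohort()].
#' @param min_age Eligibility age cutoff (years).
#' @param grid `c(n_rows, n_cols)` or `"auto"` for the `5*sqrt(n)`
#'   heuristic.
#' @param init Codebook initialization method.
#' @param schedule A [som_schedule()].
#' @param k Number of profile clusters.
#' @param linkage Codebook linkage.
#' @param alpha Significance level for the statistics stages.
#' @param reference Reference cluster for associations.
#' @param conditions Condition columns for the association stage.
#' @param outdir Output directory.
#' @param seed Master seed (propagated to generation/initialization).
#' @param render If `TRUE`, write the heat maps and cluster map.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, sex = NULL,
                            schema = NULL, min_age = 60, grid = "auto",
                            init = "pca_plane", schedule = som_schedule(),
                            k = 7, linkage = "ward", alpha = 0.05,
                            reference = 1,
                            conditions = c("CI", "ADLD", "FF", "educ_years",
                                           "PVD", "HTN"),
                            outdir = "som_run", seed = 1, render = TRUE) {
  if (is.null(input) && is.null(synthetic))
    stop("one of input or synthetic is required")
  if (!identical(grid, "auto")) {
    grid <- as.integer(grid)
    stopifnot(length(grid) == 2, all(grid >= 1))
    if (k > prod(grid)) stop("k exceeds the number of lattice units")
  }
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  structure(list(input = input, synthetic = synthetic, sex = sex,
                 schema = schema, min_age = min_age, grid = grid,
                 init = init, schedule = schedule, k = k, linkage = linkage,
                 alpha = alpha, reference = reference,
                 conditions = conditions, outdir = outdir, seed = seed,
                 render = render),
            class = "pipeline_config")
}

#' Run the full profiling pipeline
#'
#' load/generate -> eligibility -> ratio derivation and per-sex
#' standardization -> SOM training -> codebook clustering with severity
#' ordering -> pairwise comparison matrix -> association models -> map
#' renderings; every artifact is written under `config$outdir` together
#' with a manifest (config, seed, package version, per-file checksums).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object.
#' @export
run_profile_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  cohort <- stage("load", {
    if (!is.null(config$input)) {
      load_cohort(config$input, schema = config$schema)
    } else {
      spec <- config$synthetic
      if (is.character(spec))
        spec <- read_synthetic_spec(spec, seed = config$seed)
      gen <- generate_cohort(spec)
      truth <- gen$truth
      write_cohort(gen$cohort, file.path(out, "cohort.csv"))
      gen$cohort
    }
  })
  if (!is.null(config$sex)) {
    keep <- cohort$sex == config$sex
    truth <- truth[keep]
    cohort <- new_cohort_table(as.data.frame(cohort)[keep, , drop = FALSE],
                               attr(cohort, "provenance"))
  }

  elig <- stage("eligibility", apply_eligibility(cohort, config$min_age))
  utils::write.csv(exclusion_log(elig), file.path(out, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(truth) && nrow(elig) < nrow(cohort))
    truth <- truth[match(elig$id, cohort$id)]

  fm <- stage("features", {
    raw <- derive_ratios(elig)
    fm <- standardize_features(raw)
    utils::write.csv(cbind(id = fm$ids, as.data.frame(fm$X)),
                     file.path(out, "features.csv"), row.names = FALSE)
    write_scaling(fm, file.path(out, "scaling.json"))
    fm
  })

  som <- stage("som", {
    dims <- if (identical(config$grid, "auto"))
      default_lattice_dims(nrow(fm$X), fm$X) else config$grid
    if (config$k > prod(dims))
      stop("k = ", config$k, " exceeds ", prod(dims), " lattice units")
    lattice <- hex_lattice(dims[1], dims[2])
    W0 <- init_codebook(lattice, fm, method = config$init, seed = config$seed)
    tr <- som_train(W0, fm, config$schedule)
    write_codebook(tr$codebook, file.path(out, "codebook.json"))
    tr
  })

  part <- stage("clusters", {
    bmu <- find_bmu(som$codebook, fm)
    part <- cluster_codebook(som$codebook, config$k, config$linkage)
    part <- assign_members(part, bmu)
    part <- severity_order(part, som$codebook, fm$worse_direction)
    write_partition(part, ids = fm$ids,
                    members_path = file.path(out, "partition_members.csv"),
                    units_path = file.path(out, "partition_units.csv"))
    part
  })

  cells <- stage("stats", {
    raw <- derive_ratios(elig)
    cells <- pairwise_matrix(raw, part$member_labels, alpha = config$alpha)
    utils::write.csv(cells, file.path(out, "comparisons.csv"),
                     row.names = FALSE)
    writeLines(format_comparison_matrix(cells),
               file.path(out, "comparisons.txt"))
    cells
  })

  assoc <- stage("associations", {
    assoc <- association_table(part$member_labels, elig,
                               conditions = config$conditions,
                               alpha = config$alpha)
    utils::write.csv(assoc, file.path(out, "associations.csv"),
                     row.names = FALSE)
    writeLines(format_association_table(assoc),
               file.path(out, "associations.txt"))
    assoc
  })

  if (config$render) stage("render", {
    render_heatmaps(som$codebook, scaling = fm$scaling, partition = part,
                    out_dir = out)
    render_cluster_map(part, out = file.path(out, "cluster_map.png"))
    utils::write.csv(unit_color_table(som$codebook, fm$scaling),
                     file.path(out, "unit_colors.csv"), row.names = FALSE)
  })

  stage("manifest", {
    files <- setdiff(list.files(out), "manifest.json")
    manifest <- list(
      package = "somprofiles",
      version = as.character(utils::packageVersion("somprofiles")),
      seed = config$seed,
      config = config[c("sex", "min_age", "grid", "init", "k", "linkage",
                        "alpha", "reference", "min_age")],
      schedule = unclass(config$schedule),
      quantization_error = utils::tail(som$qe_trace, 1),
      checksums = as.list(tools::md5sum(file.path(out, files))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(cohort = cohort, eligible = elig, truth = truth,
                 features = fm, som = som, partition = part,
                 comparisons = cells, associations = assoc,
                 outdir = out))
}
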