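#' Analysis variable names
#'
#' The six variables defining a physical profile: age, gait speed over
#' height, grip strength over BMI, one-legged stance, lean appendicular
#' mass percentage, and fat percentage.
#'
#' @param display If `TRUE`, return field-standard display labels.
#' @return Character vector of length 6.
#' @export
analysis_variables <- function(display = FALSE) {
  if (display) c("Age", "Gait/Height", "Grip/BMI", "Balance", "LAM%", "Fat%")
  else c("age", "gait_height", "grip_bmi", "balance", "lam_pct", "fat_pct")
}

#' Per-variable direction of worsening
#'
#' +1 where larger values mean a worse profile (Age, Fat%), -1 where smaller
#' values are worse (Gait/Height, Grip/BMI, Balance, LAM%).
#'
#' @return Named numeric vector over [analysis_variables()].
#' @export
worse_direction <- function() {
  c(age = 1, gait_height = -1, grip_bmi = -1,
    balance = -1, lam_pct = -1, fat_pct = 1)
}

default_truncation <- function() {
  list(age = c(60, Inf), gait_height = c(0, Inf), grip_bmi = c(0, Inf),
       balance = c(0, BALANCE_CAP), lam_pct = c(0, 100), fat_pct = c(0, 100))
}

#' Define one synthetic profile cluster
#'
#' @param label Cluster label (unique within a spec).
#' @param n Nominal cluster size; mixture weights are `n / sum(n)`.
#' @param mean,sd Named vectors/lists over [analysis_variables()]: centroid
#'   and spread of the six profile variables (variables are sampled
#'   independently within a cluster).
#' @param prevalence Named probabilities for condition codes profiled in
#'   this cluster (Bernoulli per participant).
#' @param comorbid_rate Mean comorbidity count (Poisson).
#' @param educ Optional `list(mean=, sd=)` for years of education.
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(label, n, mean, sd, prevalence = list(),
                         comorbid_rate = NA_real_, educ = NULL) {
  vars <- analysis_variables()
  mean <- unlist(mean)[vars]; sd <- unlist(sd)[vars]
  if (anyNA(mean) || anyNA(sd))
    stop("cluster ", label, ": mean/sd must cover all six analysis variables")
  if (any(sd < 0)) stop("cluster ", label, ": negative sd")
  structure(list(label = label, n = n, mean = mean, sd = sd,
                 prevalence = unlist(prevalence), comorbid_rate = comorbid_rate,
                 educ = educ),
            class = "cluster_spec")
}

#' Define a synthetic cohort
#'
#' @param sex `"woman"` or `"man"`.
#' @param clusters List of [cluster_spec()]s.
#' @param n Cohort size (weights follow the clusters' nominal sizes).
#' @param seed Integer RNG seed.
#' @param height,bmi `list(mean=, sd=)` sex-level distributions used to
#'   back-derive raw gait speed and grip strength from the two ratios.
#' @param educ Sex-level education fallback for clusters without their own.
#' @param background_prevalence Named sex-level probabilities for condition
#'   codes not profiled per cluster.
#' @param truncation Named list of `c(lower, upper)` physical bounds applied
#'   by rejection sampling.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(sex, clusters, n = NULL, seed = 1,
                           height = list(mean = 1.6, sd = 0.07),
                           bmi = list(mean = 27.5, sd = 4.3),
                           educ = NULL, background_prevalence = list(),
                           truncation = default_truncation()) {
  stopifnot(sex %in% c("woman", "man"))
  labels <- vapply(clusters, `[[`, numeric(1), "label")
  if (anyDuplicated(labels)) stop("cluster labels must be unique")
  sizes <- vapply(clusters, `[[`, numeric(1), "n")
  w <- sizes / sum(sizes)
  if (abs(sum(w) - 1) > 1e-9) stop("cluster weights must sum to 1")
  if (is.null(n)) n <- sum(sizes)
  trunc <- utils::modifyList(default_truncation(), as.list(truncation))
  structure(list(sex = sex, clusters = clusters, weights = w, n = n,
                 seed = seed, height = height, bmi = bmi, educ = educ,
                 background_prevalence = unlist(background_prevalence),
                 truncation = trunc),
            class = "synthetic_spec")
}

#' Read a synthetic-cohort specification from YAML
#'
#' Shipped specifications transcribing the published per-sex cluster tables
#' are available via [study_spec()].
#'
#' @param path YAML file.
#' @param seed RNG seed stored on the spec.
#' @param n Cohort size override (default: sum of the nominal cluster sizes).
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path, seed = 1, n = NULL) {
  y <- yaml::read_yaml(path)
  clusters <- lapply(y$clusters, function(cl)
    cluster_spec(cl$label, cl$size, cl$mean, cl$sd,
                 prevalence = cl$prevalence %||% list(),
                 comorbid_rate = cl$comorbid_rate %||% NA_real_,
                 educ = cl$educ))
  synthetic_spec(sex = y$sex, clusters = clusters, n = n, seed = seed,
                 height = y$height, bmi = y$bmi, educ = y$educ,
                 background_prevalence = y$background_prevalence %||% list(),
                 truncation = lapply(y$truncation %||% list(), unlist))
}

#' @rdname read_synthetic_spec
#' @param sex Which shipped spec to load.
#' @export
study_spec <- function(sex = c("woman", "man"), seed = 1, n = NULL) {
  sex <- match.arg(sex)
  f <- if (sex == "woman") "women_clusters.yaml" else "men_clusters.yaml"
  read_synthetic_spec(system.file("extdata", f, package = "somprofiles",
                                  mustWork = TRUE), seed = seed, n = n)
}

# truncated-normal draws by rejection; sd 0 degenerates to the mean
rtruncnorm_rej <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate draw outside bounds")
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1
    if (guard > 10000) stop("rejection sampling failed: bounds too tight for (",
                            mean, ", ", sd, ")")
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws each participant's cluster by mixture weight (or with fixed
#' per-cluster sizes), samples the six profile variables from independent
#' truncated normals at the cluster centroid, conditions as Bernoulli at the
#' cluster (or background) prevalence, comorbidity counts as Poisson, and
#' back-derives raw gait speed and grip strength via sampled heights and
#' BMIs so the result passes the cohort schema. Truth labels are returned
#' alongside and never written into the cohort itself.
#'
#' @param spec A [synthetic_spec()].
#' @param method `"multinomial"` draws cluster sizes from the weights;
#'   `"fixed"` uses the nominal per-cluster sizes scaled to `n`.
#' @param id_prefix Prefix for participant ids.
#' @return `list(cohort = cohort_table, truth = integer cluster labels)`.
#' @export
generate_cohort <- function(spec, method = c("multinomial", "fixed"),
                            id_prefix = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(vapply(spec$clusters, function(cl) any(cl$sd < 0), TRUE)))
    stop("negative sd in cluster spec")
  if (abs(sum(spec$weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  vars <- analysis_variables()
  if (is.null(id_prefix)) id_prefix <- if (spec$sex == "woman") "W" else "M"

  if (n == 0) {
    empty <- as.data.frame(matrix(nrow = 0, ncol = length(cohort_schema())),
                           stringsAsFactors = FALSE)
    names(empty) <- cohort_schema()
    return(list(cohort = new_cohort_table(empty, "synthetic"),
                truth = integer(0)))
  }

  labels <- vapply(spec$clusters, `[[`, numeric(1), "label")
  if (method == "multinomial") {
    truth <- sample(labels, n, replace = TRUE, prob = spec$weights)
  } else {
    sizes <- round(spec$weights * n)
    while (sum(sizes) != n) {        # fix rounding drift on the largest cluster
      j <- which.max(sizes)
      sizes[j] <- sizes[j] + sign(n - sum(sizes))
    }
    truth <- rep(labels, times = sizes)
  }

  prof <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  conds <- matrix(NA_integer_, n, length(condition_codes()),
                  dimnames = list(NULL, condition_codes()))
  educ <- rep(NA_real_, n)
  ncom <- rep(NA_integer_, n)
  for (cl in spec$clusters) {
    idx <- which(truth == cl$label)
    if (!length(idx)) next
    for (v in vars) {
      b <- spec$truncation[[v]]
      prof[idx, v] <- rtruncnorm_rej(length(idx), cl$mean[[v]], cl$sd[[v]],
                                     b[1], b[2])
    }
    for (cc in condition_codes()) {
      p <- if (cc %in% names(cl$prevalence)) cl$prevalence[[cc]]
           else if (cc %in% names(spec$background_prevalence))
             spec$background_prevalence[[cc]]
           else NA_real_
      if (!is.na(p)) conds[idx, cc] <- stats::rbinom(length(idx), 1, p)
    }
    if (!is.na(cl$comorbid_rate))
      ncom[idx] <- stats::rpois(length(idx), cl$comorbid_rate)
    ed <- cl$educ %||% spec$educ
    if (!is.null(ed))
      educ[idx] <- rtruncnorm_rej(length(idx), ed$mean, ed$sd, 0, Inf)
  }

  height <- rtruncnorm_rej(n, spec$height$mean, spec$height$sd, 0.5, Inf)
  bmi <- rtruncnorm_rej(n, spec$bmi$mean, spec$bmi$sd, 10, Inf)
  df <- data.frame(id = sprintf("%s-%05d", id_prefix, seq_len(n)),
                   sex = spec$sex,
                   age = prof[, "age"],
                   gait_speed = prof[, "gait_height"] * height,
                   height = height,
                   grip_strength = prof[, "grip_bmi"] * bmi,
                   bmi = bmi,
                   balance = prof[, "balance"],
                   lam_pct = prof[, "lam_pct"],
                   fat_pct = prof[, "fat_pct"],
                   stringsAsFactors = FALSE)
  for (cc in condition_codes()) df[[cc]] <- conds[, cc]
  df$educ_years <- educ
  df$num_comorbid <- ncom
  df$complete_tests <- TRUE
  validate_cohort(df)
  list(cohort = new_cohort_table(df, provenance = "synthetic"),
       truth = as.integer(truth))
}

#' Simulate a full study-shaped database (synthetic stand-in)
#'
#' Builds a synthetic participant database with the shape of the deposited
#' study file: the per-sex cluster cohorts at their nominal sizes (412 women
#' + 150 men eligible), two additional participants who did not complete the
#' physical tests, and 56 participants younger than 60, for 620 rows in
#' total. Applying [apply_eligibility()] at 60 years therefore retains
#' exactly 562 records. All values are simulated from the shipped cluster
#' specifications; this is a synthetic stand-in, not the deposited data.
#'
#' @param seed Integer RNG seed.
#' @param path Optional CSV path to write the database to.
#' @return A `cohort_table` of 620 records (truth labels not included).
#' @export
simulate_study_database <- function(seed = 1, path = NULL) {
  women <- generate_cohort(study_spec("woman", seed = seed), method = "fixed")
  men <- generate_cohort(study_spec("man", seed = seed + 1), method = "fixed",
                         id_prefix = "M")
  df <- rbind(as.data.frame(women$cohort), as.data.frame(men$cohort))

  set.seed(seed + 2)
  # two 60+ participants who did not complete the physical tests
  inc <- as.data.frame(generate_cohort(
    study_spec("woman", seed = seed + 3, n = 2), method = "multinomial",
    id_prefix = "X")$cohort)
  inc$balance[1] <- NA; inc$lam_pct[2] <- NA
  inc$complete_tests <- FALSE
  # 56 participants below the age cutoff (roughly the cohort's sex ratio)
  set.seed(seed + 4)
  young <- as.data.frame(generate_cohort(
    study_spec("woman", seed = seed + 4, n = 41), method = "multinomial",
    id_prefix = "YW")$cohort)
  young_m <- as.data.frame(generate_cohort(
    study_spec("man", seed = seed + 5, n = 15), method = "multinomial",
    id_prefix = "YM")$cohort)
  young <- rbind(young, young_m)
  set.seed(seed + 6)
  young$age <- stats::runif(nrow(young), 50, 59.9)

  out <- rbind(df, inc, young)
  rownames(out) <- NULL
  out <- new_cohort_table(out, provenance = "synthetic study database")
  if (!is.null(path)) write_cohort(out, path)
  out
}
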