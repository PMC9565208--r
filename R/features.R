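#' Derive the six analysis variables from raw measurements
#'
#' Gait speed is divided by height (1/s) and grip strength by BMI (m^2) to
#' adjust the two performance measures for body size; age, one-legged
#' stance, lean appendicular mass % and fat % are carried through.
#'
#' @param cohort A `cohort_table` with non-missing, positive raw inputs.
#' @return Data frame with `id` plus the columns of [analysis_variables()].
#' @export
derive_ratios <- function(cohort) {
  df <- as.data.frame(cohort)
  for (v in c("height", "bmi")) {
    bad <- is.na(df[[v]]) | df[[v]] <= 0
    if (any(bad))
      stop("non-positive or missing ", v, " for id(s): ",
           paste(df$id[bad], collapse = ", "))
  }
  data.frame(id = df$id,
             age = df$age,
             gait_height = df$gait_speed / df$height,
             grip_bmi = df$grip_strength / df$bmi,
             balance = df$balance,
             lam_pct = df$lam_pct,
             fat_pct = df$fat_pct,
             stringsAsFactors = FALSE)
}

#' Standardize profile variables to z-scores
#'
#' Column-wise standardization (mean 0, sd 1; sample sd with n-1
#' denominator) computed on the supplied cohort itself, or with a
#' previously stored scaling (to project new individuals onto an existing
#' map). Standardization is done within one sex at a time, so each map's
#' inputs are centered for its own population.
#'
#' @param raw Data frame from [derive_ratios()] (id + six variables).
#' @param scaling Optional scaling (as stored on a `feature_matrix`) to
#'   apply instead of estimating from `raw`.
#' @return A `feature_matrix`: list with `ids`, matrix `X` (n x 6),
#'   `scaling` (`mean`, `sd` per variable) and `worse_direction`.
#' @export
standardize_features <- function(raw, scaling = NULL) {
  vars <- analysis_variables()
  stopifnot(all(vars %in% names(raw)))
  M <- as.matrix(raw[vars])
  if (anyNA(M)) stop("missing values in analysis variables; filter upstream")
  if (is.null(scaling)) {
    mu <- colMeans(M)
    sdev <- apply(M, 2, stats::sd)
    if (any(sdev <= 0))
      stop("degenerate (constant) column(s): ",
           paste(vars[sdev <= 0], collapse = ", "))
    scaling <- list(mean = mu, sd = sdev)
  }
  X <- sweep(sweep(M, 2, scaling$mean[vars]), 2, scaling$sd[vars], "/")
  structure(list(ids = raw$id, X = X, scaling = scaling,
                 worse_direction = worse_direction()),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d participants x %d standardized variables\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Invert standardization back to raw analysis units
#'
#' @param fm A `feature_matrix`.
#' @param X Optional matrix in standardized units (defaults to `fm$X`).
#' @return Data frame of the six variables in raw units (plus `id` when
#'   inverting the matrix's own rows).
#' @export
inverse_transform <- function(fm, X = NULL) {
  own <- is.null(X)
  if (own) X <- fm$X
  vars <- analysis_variables()
  raw <- sweep(sweep(X, 2, fm$scaling$sd[vars], "*"), 2, fm$scaling$mean[vars], "+")
  out <- as.data.frame(raw)
  names(out) <- vars
  if (own) out <- cbind(data.frame(id = fm$ids, stringsAsFactors = FALSE), out)
  out
}

#' Export / import scaling parameters
#'
#' @param fm A `feature_matrix`.
#' @param path JSON path.
#' @return `path` (write) or a scaling list (read).
#' @export
write_scaling <- function(fm, path) {
  jsonlite::write_json(lapply(fm$scaling, as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  s <- jsonlite::read_json(path)
  list(mean = unlist(s$mean), sd = unlist(s$sd))
}
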