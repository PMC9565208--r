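#' Hexagonal lattice geometry
#'
#' Offset-hexagonal layout: units are indexed row-major (1-based), odd rows
#' (second, fourth, ...) are shifted +0.5 in x and the row pitch is
#' sqrt(3)/2, so every nearest-neighbor pair sits at plane distance 1 and
#' each interior unit has exactly six neighbors.
#'
#' @param n_rows,n_cols Positive integers.
#' @return A `hex_lattice`: list with `n_rows`, `n_cols`, `n_units` and
#'   `coords` (n_units x 2 plane positions).
#' @export
hex_lattice <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  r <- rep(seq_len(n_rows) - 1, each = n_cols)
  cc <- rep(seq_len(n_cols) - 1, times = n_rows)
  coords <- cbind(x = cc + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 n_units = n_rows * n_cols, coords = coords,
                 row = r + 1L, col = cc + 1L),
            class = "hex_lattice")
}

#' @rdname hex_lattice
#' @param lattice A `hex_lattice`.
#' @export
lattice_distances <- function(lattice) {
  as.matrix(stats::dist(lattice$coords))
}

#' @rdname hex_lattice
#' @param tol Tolerance on the unit plane distance.
#' @export
lattice_adjacency <- function(lattice, tol = 1e-6) {
  D <- lattice_distances(lattice)
  abs(D - 1) < tol
}

#' Heuristic lattice dimensions
#'
#' Targets about `5 * sqrt(n)` units, with the rows:cols ratio following the
#' square root of the ratio of the first two eigenvalues of the data
#' covariance (longer side along the dominant principal axis).
#'
#' @param n Number of observations.
#' @param X Optional data matrix used for the eigenvalue ratio.
#' @return `c(n_rows, n_cols)`.
#' @export
default_lattice_dims <- function(n, X = NULL) {
  munits <- max(4, round(5 * sqrt(n)))
  ratio <- 1
  if (!is.null(X) && nrow(X) > 2) {
    ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    if (length(ev) >= 2 && ev[2] > 0) ratio <- sqrt(ev[1] / ev[2])
    ratio <- min(max(ratio, 1), 4)
  }
  rows <- max(2, round(sqrt(munits / ratio)))
  cols <- max(2, round(munits / rows))
  c(rows, cols)
}

new_codebook <- function(W, lattice) {
  stopifnot(nrow(W) == lattice$n_units, all(is.finite(W)))
  structure(list(W = W, lattice = lattice), class = "som_codebook")
}

#' @export
print.som_codebook <- function(x, ...) {
  cat(sprintf("<som_codebook> %d x %d hexagonal map, %d variables\n",
              x$lattice$n_rows, x$lattice$n_cols, ncol(x$W)))
  invisible(x)
}

#' Initialize a codebook
#'
#' `pca_plane` spans the first two principal axes of the data linearly
#' across the lattice (deterministic given `X`); `random_sample` draws unit
#' weights from data rows with a seeded RNG. A rank-deficient `X` (fewer
#' than two informative dimensions) falls back to `random_sample` with a
#' warning.
#'
#' @param lattice A [hex_lattice()].
#' @param X Feature matrix (rows = observations, standardized units) or a
#'   `feature_matrix`.
#' @param method `"pca_plane"` or `"random_sample"`.
#' @param seed RNG seed for `random_sample`.
#' @return A `som_codebook`.
#' @export
init_codebook <- function(lattice, X, method = c("pca_plane", "random_sample"),
                          seed = 1) {
  method <- match.arg(method)
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty data")
  if (method == "pca_plane") {
    if (nrow(X) < 2) {
      W <- matrix(rep(colMeans(X), each = lattice$n_units),
                  nrow = lattice$n_units,
                  dimnames = list(NULL, colnames(X)))
      return(new_codebook(W, lattice))
    }
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12 * pc$sdev[1]) {
      warning("rank-deficient data for pca_plane; falling back to random_sample")
      method <- "random_sample"
    } else {
      sc1 <- pc$x[, 1]; sc2 <- pc$x[, 2]
      # symmetric linear ramps across the lattice plane spanning the score
      # ranges (centered, so a degenerate lattice sits at the data mean);
      # the longer lattice side carries the first principal axis
      ramp <- function(z) {
        if (max(z) == 0) rep(0, length(z)) else 2 * z / max(z) - 1
      }
      u <- ramp(lattice$coords[, 1]); v <- ramp(lattice$coords[, 2])
      if (lattice$n_rows > lattice$n_cols) { tmp <- u; u <- v; v <- tmp }
      a1 <- u * max(abs(sc1))
      a2 <- v * max(abs(sc2))
      W <- matrix(rep(colMeans(X), each = lattice$n_units), lattice$n_units) +
        outer(a1, pc$rotation[, 1]) + outer(a2, pc$rotation[, 2])
      colnames(W) <- colnames(X)
      return(new_codebook(W, lattice))
    }
  }
  set.seed(seed)
  W <- X[sample.int(nrow(X), lattice$n_units, replace = TRUE), , drop = FALSE]
  rownames(W) <- NULL
  new_codebook(W, lattice)
}

#' Best-matching unit(s)
#'
#' For each query vector, the unit with minimal Euclidean distance to its
#' weight vector; ties are broken by the lowest unit index.
#'
#' @param codebook A `som_codebook`.
#' @param X Query matrix (rows) or a single vector, or a `feature_matrix`.
#' @return List with `index` (unit per query) and `dist` (Euclidean
#'   quantization distance per query).
#' @export
find_bmu <- function(codebook, X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!all(is.finite(X))) stop("non-finite query values")
  if (nrow(codebook$W) == 0) stop("empty codebook")
  X <- as.matrix(X)
  D2 <- cross_dist2(X, codebook$W)
  idx <- apply(D2, 1, which.min)          # which.min takes the lowest index on ties
  # recompute the winning distances directly: the quadratic form above is
  # accurate enough for the argmin but loses ~1e-8 absolute precision
  d <- sqrt(rowSums((X - codebook$W[idx, , drop = FALSE])^2))
  list(index = as.integer(idx), dist = d)
}

#' Training schedule
#'
#' @param mode `"batch"` (deterministic given the initial codebook) or
#'   `"online"` (classic per-sample Kohonen rule with seeded shuffling).
#' @param n_epochs Number of passes over the data.
#' @param sigma0,sigma_final Initial/final Gaussian neighborhood radius in
#'   lattice-distance units; `sigma0 = NULL` defaults to
#'   `max(n_rows, n_cols) / 2` at training time. Linear decay per epoch.
#' @param alpha0,alpha_final Learning rates (online mode only).
#' @param seed RNG seed (online shuffling).
#' @return A `som_schedule` list.
#' @export
som_schedule <- function(mode = c("batch", "online"), n_epochs = 50,
                         sigma0 = NULL, sigma_final = 1,
                         alpha0 = 0.5, alpha_final = 0.01, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_epochs >= 1, sigma_final > 0,
            alpha_final > 0, alpha_final <= alpha0, alpha0 <= 1)
  if (!is.null(sigma0)) stopifnot(sigma0 >= sigma_final)
  structure(list(mode = mode, n_epochs = n_epochs, sigma0 = sigma0,
                 sigma_final = sigma_final, alpha0 = alpha0,
                 alpha_final = alpha_final, seed = seed),
            class = "som_schedule")
}

lin_decay <- function(from, to, epoch, n_epochs) {
  if (n_epochs == 1) return(from)
  from + (epoch - 1) / (n_epochs - 1) * (to - from)
}

#' Train a self-organizing map
#'
#' Batch mode replaces every unit weight each epoch by the neighborhood-
#' weighted mean of the data, `w_u <- sum_i h(d(bmu_i, u), sigma) x_i /
#' sum_i h`, with the Gaussian kernel `h = exp(-d^2 / (2 sigma^2))` on plane
#' lattice distances and sigma decayed linearly per epoch. Online mode
#' applies the classic per-sample rule `w <- w + alpha h (x - w)` in
#' seeded-shuffled order. The per-epoch quantization error is traced.
#'
#' @param codebook Initial `som_codebook` (see [init_codebook()]).
#' @param X Data matrix or `feature_matrix`.
#' @param schedule A [som_schedule()].
#' @return List with the trained `codebook` and `qe_trace`.
#' @export
som_train <- function(codebook, X, schedule = som_schedule()) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty data")
  W <- codebook$W
  lattice <- codebook$lattice
  m <- nrow(W)
  Dlat2 <- lattice_distances(lattice)^2
  sigma0 <- schedule$sigma0 %||% (max(lattice$n_rows, lattice$n_cols) / 2)
  sigma0 <- max(sigma0, schedule$sigma_final)
  qe <- numeric(schedule$n_epochs)

  if (schedule$mode == "online" && !is.null(schedule$seed))
    set.seed(schedule$seed)

  for (e in seq_len(schedule$n_epochs)) {
    sigma <- lin_decay(sigma0, schedule$sigma_final, e, schedule$n_epochs)
    if (schedule$mode == "batch") {
      bmu <- find_bmu(new_codebook(W, lattice), X)$index
      H <- exp(-Dlat2 / (2 * sigma^2))
      S <- matrix(0, m, ncol(X))
      agg <- rowsum(X, bmu)
      S[as.integer(rownames(agg)), ] <- agg
      cnt <- tabulate(bmu, m)
      numer <- H %*% S
      denom <- as.vector(H %*% cnt)
      upd <- denom > 1e-300
      W[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
    } else {
      alpha <- lin_decay(schedule$alpha0, schedule$alpha_final, e,
                         schedule$n_epochs)
      for (i in sample.int(nrow(X))) {
        x <- X[i, ]
        d2 <- rowSums(sweep(W, 2, x)^2)
        b <- which.min(d2)
        h <- exp(-Dlat2[, b] / (2 * sigma^2))
        W <- W + alpha * h * sweep(-W, 2, x, "+")
      }
    }
    if (!all(is.finite(W)))
      stop("non-finite weights at epoch ", e, "; aborting training")
    qe[e] <- mean(find_bmu(new_codebook(W, lattice), X)$dist)
  }
  list(codebook = new_codebook(W, lattice), qe_trace = qe)
}

#' Map quality metrics
#'
#' Quantization error: mean Euclidean distance from each observation to its
#' best-matching unit. Topographic error: fraction of observations whose
#' best and second-best units are not lattice neighbors.
#'
#' @param codebook A `som_codebook`.
#' @param X Data matrix or `feature_matrix`.
#' @return Numeric scalar.
#' @export
quantization_error <- function(codebook, X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.null(dim(X)) || nrow(X) == 0) stop("empty data")
  mean(find_bmu(codebook, X)$dist)
}

#' @rdname quantization_error
#' @export
topographic_error <- function(codebook, X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty data")
  if (nrow(codebook$W) < 2) stop("topographic error needs at least 2 units")
  adj <- lattice_adjacency(codebook$lattice)
  D2 <- cross_dist2(X, codebook$W)
  err <- vapply(seq_len(nrow(X)), function(i) {
    o <- order(D2[i, ])[1:2]
    !adj[o[1], o[2]]
  }, TRUE)
  mean(err)
}

#' Component plane of one variable
#'
#' @param codebook A `som_codebook`.
#' @param variable Variable name or column index.
#' @param scaling Optional scaling (from a `feature_matrix`) to express the
#'   plane in raw units (`value * sd + mean`).
#' @return Data frame (unit, row, col, value).
#' @export
component_plane <- function(codebook, variable, scaling = NULL) {
  v <- codebook$W[, variable]
  if (!is.null(scaling)) {
    nm <- if (is.character(variable)) variable else colnames(codebook$W)[variable]
    v <- v * scaling$sd[[nm]] + scaling$mean[[nm]]
  }
  data.frame(unit = seq_len(codebook$lattice$n_units),
             row = codebook$lattice$row, col = codebook$lattice$col,
             value = as.numeric(v))
}

#' Serialize a codebook (with lattice) to JSON
#'
#' @param codebook A `som_codebook`.
#' @param path JSON file path.
#' @return `path` (write) / a `som_codebook` (read).
#' @export
write_codebook <- function(codebook, path) {
  obj <- list(n_rows = codebook$lattice$n_rows,
              n_cols = codebook$lattice$n_cols,
              variables = colnames(codebook$W),
              W = apply(codebook$W, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$W
  if (is.list(W)) W <- do.call(rbind, W)
  if (is.null(dim(W))) W <- matrix(W, nrow = obj$n_rows * obj$n_cols,
                                   byrow = TRUE)
  colnames(W) <- obj$variables
  new_codebook(W, hex_lattice(obj$n_rows, obj$n_cols))
}
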