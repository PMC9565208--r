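# fixtures are built in code; nothing is read from disk except the shipped
# YAML specifications

# minimal valid cohort data frame (one sex unless given)
make_cohort_df <- function(n, sex = "woman", seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = rep(sex, length.out = n),
    age = runif(n, 60, 85),
    gait_speed = runif(n, 0.5, 1.6),
    height = runif(n, 1.4, 1.8),
    grip_strength = runif(n, 10, 40),
    bmi = runif(n, 20, 35),
    balance = runif(n, 0, 45),
    lam_pct = runif(n, 18, 30),
    fat_pct = runif(n, 25, 50),
    HTN = rbinom(n, 1, 0.5),
    educ_years = runif(n, 0, 20),
    num_comorbid = rpois(n, 2),
    stringsAsFactors = FALSE
  )
}

# drop bookkeeping attributes so record content can be compared directly
strip_meta <- function(cohort) {
  df <- as.data.frame(cohort)
  attr(df, "provenance") <- NULL
  attr(df, "exclusions") <- NULL
  rownames(df) <- NULL
  df
}

as_cohort <- function(df, provenance = "fixture") {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  on.exit(unlink(path))
  somprofiles::load_cohort(path, provenance = provenance)
}

# two well-separated 6-D Gaussian blobs (centers 10 sd apart on axis 1)
two_blob_data <- function(n_per = 60, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 6, 0, 1), n_per),
             matrix(rnorm(n_per * 6, 0, 1), n_per))
  X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + 10
  colnames(X) <- somprofiles::analysis_variables()
  list(X = X, truth = rep(1:2, each = n_per))
}

# one Lloyd (k-means) assignment-update step for the sigma -> 0 oracle:
# each unit with members moves to its Voronoi-cell mean, others stay
lloyd_step <- function(W, X) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  cell <- apply(d2, 1, which.min)
  W2 <- W
  for (u in unique(cell)) W2[u, ] <- colMeans(X[cell == u, , drop = FALSE])
  W2
}

# exhaustive minimal within-SS 2-partition of <= 12 rows
best_two_partition <- function(W) {
  m <- nrow(W)
  stopifnot(m <= 12)
  ss <- function(rows) {
    if (length(rows) <= 1) return(0)
    sum(sweep(W[rows, , drop = FALSE], 2,
              colMeans(W[rows, , drop = FALSE]))^2)
  }
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^(m - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:m]
    cost <- ss(which(grp == 1)) + ss(which(grp == 0))
    if (cost < best_cost) { best_cost <- cost; best <- grp }
  }
  best + 1L
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1)) {
      q <- ifelse(p >= i, p + 1L, p)
      out[[length(out) + 1]] <- c(i, q)
    }
  }
  out
}

# best-permutation RMSE between estimated member centroids and the
# generator's centroids, both in standardized units
centroid_rmse <- function(fm, member_labels, spec) {
  vars <- somprofiles::analysis_variables()
  true_mu <- t(sapply(spec$clusters, function(cl) unlist(cl$mean)[vars]))
  true_z <- sweep(sweep(true_mu, 2, fm$scaling$mean[vars]), 2,
                  fm$scaling$sd[vars], "/")
  k <- nrow(true_z)
  est <- t(sapply(seq_len(k), function(cl) {
    rows <- member_labels == cl
    if (!any(rows)) return(rep(Inf, length(vars)))
    colMeans(fm$X[rows, , drop = FALSE])
  }))
  best <- Inf
  for (p in all_permutations(k)) {
    r <- sqrt(mean((est[p, ] - true_z)^2))
    if (r < best) best <- r
  }
  best
}

# closed-form mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sigma, lo, hi) {
  if (sigma == 0) return(mu)
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# table-parameterized women pipeline used by the recovery checks
run_recovery <- function(seed, n = 2000) {
  spec <- somprofiles::study_spec("woman", seed = seed, n = n)
  gen <- somprofiles::generate_cohort(spec)
  fm <- somprofiles::standardize_features(somprofiles::derive_ratios(gen$cohort))
  dims <- somprofiles::default_lattice_dims(nrow(fm$X), fm$X)
  lat <- somprofiles::hex_lattice(dims[1], dims[2])
  tr <- somprofiles::som_train(
    somprofiles::init_codebook(lat, fm, "pca_plane"), fm,
    somprofiles::som_schedule())
  part <- somprofiles::assign_members(
    somprofiles::cluster_codebook(tr$codebook, 7),
    somprofiles::find_bmu(tr$codebook, fm))
  list(spec = spec, gen = gen, fm = fm, part = part)
}
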