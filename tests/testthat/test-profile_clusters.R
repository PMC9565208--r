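make_codebook <- function(W, rows, cols) {
  structure(list(W = W, lattice = hex_lattice(rows, cols)),
            class = "som_codebook")
}

test_that("dendrogram cuts hit the degenerate and oracle cases", {
  set.seed(2)
  W <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, analysis_variables()))
  cb <- make_codebook(W, 2, 5)
  expect_equal(sort(unique(cluster_codebook(cb, 10)$unit_labels)), 1:10)
  expect_equal(unique(cluster_codebook(cb, 1)$unit_labels), 1L)
  expect_error(cluster_codebook(cb, 0), "k must be")
  expect_error(cluster_codebook(cb, 11), "k must be")

  # two tight, well-separated unit groups: the Ward cut equals the
  # exhaustive minimal within-SS 2-partition
  set.seed(5)
  W2 <- rbind(matrix(rnorm(5 * 6, 0, 0.1), 5),
              matrix(rnorm(5 * 6, 8, 0.1), 5))
  colnames(W2) <- analysis_variables()
  cb2 <- make_codebook(W2, 2, 5)
  got <- cluster_codebook(cb2, 2)$unit_labels
  oracle <- best_two_partition(W2)
  expect_equal(adjusted_rand_index(got, oracle), 1)
})

test_that("ward clustering is invariant to unit index order", {
  set.seed(9)
  W <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, analysis_variables()))
  cb <- make_codebook(W, 3, 4)
  lab <- cluster_codebook(cb, 3)$unit_labels
  perm <- sample(12)
  cbp <- make_codebook(W[perm, ], 3, 4)
  labp <- cluster_codebook(cbp, 3)$unit_labels
  expect_equal(adjusted_rand_index(lab, labp[order(perm)]), 1)
})

test_that("severity ordering formalizes 'worse profile, higher label'", {
  # cluster sitting at the data mean (all-zero weights) has severity 0
  W <- rbind(matrix(0, 3, 6), matrix(1, 3, 6))
  colnames(W) <- analysis_variables()
  cb <- make_codebook(W, 2, 3)
  part <- cluster_codebook(cb, 2)
  part <- severity_order(part, cb)
  expect_equal(part$severity[1], min(part$severity))
  expect_true(0 %in% part$severity)
  expect_equal(diff(part$severity) >= 0, rep(TRUE, part$k - 1))

  # printed women centroids, standardized with the sex-level summary
  # statistics: youngest/best centroid ranks 1, oldest/worst ranks 7
  spec <- study_spec("woman")
  vars <- analysis_variables()
  mu <- t(sapply(spec$clusters, function(cl) unlist(cl$mean)[vars]))
  sex_mean <- c(age = 71.0, gait_height = 0.657, grip_bmi = 0.583,
                balance = 25.4, lam_pct = 21.6, fat_pct = 42.3)
  sex_sd <- c(age = 7.1, gait_height = 0.165, grip_bmi = 0.215,
              balance = 19.3, lam_pct = 2.2, fat_pct = 5.0)
  Z <- sweep(sweep(mu, 2, sex_mean[vars]), 2, sex_sd[vars], "/")
  cbZ <- make_codebook(Z, 1, 7)
  pZ <- cluster_codebook(cbZ, 7)           # singletons
  pZ <- severity_order(pZ, cbZ)
  # unit i holds printed cluster i; check which centroid got rank 1 and 7
  expect_equal(which(pZ$unit_labels == 1), 1L)   # age 62.9, best profile
  expect_equal(which(pZ$unit_labels == 7), 7L)   # age 77.1, worst profile

  # ties broken by size: the larger cluster takes the lower label
  # both groups score severity 0 (age and fat offsets cancel)
  W3 <- rbind(matrix(0, 4, 6),
              matrix(c(1, 0, 0, 0, 0, -1), 2, 6, byrow = TRUE))
  colnames(W3) <- analysis_variables()
  cb3 <- make_codebook(W3, 2, 3)
  p3 <- severity_order(cluster_codebook(cb3, 2), cb3)
  expect_equal(sum(p3$unit_labels == 1), 4)
})

test_that("members inherit their hexagon's cluster", {
  blobs <- two_blob_data(40, seed = 3)
  lat <- hex_lattice(4, 5)
  tr <- som_train(init_codebook(lat, blobs$X, "random_sample", seed = 1),
                  blobs$X, som_schedule(n_epochs = 15))
  bmu <- find_bmu(tr$codebook, blobs$X)
  part <- assign_members(cluster_codebook(tr$codebook, 2), bmu)
  expect_equal(part$member_labels, part$unit_labels[bmu$index])
  expect_equal(sum(part$sizes), nrow(blobs$X))
  # permutation-invariant accuracy 1.0 on well-separated blobs
  expect_equal(adjusted_rand_index(part$member_labels, blobs$truth), 1)

  # severity relabeling is a bijection preserving label multisets
  before <- table(part$member_labels)
  part2 <- severity_order(part, tr$codebook)
  expect_setequal(as.numeric(table(part2$member_labels)), as.numeric(before))
})

test_that("cluster adjacency reflects shared lattice edges", {
  W <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(NULL, analysis_variables()))
  cb <- make_codebook(W, 1, 2)
  p1 <- cluster_codebook(cb, 1)
  expect_false(any(cluster_adjacency(p1)))
  p2 <- cluster_codebook(cb, 2)            # singleton clusters, units touch
  expect_true(cluster_adjacency(p2)[1, 2])

  set.seed(4)
  W4 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, analysis_variables()))
  cb4 <- make_codebook(W4, 4, 5)
  for (k in c(2, 4, 6)) {
    adjm <- cluster_adjacency(cluster_codebook(cb4, k))
    expect_identical(adjm, t(adjm))
    expect_false(any(diag(adjm)))
  }
})

test_that("adjusted Rand agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(6)
  for (rep in 1:10) {
    a <- sample(1:5, 60, replace = TRUE)
    b <- sample(1:4, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:3, 5), rep(1:3, 5)), 1)
})

test_that("silhouette scan covers the requested range", {
  set.seed(11)
  W <- rbind(matrix(rnorm(8 * 6, 0, .3), 8), matrix(rnorm(8 * 6, 5, .3), 8),
             matrix(rnorm(8 * 6, -5, .3), 8))
  colnames(W) <- analysis_variables()
  cb <- make_codebook(W, 4, 6)
  scan <- silhouette_scan(cb, ks = 2:6)
  expect_equal(scan$k, 2:6)
  expect_equal(scan$k[which.max(scan$mean_silhouette)], 3)
})
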