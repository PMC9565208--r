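test_that("hexagonal lattice geometry is regular", {
  for (dims in list(c(2, 2), c(3, 5), c(6, 4))) {
    lat <- hex_lattice(dims[1], dims[2])
    D <- lattice_distances(lat)
    diag(D) <- Inf
    expect_equal(min(D), 1, tolerance = 1e-9)
    nn <- rowSums(abs(D - 1) < 1e-9)
    expect_true(all(nn >= 2 & nn <= 6))
  }
  # interior units of a large-enough lattice have exactly six neighbors
  lat <- hex_lattice(5, 6)
  adj <- lattice_adjacency(lat)
  interior <- which(lat$row %in% 2:4 & lat$col %in% 2:5)
  expect_true(all(rowSums(adj[interior, ]) == 6))
})

test_that("codebook initialization is deterministic and spans the data plane", {
  X <- two_blob_data(40)$X
  lat <- hex_lattice(4, 5)
  a <- init_codebook(lat, X, "random_sample", seed = 7)
  b <- init_codebook(lat, X, "random_sample", seed = 7)
  expect_identical(a$W, b$W)

  # data exactly on a 2-plane: pca_plane units lie on that plane
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  scores <- matrix(rnorm(120), 60, 2)
  Xp <- scores %*% t(basis)
  colnames(Xp) <- analysis_variables()
  cb <- init_codebook(lat, Xp, "pca_plane")
  resid <- cb$W - cb$W %*% basis %*% t(basis)
  expect_lt(max(abs(resid)), 1e-9)

  one <- init_codebook(hex_lattice(1, 1), Xp, "pca_plane")
  expect_equal(unname(one$W[1, ]), unname(colMeans(Xp)), tolerance = 1e-12)

  # rank-deficient data falls back with a warning
  X1 <- outer(rnorm(30), c(1, 0, 0, 0, 0, 0))
  colnames(X1) <- analysis_variables()
  expect_warning(init_codebook(lat, X1, "pca_plane"), "rank-deficient")
})

test_that("best-matching-unit search matches an exhaustive oracle", {
  set.seed(3)
  W <- matrix(rnorm(20 * 6), 20, 6)
  cb <- structure(list(W = W, lattice = hex_lattice(4, 5)),
                  class = "som_codebook")
  expect_equal(find_bmu(cb, W[7, ])$index, 7L)

  # tie broken by the lowest unit index
  cb2 <- cb
  cb2$W[5, ] <- cb2$W[12, ]
  expect_equal(find_bmu(cb2, cb2$W[12, ])$index, 5L)

  Q <- matrix(rnorm(100 * 6), 100, 6)
  got <- find_bmu(cb, Q)$index
  oracle <- vapply(seq_len(100), function(i)
    which.min(vapply(1:20, function(u) sqrt(sum((Q[i, ] - W[u, ])^2)),
                     numeric(1))), integer(1))
  expect_equal(got, oracle)
})

test_that("batch training collapses to the constant point and stays convex", {
  lat <- hex_lattice(3, 3)
  p <- c(1, -2, 0.5, 3, -1, 2)
  X <- matrix(rep(p, each = 12), 12, dimnames = list(NULL, analysis_variables()))
  W0 <- init_codebook(lat, X, "random_sample", seed = 1)
  set.seed(2)
  W0$W <- matrix(rnorm(9 * 6), 9, 6)     # arbitrary start, h > 0 everywhere
  tr <- som_train(W0, X, som_schedule(n_epochs = 1, sigma0 = 2))
  expect_equal(tr$codebook$W, matrix(rep(p, each = 9), 9), tolerance = 1e-9,
               ignore_attr = TRUE)

  # convex-combination conservation: one batch epoch keeps every unit
  # inside the data bounding box
  Xr <- two_blob_data(50, seed = 2)$X
  W1 <- init_codebook(hex_lattice(4, 4), Xr, "random_sample", seed = 5)
  t1 <- som_train(W1, Xr, som_schedule(n_epochs = 1, sigma0 = 3))
  lo <- apply(Xr, 2, min); hi <- apply(Xr, 2, max)
  expect_true(all(sweep(t1$codebook$W, 2, lo, ">=")))
  expect_true(all(sweep(t1$codebook$W, 2, hi, "<=")))
})

test_that("a vanishing neighborhood reduces the batch step to Lloyd's", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, analysis_variables()))
  W0 <- init_codebook(hex_lattice(1, 5), X, "random_sample", seed = 2)
  tr <- som_train(W0, X, som_schedule(n_epochs = 1, sigma0 = 1e-3,
                                      sigma_final = 1e-3))
  expect_equal(tr$codebook$W, lloyd_step(W0$W, X), tolerance = 1e-9)
})

test_that("training is deterministic given schedule and seed", {
  X <- two_blob_data(40, seed = 4)$X
  W0 <- init_codebook(hex_lattice(4, 5), X, "random_sample", seed = 3)
  for (mode in c("batch", "online")) {
    s <- som_schedule(mode = mode, n_epochs = 5, seed = 11)
    a <- som_train(W0, X, s)
    b <- som_train(W0, X, s)
    expect_identical(a$codebook$W, b$codebook$W)
    expect_identical(a$qe_trace, b$qe_trace)
  }
})

test_that("quality metrics hit their exact cases and improve with training", {
  X <- two_blob_data(30, seed = 6)$X
  cb <- init_codebook(hex_lattice(4, 5), X, "random_sample", seed = 1)
  expect_equal(quantization_error(cb, cb$W), 0)
  # 1x2 lattice: the only unit pair is adjacent, so no topographic errors
  cb2 <- init_codebook(hex_lattice(1, 2), X, "random_sample", seed = 1)
  expect_equal(topographic_error(cb2, X), 0)

  # trained map never quantizes worse than its own random init (annealed
  # to a sub-unit radius so the final epochs refine rather than smooth)
  for (s in 1:20) {
    gen <- generate_cohort(study_spec("woman", seed = 300 + s, n = 500))
    fm <- standardize_features(derive_ratios(gen$cohort))
    W0 <- init_codebook(hex_lattice(4, 5), fm, "random_sample", seed = s)
    tr <- som_train(W0, fm, som_schedule(n_epochs = 20, sigma_final = 0.5))
    expect_lte(quantization_error(tr$codebook, fm),
               quantization_error(W0, fm))
  }
})

test_that("component planes are exact projections with affine rescaling", {
  X <- two_blob_data(30, seed = 9)$X
  cb <- init_codebook(hex_lattice(3, 4), X, "random_sample", seed = 2)
  pl <- component_plane(cb, "age")
  expect_equal(pl$value, unname(cb$W[, "age"]))
  scaling <- list(mean = c(age = 70), sd = c(age = 7))
  pl2 <- component_plane(cb, "age", scaling)
  expect_equal(pl2$value, pl$value * 7 + 70)

  # JSON round-trip preserves the codebook bit-for-bit
  p <- tempfile(fileext = ".json")
  write_codebook(cb, p)
  cb2 <- read_codebook(p)
  expect_equal(cb2$W, cb$W, tolerance = 1e-12)
  expect_equal(cb2$lattice$coords, cb$lattice$coords)
})
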