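test_that("kNN graph matches an exhaustive-sort oracle with index ties", {
  cl <- random_cloud(50, seed = 14)
  g <- knn_graph(cl, k = 8)
  # brute force
  for (i in c(1, 17, 50)) {
    d <- sqrt(colSums((t(cl) - cl[i, ])^2))
    d[i] <- Inf
    expect_setequal(g[i, ], order(d)[1:8])
  }
  expect_true(all(g != row(g)[, 1:8]))     # no self loops

  # 3 collinear equidistant points, k = 2: each node's neighbors are the
  # other two
  cl3 <- cbind(c(0, 1, 2), 0, 0)
  g3 <- knn_graph(cl3, k = 2)
  expect_setequal(g3[1, ], c(2, 3))
  expect_setequal(g3[2, ], c(1, 3))

  # duplicated coordinates: deterministic ascending-index tie-break
  cld <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(5, 0, 0))
  gd <- knn_graph(cld, k = 2)
  expect_equal(gd[1, ], c(2L, 3L))
  expect_equal(gd[4, ], c(1L, 2L))
  expect_error(knn_graph(cl3, k = 3), "N > k")
})

test_that("denoising loss is the mean squared entry difference", {
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(denoising_loss(a, a), 0)
  expect_equal(denoising_loss(a, a + 1), 1)
  b <- matrix(rnorm(60), 20, 3)
  oracle <- 0
  for (i in 1:20) for (j in 1:3) oracle <- oracle + (a[i, j] - b[i, j])^2
  expect_equal(denoising_loss(a, b), oracle / 60, tolerance = 1e-12)
  expect_error(denoising_loss(a, b[1:5, ]), "shape")
})

test_that("SI-weighted similarity loss scales only the SI axis", {
  cl <- random_cloud(25, seed = 3)
  expect_equal(weighted_mse(cl, cl), 0)
  expect_equal(weighted_mse(cl + matrix(c(0, 0, 1), 25, 3, byrow = TRUE),
                            cl), 3)
  expect_equal(weighted_mse(cl + matrix(c(1, 0, 0), 25, 3, byrow = TRUE),
                            cl), 1)
  expect_equal(weighted_mse(cl + matrix(c(0, 1, 0), 25, 3, byrow = TRUE),
                            cl), 1)
})

test_that("Laplacian coordinates and loss are translation invariant", {
  cl <- random_cloud(30, seed = 6)
  g <- knn_graph(cl, 5)
  lc <- laplacian_coords(cl, g)
  # per-node loop oracle
  for (i in c(2, 30)) {
    expect_equal(lc[i, ], cl[i, ] - colMeans(cl[g[i, ], ]),
                 tolerance = 1e-12)
  }
  # a node at the centroid of its neighbors has zero Laplacian coordinate
  cl2 <- cl
  cl2[1, ] <- colMeans(cl[g[1, ], ])
  expect_equal(laplacian_coords(cl2, g)[1, ], c(0, 0, 0),
               tolerance = 1e-12)
  # translation invariance (exact), hence zero loss for rigid translations
  tr <- sweep(cl, 2, c(4, -7, 2), "+")
  expect_equal(laplacian_coords(tr, g), lc, tolerance = 1e-12)
  expect_equal(laplacian_loss(cl, tr, g), 0)
  expect_equal(laplacian_loss(cl, cl, g), 0)

  # small hand-computed example: 5 nodes on a line, k=2, stretch last node
  cl5 <- cbind(c(0, 1, 2, 3, 4), 0, 0)
  g5 <- knn_graph(cl5, 2)
  after <- cl5; after[5, 1] <- 5
  # oracle by explicit loop
  lb <- laplacian_coords(cl5, g5); la <- laplacian_coords(after, g5)
  expect_equal(laplacian_loss(cl5, after, g5), sum((la - lb)^2) / 5,
               tolerance = 1e-14)
})

test_that("deformation energy vanishes for uniform fields, matches a loop oracle", {
  cl <- random_cloud(10, seed = 7)
  g <- knn_graph(cl, 3)
  expect_equal(energy_loss(matrix(0, 10, 3), g), 0)
  expect_equal(energy_loss(matrix(c(2, -1, 5), 10, 3, byrow = TRUE), g), 0,
               tolerance = 1e-12)
  set.seed(8)
  d <- matrix(rnorm(30), 10, 3)
  oracle <- 0
  for (i in 1:10) {
    lap <- d[i, ] - colMeans(d[g[i, ], ])
    oracle <- oracle + sum(d[i, ] * lap)
  }
  expect_equal(energy_loss(d, g), oracle / 10, tolerance = 1e-12)
})

test_that("deformation energy may be negative for asymmetric kNN graphs", {
  # construct a case where the kNN graph is non-mutual and the quadratic
  # form goes negative: documented property, not an error. The energy is
  # d' (I - A) d summed per axis; take d along the most negative eigenvector
  # of the symmetrized operator.
  found_negative <- FALSE
  for (s in 1:20) {
    cl <- random_cloud(12, seed = s, half = 10)
    g <- knn_graph(cl, 3)
    A <- matrix(0, 12, 12)
    for (i in 1:12) A[i, g[i, ]] <- 1 / 3
    M <- diag(12) - (A + t(A)) / 2
    eg <- eigen(M, symmetric = TRUE)
    if (min(eg$values) < -1e-8) {
      d <- cbind(eg$vectors[, 12], 0, 0)
      expect_lt(energy_loss(d, g), 0)
      found_negative <- TRUE
      break
    }
  }
  expect_true(found_negative)
})

test_that("total loss is the stated weighted sum", {
  w <- loss_weights()
  expect_equal(total_loss(list(noise = 0, sim = 0, lap = 0, eng = 0), w), 0)
  expect_equal(total_loss(list(noise = 1, sim = 1, lap = 1, eng = 1), w),
               2.02)
  set.seed(9)
  p <- as.list(abs(rnorm(4))); names(p) <- c("noise", "sim", "lap", "eng")
  expect_equal(total_loss(p, w),
               p$noise + w$lambda_sim * p$sim + w$lambda_lap * p$lap +
                 w$lambda_eng * p$eng, tolerance = 1e-15)
  expect_error(total_loss(list(noise = NaN, sim = 0, lap = 0, eng = 0), w),
               "finite")
})
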