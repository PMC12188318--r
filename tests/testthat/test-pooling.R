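test_that("the default backbone pools exactly 3840 values per node", {
  bb <- init_backbone(backbone_config(), seed = 1)
  set.seed(2)
  proj <- matrix(runif(64 * 48), 48, 64)
  st <- extract_feature_stack(proj, bb)
  expect_equal(sum(st$channels), 3840)
  expect_equal(st$channels, c(256L, 512L, 1024L, 2048L))
  expect_equal(st$downscales, c(4L, 8L, 16L, 32L))
  g <- tiny_geometry(0, cols = 64, rows = 48, pitch = 5)
  cl <- random_cloud(10, seed = 3, half = 40)
  pf <- pool_features(st, g, cl)
  expect_equal(dim(pf), c(10L, 3840L))
})

test_that("tiny backbone config arithmetic and determinism", {
  bb <- init_backbone(tiny_backbone_config(), seed = 4)
  set.seed(5)
  proj <- matrix(runif(64 * 48), 48, 64)
  s1 <- extract_feature_stack(proj, bb)
  s2 <- extract_feature_stack(proj, bb)
  expect_equal(sum(s1$channels), 56)
  expect_identical(s1$maps, s2$maps)
  # stage shapes follow the strides
  expect_equal(dim(s1$maps[[1]])[1:2], c(24L, 32L))
  expect_equal(dim(s1$maps[[2]])[1:2], c(12L, 16L))
  expect_equal(dim(s1$maps[[3]])[1:2], c(6L, 8L))
  expect_error(extract_feature_stack(matrix(NA_real_, 4, 4), bb),
               "finite")
})

test_that("bilinear pooling matches hand values and knot exactness", {
  ns <- asNamespace("pcdtrack")
  # 2x2 single-channel map [[0,1],[2,3]] (rows y, cols x), query (0.5, 0.5)
  map <- array(0, c(2, 2, 1))
  map[1, 1, 1] <- 0; map[1, 2, 1] <- 1; map[2, 1, 1] <- 2; map[2, 2, 1] <- 3
  bp <- ns$bilinear_pool_map(map, cbind(0.5, 0.5), TRUE, 1)
  expect_equal(bp$val[1, 1], 1.5)
  # exact integer knots return the pixel value
  for (xy in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    v <- ns$bilinear_pool_map(map, cbind(xy[1], xy[2]), TRUE, 1)$val[1, 1]
    expect_equal(v, map[xy[2] + 1, xy[1] + 1, 1])
  }
  # constant map pools the constant for every in-view node
  cmap <- array(7.5, c(6, 8, 2))
  px <- cbind(runif(20, 0, 7), runif(20, 0, 5))
  vc <- ns$bilinear_pool_map(cmap, px, rep(TRUE, 20), 1)
  expect_true(all(abs(vc$val - 7.5) < 1e-12))
})

test_that("pooling agrees with a per-node loop oracle and stays in bounds", {
  bb <- init_backbone(tiny_backbone_config(), seed = 6)
  set.seed(7)
  proj <- matrix(runif(64 * 48, 0, 3), 48, 64)
  st <- extract_feature_stack(proj, bb)
  g <- tiny_geometry(30, cols = 64, rows = 48, pitch = 5)
  cl <- random_cloud(40, seed = 8, half = 50)
  pf <- pool_features(st, g, cl)
  pr <- project_points(g, cl)
  # naive per-node, per-map, per-channel bilinear oracle
  for (i in c(1, 13, 40)) {
    if (!pr$valid[i]) next
    feats <- c()
    for (m in seq_along(st$maps)) {
      mp <- st$maps[[m]]
      H <- dim(mp)[1]; W <- dim(mp)[2]
      x <- min(max(pr$pixels[i, 1] / st$downscales[m], 0), W - 1)
      y <- min(max(pr$pixels[i, 2] / st$downscales[m], 0), H - 1)
      x0 <- floor(x); y0 <- floor(y)
      x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
      fx <- x - x0; fy <- y - y0
      for (ch in seq_len(dim(mp)[3])) {
        feats <- c(feats,
                   (1 - fx) * (1 - fy) * mp[y0 + 1, x0 + 1, ch] +
                     (1 - fx) * fy * mp[y1 + 1, x0 + 1, ch] +
                     fx * (1 - fy) * mp[y0 + 1, x1 + 1, ch] +
                     fx * fy * mp[y1 + 1, x1 + 1, ch])
      }
    }
    expect_equal(unname(pf[i, ]), feats, tolerance = 1e-6)
  }
  # bilinear convexity: every pooled value within its map's range
  off <- 0
  for (m in seq_along(st$maps)) {
    C <- dim(st$maps[[m]])[3]
    vals <- pf[pr$valid, off + seq_len(C)]
    expect_true(all(vals >= min(st$maps[[m]]) - 1e-9))
    expect_true(all(vals <= max(st$maps[[m]]) + 1e-9))
    off <- off + C
  }
  # out-of-view nodes pool zeros
  far <- matrix(c(0, 0, 3000), 1, 3)
  pff <- suppressWarnings(pool_features(st, g, rbind(cl, far)))
  expect_true(all(pff[41, ] == 0))
})

test_that("pooled features are equivariant under joint gantry/cloud rotation", {
  bb <- init_backbone(tiny_backbone_config(), seed = 9)
  set.seed(10)
  proj <- matrix(runif(64 * 48, 0, 3), 48, 64)
  st <- extract_feature_stack(proj, bb)
  cl <- random_cloud(25, seed = 11, half = 50)
  for (theta in c(25, 130)) {
    f1 <- pool_features(st, tiny_geometry(theta, 64, 48, 5), cl)
    f2 <- pool_features(st, tiny_geometry(0, 64, 48, 5),
                        cl %*% t(rotation_z(-theta)))
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("global pooling mode returns spatial means at the same width", {
  bb <- init_backbone(tiny_backbone_config(), seed = 12)
  set.seed(13)
  proj <- matrix(runif(64 * 48), 48, 64)
  st <- extract_feature_stack(proj, bb)
  g <- tiny_geometry(0, 64, 48, 5)
  cl <- random_cloud(15, seed = 14, half = 40)
  pf <- pool_features(st, g, cl, mode = "global")
  expect_equal(dim(pf), c(15L, 56L))
  expect_true(all(apply(pf, 2, function(col) all(col == col[1]))))
  m1 <- st$maps[[1]]
  expect_equal(pf[1, 1], mean(m1[, , 1]), tolerance = 1e-12)
})

test_that("pooling backward pass matches finite differences", {
  ns <- asNamespace("pcdtrack")
  set.seed(15)
  maps <- list(array(rnorm(6 * 8 * 2), c(6, 8, 2)),
               array(rnorm(3 * 4 * 3), c(3, 4, 3)))
  g <- tiny_geometry(0, cols = 8, rows = 6, pitch = 40)
  cl <- random_cloud(12, seed = 16, half = 60)
  fw <- ns$pool_fwd(maps, c(1, 2), g, cl, "geometry", warn_oov = FALSE)
  dfeat <- matrix(rnorm(length(fw$feat)), nrow(fw$feat))
  dmaps <- ns$pool_bwd(fw$cache, dfeat)
  for (m in 1:2) {
    eps <- 1e-6
    idx <- sample(length(maps[[m]]), 10)
    for (i in idx) {
      mp <- maps; mp[[m]][i] <- maps[[m]][i] + eps
      lp <- sum(ns$pool_fwd(mp, c(1, 2), g, cl, "geometry",
                            warn_oov = FALSE)$feat * dfeat)
      mp[[m]][i] <- maps[[m]][i] - eps
      lm <- sum(ns$pool_fwd(mp, c(1, 2), g, cl, "geometry",
                            warn_oov = FALSE)$feat * dfeat)
      expect_equal(dmaps[[m]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})
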