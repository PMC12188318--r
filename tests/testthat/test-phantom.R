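test_that("phantom construction is deterministic and geometrically sound", {
  p1 <- tiny_phantom(seed = 7)
  p2 <- tiny_phantom(seed = 7)
  expect_identical(p1$volume, p2$volume)
  expect_identical(p1$liver_cloud, p2$liver_cloud)

  # surface nodes sit on the mask boundary within one voxel: the
  # superellipsoid value at each node is 1 by construction
  v <- pcdtrack:::superellipsoid_value(p1$liver_cloud,
                                       p1$liver_center,
                                       p1$params$liver_semiaxes,
                                       p1$params$exponent)
  expect_true(all(abs(v - 1) < 1e-10))

  # tumor points strictly inside the liver surface
  vt <- pcdtrack:::superellipsoid_value(p1$tumor_points, p1$liver_center,
                                        p1$params$liver_semiaxes,
                                        p1$params$exponent)
  expect_true(all(vt < 1))

  expect_error(make_phantom(tumor_radius = 100), "fit|outside")
  expect_error(make_phantom(tumor_offset = c(55, 0, 0), tumor_radius = 8),
               "outside")
  expect_error(make_phantom(grid = 8), "grid")
})

test_that("zero liver contrast gives zero CNR up to texture noise", {
  # both ROIs inside the soft-tissue body, the background outside the liver
  tgt <- list(center = c(0, 0, 0), radius = 20)
  bkg <- list(center = c(0, -75, 0), radius = 20)
  cnrs <- sapply(1:4, function(s) {
    p <- make_phantom(grid = 48, spacing = 5, contrast = 0, seed = s)
    compute_cnr(p$volume, p$spacing, tgt, bkg)
  })
  expect_lt(abs(mean(cnrs)), 0.25)
  # and a positive contrast produces a clearly positive CNR
  p2 <- make_phantom(grid = 48, spacing = 5, contrast = 0.004, seed = 3)
  cnr2 <- compute_cnr(p2$volume, p2$spacing, tgt, bkg)
  expect_gt(cnr2, 1)
})

test_that("PCA motion model recovers a known component subspace", {
  set.seed(11)
  m <- 120
  D0 <- matrix(rnorm(3 * m), m, 3)
  # two orthonormal components
  C1 <- matrix(rnorm(3 * m), m, 3); C1 <- C1 / sqrt(sum(C1^2))
  C2 <- matrix(rnorm(3 * m), m, 3)
  C2 <- C2 - sum(C2 * C1) * C1; C2 <- C2 / sqrt(sum(C2^2))
  a <- rnorm(8, sd = 2); b <- rnorm(8, sd = 1)
  dvfs <- lapply(1:8, function(i) D0 + a[i] * C1 + b[i] * C2)
  mm <- build_motion_model(dvfs, n_components = 2)

  # mean equals the arithmetic mean of inputs
  expect_equal(mm$mean, D0 + mean(a) * C1 + mean(b) * C2, tolerance = 1e-12)

  # principal angles between recovered and true subspace < 1e-6 rad
  U <- cbind(as.numeric(mm$components[[1]]), as.numeric(mm$components[[2]]))
  V <- cbind(as.numeric(C1), as.numeric(C2))
  sv <- svd(crossprod(U, V))$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-6))

  # full-rank reconstruction: any input is mean + scores %*% components
  mm3 <- build_motion_model(dvfs, n_components = 3)
  for (i in c(1, 5)) {
    rec <- mm3$mean
    for (k in 1:3)
      rec <- rec + mm3$scores[i, k] * mm3$components[[k]]
    expect_lt(sqrt(mean((rec - dvfs[[i]])^2)), 1e-8)
  }

  # degenerate case: identical inputs -> mean is that input, zero spread
  same <- lapply(1:5, function(i) D0)
  mm0 <- build_motion_model(same, n_components = 3)
  expect_equal(mm0$mean, D0, tolerance = 1e-12)
  expect_true(all(mm0$sdev < 1e-8))

  expect_error(build_motion_model(dvfs[1:3], n_components = 3), "at least")
})

test_that("synthesize_dvf is an exact linear combination", {
  set.seed(4)
  dvfs <- lapply(1:6, function(i) matrix(rnorm(90), 30, 3))
  mm <- build_motion_model(dvfs, 3)
  expect_equal(synthesize_dvf(mm, c(0, 0, 0, 0)), matrix(0, 30, 3))
  expect_equal(synthesize_dvf(mm, c(1, 0, 0, 0)), mm$mean)
  w <- rnorm(4)
  oracle <- w[1] * mm$mean
  for (k in 1:3) oracle <- oracle + w[k + 1] * mm$components[[k]]
  expect_equal(synthesize_dvf(mm, w), oracle, tolerance = 1e-15)
  # linearity
  v <- rnorm(4)
  expect_equal(synthesize_dvf(mm, 2 * w + 3 * v),
               2 * synthesize_dvf(mm, w) + 3 * synthesize_dvf(mm, v),
               tolerance = 1e-12)
  expect_error(synthesize_dvf(mm, w[1:3]), "length")
})

test_that("analytic breathing phases have SI-dominant, 3-component structure", {
  ph <- tiny_phantom()
  dvfs <- phase_displacements(ph$liver_cloud, ph, n_phases = 10)
  expect_identical(dvfs[[1]], matrix(0, nrow(ph$liver_cloud), 3))
  rng <- sapply(1:3, function(ax)
    max(sapply(dvfs, function(d) max(abs(d[, ax])))))
  expect_true(rng[3] > rng[2] && rng[2] > rng[1])  # SI > AP > LR
  mm <- build_motion_model(dvfs, 3)
  expect_gt(mm$var_explained, 0.999)
})

test_that("augmentation plan reproduces the protocol's exact counts", {
  plan <- make_augmentation_plan(seed = 5)
  d <- plan$deformations; v <- plan$volumes
  expect_equal(sum(d$split == "train"), 768)
  expect_equal(sum(d$split == "val"), 384)
  expect_equal(sum(d$split == "test"), 45)
  expect_equal(sum(v$split == "train"), 3072)
  expect_equal(sum(v$split == "val"), 1536)
  expect_equal(sum(v$split == "test"), 135)
  # counts are seed-independent
  plan2 <- make_augmentation_plan(seed = 99)
  expect_equal(table(plan2$deformations$split), table(d$split))
  # but sampled values differ
  expect_false(isTRUE(all.equal(plan2$deformations$s1, d$s1)))

  # coefficients and translations within their declared ranges
  tv <- d[d$split != "test", ]
  expect_true(all(tv$s0 >= 0.95 & tv$s0 <= 1.05))
  expect_true(all(tv$s1 >= -1.5 & tv$s1 <= 3.0))
  expect_true(all(tv$s3 >= -1.5 & tv$s3 <= 1.5))
  te <- d[d$split == "test", ]
  expect_true(all(te$s0 == 1))
  expect_true(all(te$s1 >= 0 & te$s1 <= 4))
  expect_true(all(te$s3 >= 0 & te$s3 <= 2))
  vt <- v[v$split == "test", ]
  expect_true(all(as.matrix(vt[, c("tx", "ty", "tz")]) >= 0 &
                    as.matrix(vt[, c("tx", "ty", "tz")]) <= 10))
  # each test deformation yields exactly 3 volumes, none untranslated
  expect_true(all(table(vt$def_id) == 3))
  expect_true(all(rowSums(abs(vt[, c("tx", "ty", "tz")])) > 0))
  # train/val volumes: one untranslated + three translated per deformation
  vtr <- v[v$split != "test", ]
  zero <- rowSums(abs(vtr[, c("tx", "ty", "tz")])) == 0
  expect_true(all(tapply(zero, vtr$def_id, sum) == 1))

  # empty plan
  p0 <- make_augmentation_plan(train_phases = integer(0),
                               test_phases = integer(0))
  expect_equal(nrow(p0$deformations), 0)
  expect_error(make_augmentation_plan(trainval_ranges = list(w0 = c(2, 1),
                                                             w1 = c(0, 1),
                                                             w2 = c(0, 1),
                                                             w3 = c(0, 1))),
               "malformed")
})

test_that("apply_dvf displaces nodes exactly and invertibly", {
  cl <- random_cloud(40, seed = 2)
  zero <- matrix(0, 40, 3)
  expect_identical(apply_dvf(cl, zero), cl)
  shifted <- apply_dvf(cl, zero, c(0, 0, 5))
  expect_equal(shifted[, 3], cl[, 3] + 5)
  expect_equal(shifted[, 1:2], cl[, 1:2])
  set.seed(3)
  d <- matrix(rnorm(120), 40, 3)
  expect_equal(apply_dvf(apply_dvf(cl, d), -d), cl, tolerance = 1e-12)
  expect_error(apply_dvf(cl, d[1:10, ]), "node counts")
})
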