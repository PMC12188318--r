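# Digital liver phantom and respiratory motion simulation.
#
# The phantom stands in for a patient 4D-CT: a superellipsoidal liver with a
# spherical tumor embedded in a soft-tissue body, plus an analytic family of
# breathing-phase displacement fields whose statistical structure mimics
# clinical liver motion (SI-dominant bulk displacement >> AP tilt >> LR, with
# a local bulge component and hysteresis between phases).

superellipsoid_value <- function(pts, center, semiaxes, exponent) {
  u <- sweep(pts, 2, center)
  u <- sweep(abs(u), 2, semiaxes, "/")
  rowSums(u^exponent)
}

# radius along unit direction u at which the superellipsoid value equals 1
superellipsoid_radius <- function(dirs, semiaxes, exponent) {
  s <- rowSums(sweep(abs(dirs), 2, semiaxes, "/")^exponent)
  s^(-1 / exponent)
}

smooth3d <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  r <- max(1L, ceiling(2 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  filt <- function(v)
    stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)), k,
                  sides = 2)[(r + 1):(r + length(v))]
  x <- apply(x, c(2, 3), filt)                      # along axis 1
  x <- aperm(apply(x, c(1, 3), filt), c(2, 1, 3))   # along axis 2
  aperm(apply(x, c(1, 2), filt), c(2, 3, 1))        # along axis 3
}

#' Build a synthetic liver phantom
#'
#' Creates an isotropic attenuation volume containing a soft-tissue body, a
#' superellipsoidal liver with configurable contrast against the body, and a
#' spherical tumor strictly inside the liver. The liver surface point cloud is
#' sampled quasi-uniformly (Fibonacci lattice) on the exact superellipsoid
#' boundary, so nodes lie on the binary mask boundary within one voxel.
#'
#' Axis convention: x = LR, y = AP, z = SI; coordinates in mm with the volume
#' centred on the isocenter.
#'
#' @param grid volume dimension (cubic, >= 16); default 64.
#' @param spacing isotropic voxel size in mm; default 4.
#' @param liver_semiaxes superellipsoid semi-axes (mm), LR/AP/SI.
#' @param liver_center liver centre offset from isocenter (mm).
#' @param exponent superellipsoid exponent (2 = ellipsoid; >2 boxier).
#' @param n_nodes number of liver surface nodes (>= 4).
#' @param tumor_offset tumor centre relative to liver centre (mm).
#' @param tumor_radius tumor radius (mm).
#' @param n_tumor_points interior points sampled inside the tumor.
#' @param base_mu soft-tissue attenuation (1/mm).
#' @param contrast liver attenuation excess over soft tissue (1/mm); 0 makes
#'   the liver invisible (zero CNR by construction).
#' @param tumor_contrast tumor attenuation excess over liver (1/mm).
#' @param texture_sd s.d. of the smoothed random soft-tissue texture (1/mm).
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return object of class `pcd_phantom`: list with `volume`, `spacing`,
#'   `liver_cloud` (N x 3 mm), `tumor_points` (M x 3 mm), `liver_mask`
#'   (logical array), `liver_center`, `params`.
#' @export
make_phantom <- function(grid = 64, spacing = 4,
                         liver_semiaxes = c(60, 45, 70),
                         liver_center = c(0, 0, 0),
                         exponent = 2.5,
                         n_nodes = 200,
                         tumor_offset = c(15, -10, -25),
                         tumor_radius = 8,
                         n_tumor_points = 40,
                         base_mu = 0.019,
                         contrast = 0.004,
                         tumor_contrast = 0.002,
                         texture_sd = 0.0015,
                         seed = 1L) {
  if (grid < 16) stop("grid must be at least 16 voxels per side")
  if (n_nodes < 4) stop("a surface cloud needs at least 4 nodes")
  if (tumor_radius >= min(liver_semiaxes))
    stop("tumor does not fit inside the liver (radius exceeds a semi-axis)")
  dims <- rep(as.integer(grid), 3)
  tumor_center <- liver_center + tumor_offset
  # tumor must be strictly inside the closed liver surface
  probe <- sweep(fibonacci_sphere(64) * tumor_radius, 2, tumor_center, "+")
  if (any(superellipsoid_value(probe, liver_center, liver_semiaxes,
                               exponent) >= 1))
    stop("tumor outside liver: tumor sphere crosses the liver surface")

  with_seed(seed, {
    pts <- voxel_grid_coords(dims, spacing)
    half <- (grid - 1) / 2 * spacing
    body <- superellipsoid_value(pts, c(0, 0, 0),
                                 rep(half * 0.96, 3), 4) <= 1
    liver_val <- superellipsoid_value(pts, liver_center, liver_semiaxes,
                                      exponent)
    liver <- liver_val <= 1
    tum <- sqrt(rowSums(sweep(pts, 2, tumor_center)^2)) <= tumor_radius
    vol <- numeric(nrow(pts))
    vol[body] <- base_mu
    vol[liver] <- vol[liver] + contrast
    vol[tum] <- vol[tum] + tumor_contrast
    dim(vol) <- dims
    if (texture_sd > 0) {
      tex <- array(stats::rnorm(prod(dims)), dims)
      tex <- smooth3d(tex, 1.0)
      tex <- tex / stats::sd(tex) * texture_sd
      tex[!array(body, dims)] <- 0
      vol <- vol + tex
    }
    dirs <- fibonacci_sphere(n_nodes)
    rad <- superellipsoid_radius(dirs, liver_semiaxes, exponent)
    cloud <- sweep(dirs * rad, 2, liver_center, "+")
    u <- fibonacci_sphere(n_tumor_points)
    rr <- tumor_radius * stats::runif(n_tumor_points)^(1 / 3)
    tumor_points <- sweep(u * rr, 2, tumor_center, "+")
    structure(list(volume = vol, spacing = spacing,
                   liver_cloud = cloud, tumor_points = tumor_points,
                   liver_mask = array(liver, dims),
                   liver_center = liver_center,
                   tumor_center = tumor_center,
                   params = list(grid = grid, spacing = spacing,
                                 liver_semiaxes = liver_semiaxes,
                                 exponent = exponent, contrast = contrast,
                                 base_mu = base_mu, texture_sd = texture_sd,
                                 tumor_radius = tumor_radius, seed = seed)),
              class = "pcd_phantom")
  })
}

#' @export
print.pcd_phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("Liver phantom: %dx%dx%d voxels @ %.1f mm, %d surface nodes, %d tumor points\n",
              d[1], d[2], d[3], x$spacing, nrow(x$liver_cloud),
              nrow(x$tumor_points)))
  invisible(x)
}

#' Analytic breathing-phase displacement fields
#'
#' Evaluates a 3-component analytic motion family at arbitrary points for a
#' 10-phase (default) breathing cycle: an SI-dominant bulk displacement, an AP
#' tilt that varies along SI (with hysteresis relative to the bulk component),
#' and a localized radial bulge. Phase 0 is the reference (zero displacement).
#' The amplitudes default to an SI >> AP >> LR ordering typical of liver
#' motion.
#'
#' @param points m x 3 matrix of positions (mm) at which to evaluate.
#' @param phantom a `pcd_phantom` (supplies the liver centre and extent).
#' @param n_phases number of respiratory phases (>= 4).
#' @param amplitudes named vector: `si` bulk (mm), `tilt` (mm), `bulge` (mm).
#' @return list of `n_phases` m x 3 displacement matrices (phase 0 first,
#'   identically zero).
#' @export
phase_displacements <- function(points, phantom, n_phases = 10,
                                amplitudes = c(si = 9, tilt = 3, bulge = 2)) {
  stop_if_not_matrix3(points, "points")
  stopifnot(n_phases >= 4)
  ctr <- phantom$liver_center
  sax <- phantom$params$liver_semiaxes
  L <- 1.6 * sax
  u <- sweep(points, 2, ctr)
  env <- exp(-rowSums(sweep(u, 2, L, "/")^2))
  dir1 <- c(0.12, 0.35, 1)
  B1 <- amplitudes[["si"]] * env %o% dir1
  dir2 <- c(0.15, 1, -0.25)
  B2 <- amplitudes[["tilt"]] * (env * u[, 3] / sax[3]) %o% dir2
  b0 <- ctr + c(0.3, -0.4, -0.6) * sax
  r0 <- 0.6 * min(sax)
  v <- sweep(points, 2, b0)
  g <- exp(-rowSums(v^2) / r0^2)
  B3 <- amplitudes[["bulge"]] * v / r0 * g
  p <- (seq_len(n_phases) - 1) / n_phases
  lapply(p, function(ph) {
    a1 <- (1 - cos(2 * pi * ph)) / 2
    a2 <- 0.5 * sin(2 * pi * ph)
    a3 <- a1^2
    out <- a1 * B1 + a2 * B2 + a3 * B3
    dimnames(out) <- NULL
    out
  })
}

#' Build a PCA respiratory motion model from phase DVFs
#'
#' The mean field is the arithmetic mean of the inputs; the principal
#' components are the top right-singular vectors of the mean-removed phase
#' matrix, unit-normalized, with the sign fixed so that each component's
#' largest-magnitude entry is positive. Per-phase scores (projections onto the
#' components) are retained so that any input phase can be reconstructed as
#' mean + scores %*% components.
#'
#' @param phase_dvfs list of m x 3 displacement matrices over the same points.
#' @param n_components number of principal components to keep (default 3).
#' @return object of class `motion_model`: `mean` (m x 3), `components`
#'   (list of unit-norm m x 3 matrices), `scores` (phases x k), `sdev`
#'   (singular values / sqrt(P-1)), `var_explained`.
#' @export
build_motion_model <- function(phase_dvfs, n_components = 3) {
  P <- length(phase_dvfs)
  if (P < n_components + 1)
    stop("need at least n_components + 1 phase DVFs")
  m <- nrow(phase_dvfs[[1]])
  X <- t(vapply(phase_dvfs, function(d) {
    stopifnot(nrow(d) == m)
    as.numeric(d)
  }, numeric(3 * m)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # eigen on the small P x P Gram matrix (3m can be large)
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- n_components
  comps <- vector("list", k)
  sdev <- sqrt(ev[seq_len(k)] / max(1, P - 1))
  total_var <- sum(ev)
  for (i in seq_len(k)) {
    if (ev[i] > 1e-12 * max(ev, 1e-300)) {
      v <- crossprod(Xc, eg$vectors[, i])[, 1] / sqrt(ev[i])
    } else {
      v <- numeric(3 * m)  # degenerate direction: zero component
    }
    if (any(v != 0)) {
      j <- which.max(abs(v))
      if (v[j] < 0) v <- -v
    }
    comps[[i]] <- matrix(v, m, 3)
  }
  scores <- Xc %*% vapply(comps, as.numeric, numeric(3 * m))
  structure(list(mean = matrix(mu, m, 3), components = comps,
                 scores = scores, sdev = sdev,
                 var_explained = if (total_var > 0)
                   sum(ev[seq_len(k)]) / total_var else 1),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("PCA motion model: %d points, %d components (%.2f%% variance)\n",
              nrow(x$mean), length(x$components), 100 * x$var_explained))
  invisible(x)
}

#' Synthesize a DVF as a weighted combination of motion-model fields
#'
#' Computes `weights[1] * mean + sum_i weights[i+1] * component_i` exactly.
#'
#' @param model a `motion_model`.
#' @param weights numeric vector of length 1 + n_components (w0 scales the
#'   mean field; the rest scale the unit principal components).
#' @return m x 3 displacement matrix.
#' @export
synthesize_dvf <- function(model, weights) {
  k <- length(model$components)
  if (length(weights) != k + 1)
    stop(sprintf("weights must have length %d (mean + %d components)",
                 k + 1, k))
  out <- weights[1] * model$mean
  for (i in seq_len(k)) out <- out + weights[i + 1] * model$components[[i]]
  out
}

#' Effective component weights for an augmentation-plan entry
#'
#' Plan entries carry per-coefficient scaling factors applied to a phase's own
#' PCA scores: effective weights are `(s0, s1*score1, s2*score2, s3*score3)`.
#'
#' @param model a `motion_model` built over the same phases as the plan.
#' @param phase phase index (1-based row of the model's score matrix).
#' @param scaling numeric length-4 scaling factors (s0..s3).
#' @return numeric weight vector consumable by [synthesize_dvf()].
#' @export
plan_weights <- function(model, phase, scaling) {
  stopifnot(length(scaling) == length(model$components) + 1)
  c(scaling[1], scaling[-1] * model$scores[phase, ])
}

#' Generate the training/validation/testing augmentation plan
#'
#' Reproduces the combinatorics of the augmentation protocol: for each of the
#' training phases, 4 / 6 / 4 / 2 scaling factors are sampled uniformly for
#' coefficients w0..w3 from `trainval_ranges` and expanded as a Cartesian
#' product (192 deformations per phase), randomly assigned 2:1 to train and
#' validation; each deformation yields one untranslated volume plus 3 rigidly
#' translated copies (translations uniform in `trainval_shift_mm` per axis).
#' For each test phase, `n_test_combos` coefficient combinations are sampled
#' from `test_ranges` (w0 fixed at 1) and each yields 3 translated volumes
#' only (the zero-shift volume is discarded, translations uniform in
#' `test_shift_mm`).
#'
#' The counts are exact and seed-independent; only the sampled values vary
#' with the seed.
#'
#' @param train_phases,test_phases integer phase indices (1-based; phase 1 is
#'   the 0% reference and is never augmented). Defaults follow the protocol:
#'   phases 10--40% and 70--80% train/validate, 50--60% and 90% test.
#' @param trainval_ranges list of length-2 ranges for w0..w3.
#' @param test_ranges list of length-2 ranges for w0..w3 used in testing.
#' @param trainval_shift_mm,test_shift_mm per-axis translation ranges (mm).
#' @param n_samples per-coefficient sample counts (default 4, 6, 4, 2).
#' @param n_test_combos coefficient combinations per test phase (default 15).
#' @param seed integer seed.
#' @return object of class `augmentation_plan`: list with `deformations` and
#'   `volumes` data frames.
#' @export
make_augmentation_plan <- function(
    train_phases = c(2, 3, 4, 5, 8, 9),
    test_phases = c(6, 7, 10),
    trainval_ranges = list(w0 = c(0.95, 1.05), w1 = c(-1.5, 3.0),
                           w2 = c(-1.5, 3.0), w3 = c(-1.5, 1.5)),
    test_ranges = list(w0 = c(1, 1), w1 = c(0, 4), w2 = c(0, 4),
                       w3 = c(0, 2)),
    trainval_shift_mm = c(-6, 6), test_shift_mm = c(0, 10),
    n_samples = c(4, 6, 4, 2), n_test_combos = 15, seed = 1L) {
  check_range <- function(r, nm) {
    if (length(r) != 2 || !is.numeric(r) || r[2] < r[1])
      stop(sprintf("malformed range for %s", nm))
  }
  for (nm in names(trainval_ranges)) check_range(trainval_ranges[[nm]], nm)
  for (nm in names(test_ranges)) check_range(test_ranges[[nm]], nm)
  check_range(trainval_shift_mm, "trainval_shift_mm")
  check_range(test_shift_mm, "test_shift_mm")
  stopifnot(length(n_samples) == 4)

  runifr <- function(n, r) stats::runif(n, r[1], r[2])
  with_seed(seed, {
    defs <- list(); vols <- list()
    for (ph in train_phases) {
      draws <- Map(function(n, r) runifr(n, r), as.list(n_samples),
                   trainval_ranges)
      combos <- as.matrix(expand.grid(draws, KEEP.OUT.ATTRS = FALSE))
      n_def <- nrow(combos)                       # 4*6*4*2 = 192
      d <- data.frame(phase = ph,
                      split = sample(rep(c("train", "val"),
                                         c(2, 1) * n_def / 3)),
                      s0 = combos[, 1], s1 = combos[, 2],
                      s2 = combos[, 3], s3 = combos[, 4])
      defs[[length(defs) + 1L]] <- d
      # per deformation: one untranslated volume plus three translated
      sh <- matrix(0, 4 * n_def, 3)
      moved <- rep(c(FALSE, TRUE, TRUE, TRUE), n_def)
      sh[moved, ] <- matrix(runifr(9 * n_def, trainval_shift_mm),
                            3 * n_def, 3)
      v <- d[rep(seq_len(n_def), each = 4), ]
      v$tx <- sh[, 1]; v$ty <- sh[, 2]; v$tz <- sh[, 3]
      v$def_row <- rep(seq_len(n_def), each = 4)
      vols[[length(vols) + 1L]] <- v
    }
    for (ph in test_phases) {
      if (n_test_combos == 0) next
      d <- data.frame(phase = ph, split = "test",
                      s0 = runifr(n_test_combos, test_ranges$w0),
                      s1 = runifr(n_test_combos, test_ranges$w1),
                      s2 = runifr(n_test_combos, test_ranges$w2),
                      s3 = runifr(n_test_combos, test_ranges$w3))
      defs[[length(defs) + 1L]] <- d
      # zero-shift volume discarded: three translated volumes only
      sh <- matrix(runifr(9 * n_test_combos, test_shift_mm),
                   3 * n_test_combos, 3)
      v <- d[rep(seq_len(n_test_combos), each = 3), ]
      v$tx <- sh[, 1]; v$ty <- sh[, 2]; v$tz <- sh[, 3]
      v$def_row <- rep(seq_len(n_test_combos), each = 3)
      vols[[length(vols) + 1L]] <- v
    }
    empty <- data.frame(phase = integer(), split = character(),
                        s0 = numeric(), s1 = numeric(), s2 = numeric(),
                        s3 = numeric())
    deformations <- if (length(defs)) do.call(rbind, defs) else empty
    rownames(deformations) <- NULL
    deformations$def_id <- seq_len(nrow(deformations))
    volumes <- if (length(vols)) do.call(rbind, vols) else
      cbind(empty, data.frame(tx = numeric(), ty = numeric(),
                              tz = numeric(), def_row = integer()))
    rownames(volumes) <- NULL
    if (nrow(volumes)) {
      # def_row is per-phase; rebuild the global deformation id
      offsets <- c(0, cumsum(vapply(defs, nrow, integer(1))))
      blk <- rep(seq_along(vols), vapply(vols, nrow, integer(1)))
      volumes$def_id <- volumes$def_row + offsets[blk]
      volumes$def_row <- NULL
    } else volumes$def_id <- integer(0)
    volumes$vol_id <- seq_len(nrow(volumes))
    structure(list(deformations = deformations, volumes = volumes,
                   seed = seed), class = "augmentation_plan")
  })
}

#' @export
print.augmentation_plan <- function(x, ...) {
  d <- x$deformations
  v <- x$volumes
  for (s in c("train", "val", "test"))
    cat(sprintf("%-5s: %4d deformations, %4d volumes\n", s,
                sum(d$split == s), sum(v$split == s)))
  invisible(x)
}

#' Apply a displacement field (and optional rigid shift) to a point cloud
#'
#' @param cloud N x 3 matrix of node positions (mm).
#' @param dvf N x 3 matrix of per-node displacements (mm), node-aligned.
#' @param shift length-3 rigid translation (mm).
#' @return N x 3 matrix of displaced positions; node order preserved.
#' @export
apply_dvf <- function(cloud, dvf, shift = c(0, 0, 0)) {
  stop_if_not_matrix3(cloud, "cloud")
  stop_if_not_matrix3(dvf, "dvf")
  if (nrow(cloud) != nrow(dvf))
    stop("cloud and dvf have different node counts")
  sweep(cloud + dvf, 2, shift, "+")
}
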