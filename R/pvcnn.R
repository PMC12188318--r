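# Point-voxel network: the per-node regressor used as the diffusion model's
# noise predictor and (without a timestep input) as the rigid alignment
# model's backbone. Two branches are fused by addition: a voxel branch that
# normalizes the point coordinates into the unit sphere, averages point
# features onto a regular grid, applies 3D convolutions, and maps the result
# back to the points by trilinear devoxelization; and a point branch (shared
# per-point MLP) that keeps full per-node resolution. Timesteps enter through
# a sinusoidal embedding added to the hidden features.

# ---- voxelization ----------------------------------------------------------

# normalize coordinates to the unit sphere around their centroid
normalize_coords <- function(coords) {
  ctr <- colMeans(coords)
  u <- sweep(coords, 2, ctr)
  scale <- max(sqrt(rowSums(u^2)), 1e-8)
  list(xn = u / scale, center = ctr, scale = scale)
}

# average point features into a G^3 grid (floor binning of normalized coords)
voxelize_fwd <- function(xn, feats, G) {
  b <- clamp(floor((xn * 0.5 + 0.5) * G), 0, G - 1)
  lin <- b[, 1] + G * b[, 2] + G * G * b[, 3] + 1
  counts <- tabulate(lin, nbins = G^3)
  grid <- matrix(0, G^3, ncol(feats))
  agg <- rowsum(feats, group = lin)
  ids <- as.integer(rownames(agg))
  grid[ids, ] <- agg / counts[ids]
  list(grid = grid, cache = list(lin = lin, counts = counts, G = G))
}

voxelize_bwd <- function(cache, dgrid) {
  dgrid[cache$lin, , drop = FALSE] / cache$counts[cache$lin]
}

# trilinear interpolation of grid features back to the points
devoxelize_fwd <- function(grid, xn, G) {
  g <- (xn * 0.5 + 0.5) * G - 0.5
  g <- clamp(g, 0, G - 1)
  g0 <- clamp(floor(g), 0, G - 1)
  g1 <- pmin(g0 + 1, G - 1)
  f <- g - g0
  idx <- matrix(0, nrow(xn), 8)
  w <- matrix(0, nrow(xn), 8)
  k <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1L
    xi <- if (dx) g1[, 1] else g0[, 1]
    yi <- if (dy) g1[, 2] else g0[, 2]
    zi <- if (dz) g1[, 3] else g0[, 3]
    idx[, k] <- xi + G * yi + G * G * zi + 1
    w[, k] <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
  }
  out <- matrix(0, nrow(xn), ncol(grid))
  for (k in 1:8)
    out <- out + w[, k] * grid[idx[, k], , drop = FALSE]
  list(y = out, cache = list(idx = idx, w = w, n_vox = nrow(grid)))
}

devoxelize_bwd <- function(cache, dy) {
  dgrid <- matrix(0, cache$n_vox, ncol(dy))
  for (k in 1:8) {
    agg <- rowsum(dy * cache$w[, k], group = cache$idx[, k])
    ids <- as.integer(rownames(agg))
    dgrid[ids, ] <- dgrid[ids, ] + agg
  }
  dgrid
}

# ---- the network -----------------------------------------------------------

#' Initialize a point-voxel network
#'
#' @param in_dim per-node input width (3 coordinates + F condition features).
#' @param hidden hidden width of both branches.
#' @param grid voxel grid resolution per axis (default 16 at desk scale).
#' @param with_time whether the network takes a diffusion timestep (TRUE for
#'   the noise predictor, FALSE for the rigid alignment backbone).
#' @param seed integer seed for weight initialization.
#' @return object of class `pvcnn`.
#' @export
init_pvcnn <- function(in_dim, hidden = 32, grid = 16, with_time = TRUE,
                       seed = 1L) {
  with_seed(seed, {
    params <- list(
      inp = dense_init(in_dim, hidden),
      pt1 = dense_init(hidden, hidden),
      pt2 = dense_init(hidden, hidden),
      vc1 = conv3d_init(hidden, hidden),
      vc2 = conv3d_init(hidden, hidden),
      head = dense_init(hidden, 3, scale = 0),
      # zero-initialized linear skip from the raw input row to the output:
      # linear read-outs of the condition (and of x_t) are reachable without
      # traversing the deep path
      skip = dense_init(in_dim, 3, scale = 0),
      # global context: node-averaged hidden features feed a small MLP whose
      # output is broadcast to every node — the cross-node integration path
      # (cloud-level cues such as magnification live here)
      ctx1 = dense_init(hidden, hidden),
      ctx2 = dense_init(hidden, 3, scale = 0))
    if (with_time) params$temb <- dense_init(hidden, hidden)
    structure(list(params = params, in_dim = as.integer(in_dim),
                   hidden = as.integer(hidden), grid = as.integer(grid),
                   with_time = with_time, seed = seed),
              class = "pvcnn")
  })
}

#' @export
print.pvcnn <- function(x, ...) {
  cat(sprintf("Point-voxel network: in %d -> hidden %d (grid %d^3)%s\n",
              x$in_dim, x$hidden, x$grid,
              if (x$with_time) ", timestep-conditioned" else ""))
  invisible(x)
}

pvcnn_fwd <- function(model, x, t = NULL) {
  if (nrow(x) == 0) stop("empty point cloud")
  if (ncol(x) != model$in_dim)
    stop(sprintf("input width %d does not match model width %d", ncol(x),
                 model$in_dim))
  p <- model$params
  G <- model$grid
  nc <- normalize_coords(x[, 1:3, drop = FALSE])
  d_in <- dense_fwd(p$inp, x)
  r_in <- relu_fwd(d_in$y)
  h <- r_in$y
  if (model$with_time) {
    if (is.null(t)) stop("model requires a timestep t")
    e <- time_embedding(t, model$hidden)
    d_t <- dense_fwd(p$temb, matrix(e, 1))
    h <- sweep(h, 2, d_t$y[1, ], "+")
  } else d_t <- NULL
  # point branch
  d1 <- dense_fwd(p$pt1, h)
  r1 <- relu_fwd(d1$y)
  d2 <- dense_fwd(p$pt2, r1$y)
  # voxel branch
  vx <- voxelize_fwd(nc$xn, h, G)
  c1 <- conv3d_fwd(p$vc1, vx$grid, G)
  rv <- relu_fwd(c1$y)
  c2 <- conv3d_fwd(p$vc2, rv$y, G)
  dv <- devoxelize_fwd(c2$y, nc$xn, G)
  fsum <- d2$y + dv$y
  rf <- relu_fwd(fsum)
  hd <- dense_fwd(p$head, rf$y)
  sk <- dense_fwd(p$skip, x)
  cg <- dense_fwd(p$ctx1, matrix(colMeans(h), 1))
  cr <- relu_fwd(cg$y)
  cy <- dense_fwd(p$ctx2, cr$y)
  y <- hd$y + sk$y
  y <- sweep(y, 2, cy$y[1, ], "+")
  list(y = y,
       cache = list(d_in = d_in, r_in = r_in, d_t = d_t, d1 = d1, r1 = r1,
                    d2 = d2, vx = vx, c1 = c1, rv = rv, c2 = c2, dv = dv,
                    rf = rf, hd = hd, sk = sk, cg = cg, cr = cr, cy = cy,
                    n = nrow(x)))
}

pvcnn_bwd <- function(model, cache, dy) {
  p <- model$params
  G <- model$grid
  hb <- dense_bwd(p$head, cache$hd, dy)
  df <- relu_bwd(cache$rf, hb$dx)
  # point branch
  b2 <- dense_bwd(p$pt2, cache$d2, df)
  b1 <- dense_bwd(p$pt1, cache$d1, relu_bwd(cache$r1, b2$dx))
  dh <- b1$dx
  # voxel branch
  dgrid2 <- devoxelize_bwd(cache$dv$cache, df)
  cb2 <- conv3d_bwd(p$vc2, cache$c2$cache, dgrid2)
  cb1 <- conv3d_bwd(p$vc1, cache$c1$cache, relu_bwd(cache$rv, cb2$dx))
  dh <- dh + voxelize_bwd(cache$vx$cache, cb1$dx)
  grads <- list(inp = NULL, pt1 = b1$grad, pt2 = b2$grad, vc1 = cb1$grad,
                vc2 = cb2$grad, head = hb$grad)
  # global context path (contributes to dh before the time embedding, which
  # also feeds the context through h)
  cyb <- dense_bwd(p$ctx2, cache$cy, matrix(colSums(dy), 1))
  cgb <- dense_bwd(p$ctx1, cache$cg, relu_bwd(cache$cr, cyb$dx))
  grads$ctx1 <- cgb$grad
  grads$ctx2 <- cyb$grad
  dh <- dh + matrix(cgb$dx[1, ], cache$n, length(cgb$dx), byrow = TRUE) /
    cache$n
  if (model$with_time) {
    tb <- dense_bwd(p$temb, cache$d_t, matrix(colSums(dh), 1))
    grads$temb <- tb$grad
  }
  ib <- dense_bwd(p$inp, cache$d_in, relu_bwd(cache$r_in, dh))
  grads$inp <- ib$grad
  sb <- dense_bwd(p$skip, cache$sk, dy)
  grads$skip <- sb$grad
  list(dx = ib$dx + sb$dx, grad = grads[names(p)])
}

#' Forward pass of the point-voxel network
#'
#' @param model a [init_pvcnn()] object.
#' @param aug_cloud N x (3 + F) matrix: the first three columns are the point
#'   coordinates (used for voxelization), the rest per-node condition
#'   features.
#' @param t diffusion timestep (required when the model is
#'   timestep-conditioned).
#' @return N x 3 matrix of per-node output vectors.
#' @export
pvcnn_forward <- function(model, aug_cloud, t = NULL) {
  pvcnn_fwd(model, aug_cloud, t)$y
}
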