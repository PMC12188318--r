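# Geometry-informed perceptual feature pooling: a strided convolutional
# backbone turns a projection into a stack of multi-scale 2D feature maps, and
# each surface node pools a feature vector by projecting onto every map and
# sampling bilinearly at its (continuous) projected pixel location.
#
# The backbone is a configurable pyramid of stride-s 3x3 convolutions with
# ReLU; each stage output is one feature map of the stack. The default
# configuration mirrors the four stage outputs of a 50-layer residual network
# (256/512/1024/2048 channels at downscales 4/8/16/32, 3840 channels total);
# the tiny configuration is the desk-scale default used for training. The
# backbone is trained jointly with each downstream model, so the rigid model
# and the diffusion model each own a backbone instance.

#' Backbone configuration for the feature extractor
#'
#' @param channels per-stage output channels. The default (256, 512, 1024,
#'   2048) reproduces the stage widths of a 50-layer residual backbone and
#'   pools 3840 feature values per node.
#' @param strides per-stage stride (each a power of 2); the stack's downscale
#'   factors are the cumulative products.
#' @param include_input if TRUE, the standardized projection itself is
#'   prepended to the stack (parameter-free), giving the pooling layer direct
#'   access to the raw line integrals alongside the learned features.
#' @param input_pyramid average-pooling factors (powers of 2) of the raw
#'   input levels prepended when `include_input` is TRUE; each level is a
#'   single-channel map whose coarser levels average quantum noise over
#'   pixels. Default `1` (the input itself).
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(channels = c(256, 512, 1024, 2048),
                            strides = c(4, 2, 2, 2),
                            include_input = FALSE,
                            input_pyramid = 1) {
  stopifnot(length(channels) == length(strides), all(channels >= 1),
            all(strides %in% c(1, 2, 4, 8)))
  inc <- isTRUE(include_input)
  pyr <- if (inc) as.integer(input_pyramid) else integer(0)
  stopifnot(all(pyr %in% c(1L, 2L, 4L, 8L)))
  structure(list(channels = as.integer(channels),
                 strides = as.integer(strides),
                 downscales = as.integer(cumprod(strides)),
                 include_input = inc,
                 input_pyramid = pyr,
                 stack_channels = as.integer(c(rep(1L, length(pyr)),
                                               channels)),
                 stack_downscales = as.integer(c(pyr, cumprod(strides)))),
            class = "backbone_config")
}

# box average-pooling by an integer factor (crops to a multiple of f)
avg_pool2 <- function(m, f) {
  if (f == 1) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- colMeans(array(m, c(f, nr / f, nc)))           # rows
  t(colMeans(array(t(m), c(f, nc / f, nr / f))))      # columns
}

#' Desk-scale backbone configuration (8/16/32 channels, 56 total)
#' @export
tiny_backbone_config <- function() {
  backbone_config(channels = c(8, 16, 32), strides = c(2, 2, 2))
}

#' Initialize a feature-extraction backbone
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the weight initialization.
#' @return object of class `pcd_backbone` (weights plus configuration);
#'   deterministic given the seed.
#' @export
init_backbone <- function(config = tiny_backbone_config(), seed = 1L) {
  with_seed(seed, {
    cin <- c(1L, config$channels[-length(config$channels)])
    params <- Map(function(ci, co) conv2d_init(ci, co),
                  as.list(cin), as.list(config$channels))
    structure(list(params = params, config = config, seed = seed),
              class = "pcd_backbone")
  })
}

# forward pass with caches kept for training
backbone_fwd <- function(backbone, proj) {
  cfg <- backbone$config
  mu <- mean(proj); sdv <- stats::sd(proj)
  x <- array((proj - mu) / (sdv + 1e-8), c(nrow(proj), ncol(proj), 1))
  maps <- vector("list", length(cfg$channels))
  caches <- vector("list", length(cfg$channels))
  inp <- x
  for (i in seq_along(cfg$channels)) {
    cv <- conv2d_fwd(backbone$params[[i]], x, cfg$strides[i])
    rl <- relu_fwd(cv$y)
    maps[[i]] <- rl$y
    caches[[i]] <- list(conv = cv$cache, relu = rl$mask)
    x <- rl$y
  }
  if (cfg$include_input) {
    pyr <- lapply(cfg$input_pyramid, function(f) {
      m <- avg_pool2(inp[, , 1], f)
      array(m, c(dim(m), 1))
    })
    maps <- c(pyr, maps)
  }
  list(maps = maps, caches = caches)
}

# backward: dmaps[[i]] is the gradient arriving directly at stage output i
# (from pooling); gradients are chained down through the stages.
backbone_bwd <- function(backbone, caches, dmaps) {
  npyr <- length(backbone$config$input_pyramid)
  if (npyr > 0) dmaps <- dmaps[-seq_len(npyr)]
  n <- length(backbone$params)
  grads <- vector("list", n)
  dtop <- 0
  for (i in n:1) {
    dy <- dmaps[[i]]
    if (is.null(dy)) dy <- 0
    dy <- dy + dtop
    if (is.numeric(dy) && length(dy) == 1 && dy[1] == 0) {
      grads[[i]] <- tree_zero(backbone$params[[i]])
      dtop <- 0
      next
    }
    dy <- dy * caches[[i]]$relu
    bk <- conv2d_bwd(backbone$params[[i]], caches[[i]]$conv, dy)
    grads[[i]] <- bk$grad
    dtop <- bk$dx
  }
  grads
}

#' Extract the multi-scale feature stack of a projection
#'
#' The projection is standardized (per image) and passed through the backbone;
#' the stage outputs form the stack. Deterministic given the weights.
#'
#' @param proj rows x cols matrix of line integrals.
#' @param backbone a [init_backbone()] object.
#' @return object of class `pcd_feature_stack`: `maps` (list of H x W x C
#'   arrays), `downscales`, `channels`, and the projection size.
#' @export
extract_feature_stack <- function(proj, backbone) {
  if (!all(is.finite(proj))) stop("projection contains non-finite values")
  fw <- backbone_fwd(backbone, proj)
  structure(list(maps = fw$maps,
                 downscales = backbone$config$stack_downscales,
                 channels = backbone$config$stack_channels,
                 proj_dim = dim(proj)),
            class = "pcd_feature_stack")
}

#' @export
print.pcd_feature_stack <- function(x, ...) {
  cat(sprintf("Feature stack: %d maps, %d channels total, downscales %s\n",
              length(x$maps), sum(x$channels),
              paste(x$downscales, collapse = "/")))
  invisible(x)
}

# bilinear sample one map (H, W, C) for all nodes; px = (col, row) in
# projection pixels, ds = downscale; returns value matrix and a cache
bilinear_pool_map <- function(map, px, valid, ds) {
  d <- dim(map); H <- d[1]; W <- d[2]; C <- d[3]
  n <- nrow(px)
  mx <- clamp(px[, 1] / ds, 0, W - 1)
  my <- clamp(px[, 2] / ds, 0, H - 1)
  mx[!valid] <- 0; my[!valid] <- 0
  x0 <- clamp(floor(mx), 0, W - 1)
  y0 <- clamp(floor(my), 0, H - 1)
  x1 <- pmin(x0 + 1, W - 1)
  y1 <- pmin(y0 + 1, H - 1)
  fx <- mx - x0; fy <- my - y0
  m2 <- matrix(map, H * W, C)
  i00 <- y0 + H * x0 + 1
  i10 <- y1 + H * x0 + 1  # row + 1
  i01 <- y0 + H * x1 + 1  # col + 1
  i11 <- y1 + H * x1 + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy); w11 <- fx * fy
  val <- w00 * m2[i00, , drop = FALSE] + w10 * m2[i10, , drop = FALSE] +
    w01 * m2[i01, , drop = FALSE] + w11 * m2[i11, , drop = FALSE]
  val[!valid, ] <- 0
  list(val = val,
       cache = list(idx = cbind(i00, i10, i01, i11),
                    w = cbind(w00, w10, w01, w11), valid = valid,
                    dims = d))
}

bilinear_pool_map_bwd <- function(cache, dval) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  dval[!cache$valid, ] <- 0
  dm2 <- matrix(0, H * W, C)
  for (c4 in 1:4) {
    contrib <- dval * cache$w[, c4]
    agg <- rowsum(contrib, group = cache$idx[, c4])
    ids <- as.integer(rownames(agg))
    dm2[ids, ] <- dm2[ids, ] + agg
  }
  array(dm2, d)
}

# internal pooling with cache; mode "global" implements the no-geometry
# ablation: every node receives the spatial mean of each feature map.
pool_fwd <- function(maps, downscales, geom, cloud,
                     mode = c("geometry", "global"), warn_oov = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(cloud)
  if (mode == "global") {
    feats <- lapply(maps, function(m) {
      d <- dim(m)
      gm <- colMeans(matrix(m, d[1] * d[2], d[3]))
      matrix(gm, n, d[3], byrow = TRUE)
    })
    return(list(feat = do.call(cbind, feats),
                cache = list(mode = "global", n = n,
                             dims = lapply(maps, dim))))
  }
  pr <- project_points(geom, cloud)
  if (warn_oov && mean(pr$valid) < 0.5)
    warning("more than 50% of nodes project outside the detector; check the geometry")
  caches <- vector("list", length(maps))
  feats <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    bp <- bilinear_pool_map(maps[[i]], pr$pixels, pr$valid, downscales[i])
    feats[[i]] <- bp$val
    caches[[i]] <- bp$cache
  }
  list(feat = do.call(cbind, feats),
       cache = list(mode = "geometry", maps = caches,
                    channels = vapply(maps, function(m) dim(m)[3],
                                      integer(1))))
}

pool_bwd <- function(cache, dfeat) {
  if (cache$mode == "global") {
    off <- 0L
    return(lapply(cache$dims, function(d) {
      C <- d[3]
      dg <- colSums(dfeat[, off + seq_len(C), drop = FALSE]) / (d[1] * d[2])
      off <<- off + C
      array(rep(dg, each = d[1] * d[2]), d)
    }))
  }
  out <- vector("list", length(cache$maps))
  off <- 0L
  for (i in seq_along(cache$maps)) {
    C <- cache$channels[i]
    out[[i]] <- bilinear_pool_map_bwd(cache$maps[[i]],
                                      dfeat[, off + seq_len(C),
                                            drop = FALSE])
    off <- off + C
  }
  out
}

#' Pool per-node feature vectors from a feature stack
#'
#' Each node is projected onto the detector via [project_points()], its pixel
#' coordinate divided by each map's downscale factor, and every map sampled
#' bilinearly at that location; the per-node vector concatenates all maps and
#' channels. Nodes projecting outside the detector pool zeros. A warning is
#' raised if more than half of the nodes are out of view (a sign of wrong
#' geometry).
#'
#' @param stack a [extract_feature_stack()] result.
#' @param geom the [cone_beam_geometry()] of the projection.
#' @param cloud N x 3 node positions (mm).
#' @param mode "geometry" (default) or "global" (no geometry awareness: every
#'   node receives the spatially averaged features; the NG ablation).
#' @return N x F matrix, F = sum of stack channels.
#' @export
pool_features <- function(stack, geom, cloud, mode = "geometry") {
  stop_if_not_matrix3(cloud, "cloud")
  pool_fwd(stack$maps, stack$downscales, geom, cloud, mode)$feat
}
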