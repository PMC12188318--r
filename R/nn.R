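# Minimal neural-network primitives on BLAS: dense layers, 2D/3D convolution
# via im2col + GEMM, ReLU, sinusoidal timestep embeddings, and Adam. Gradients
# are hand-derived; layer caches hold what the backward pass needs. All
# internal.

he_init <- function(fan_in, n_out, n_in = fan_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

dense_init <- function(d_in, d_out, scale = 1) {
  list(W = he_init(d_in, d_out) * scale, b = numeric(d_out))
}

dense_fwd <- function(p, x) {
  y <- x %*% p$W
  y <- sweep(y, 2, p$b, "+")
  list(y = y, x = x)
}

dense_bwd <- function(p, cache, dy) {
  list(dx = dy %*% t(p$W),
       grad = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dy) dy * cache$mask

# ---- 2D convolution (kernel 3, pad 1, configurable stride) ----------------

conv2d_init <- function(c_in, c_out) {
  k <- 3L
  list(W = he_init(k * k * c_in, c_out), b = numeric(c_out))
}

conv2d_out_dim <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

# x: (H, W, C) array -> list(y = (Ho, Wo, Cout) array, cache)
conv2d_fwd <- function(p, x, stride) {
  k <- 3L; pad <- 1L
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  xp <- array(0, c(Hp, Wp, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- conv2d_out_dim(H, k, stride, pad)
  Wo <- conv2d_out_dim(W, k, stride, pad)
  n <- Ho * Wo
  patches <- matrix(0, n, k * k * C)
  blk <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    ci <- seq(j, by = stride, length.out = Wo)
    patches[, blk + seq_len(C)] <- xp[ri, ci, ]
    blk <- blk + C
  }
  y <- sweep(patches %*% p$W, 2, p$b, "+")
  list(y = array(y, c(Ho, Wo, ncol(p$W))),
       cache = list(patches = patches, dims = c(H, W, C, Ho, Wo),
                    stride = stride, pad = pad, k = k))
}

conv2d_bwd <- function(p, cache, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; Ho <- d[4]; Wo <- d[5]
  k <- cache$k; pad <- cache$pad; stride <- cache$stride
  dym <- matrix(dy, Ho * Wo, dim(dy)[3])
  grad <- list(W = crossprod(cache$patches, dym), b = colSums(dym))
  dpatch <- dym %*% t(p$W)
  dxp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  blk <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    ci <- seq(j, by = stride, length.out = Wo)
    dxp[ri, ci, ] <- array(dxp[ri, ci, ], c(Ho, Wo, C)) +
      array(dpatch[, blk + seq_len(C)], c(Ho, Wo, C))
    blk <- blk + C
  }
  list(dx = dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE],
       grad = grad)
}

# ---- 3D convolution (kernel 3, pad 1, stride 1) on a cubic grid -----------
#
# Voxel features are flat (G^3, C) matrices. Patch extraction uses cached
# gather indices; the input gradient is computed as a transposed convolution
# (patches of the output gradient times the flipped, transposed kernel), which
# avoids any scatter-accumulate loop. Weight rows are laid out channel-major
# (for channel c, its 27 offsets are contiguous), which lets the patch matrix
# be a zero-copy reinterpretation of one big gather.

conv3d_init <- function(c_in, c_out) {
  k <- 3L
  list(W = he_init(k^3 * c_in, c_out), b = numeric(c_out))
}

.conv3d_idx_cache <- new.env(parent = emptyenv())

# gather indices: for each of the 27 kernel offsets, the padded-grid linear
# index of every output voxel's contributing input voxel
conv3d_indices <- function(G) {
  key <- as.character(G)
  if (!is.null(.conv3d_idx_cache[[key]])) return(.conv3d_idx_cache[[key]])
  Gp <- G + 2L
  ax <- seq_len(G)
  vox <- as.matrix(expand.grid(i = ax, j = ax, k = ax))
  # linear index of voxel (i,j,k) within the padded grid (pad offset +1)
  interior <- (vox[, 1] + 1) + Gp * vox[, 2] + Gp * Gp * vox[, 3]
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  gather <- matrix(0L, G^3, 27)
  for (o in seq_len(27))
    gather[, o] <- interior + off[o, 1] + Gp * off[o, 2] +
      Gp * Gp * off[o, 3]
  out <- list(interior = interior, gather = gather, Gp = Gp)
  .conv3d_idx_cache[[key]] <- out
  out
}

conv3d_patches <- function(xm, G) {
  ix <- conv3d_indices(G)
  C <- ncol(xm)
  xpm <- matrix(0, ix$Gp^3, C)
  xpm[ix$interior, ] <- xm
  # one gather for all 27 offsets; the column-major layout of the result is
  # already the channel-major patch matrix (columns: offset within channel)
  big <- xpm[as.vector(ix$gather), , drop = FALSE]   # (G^3 * 27) x C
  dim(big) <- c(G^3, 27 * C)
  big
}

# x: (G^3, C) matrix -> y: (G^3, Cout) matrix
conv3d_fwd <- function(p, x, G) {
  patches <- conv3d_patches(x, G)
  y <- patches %*% p$W
  y <- sweep(y, 2, p$b, "+")
  list(y = y, cache = list(patches = patches, G = G, C = ncol(x)))
}

conv3d_bwd <- function(p, cache, dy) {
  G <- cache$G; C <- cache$C
  grad <- list(W = crossprod(cache$patches, dy), b = colSums(dy))
  # transposed convolution: flip the 27 offsets, swap in/out channels
  # (channel-major layout: W[(c-1)*27 + o, cout])
  c_out <- ncol(p$W)
  Wa <- array(p$W, c(27, C, c_out))
  Wt <- matrix(aperm(Wa[27:1, , , drop = FALSE], c(1, 3, 2)),
               27 * c_out, C)
  dx <- conv3d_patches(dy, G) %*% Wt
  list(dx = dx, grad = grad)
}

# ---- sinusoidal timestep embedding ----------------------------------------

time_embedding <- function(t, dim) {
  half <- dim %/% 2
  freqs <- exp(-log(1e4) * (seq_len(half) - 1) / max(1, half - 1))
  emb <- c(sin(t * freqs), cos(t * freqs))
  if (length(emb) < dim) emb <- c(emb, 0)
  emb
}

# ---- parameter-tree utilities and Adam ------------------------------------

is_param_leaf <- function(x) is.numeric(x)

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    out[[i]] <- tree_map2(f, a[[i]], b[[i]])
  }
  out
}

tree_zero <- function(a) {
  if (is_param_leaf(a)) return(a * 0)
  out <- a
  for (i in seq_along(a)) if (!is.null(a[[i]]))
    out[[i]] <- tree_zero(a[[i]])
  out
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_sumsq <- function(a) {
  if (is_param_leaf(a)) return(sum(a^2))
  s <- 0
  for (i in seq_along(a)) if (!is.null(a[[i]]))
    s <- s + tree_sumsq(a[[i]])
  s
}

# clip the global L2 norm of a gradient tree
tree_clip <- function(g, max_norm) {
  nrm <- sqrt(tree_sumsq(g))
  if (is.finite(nrm) && nrm > max_norm) g <- tree_scale(g, max_norm / nrm)
  g
}
tree_scale <- function(a, s) {
  if (is_param_leaf(a)) return(a * s)
  out <- a
  for (i in seq_along(a)) if (!is.null(a[[i]]))
    out[[i]] <- tree_scale(a[[i]], s)
  out
}
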