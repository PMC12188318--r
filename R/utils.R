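# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package functions
#' do not perturb the global random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Trilinear sampling of a 3D array at world coordinates
#'
#' The volume is centred on the isocenter: voxel (i,j,k) (1-based) sits at
#' world position ((i-1) - (n-1)/2) * spacing along each axis. Points outside
#' the grid sample 0 (zero padding).
#'
#' @param vol 3D numeric array.
#' @param pts m x 3 matrix of world coordinates (mm).
#' @param spacing voxel size (mm, isotropic).
#' @return numeric vector of m sampled values.
#' @keywords internal
sample_volume <- function(vol, pts, spacing, chunk = 250000L) {
  n <- nrow(pts)
  if (n > chunk) {
    # bounded working-set size: large queries are processed in slices
    out <- numeric(n)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      out[s:e] <- sample_volume(vol, pts[s:e, , drop = FALSE], spacing,
                                chunk)
    }
    return(out)
  }
  d <- dim(vol)
  # continuous 0-based voxel coordinates
  gx <- pts[, 1] / spacing + (d[1] - 1) / 2
  gy <- pts[, 2] / spacing + (d[2] - 1) / 2
  gz <- pts[, 3] / spacing + (d[3] - 1) / 2
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  out <- numeric(nrow(pts))
  nxy <- d[1] * d[2]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3] &
      w > 0
    if (any(ok)) {
      idx <- xi[ok] + d[1] * yi[ok] + nxy * zi[ok] + 1
      out[ok] <- out[ok] + w[ok] * vol[idx]
    }
  }
  out
}

# world coordinates (mm) of every voxel centre of a cubic grid
voxel_grid_coords <- function(dims, spacing) {
  ax <- function(n) (seq_len(n) - 1 - (n - 1) / 2) * spacing
  as.matrix(expand.grid(x = ax(dims[1]), y = ax(dims[2]), z = ax(dims[3]),
                        KEEP.OUT.ATTRS = FALSE))
}

stop_if_not_matrix3 <- function(x, name) {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric N x 3 matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}
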