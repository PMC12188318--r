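# Cone-beam projector: perspective point projection, DRR rendering, detector
# noise, and contrast-to-noise measurement.
#
# Conventions (used consistently by the pooling layer):
#   * the gantry rotates about the SI (z) axis; at gantry 0 the source lies on
#     the +AP (+y) axis at distance SAD from the isocenter;
#   * the detector is a flat panel perpendicular to the central ray at
#     distance SDD from the source, with column axis u in the rotation plane
#     and row axis v along +z;
#   * pixel coordinates are continuous, (0, 0) at the centre of the corner
#     pixel; the isocenter projects to ((cols-1)/2, (rows-1)/2).

#' Cone-beam imaging geometry
#'
#' @param gantry_angle_deg gantry angle in degrees (rotation about SI).
#' @param sad source-to-axis distance (mm).
#' @param sdd source-to-detector distance (mm; must exceed `sad`).
#' @param detector_cols,detector_rows detector grid size in pixels.
#' @param pixel_pitch_mm detector pixel size (mm).
#' @return object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(gantry_angle_deg = 0, sad = 1000, sdd = 1500,
                               detector_cols = 512, detector_rows = 384,
                               pixel_pitch_mm = 0.776) {
  if (!(sdd > sad && sad > 0)) stop("require SDD > SAD > 0")
  if (pixel_pitch_mm <= 0) stop("pixel pitch must be positive")
  structure(list(gantry_angle_deg = gantry_angle_deg, sad = sad, sdd = sdd,
                 detector_cols = as.integer(detector_cols),
                 detector_rows = as.integer(detector_rows),
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf("Cone-beam geometry: gantry %.1f deg, SAD %.0f / SDD %.0f mm, %dx%d px @ %.3f mm\n",
              x$gantry_angle_deg, x$sad, x$sdd, x$detector_cols,
              x$detector_rows, x$pixel_pitch_mm))
  invisible(x)
}

rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# source position and detector basis in world coordinates
geometry_frame <- function(geom) {
  R <- rot_z(geom$gantry_angle_deg)
  list(source = as.numeric(R %*% c(0, geom$sad, 0)),
       # detector centre, u (columns) and v (rows) unit vectors
       center = as.numeric(R %*% c(0, geom$sad - geom$sdd, 0)),
       u = as.numeric(R %*% c(1, 0, 0)),
       v = c(0, 0, 1))
}

#' Project 3D points onto the detector
#'
#' Points are rotated by minus the gantry angle into the source frame and
#' perspective-divided onto the detector plane. Points at or behind the source
#' plane are flagged invalid (not an error), as are points projecting outside
#' the detector.
#'
#' @param geom a [cone_beam_geometry()].
#' @param points N x 3 matrix (mm, world frame).
#' @return list with `pixels` (N x 2 continuous pixel coordinates, columns
#'   (col, row)) and `valid` (logical N).
#' @export
project_points <- function(geom, points) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  p <- points %*% t(rot_z(-geom$gantry_angle_deg))
  denom <- geom$sad - p[, 2]
  ok <- is.finite(denom) & denom > 1e-6
  s <- ifelse(ok, geom$sdd / denom, NA_real_)
  u <- s * p[, 1]
  v <- s * p[, 3]
  col <- u / geom$pixel_pitch_mm + (geom$detector_cols - 1) / 2
  row <- v / geom$pixel_pitch_mm + (geom$detector_rows - 1) / 2
  inview <- ok & col >= 0 & col <= geom$detector_cols - 1 &
    row >= 0 & row <= geom$detector_rows - 1
  inview[is.na(inview)] <- FALSE
  list(pixels = cbind(col = col, row = row), valid = inview)
}

#' Render a digitally reconstructed radiograph (DRR)
#'
#' Computes, for every detector pixel, the line integral of attenuation along
#' the ray from the source through the pixel centre, by ray marching with
#' trilinear volume sampling. The march step is at most half a voxel; rays
#' missing the volume integrate to zero.
#'
#' @param volume 3D attenuation array (1/mm), isocentric.
#' @param geom a [cone_beam_geometry()].
#' @param spacing voxel size (mm).
#' @param step_mm march step (default `spacing / 2`).
#' @return rows x cols matrix of line integrals (dimensionless).
#' @export
simulate_drr <- function(volume, geom, spacing, step_mm = spacing / 2) {
  stopifnot(length(dim(volume)) == 3, spacing > 0, step_mm > 0)
  fr <- geometry_frame(geom)
  nc <- geom$detector_cols; nr <- geom$detector_rows
  uu <- (seq_len(nc) - 1 - (nc - 1) / 2) * geom$pixel_pitch_mm
  vv <- (seq_len(nr) - 1 - (nr - 1) / 2) * geom$pixel_pitch_mm
  # detector pixel centres, pixel index varying over (row, col)
  px <- outer(vv * 0, uu, "+")  # nr x nc of u offsets
  pv <- outer(vv, uu * 0, "+")
  det <- cbind(fr$center[1] + as.numeric(px) * fr$u[1] + as.numeric(pv) * fr$v[1],
               fr$center[2] + as.numeric(px) * fr$u[2] + as.numeric(pv) * fr$v[2],
               fr$center[3] + as.numeric(px) * fr$u[3] + as.numeric(pv) * fr$v[3])
  S <- fr$source
  dirs <- sweep(det, 2, S)                # source -> pixel
  len <- sqrt(rowSums(dirs^2))
  dirs <- dirs / len
  # slab intersection with the volume bounding box
  d <- dim(volume)
  half <- (d - 1) / 2 * spacing + spacing / 2
  tmin <- rep(0, nrow(dirs)); tmax <- len
  for (ax in 1:3) {
    da <- dirs[, ax]
    near <- (-half[ax] - S[ax]) / da
    far <- (half[ax] - S[ax]) / da
    sw <- near > far
    tmp <- near[sw]; near[sw] <- far[sw]; far[sw] <- tmp
    para <- abs(da) < 1e-12
    near[para] <- if (abs(S[ax]) <= half[ax]) -Inf else Inf
    far[para] <- if (abs(S[ax]) <= half[ax]) Inf else -Inf
    tmin <- pmax(tmin, near); tmax <- pmin(tmax, far)
  }
  hit <- tmax > tmin
  out <- numeric(nrow(dirs))
  if (any(hit)) {
    t0 <- tmin[hit]; t1 <- tmax[hit]
    seg <- t1 - t0
    M <- max(2L, ceiling(max(seg) / step_mm))
    # midpoint rule with M equal sub-intervals per ray, all steps sampled in
    # one vectorized call
    nh <- sum(hit)
    dl <- seg / M
    hd <- dirs[hit, , drop = FALSE]
    tm <- rep(t0, M) + (rep(seq_len(M), each = nh) - 0.5) * rep(dl, M)
    pts <- cbind(S[1] + rep(hd[, 1], M) * tm,
                 S[2] + rep(hd[, 2], M) * tm,
                 S[3] + rep(hd[, 3], M) * tm)
    vals <- sample_volume(volume, pts, spacing)
    out[hit] <- .rowSums(matrix(vals, nh, M), nh, M) * dl
  }
  matrix(out, nr, nc)
}

#' Add photon (Poisson) and electronic (Gaussian) detector noise
#'
#' The input line integrals g are converted to expected photon counts
#' `photons_mean * exp(-g)`, Poisson noise and zero-mean Gaussian electronic
#' noise are added, counts are clamped at 1, and the result is mapped back to
#' the line-integral domain `-log(counts / photons_mean)`.
#'
#' @param proj matrix of line integrals.
#' @param photons_mean mean photons per pixel for an unattenuated ray (> 0).
#' @param electronic_sigma s.d. of the additive electronic noise (photons).
#' @param seed integer seed (deterministic output per seed).
#' @param noiseless if TRUE, return the input unchanged.
#' @return matrix of noisy line integrals (same shape).
#' @export
add_noise <- function(proj, photons_mean = 1e5, electronic_sigma = 10,
                      seed = 1L, noiseless = FALSE) {
  if (noiseless) return(proj)
  if (photons_mean <= 0) stop("photons_mean must be positive")
  with_seed(seed, {
    lam <- photons_mean * exp(-proj)
    counts <- stats::rpois(length(lam), as.numeric(lam)) +
      stats::rnorm(length(lam), 0, electronic_sigma)
    counts <- pmax(counts, 1)
    matrix(-log(counts / photons_mean), nrow(proj), ncol(proj))
  })
}

#' Contrast-to-noise ratio between two spherical ROIs
#'
#' CNR = (mean(target) - mean(background)) / sd(background), computed over
#' voxels whose centres fall inside each sphere.
#'
#' @param volume 3D array.
#' @param spacing voxel size (mm).
#' @param target,background lists with `center` (mm, length 3) and `radius`
#'   (mm, > 0).
#' @return scalar CNR.
#' @export
compute_cnr <- function(volume, spacing, target, background) {
  roi_values <- function(roi) {
    stopifnot(roi$radius > 0)
    d <- dim(volume)
    g <- roi$center / spacing + (d - 1) / 2
    lo <- pmax(1, floor(g - roi$radius / spacing))
    hi <- pmin(d, ceiling(g + roi$radius / spacing) + 1)
    if (any(lo > hi)) stop("ROI lies outside the volume")
    sub <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    pos <- (as.matrix(sub) - 1 - matrix((d - 1) / 2, nrow(sub), 3,
                                        byrow = TRUE)) * spacing
    inside <- rowSums(sweep(pos, 2, roi$center)^2) <= roi$radius^2
    if (!any(inside)) stop("ROI contains no voxel centres")
    volume[as.matrix(sub[inside, ])]
  }
  tv <- roi_values(target)
  bv <- roi_values(background)
  sb <- stats::sd(bv)
  if (!is.finite(sb) || sb == 0)
    stop("background s.d. is zero; CNR undefined")
  (mean(tv) - mean(bv)) / sb
}
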