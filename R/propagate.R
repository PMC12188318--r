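# Propagation of liver-surface motion to interior points for tumor
# localization. The surface DVF is split into a spatially uniform (DC)
# component representing rigid motion and a residual (AC) component; only the
# AC part is interpolated into the interior, and the DC part is added back.
#
# The interior interpolant is a deterministic polyharmonic (thin-plate-type)
# spline with affine terms, fitted per axis to the surface nodes. It is a
# synthetic stand-in for a learned biomechanical model: it reproduces the
# surface DVF at the nodes (up to the regularization tolerance), is exact for
# affine fields, and exposes the same interface (surface DVF in, interior
# field out, AC-only input) so a learned backend can be swapped in.

#' Decompose a displacement field into DC and AC components
#'
#' DC is the per-axis mean (rigid-like part); AC is the zero-mean residual.
#' `DC + AC` reconstructs the input exactly.
#'
#' @param dvf N x 3 displacement matrix.
#' @return list with `dc` (length 3) and `ac` (N x 3).
#' @export
decompose_dvf <- function(dvf) {
  stop_if_not_matrix3(dvf, "dvf")
  if (nrow(dvf) == 0) stop("empty displacement field")
  dc <- colMeans(dvf)
  list(dc = dc, ac = sweep(dvf, 2, dc))
}

#' Interpolate surface displacements to interior points
#'
#' Fits, per axis, a polyharmonic spline (kernel phi(r) = r, the biharmonic
#' kernel in 3D) with affine polynomial terms to the AC component of the
#' surface DVF, evaluates it at the query points, and re-adds the DC
#' component. Affine surface fields are reproduced exactly; at the surface
#' nodes the field is reproduced up to the regularization tolerance.
#'
#' @param surface_cloud N x 3 surface node positions (mm).
#' @param surface_dvf N x 3 surface displacements (mm).
#' @param query_points M x 3 interior positions (mm).
#' @param regularization ridge added to the kernel diagonal (default 1e-6) to
#'   tolerate noisy surface DVFs.
#' @return M x 3 matrix of interior displacements (mm).
#' @export
interpolate_interior <- function(surface_cloud, surface_dvf, query_points,
                                 regularization = 1e-6) {
  stop_if_not_matrix3(surface_cloud, "surface_cloud")
  stop_if_not_matrix3(surface_dvf, "surface_dvf")
  stop_if_not_matrix3(query_points, "query_points")
  n <- nrow(surface_cloud)
  if (nrow(surface_dvf) != n) stop("surface cloud/DVF node count mismatch")
  if (n < 5) stop("need at least 5 surface nodes")
  if (qr(cbind(1, surface_cloud))$rank < 4)
    stop("degenerate (coplanar) surface nodes")
  parts <- decompose_dvf(surface_dvf)
  K <- as.matrix(stats::dist(surface_cloud))
  P <- cbind(1, surface_cloud)
  A <- rbind(cbind(K + regularization * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(parts$ac, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  w <- sol[seq_len(n), , drop = FALSE]
  a <- sol[n + 1:4, , drop = FALSE]
  # kernel matrix between queries and surface nodes
  qq <- rowSums(query_points^2)
  ss <- rowSums(surface_cloud^2)
  Kq <- sqrt(pmax(outer(qq, ss, "+") - 2 * tcrossprod(query_points,
                                                      surface_cloud), 0))
  out <- Kq %*% w + cbind(1, query_points) %*% a
  sweep(out, 2, parts$dc, "+")
}

#' Localize the tumor from a predicted surface DVF
#'
#' Evaluates the interior displacement field (surface DVF plus rigid shift as
#' boundary condition) at the phantom's tumor points and displaces them.
#'
#' @param phantom a `pcd_phantom`.
#' @param surface_dvf N x 3 predicted deformable surface DVF (mm).
#' @param rigid_shift length-3 predicted rigid translation (mm).
#' @param regularization passed to [interpolate_interior()].
#' @return M x 3 predicted tumor point positions (mm).
#' @export
localize_tumor <- function(phantom, surface_dvf, rigid_shift = c(0, 0, 0),
                           regularization = 1e-6) {
  cloud <- phantom$liver_cloud
  tum <- phantom$tumor_points
  lo <- apply(cloud, 2, min); hi <- apply(cloud, 2, max)
  if (any(tum < matrix(lo, nrow(tum), 3, byrow = TRUE)) ||
      any(tum > matrix(hi, nrow(tum), 3, byrow = TRUE)))
    stop("tumor points outside the surface bounding volume")
  full <- sweep(surface_dvf, 2, rigid_shift, "+")
  field <- interpolate_interior(cloud, full, tum, regularization)
  tum + field
}
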