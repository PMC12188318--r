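# Composite training objective: denoising loss, SI-weighted similarity loss,
# Laplacian mesh regularization, and deformation energy, over a fixed k-NN
# neighbor graph built on the reference cloud.

#' k-nearest-neighbor graph of a point cloud
#'
#' Euclidean k-NN excluding self; exact distance ties are broken by ascending
#' node index, so the graph is deterministic even for duplicated coordinates.
#' The graph is built once on the reference cloud and reused for deformed
#' clouds (node correspondence is fixed).
#'
#' @param cloud N x 3 matrix.
#' @param k neighbors per node (default 8; must satisfy k < N).
#' @return N x k integer matrix of neighbor indices.
#' @export
knn_graph <- function(cloud, k = 8) {
  stop_if_not_matrix3(cloud, "cloud")
  n <- nrow(cloud)
  if (n <= k) stop("need more nodes than neighbors (N > k)")
  d2 <- as.matrix(stats::dist(cloud))^2
  diag(d2) <- Inf
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))   # ties -> ascending index
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

# neighbor-mean operator: rows of x averaged over each node's neighbors
neighbor_mean <- function(x, graph) {
  k <- ncol(graph)
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) out <- out + x[graph[, j], , drop = FALSE]
  out / k
}

#' Denoising loss: mean squared error between true and predicted noise
#' @param eps_true,eps_pred N x 3 matrices.
#' @return scalar (mean over all entries).
#' @export
denoising_loss <- function(eps_true, eps_pred) {
  if (!all(dim(eps_true) == dim(eps_pred))) stop("shape mismatch")
  mean((eps_true - eps_pred)^2)
}

#' SI-weighted similarity loss between matched point clouds
#'
#' Mean over nodes of `dx^2 + dy^2 + si_weight * dz^2`: the squared error along
#' the superior-inferior axis is scaled (default factor 3) because liver
#' respiratory motion is SI-dominant.
#'
#' @param pred_cloud,tar_cloud node-aligned N x 3 matrices (mm).
#' @param si_weight weight on the squared SI error.
#' @return scalar (mm^2).
#' @export
weighted_mse <- function(pred_cloud, tar_cloud, si_weight = 3) {
  if (nrow(pred_cloud) != nrow(tar_cloud)) stop("node count mismatch")
  d <- pred_cloud - tar_cloud
  mean(d[, 1]^2 + d[, 2]^2 + si_weight * d[, 3]^2)
}

#' Laplacian coordinates of a point cloud
#'
#' `delta_p = p - mean(neighbors of p)`; translation-invariant by
#' construction.
#'
#' @param cloud N x 3 matrix.
#' @param graph N x k neighbor index matrix from [knn_graph()].
#' @return N x 3 matrix of Laplacian coordinates.
#' @export
laplacian_coords <- function(cloud, graph) {
  stopifnot(nrow(cloud) == nrow(graph))
  cloud - neighbor_mean(cloud, graph)
}

#' Laplacian regularization loss
#'
#' `(1/N) * sum_p ||delta'_p - delta_p||^2` between the Laplacian coordinates
#' of a cloud before and after deformation (same node order and graph).
#'
#' @param cloud_before,cloud_after N x 3 matrices.
#' @param graph neighbor graph built on the reference cloud.
#' @return scalar (mm^2).
#' @export
laplacian_loss <- function(cloud_before, cloud_after, graph) {
  if (nrow(cloud_before) != nrow(cloud_after)) stop("node count mismatch")
  d <- laplacian_coords(cloud_after, graph) -
    laplacian_coords(cloud_before, graph)
  sum(d^2) / nrow(d)
}

#' Deformation energy of a displacement field
#'
#' `(1/N) * sum_p dvf_p . (dvf_p - mean(dvf over neighbors of p))`: the mean
#' dot product between each node's displacement and its graph Laplacian.
#' Uniform fields have zero energy exactly. The value can be negative for
#' asymmetric k-NN graphs (the graph Laplacian need not be positive
#' semi-definite when neighborhoods are not mutual); this is a property of the
#' definition, not an error.
#'
#' @param dvf N x 3 displacement matrix aligned with the graph's cloud.
#' @param graph neighbor graph.
#' @return scalar (mm^2).
#' @export
energy_loss <- function(dvf, graph) {
  if (nrow(dvf) != nrow(graph)) stop("node count mismatch")
  lap <- dvf - neighbor_mean(dvf, graph)
  sum(dvf * lap) / nrow(dvf)
}

#' Loss weights for the composite objective
#' @param lambda_sim,lambda_lap,lambda_eng nonnegative weights.
#' @param si_weight SI scaling inside the similarity loss.
#' @export
loss_weights <- function(lambda_sim = 1, lambda_lap = 0.01,
                         lambda_eng = 0.01, si_weight = 3) {
  stopifnot(lambda_sim >= 0, lambda_lap >= 0, lambda_eng >= 0,
            si_weight >= 0)
  list(lambda_sim = lambda_sim, lambda_lap = lambda_lap,
       lambda_eng = lambda_eng, si_weight = si_weight)
}

#' Composite total loss
#'
#' `L_total = L_noise + lambda_sim L_sim + lambda_lap L_lap + lambda_eng
#' L_eng`.
#'
#' @param parts named list/vector with elements `noise`, `sim`, `lap`, `eng`.
#' @param weights a [loss_weights()] list.
#' @return scalar.
#' @export
total_loss <- function(parts, weights = loss_weights()) {
  p <- unlist(parts[c("noise", "sim", "lap", "eng")])
  if (any(!is.finite(p))) stop("non-finite loss component")
  unname(p["noise"] + weights$lambda_sim * p["sim"] +
           weights$lambda_lap * p["lap"] + weights$lambda_eng * p["eng"])
}
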