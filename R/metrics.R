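# Surface and tumor localization metrics: RMSE, HD95, COME.

#' Root-mean-square node-wise error between matched clouds
#'
#' `sqrt(mean(||pred_p - tar_p||^2))` over corresponding nodes (this is a
#' correspondence metric, not a nearest-neighbor one).
#'
#' @param pred,tar node-aligned N x 3 matrices (mm).
#' @return scalar (mm).
#' @export
rmse_cloud <- function(pred, tar) {
  if (nrow(pred) != nrow(tar)) stop("node count mismatch")
  sqrt(mean(rowSums((pred - tar)^2)))
}

directed_nn_dist <- function(a, b) {
  # for each row of a, distance to the nearest row of b; the quadratic
  # expansion finds the argmin, the distance itself is recomputed exactly
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  j <- apply(d2, 1, which.min)
  sqrt(rowSums((a - b[j, , drop = FALSE])^2))
}

#' 95th-percentile symmetric Hausdorff distance
#'
#' Directed nearest-neighbor distances are computed each way, their 95th
#' percentiles taken, and the maximum returned. Correspondence between the
#' clouds is not required.
#'
#' @param pred,tar nonempty point matrices (mm).
#' @param percentile percentile of the directed distances (default 95).
#' @param type quantile convention: "linear" (interpolation between order
#'   statistics, default) or "nearest_rank" (for sensitivity checks).
#' @return scalar (mm).
#' @export
hd95 <- function(pred, tar, percentile = 95, type = c("linear",
                                                      "nearest_rank")) {
  if (nrow(pred) == 0 || nrow(tar) == 0) stop("empty point cloud")
  type <- match.arg(type)
  qt <- if (type == "linear") {
    function(x) unname(stats::quantile(x, percentile / 100, type = 7))
  } else {
    function(x) {
      xs <- sort(x)
      xs[max(1L, ceiling(percentile / 100 * length(xs)))]
    }
  }
  max(qt(directed_nn_dist(pred, tar)), qt(directed_nn_dist(tar, pred)))
}

#' Center-of-mass error between two point sets
#'
#' Euclidean distance between the unweighted coordinate means of the predicted
#' and ground-truth tumor point sets.
#'
#' @param pred_tumor,tar_tumor nonempty point matrices (mm).
#' @return scalar (mm).
#' @export
come <- function(pred_tumor, tar_tumor) {
  if (nrow(pred_tumor) == 0 || nrow(tar_tumor) == 0) stop("empty point set")
  sqrt(sum((colMeans(pred_tumor) - colMeans(tar_tumor))^2))
}
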