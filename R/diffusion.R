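# Conditional denoising diffusion over per-node surface DVFs.
#
# The diffusion state x_t lives in normalized DVF units: the deformable
# residual (after removing the rigid shift predicted by the frozen alignment
# model) divided by a configurable scale (default 10 mm), so that targets are
# near-unit, zero-centred quantities — the rigid model carries the mean. The
# sampling loop follows the conditional workflow: at each step the
# intermediate cloud ref + scale * x_t + shift is projected onto the feature
# maps to pool fresh per-node condition features.

#' Create a variance schedule
#'
#' @param T_steps number of diffusion steps.
#' @param beta_start,beta_end linear schedule endpoints
#'   (0 <= beta_start <= beta_end < 1).
#' @param kind only "linear" is implemented.
#' @return object of class `variance_schedule` with `beta`, `alpha`,
#'   `alpha_bar` (cumulative product), `T`.
#' @export
make_schedule <- function(T_steps = 100, beta_start = 1e-4, beta_end = 0.02,
                          kind = "linear") {
  kind <- match.arg(kind, "linear")
  if (!(beta_start >= 0 && beta_start <= beta_end && beta_end < 1))
    stop("require 0 <= beta_start <= beta_end < 1")
  beta <- if (T_steps == 1) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)), class = "variance_schedule")
}

#' @export
print.variance_schedule <- function(x, ...) {
  cat(sprintf("Variance schedule: T = %d, beta in [%.2e, %.2e], alpha_bar[T] = %.4g\n",
              x$T, min(x$beta), max(x$beta), x$alpha_bar[x$T]))
  invisible(x)
}

#' Forward noising (closed form)
#'
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`, exactly.
#'
#' @param x0 N x 3 clean state (normalized DVF units).
#' @param t timestep index in 1..T.
#' @param eps N x 3 noise draw (same shape as `x0`).
#' @param sched a [make_schedule()] object.
#' @return list with `x` (N x 3) and `t` (the noisy state).
#' @export
forward_noise <- function(x0, t, eps, sched) {
  if (t < 1 || t > sched$T) stop("t out of range [1, T]")
  if (!all(dim(x0) == dim(eps))) stop("eps must match x0's shape")
  ab <- sched$alpha_bar[t]
  list(x = sqrt(ab) * x0 + sqrt(1 - ab) * eps, t = t)
}

#' One ancestral denoising step
#'
#' Given the noisy state at t, predicts the noise with the point-voxel network
#' on the augmented cloud `[x_t | cond]` and draws the DDPM posterior sample
#' at t-1 with variance `beta_t` (the noise term is omitted at t = 1).
#' Consumes the current RNG stream, so a chain is reproducible given a seed.
#'
#' @param model a timestep-conditioned [init_pvcnn()].
#' @param state list with `x` (N x 3) and `t` (>= 1).
#' @param cond N x F per-node condition features.
#' @param sched a [make_schedule()].
#' @return list with `x` and `t = t - 1`.
#' @export
denoise_step <- function(model, state, cond, sched) {
  t <- state$t
  if (t < 1) stop("denoise_step requires t >= 1")
  x <- state$x
  eps_hat <- pvcnn_forward(model, cbind(x, cond), t)
  beta <- sched$beta[t]
  ab <- sched$alpha_bar[t]
  # beta = 0 implies alpha_bar = 1; the posterior mean is then x itself
  coef <- if (beta > 0) beta / sqrt(1 - ab) else 0
  mu <- (x - coef * eps_hat) / sqrt(sched$alpha[t])
  if (t > 1 && beta > 0) {
    z <- matrix(stats::rnorm(length(x)), nrow(x), 3)
    mu <- mu + sqrt(beta) * z
  }
  list(x = mu, t = t - 1L)
}

#' Sample a surface DVF from the conditional diffusion model
#'
#' Implements the full inference loop: (1) the rigid shift is predicted once
#' from features pooled at the reference cloud; (2) x_T is drawn from a
#' standard normal; (3) for t = T..1 the intermediate cloud
#' `ref + scale * x_t + shift` is pooled for fresh condition features and one
#' denoising step is taken; (4) the deformable DVF `scale * x_0` and the shift
#' are returned (their sum is the complete DVF).
#'
#' @param model a trained `diffusion_model` (see [train_diffusion()]).
#' @param rigid_model a trained `rigid_model`, or NULL to run without rigid
#'   alignment (the no-rigid ablation; the shift is then zero).
#' @param cloud_ref N x 3 reference surface cloud (mm).
#' @param proj projection (line integrals).
#' @param geom the projection's [cone_beam_geometry()].
#' @param seed integer seed; the chain is bit-reproducible given the seed.
#' @return list with `dvf` (N x 3 mm, deformable part), `shift` (length 3 mm)
#'   and `cloud_pred` (ref + dvf + shift).
#' @export
sample_dvf <- function(model, rigid_model, cloud_ref, proj, geom,
                       seed = 1L) {
  if (!inherits(model, "diffusion_model")) stop("model is not trained")
  stop_if_not_matrix3(cloud_ref, "cloud_ref")
  shift <- if (is.null(rigid_model)) c(0, 0, 0) else
    rigid_shift_from_projection(rigid_model, cloud_ref, proj, geom)
  sched <- model$sched
  scale <- model$scale
  stack <- extract_feature_stack(proj, model$backbone)
  n <- nrow(cloud_ref)
  with_seed(seed, {
    state <- list(x = matrix(stats::rnorm(3 * n), n, 3), t = sched$T)
    while (state$t >= 1) {
      inter <- sweep(cloud_ref + scale * state$x, 2, shift, "+")
      cond <- pool_fwd(stack$maps, stack$downscales, geom, inter,
                       mode = model$pool_mode, warn_oov = FALSE)$feat
      state <- denoise_step(model$net, state, cond, sched)
    }
    dvf <- scale * state$x
    list(dvf = dvf, shift = shift,
         cloud_pred = sweep(cloud_ref + dvf, 2, shift, "+"))
  })
}

# transpose of the neighbor-mean operator (scatter form)
neighbor_mean_t <- function(x, graph) {
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(graph))) {
    agg <- rowsum(x, group = graph[, j])
    ids <- as.integer(rownames(agg))
    out[ids, ] <- out[ids, ] + agg
  }
  out / ncol(graph)
}

#' Train the conditional point-cloud diffusion model
#'
#' Stochastic training of the noise predictor with the composite objective:
#' at each step a sample, a timestep and a noise draw are taken; the clean
#' state is the normalized deformable residual
#' `x0 = (X_tar - X_ref - shift) / scale` with the shift predicted by the
#' frozen rigid model; condition features are pooled at the intermediate cloud
#' `ref + scale * x_t + shift`; the loss combines the denoising MSE with the
#' SI-weighted similarity, Laplacian and deformation-energy terms evaluated on
#' the cloud reconstructed from the implied
#' `x0_hat = (x_t - sqrt(1-alpha_bar) eps_hat) / sqrt(alpha_bar)`. The
#' network and its pooling backbone are updated jointly by Adam.
#'
#' @param dataset list of samples, each a list with `cloud_ref`, `cloud_tar`
#'   (N x 3 mm), `proj`, `geom`.
#' @param rigid_model frozen [train_rigid()] model, or NULL (no-rigid
#'   ablation: the shift is zero and the diffusion must absorb translations).
#' @param sched a [make_schedule()].
#' @param weights a [loss_weights()] list.
#' @param steps number of optimization steps.
#' @param scale DVF normalization scale (mm; default 10).
#' @param hidden,grid point-voxel network size.
#' @param backbone a [backbone_config()] for the jointly trained feature
#'   extractor.
#' @param pool_mode "geometry" or "global" (the no-geometry ablation).
#' @param lr,batch_size Adam learning rate and gradient-accumulation batch.
#' @param k_neighbors neighbor count of the regularization graph.
#' @param seed integer seed (training is deterministic given the seed).
#' @param verbose print progress every 200 steps.
#' @return object of class `diffusion_model` with the trained `net`,
#'   `backbone`, `sched`, `scale`, `pool_mode` and a `loss_log` data frame
#'   (step, noise, sim, lap, eng, total).
#' @export
train_diffusion <- function(dataset, rigid_model, sched,
                            weights = loss_weights(), steps = 2000,
                            scale = 10, hidden = 32, grid = 16,
                            backbone = tiny_backbone_config(),
                            pool_mode = "geometry", lr = 1e-3,
                            batch_size = 4, k_neighbors = 8, seed = 1L,
                            verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  pool_mode <- match.arg(pool_mode, c("geometry", "global"))
  feat_dim <- sum(backbone$stack_channels)
  n <- nrow(dataset[[1]]$cloud_ref)
  graph <- knn_graph(dataset[[1]]$cloud_ref, k = k_neighbors)
  # frozen rigid predictions, one per sample
  shifts <- lapply(dataset, function(s) {
    if (is.null(rigid_model)) c(0, 0, 0) else
      rigid_shift_from_projection(rigid_model, s$cloud_ref, s$proj, s$geom)
  })
  with_seed(seed, {
    bb <- init_backbone(backbone, seed = stats::runif(1, 1, 1e6))
    net <- init_pvcnn(3 + feat_dim, hidden = hidden, grid = grid,
                      with_time = TRUE, seed = stats::runif(1, 1, 1e6))
    params <- list(net = net$params, bb = bb$params)
    opt <- adam_init(params)
    acc <- NULL; acc_n <- 0L
    log <- matrix(0, steps, 5)
    siw <- weights$si_weight
    for (step in seq_len(steps)) {
      i <- sample.int(length(dataset), 1)
      s <- dataset[[i]]
      shift <- shifts[[i]]
      t <- sample.int(sched$T, 1)
      eps <- matrix(stats::rnorm(3 * n), n, 3)
      x0 <- sweep(s$cloud_tar - s$cloud_ref, 2, shift) / scale
      ab <- sched$alpha_bar[t]
      xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
      inter <- sweep(s$cloud_ref + scale * xt, 2, shift, "+")
      bf <- backbone_fwd(bb, s$proj)
      pf <- pool_fwd(bf$maps, bb$config$stack_downscales, s$geom, inter,
                     mode = pool_mode, warn_oov = FALSE)
      fw <- pvcnn_fwd(net, cbind(xt, pf$feat), t)
      eps_hat <- fw$y
      # losses on the reconstructed clean state
      x0_hat <- (xt - sqrt(1 - ab) * eps_hat) / sqrt(ab)
      cloud_hat <- sweep(s$cloud_ref + scale * x0_hat, 2, shift, "+")
      l_noise <- mean((eps_hat - eps)^2)
      l_sim <- weighted_mse(cloud_hat, s$cloud_tar, siw)
      l_lap <- laplacian_loss(s$cloud_ref, cloud_hat, graph)
      dvf_pred <- scale * x0_hat
      l_eng <- energy_loss(dvf_pred, graph)
      l_tot <- total_loss(list(noise = l_noise, sim = l_sim, lap = l_lap,
                               eng = l_eng), weights)
      log[step, ] <- c(l_noise, l_sim, l_lap, l_eng, l_tot)
      # gradient wrt eps_hat
      d_eps <- 2 * (eps_hat - eps) / (3 * n)
      dd <- cloud_hat - s$cloud_tar
      d_cloud <- weights$lambda_sim * 2 / n *
        cbind(dd[, 1], dd[, 2], siw * dd[, 3])
      if (weights$lambda_lap > 0) {
        v <- cloud_hat - s$cloud_ref
        lv <- v - neighbor_mean(v, graph)
        d_cloud <- d_cloud + weights$lambda_lap * 2 / n *
          (lv - neighbor_mean_t(lv, graph))
      }
      if (weights$lambda_eng > 0) {
        d_cloud <- d_cloud + weights$lambda_eng / n *
          (2 * dvf_pred - neighbor_mean(dvf_pred, graph) -
             neighbor_mean_t(dvf_pred, graph))
      }
      d_eps <- d_eps - d_cloud * (scale * sqrt(1 - ab) / sqrt(ab))
      bk <- pvcnn_bwd(net, fw$cache, d_eps)
      dfeat <- bk$dx[, -(1:3), drop = FALSE]
      dmaps <- pool_bwd(pf$cache, dfeat)
      gbb <- backbone_bwd(bb, bf$caches, dmaps)
      g <- list(net = bk$grad, bb = gbb)
      acc <- if (is.null(acc)) g else tree_add(acc, g)
      acc_n <- acc_n + 1L
      if (acc_n == batch_size || step == steps) {
        # linear learning-rate decay to 10% settles the final iterates
        lr_t <- lr * (1 - 0.9 * step / steps)
        st <- adam_step(params, tree_clip(tree_scale(acc, 1 / acc_n), 5),
                          opt, lr = lr_t)
        params <- st$params; opt <- st$state
        net$params <- params$net; bb$params <- params$bb
        acc <- NULL; acc_n <- 0L
      }
      if (verbose && step %% 200 == 0)
        message(sprintf("step %d: L_total %.4f (noise %.4f sim %.2f)",
                        step, l_tot, l_noise, l_sim))
    }
    structure(list(net = net, backbone = bb, sched = sched, scale = scale,
                   pool_mode = pool_mode, weights = weights,
                   loss_log = data.frame(step = seq_len(steps),
                                         noise = log[, 1], sim = log[, 2],
                                         lap = log[, 3], eng = log[, 4],
                                         total = log[, 5]),
                   seed = seed),
              class = "diffusion_model")
  })
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("Conditional point-cloud diffusion model: T = %d, scale %.1f mm, %s pooling\n",
              x$sched$T, x$scale, x$pool_mode))
  n <- nrow(x$loss_log)
  cat(sprintf("  trained %d steps; final L_total (last 10%%) = %.4f\n", n,
              mean(x$loss_log$total[max(1, floor(0.9 * n)):n])))
  invisible(x)
}
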