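# Diffusion training: capacity, determinism, descent, and ablation contracts.

diffusion_fixture <- function(seed = 4, n_nodes = 24) {
  ph <- tiny_phantom(seed = seed, grid = 24, spacing = 8,
                     n_nodes = n_nodes)
  g <- tiny_geometry(0, cols = 32, rows = 24, pitch = 9)
  proj <- simulate_drr(ph$volume, g, ph$spacing)
  # a smooth (constant) target field: the capacity smoke test checks that
  # the optimizer can drive the denoising loss down on a learnable sample
  dvf <- matrix(c(3, -2, 4), n_nodes, 3, byrow = TRUE)
  list(phantom = ph, geom = g, proj = proj,
       dataset = list(list(cloud_ref = ph$liver_cloud,
                           cloud_tar = ph$liver_cloud + dvf,
                           proj = proj, geom = g)))
}

micro_bb <- function() backbone_config(channels = c(4, 8),
                                       strides = c(2, 2),
                                       include_input = TRUE)

test_that("diffusion training overfits one sample and its loss descends", {
  fx <- diffusion_fixture()
  sched <- make_schedule(40)
  expect_error(train_diffusion(list(), NULL, sched), "empty")
  dm <- train_diffusion(fx$dataset, NULL, sched, steps = 3000,
                        scale = 10, hidden = 16, grid = 4,
                        backbone = micro_bb(), lr = 8e-3,
                        k_neighbors = 6, seed = 9)
  n <- nrow(dm$loss_log)
  late <- dm$loss_log[floor(0.9 * n):n, ]
  early <- dm$loss_log[1:ceiling(0.1 * n), ]
  expect_lt(mean(late$noise), 0.05)
  expect_lt(mean(late$total), mean(early$total))
})

test_that("diffusion training is deterministic given the seed", {
  fx <- diffusion_fixture()
  sched <- make_schedule(20)
  d1 <- train_diffusion(fx$dataset, NULL, sched, steps = 40, hidden = 8,
                        grid = 4, backbone = micro_bb(),
                        k_neighbors = 6, seed = 13)
  d2 <- train_diffusion(fx$dataset, NULL, sched, steps = 40, hidden = 8,
                        grid = 4, backbone = micro_bb(),
                        k_neighbors = 6, seed = 13)
  expect_identical(d1$loss_log, d2$loss_log)
  expect_identical(d1$net$params$head, d2$net$params$head)
})

test_that("training loss gradients are consistent with finite differences", {
  # one full composite-loss step, differentiated against a numeric probe of
  # the head bias (chosen because it influences every loss term)
  fx <- diffusion_fixture(n_nodes = 12)
  sched <- make_schedule(10)
  graph <- knn_graph(fx$dataset[[1]]$cloud_ref, 4)
  w <- loss_weights()
  bb <- init_backbone(micro_bb(), seed = 1)
  feat_dim <- sum(micro_bb()$stack_channels)
  net <- init_pvcnn(3 + feat_dim, hidden = 8, grid = 4, with_time = TRUE,
                    seed = 2)
  s <- fx$dataset[[1]]
  n <- 12; t <- 5; scale <- 10
  set.seed(3)
  eps <- matrix(rnorm(36), n, 3)
  x0 <- (s$cloud_tar - s$cloud_ref) / scale
  ab <- sched$alpha_bar[t]
  xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
  inter <- s$cloud_ref + scale * xt
  bf <- pcdtrack:::backbone_fwd(bb, s$proj)
  cond <- pcdtrack:::pool_fwd(bf$maps, bb$config$stack_downscales, s$geom,
                              inter, "geometry", warn_oov = FALSE)$feat
  loss_of <- function(nn) {
    eh <- pvcnn_forward(nn, cbind(xt, cond), t)
    x0h <- (xt - sqrt(1 - ab) * eh) / sqrt(ab)
    ch <- s$cloud_ref + scale * x0h
    total_loss(list(noise = mean((eh - eps)^2),
                    sim = weighted_mse(ch, s$cloud_tar, w$si_weight),
                    lap = laplacian_loss(s$cloud_ref, ch, graph),
                    eng = energy_loss(scale * x0h, graph)), w)
  }
  # analytic gradient of the composite loss wrt eps_hat, pushed through the
  # network head bias
  fw <- pcdtrack:::pvcnn_fwd(net, cbind(xt, cond), t)
  eh <- fw$y
  x0h <- (xt - sqrt(1 - ab) * eh) / sqrt(ab)
  ch <- s$cloud_ref + scale * x0h
  d_eps <- 2 * (eh - eps) / (3 * n)
  dd <- ch - s$cloud_tar
  d_cloud <- w$lambda_sim * 2 / n *
    cbind(dd[, 1], dd[, 2], w$si_weight * dd[, 3])
  v <- ch - s$cloud_ref
  lv <- v - pcdtrack:::neighbor_mean(v, graph)
  d_cloud <- d_cloud + w$lambda_lap * 2 / n *
    (lv - pcdtrack:::neighbor_mean_t(lv, graph))
  dvf_pred <- scale * x0h
  d_cloud <- d_cloud + w$lambda_eng / n *
    (2 * dvf_pred - pcdtrack:::neighbor_mean(dvf_pred, graph) -
       pcdtrack:::neighbor_mean_t(dvf_pred, graph))
  d_eps <- d_eps - d_cloud * (scale * sqrt(1 - ab) / sqrt(ab))
  bk <- pcdtrack:::pvcnn_bwd(net, fw$cache, d_eps)
  eps_fd <- 1e-6
  for (i in 1:3) {
    n1 <- net; n1$params$head$b[i] <- eps_fd
    n2 <- net; n2$params$head$b[i] <- -eps_fd
    fd <- (loss_of(n1) - loss_of(n2)) / (2 * eps_fd)
    expect_equal(unname(bk$grad$head$b[i]), unname(fd),
                 tolerance = 1e-5)
  }
})

test_that("global pooling keeps the condition width (no-geometry ablation)", {
  fx <- diffusion_fixture()
  sched <- make_schedule(10)
  dm <- train_diffusion(fx$dataset, NULL, sched, steps = 10, hidden = 8,
                        grid = 4, backbone = micro_bb(),
                        pool_mode = "global", k_neighbors = 6, seed = 1)
  expect_equal(dm$pool_mode, "global")
  expect_equal(dm$net$in_dim, 3L + sum(micro_bb()$stack_channels))
  # sampling with the global-pooling model works end to end
  out <- sample_dvf(dm, NULL, fx$phantom$liver_cloud, fx$proj, fx$geom,
                    seed = 2)
  expect_equal(dim(out$dvf), c(24L, 3L))
})
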