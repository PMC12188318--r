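test_that("variance schedules match the sequential product oracle", {
  s1 <- make_schedule(1, 0.5, 0.5)
  expect_equal(s1$alpha_bar, 0.5)
  s0 <- make_schedule(50, 0, 0)
  expect_true(all(s0$alpha_bar == 1))
  s <- make_schedule(1000, 1e-4, 0.02)
  prod <- 1
  for (t in 1:1000) prod <- prod * (1 - s$beta[t])
  expect_equal(s$alpha_bar[1000], prod, tolerance = 1e-12)
  expect_true(all(diff(s$alpha_bar) <= 0))
  expect_error(make_schedule(10, 0.5, 0.1), "beta")
  expect_error(make_schedule(10, -0.1, 0.5), "beta")
})

test_that("forward noising follows the closed form", {
  set.seed(1)
  x0 <- matrix(rnorm(30), 10, 3)
  eps <- matrix(rnorm(30), 10, 3)
  s0 <- make_schedule(20, 0, 0)
  for (t in c(1, 10, 20))
    expect_equal(forward_noise(x0, t, eps, s0)$x, x0)
  # alpha_bar = 0.25: x0 = 0, eps = 1 -> every entry sqrt(0.75)
  s <- make_schedule(1, 0.75, 0.75)
  xt <- forward_noise(matrix(0, 4, 3), 1, matrix(1, 4, 3), s)$x
  expect_equal(xt, matrix(sqrt(0.75), 4, 3), tolerance = 1e-12)
  expect_error(forward_noise(x0, 0, eps, s), "range")
  expect_error(forward_noise(x0, 2, eps, s), "range")
  expect_error(forward_noise(x0, 1, eps[1:3, ], s), "shape")
})

test_that("forward-noise variance matches 1 - alpha_bar (Monte Carlo)", {
  s <- make_schedule(100, 1e-3, 0.05)
  set.seed(2)
  for (t in c(30, 100)) {
    eps <- matrix(rnorm(1e5 * 3), 1e5, 3)
    xt <- forward_noise(matrix(0, 1e5, 3), t, eps, s)$x
    expect_equal(var(as.numeric(xt)), 1 - s$alpha_bar[t], tolerance = 0.02)
  }
})

test_that("exact inversion with the true noise recovers x0 at every t", {
  s <- make_schedule(50, 1e-3, 0.04)
  set.seed(3)
  x0 <- matrix(rnorm(24), 8, 3)
  for (t in c(1, 17, 50)) {
    eps <- matrix(rnorm(24), 8, 3)
    xt <- forward_noise(x0, t, eps, s)$x
    rec <- (xt - sqrt(1 - s$alpha_bar[t]) * eps) / sqrt(s$alpha_bar[t])
    expect_lt(max(abs(rec - x0)), 1e-10)
  }
})

test_that("single-step transitions compose to the closed-form marginal", {
  # q(x_t | x_{t-1}) steps chained numerically vs q(x_t | x_0) moments
  s <- make_schedule(5, 0.05, 0.2)
  set.seed(4)
  n <- 2e4
  x <- matrix(2, n, 1)    # x0 = 2 for every chain
  for (t in 1:5)
    x <- sqrt(1 - s$beta[t]) * x + sqrt(s$beta[t]) * matrix(rnorm(n), n, 1)
  mu_expect <- sqrt(s$alpha_bar[5]) * 2
  var_expect <- 1 - s$alpha_bar[5]
  se_mu <- sqrt(var_expect / n)
  expect_lt(abs(mean(x) - mu_expect), 3 * se_mu)
  se_var <- var_expect * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.numeric(x)) - var_expect), 3 * se_var)
})

# a network whose output is a constant row (head bias), all else zero
constant_net <- function(value, in_dim, hidden = 8, grid = 4) {
  net <- init_pvcnn(in_dim, hidden = hidden, grid = grid, with_time = TRUE,
                    seed = 1)
  net$params <- pcdtrack:::tree_zero(net$params)
  net$params$head$b <- value
  net
}

test_that("denoise_step is a no-op for zero noise prediction and zero beta", {
  n <- 6
  net0 <- constant_net(c(0, 0, 0), 3)
  s0 <- make_schedule(10, 0, 0)
  set.seed(5)
  x <- matrix(rnorm(n * 3), n, 3)
  out <- denoise_step(net0, list(x = x, t = 5L),
                      matrix(0, n, 0), s0)
  expect_equal(out$x, x, tolerance = 1e-12)
  expect_equal(out$t, 4L)
  expect_error(denoise_step(net0, list(x = x, t = 0L), NULL, s0), "t >= 1")
})

test_that("a one-step chain with the true constant noise inverts exactly", {
  # T = 1: x1 = sqrt(a) x0 + sqrt(1-a) eps with constant eps rows; a model
  # predicting exactly that eps recovers x0 algebraically at t = 1
  s <- make_schedule(1, 0.3, 0.3)
  eps_row <- c(0.7, -0.4, 1.1)
  net <- constant_net(eps_row, 3)
  set.seed(6)
  x0 <- matrix(rnorm(15), 5, 3)
  eps <- matrix(eps_row, 5, 3, byrow = TRUE)
  x1 <- forward_noise(x0, 1, eps, s)$x
  out <- denoise_step(net, list(x = x1, t = 1L), matrix(0, 5, 0), s)
  expect_equal(out$x, x0, tolerance = 1e-10)
})

test_that("denoising chains are reproducible for a fixed seed", {
  ph <- tiny_phantom(n_nodes = 40)
  g <- tiny_geometry(0)
  proj <- simulate_drr(ph$volume, g, ph$spacing)
  # minimal "trained" diffusion model assembled by hand (zero weights) to
  # test the sampling loop contract without a training run
  sched <- make_schedule(8, 1e-3, 0.05)
  bb <- init_backbone(tiny_backbone_config(), seed = 2)
  net <- init_pvcnn(3 + 56, hidden = 8, grid = 4, with_time = TRUE,
                    seed = 3)
  model <- structure(list(net = net, backbone = bb, sched = sched,
                          scale = 10, pool_mode = "geometry"),
                     class = "diffusion_model")
  r1 <- sample_dvf(model, NULL, ph$liver_cloud, proj, g, seed = 9)
  r2 <- sample_dvf(model, NULL, ph$liver_cloud, proj, g, seed = 9)
  expect_identical(r1$dvf, r2$dvf)
  expect_equal(dim(r1$dvf), c(40L, 3L))
  expect_true(all(is.finite(r1$dvf)))
  expect_equal(r1$shift, c(0, 0, 0))
  r3 <- sample_dvf(model, NULL, ph$liver_cloud, proj, g, seed = 10)
  expect_false(isTRUE(all.equal(r1$dvf, r3$dvf)))
})
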