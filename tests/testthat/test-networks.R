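test_that("encoder and decoder honour their shape contracts in both modes", {
  for (mode in c("conv2d", "conv3d")) {
    m <- tiny_model(mode)
    x <- if (mode == "conv2d") tiny_frame() else tiny_volume()
    e <- encode(m, x)
    expect_length(e$features, m$cfg$g_dim)
    expect_identical(encode(m, x)$features, e$features)  # deterministic
    y <- decode(m, e$features, e$skips)
    expect_identical(dim(y), dim(x))
    expect_true(all(y > 0 & y < 1))  # sigmoid range
    expect_error(encode(m, if (mode == "conv2d") matrix(0, 5, 5)
                          else array(0, c(2, 5, 5))), "shape")
  }
  # full-size encoder emits the configured 128-dim feature vector
  big <- tvae_model(image_size = 64, base_channels = 4, lstm_hidden = 8,
                    seed = 1)
  expect_length(encode(big, matrix(0.5, 64, 64))$features, 128)
})

test_that("skip connections are live paths into the decoder", {
  m <- tiny_model()
  e <- encode(m, tiny_frame())
  y1 <- decode(m, e$features, e$skips)
  dead <- lapply(e$skips, function(s) if (is.null(s)) NULL else s * 0)
  y2 <- decode(m, e$features, dead)
  expect_gt(max(abs(y1 - y2)), 1e-6)
})

test_that("prior, inference and predictor steps follow their step contracts", {
  m <- tiny_model()
  x <- tiny_frame()
  st <- tvae_state(m)
  pr <- prior_step(m, x, st)
  expect_s3_class(pr$dist, "latent_distribution")
  expect_length(pr$dist$mean, m$cfg$z_dim)
  expect_length(pr$dist$log_variance, m$cfg$z_dim)
  expect_identical(prior_step(m, x, st)$dist, pr$dist)
  po <- inference_step(m, x, st)
  expect_length(po$dist$mean, m$cfg$z_dim)
  # the posterior mean is the prior mean plus the inference correction
  expect_equal(inference_step(m, x, st, prior_mean = pr$dist$mean)$dist$mean,
               po$dist$mean + pr$dist$mean)
  # posterior responds to its input (the correction head starts at zero, so
  # give it weights before probing the wiring)
  mr <- m
  set.seed(1)
  mr$params[["inf.out.W"]][] <- rnorm(length(mr$params[["inf.out.W"]]), sd = 0.01)
  po1 <- inference_step(mr, x, st)
  po2 <- inference_step(mr, x + 0.05, st)
  expect_gt(max(abs(po2$dist$mean - po1$dist$mean)), 0)
  # different accumulated histories change the prior
  stA <- prior_step(m, tiny_frame(1), tvae_state(m))$state
  stB <- prior_step(m, tiny_frame(2), tvae_state(m))$state
  prA <- prior_step(m, x, stA)$dist
  prB <- prior_step(m, x, stB)$dist
  expect_gt(max(abs(prA$mean - prB$mean)), 0)
  expect_error(prior_step(m, x, list()), "tvae_state")
  ps <- predictor_step(m, x, rnorm(m$cfg$z_dim), st)
  expect_identical(dim(ps$frame), dim(x))
  expect_true(all(ps$frame > 0 & ps$frame < 1))
  z1 <- rep(0, m$cfg$z_dim); z2 <- rep(2, m$cfg$z_dim)
  f1 <- predictor_step(m, x, z1, st)$frame
  f2 <- predictor_step(m, x, z2, st)$frame
  expect_gt(max(abs(f1 - f2)), 1e-8)  # latent is a live path
  expect_identical(predictor_step(m, x, z1, st)$frame, f1)
  expect_error(predictor_step(m, x, rnorm(7), st), "z_dim")
})

test_that("the inference model refuses to run in generation phase", {
  m <- tiny_model()
  model_phase(m) <- "generate"
  expect_error(inference_step(m, tiny_frame(), tvae_state(m)), "generation")
  model_phase(m) <- "train"
  expect_silent(inference_step(m, tiny_frame(), tvae_state(m)))
})

test_that("reparameterized sampling is correct and reproducible", {
  d <- latent_distribution(c(1, -2, 0.5), c(-40, -40, -40))
  expect_equal(sample_latent(d), d$mean, tolerance = 1e-8)
  expect_identical(sample_latent(d, seed = 4), sample_latent(d, seed = 4))
  d2 <- latent_distribution(rep(0.3, 4), rep(log(0.25), 4))
  set.seed(99)
  draws <- matrix(0, 1e5, 4)
  for (i in 1:1e5) draws[i, ] <- sample_latent(d2)
  se <- 0.5 / sqrt(1e5)
  expect_true(all(abs(colMeans(draws) - 0.3) < 4 * se))
  expect_true(all(abs(apply(draws, 2, sd) - 0.5) < 0.01))
})

test_that("teacher-forced forward pass is causal and well-formed", {
  m <- tiny_model()
  frames <- lapply(1:4, tiny_frame)
  ft <- forward_train(m, frames, seed = 5)
  expect_length(ft$predictions, 3)
  expect_length(ft$priors, 3)
  expect_length(ft$posteriors, 3)
  for (p in ft$predictions) expect_true(all(p > 0 & p < 1))
  # causality: replacing future frames leaves earlier priors untouched
  frames2 <- frames
  frames2[[4]] <- tiny_frame(99)
  ft2 <- forward_train(m, frames2, seed = 5)
  for (t in 1:2) {
    expect_identical(ft$priors[[t]], ft2$priors[[t]])
    expect_identical(ft$posteriors[[t]], ft2$posteriors[[t]])
    expect_identical(ft$predictions[[t]], ft2$predictions[[t]])
  }
  expect_error(forward_train(m, frames[1]), "at least 2")
})

test_that("training and generation paths coincide when latents are shared", {
  m <- tiny_model()
  frames <- lapply(1:4, tiny_frame)
  ft <- forward_train(m, frames, seed = 11, latent_source = "prior")
  gen <- forward_generate(m, frames[1:3], n_future = 1, seed = 11)
  expect_equal(ft$predictions[[3]], gen[[1]], tolerance = 1e-12)
})

test_that("generation is stochastic across seeds yet reproducible", {
  m <- tiny_model()
  ctx <- lapply(1:3, tiny_frame)
  g1 <- forward_generate(m, ctx, n_future = 1, seed = 1)
  g2 <- forward_generate(m, ctx, n_future = 1, seed = 2)
  g1b <- forward_generate(m, ctx, n_future = 1, seed = 1)
  expect_length(g1, 1)
  expect_identical(dim(g1[[1]]), c(16L, 16L))
  expect_identical(g1, g1b)
  expect_gt(max(abs(g1[[1]] - g2[[1]])), 0)
  g3 <- forward_generate(m, ctx, n_future = 3, seed = 1)
  expect_length(g3, 3)
  # mean-latent generation is deterministic without a seed
  expect_identical(forward_generate(m, ctx, 1, sample = "mean"),
                   forward_generate(m, ctx, 1, sample = "mean"))
})

test_that("conv3d sequences satisfy the same forward contracts", {
  m <- tiny_model("conv3d")
  vols <- lapply(1:4, tiny_volume)
  ft <- forward_train(m, vols, seed = 3)
  expect_length(ft$predictions, 3)
  expect_identical(dim(ft$predictions[[1]]), c(8L, 16L, 16L))
  gen <- forward_generate(m, vols[1:3], 1, seed = 3)
  expect_identical(dim(gen[[1]]), c(8L, 16L, 16L))
})

test_that("parameter shapes are a pure function of the configuration", {
  a <- tvae_model(image_size = 32, z_dim = 5, g_dim = 24, base_channels = 4,
                  lstm_hidden = 16, seed = 1)
  b <- tvae_model(image_size = 32, z_dim = 5, g_dim = 24, base_channels = 4,
                  lstm_hidden = 16, seed = 2)
  expect_identical(names(a$params), names(b$params))
  expect_identical(lapply(a$params, dim), lapply(b$params, dim))
  expect_identical(sum(vapply(a$params, length, 0L)), 29757L)
  expect_false(identical(a$params, b$params))  # seeds differ
})

test_that("analytic gradients match finite differences end to end", {
  pk <- asNamespace("tvae")
  set.seed(42)
  m <- tiny_model(seed = 7)
  xs <- lapply(1:3, function(t) array(runif(2 * 256), c(2, 16, 16, 1)))
  eps <- pk$draw_eps_list(2, 3, 2:3)
  wm <- array(runif(2 * 256, 1, 2), c(2, 16, 16, 1))
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    pk$loss_only(pk$fw_seq(mm, xs, eps, "posterior"), xs, wm, 1e-2)$total
  }
  fw <- pk$fw_seq(m, xs, eps, "posterior")
  lg <- pk$loss_and_grads(m, fw, xs, wm, 1e-2)
  h <- 1e-8
  for (nm in sample(names(m$params), 12)) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
    num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    ana <- lg$grads[[nm]][i]
    expect_lt(abs(num - ana) / (abs(num) + abs(ana) + 1e-6), 0.02)
  }
})

test_that("checkpoints restore bit-exact generation", {
  m <- tiny_model()
  ctx <- lapply(1:3, tiny_frame)
  f <- tempfile(fileext = ".rds")
  save_tvae(m, f)
  m2 <- load_tvae(f)
  expect_identical(forward_generate(m, ctx, 1, seed = 6),
                   forward_generate(m2, ctx, 1, seed = 6))
})
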