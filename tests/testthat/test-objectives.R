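test_that("reconstruction loss matches its closed forms", {
  a <- matrix(runif(64), 8)
  expect_identical(reconstruction_loss(a, a), 0)
  b <- a + 0.1
  expect_equal(reconstruction_loss(b, a), 0.01)
  preds <- list(a, b); gts <- list(a + 0.05, a)
  expect_gte(reconstruction_loss(preds, gts), 0)
  expect_equal(reconstruction_loss(preds, gts),
               mean((preds[[1]] - gts[[1]])^2) + mean((preds[[2]] - gts[[2]])^2))
  expect_error(reconstruction_loss(a, matrix(0, 4, 4)), "shape")
})

test_that("gaussian KL matches identities and stays non-negative", {
  d0 <- latent_distribution(rep(0, 10), rep(0, 10))
  expect_equal(gaussian_kl(d0, d0), 0)
  d1 <- latent_distribution(rep(1, 10), rep(0, 10))
  expect_equal(gaussian_kl(d1, d0), 5)  # mu^2/2 per dimension
  set.seed(31)
  for (i in 1:25) {
    q <- latent_distribution(rnorm(10, sd = 0.5), runif(10, -1, 1))
    p <- latent_distribution(rnorm(10, sd = 0.5), runif(10, -1, 1))
    expect_gte(gaussian_kl(q, p), 0)
  }
  expect_error(gaussian_kl(d0, latent_distribution(rep(0, 3), rep(0, 3))),
               "dimension")
  expect_error(latent_distribution(0, Inf), "finite")
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  set.seed(5)
  pair <- random_gaussian_pair(10)
  expect_lt(abs(gaussian_kl(pair$q, pair$p) -
                  mc_gaussian_kl(pair$q, pair$p, 1e5)), 0.01)
})

test_that("the edge mask is a truncated-Gaussian blur with mass conservation", {
  z <- matrix(0, 32, 32)
  expect_true(all(build_edge_mask(z, 5) == 0))
  expect_error(build_edge_mask(z, 0), "sigma")
  # single bright pixel reproduces the (normalized) separable kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  m <- build_edge_mask(imp, 2)
  k <- dnorm(-8:8, sd = 2); k <- k / sum(k)
  expect_lt(max(abs(m[13:29, 13:29] - outer(k, k))), 1e-12)
  # mass conservation away from borders (reflective boundary)
  set.seed(8)
  x <- matrix(0, 32, 32)
  x[10:22, 10:22] <- runif(169)
  expect_lt(abs(sum(build_edge_mask(x, 2)) - sum(x)) / sum(x), 0.01)
})

test_that("the edge mask is linear and commutes with horizontal flips", {
  set.seed(12)
  a <- matrix(runif(24 * 24, 0, 0.4), 24)
  b <- matrix(runif(24 * 24, 0, 0.4), 24)
  ga <- unclass(build_edge_mask(a, 3)); gb <- unclass(build_edge_mask(b, 3))
  expect_lt(max(abs(unclass(build_edge_mask(a + b, 3)) - (ga + gb))), 1e-12)
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_lt(max(abs(unclass(build_edge_mask(flip(a), 3)) - flip(ga))), 1e-12)
})

test_that("edge-aware loss degenerates to and dominates the plain MSE", {
  set.seed(3)
  pred <- matrix(runif(256), 16); gt <- matrix(runif(256), 16)
  mask <- build_edge_mask(gt, 2)
  expect_identical(edge_aware_loss(pred, gt, mask, lambda_weight = 0),
                   reconstruction_loss(pred, gt))
  ones <- structure(matrix(1, 16, 16), class = c("edge_mask", "matrix"))
  expect_equal(edge_aware_loss(pred, gt, ones, lambda_weight = 1),
               2 * reconstruction_loss(pred, gt))
  expect_identical(edge_aware_loss(gt, gt, mask), 0)
  for (lam in c(0, 0.3, 1))
    expect_gte(edge_aware_loss(pred, gt, mask, lam),
               reconstruction_loss(pred, gt) - 1e-14)
  expect_equal(edge_aware_loss(pred, gt, ones, 1, exponent = 1),
               2 * mean(abs(pred - gt)))
  expect_error(edge_aware_loss(pred, gt, mask, -1), "non-negative")
})

test_that("total loss combines the terms with the default KL weight", {
  tl <- total_loss(1.0, 100.0, 0.0001)
  expect_equal(tl$total, 1.01)
  expect_equal(total_loss(0.5, 0)$total, 0.5)
  expect_equal(total_loss(0.5, 123, beta_kl = 0)$total, 0.5)
  expect_equal(total_loss(2, 3)$total, 2 + 1e-4 * 3)
})

test_that("loss gradients match finite differences", {
  # edge-aware gradient wrt a prediction pixel
  set.seed(6)
  pred <- matrix(runif(64), 8); gt <- matrix(runif(64), 8)
  w <- matrix(runif(64, 0, 1), 8)
  mask <- structure(w, class = c("edge_mask", "matrix"))
  lam <- 0.7
  ana <- 2 * (1 + lam * w[3, 5]) * (pred[3, 5] - gt[3, 5]) / 64
  h <- 1e-7
  pp <- pred; pp[3, 5] <- pp[3, 5] + h
  pm <- pred; pm[3, 5] <- pm[3, 5] - h
  num <- (edge_aware_loss(pp, gt, mask, lam) -
            edge_aware_loss(pm, gt, mask, lam)) / (2 * h)
  expect_lt(abs(ana - num), 1e-6)
  # KL gradient wrt a posterior mean coordinate
  q <- latent_distribution(rnorm(5), runif(5, -1, 1))
  p <- latent_distribution(rnorm(5), runif(5, -1, 1))
  ana_kl <- (q$mean[2] - p$mean[2]) / exp(p$log_variance[2])
  qp <- q; qp$mean[2] <- qp$mean[2] + h
  qm <- q; qm$mean[2] <- qm$mean[2] - h
  num_kl <- (gaussian_kl(qp, p) - gaussian_kl(qm, p)) / (2 * h)
  expect_lt(abs(ana_kl - num_kl), 1e-5)
})
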