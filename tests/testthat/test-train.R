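small_training_set <- function(n = 8, seed = 1) {
  p <- small_phantom(lesion_prevalence = 1, lesion_onset_week = 2,
                     marrow_ar1 = 1, lesion_angle = 0)
  lapply(seq_len(n), function(i)
    generate_phantom_sequence(p, tvae:::mix_seed(seed, i)))
}

quick_fit <- function(train, epochs = 5, lr = 0.002, seed = 2, ...) {
  tvae(train, base_channels = 4, g_dim = 16, lstm_hidden = 12,
       batch_size = 4, max_epochs = epochs, patience = 50,
       learning_rate = lr, seed = seed, verbose = FALSE, ...)
}

test_that("a short fit reduces the training loss on learnable phantoms", {
  fit <- quick_fit(small_training_set(), epochs = 5)
  expect_s3_class(fit, "tvae")
  expect_lt(fit$history$train_total[5], fit$history$train_total[1])
  expect_identical(nrow(fit$history), 5L)
})

test_that("a zero learning rate leaves the weights untouched", {
  train <- small_training_set()
  set.seed(77)
  m0 <- tvae_model(image_size = 32, z_dim = 3, g_dim = 16, base_channels = 4,
                   lstm_hidden = 12, seed = 5)
  fit <- quick_fit(train, epochs = 2, lr = 0, model = m0)
  expect_identical(fit$model$params, m0$params)
})

test_that("identical seed, config and data give bit-identical fits", {
  train <- small_training_set()
  f1 <- quick_fit(train, epochs = 3, seed = 9)
  f2 <- quick_fit(train, epochs = 3, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- quick_fit(train, epochs = 3, seed = 10)
  expect_false(identical(f1$history, f3$history))
})

test_that("early stopping returns the best-validation checkpoint", {
  train <- small_training_set(10)
  fit <- tvae(train, base_channels = 4, g_dim = 16, lstm_hidden = 12,
              batch_size = 4, max_epochs = 8, patience = 2, seed = 4)
  expect_equal(fit$best_val, min(fit$history$val_total))
  expect_identical(fit$history$val_total[fit$best_epoch], fit$best_val)
})

test_that("degenerate inputs are rejected", {
  train <- small_training_set(4)
  expect_error(tvae(list()), "empty")
  expect_error(quick_fit(train, epochs = 1, val_fraction = 0.99),
               "too small")
})

test_that("week-4 prediction honours its contract", {
  train <- small_training_set()
  fit <- quick_fit(train, epochs = 2)
  ctx <- train[[1]]$frames[1:3]
  preds <- predict_week4(fit, ctx, n_samples = 6, seed = 3)
  expect_length(preds, 6)
  for (p in preds) {
    expect_identical(dim(p), c(32L, 32L))
    expect_true(all(p > 0 & p < 1))
  }
  expect_identical(predict_week4(fit, ctx, 1, seed = 8),
                   predict_week4(fit, ctx, 1, seed = 8))
  expect_gt(mean_pairwise_mse(preds), 0)  # distinct prior draws differ
  expect_error(predict_week4(fit, ctx[1:2]), "exactly 3")
  # slice_sequence input uses its first three frames
  expect_identical(predict_week4(fit, train[[1]], 1, seed = 8),
                   predict_week4(fit, ctx, 1, seed = 8))
})

test_that("volume prediction stacks per-slice week-4 predictions", {
  train <- small_training_set()
  fit <- quick_fit(train, epochs = 2)
  vols <- lapply(1:3, function(w) {
    v <- array(0, c(4, 32, 32))
    for (d in 1:4) v[d, , ] <- train[[d]]$frames[[w]]
    v
  })
  pv <- predict_volume(fit, vols, seed = 5)
  expect_identical(dim(pv), c(4L, 32L, 32L))
  expect_identical(pv, predict_volume(fit, vols, seed = 5))
  expect_true(all(pv > 0 & pv < 1))
  bad <- vols; bad[[2]] <- bad[[2]][1:3, , ]
  expect_error(predict_volume(fit, bad), "share")
  expect_error(predict_volume(fit, vols[1:2]), "exactly 3")
})

test_that("uncertainty maps count threshold exceedances per pixel", {
  lo <- matrix(0.01, 4, 4); hi <- matrix(0.9, 4, 4)
  expect_true(all(uncertainty_map(list(hi, hi, hi)) == 1))
  expect_true(all(uncertainty_map(list(lo, lo)) == 0))
  mixed <- uncertainty_map(c(replicate(3, hi, simplify = FALSE),
                             replicate(3, lo, simplify = FALSE)))
  expect_true(all(mixed == 0.5))
  expect_error(uncertainty_map(list(hi)), "at least 2")
  expect_error(uncertainty_map(list(hi, lo), nonzero_threshold = 1), "threshold")
  expect_identical(attr(uncertainty_map(list(hi, lo)), "n_samples"), 2L)
})

test_that("fitted-model S3 methods behave like a classed model object", {
  train <- small_training_set()
  fit <- quick_fit(train, epochs = 2)
  expect_output(print(fit), "Temporal VAE")
  expect_output(summary(fit), "Loss")
  expect_type(coef(fit), "list")
  expect_true("enc.conv1.W" %in% names(coef(fit)))
  s4 <- train[[2]]
  pr <- predict(fit, s4, n_samples = 2, seed = 1)
  expect_length(pr, 2)
  sim <- simulate(fit, nsim = 3, seed = 2, context = s4$frames[1:3])
  expect_length(sim, 3)
  res <- residuals(fit, s4)
  expect_identical(dim(res), c(32L, 32L))
  expect_identical(res, s4$frames[[4]] -
                     forward_generate(fit$model, s4$frames[1:3], 1,
                                      sample = "mean")[[1]])
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
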