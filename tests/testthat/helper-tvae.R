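# Shared fixtures and independent oracles, built in code at test time.

# tiny model for contract and gradient tests
tiny_model <- function(mode = "conv2d", seed = 7) {
  tvae_model(image_size = 16, z_dim = 3, g_dim = 8, base_channels = 2,
             lstm_hidden = 6, mode = mode, depth = 8, seed = seed)
}

tiny_frame <- function(seed = 1, n = 16) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

tiny_volume <- function(seed = 1, d = 8, n = 16) {
  set.seed(seed)
  array(runif(d * n * n), c(d, n, n))
}

small_phantom <- function(...) phantom_params(image_size = 32, ...)

mean_pairwise_mse <- function(samples) {
  n <- length(samples)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + mean((samples[[i]] - samples[[j]])^2)
  tot / choose(n, 2)
}

# Monte-Carlo KL oracle: E_q[log q(z) - log p(z)] over n draws from q
mc_gaussian_kl <- function(posterior, prior, n = 1e5) {
  d <- length(posterior$mean)
  sq <- exp(posterior$log_variance / 2)
  z <- sweep(sweep(matrix(rnorm(n * d), n, d), 2, sq, "*"), 2,
             posterior$mean, "+")
  loglik <- function(mu, lv) {
    zc <- sweep(z, 2, mu)
    -0.5 * (rowSums(sweep(zc * zc, 2, exp(lv), "/")) + sum(lv) +
              d * log(2 * pi))
  }
  mean(loglik(posterior$mean, posterior$log_variance) -
         loglik(prior$mean, prior$log_variance))
}

# random diagonal-Gaussian pairs sized so the Monte-Carlo standard error at
# 1e5 samples sits well inside the 0.01 comparison tolerance
random_gaussian_pair <- function(d = 10) {
  list(q = latent_distribution(rnorm(d, sd = 0.1), runif(d, -0.1, 0.1)),
       p = latent_distribution(rnorm(d, sd = 0.1), runif(d, -0.1, 0.1)))
}

# literal windowed-loop SSIM (independent of the package's separable-filter
# implementation): explicit 2D Gaussian window, population moments
ref_ssim <- function(x, y, data_range = 1) {
  k1 <- dnorm(-5:5, sd = 1.5)
  K <- outer(k1, k1)
  K <- K / sum(K)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in 1:(nrow(x) - 10)) for (j in 1:(ncol(x) - 10)) {
    wx <- x[i:(i + 10), j:(j + 10)]
    wy <- y[i:(i + 10), j:(j + 10)]
    mx <- sum(K * wx); my <- sum(K * wy)
    vx <- sum(K * wx * wx) - mx * mx
    vy <- sum(K * wy * wy) - my * my
    cxy <- sum(K * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                      ((mx * mx + my * my + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# independent nearest-neighbour-free bilinear interpolation (direct per-pixel
# evaluation) for cross-checking resize_frame
ref_bilinear <- function(frame, target) {
  n_in <- nrow(frame); m_in <- ncol(frame)
  out <- matrix(0, target, target)
  for (i in 1:target) for (j in 1:target) {
    sr <- min(max((i - 0.5) * n_in / target + 0.5, 1), n_in)
    sc <- min(max((j - 0.5) * m_in / target + 0.5, 1), m_in)
    r0 <- floor(sr); c0 <- floor(sc)
    r1 <- min(r0 + 1, n_in); c1 <- min(c0 + 1, m_in)
    wr <- sr - r0; wc <- sc - c0
    out[i, j] <- (1 - wr) * (1 - wc) * frame[r0, c0] +
      (1 - wr) * wc * frame[r0, c1] +
      wr * (1 - wc) * frame[r1, c0] + wr * wc * frame[r1, c1]
  }
  out
}

# geometry masks for phantom frames (annulus / marrow / background)
phantom_masks <- function(params, slice_index = NULL) {
  n <- params$image_size
  taper <- if (is.null(slice_index)) 1 else
    0.75 + 0.25 * (slice_index - 1) / max(1, params$n_slices - 1)
  outer_r <- params$ring_outer_radius * taper
  inner_r <- outer_r - params$ring_thickness
  r <- sqrt(outer((seq_len(n) - params$ring_center[1])^2,
                  (seq_len(n) - params$ring_center[2])^2, "+"))
  list(annulus = r <= outer_r & r >= inner_r,
       marrow = r < inner_r - 2,
       background = r > params$ring_outer_radius + 3)
}

## study conditions shared by the acceptance tests ---------------------------
# Deterministic dynamics: every subject develops a lesion at week 2 at a
# fixed angle spanning all slices, with frozen marrow texture -- the week-4
# state is a deterministic function of the earlier frames (up to noise).
# Stochastic dynamics: lesions appear only at week 4 in half the subjects at
# a random angle, and the marrow texture carries week-to-week innovations.
acceptance_conditions <- function() {
  list(
    det = phantom_params(image_size = 32, lesion_prevalence = 1,
                         lesion_onset_week = 2, marrow_ar1 = 1,
                         lesion_angle = pi / 2, lesion_band = "full"),
    sto = phantom_params(image_size = 32, lesion_prevalence = 0.5,
                         lesion_onset_week = 4))
}

acceptance_fit <- function(train, seed) {
  tvae(train, base_channels = 16, g_dim = 64, lstm_hidden = 64,
       n_skip_levels = 2, batch_size = 4, max_epochs = 40,
       beta_warmup = 30, noise_warmup = 30, seed = seed)
}

# the two trained models are expensive; memoize them across acceptance tests
.acceptance_env <- new.env(parent = emptyenv())
acceptance_models <- function() {
  if (!is.null(.acceptance_env$models)) return(.acceptance_env$models)
  cond <- acceptance_conditions()
  ds_det <- generate_dataset(cond$det, 64, 0.8, master_seed = 11,
                             slices_per_subject = 4)
  ds_sto <- generate_dataset(cond$sto, 64, 0.8, master_seed = 12,
                             slices_per_subject = 4)
  models <- list(det = list(fit = acceptance_fit(ds_det$train, 2), data = ds_det),
                 sto = list(fit = acceptance_fit(ds_sto$train, 2), data = ds_sto))
  .acceptance_env$models <- models
  models
}
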