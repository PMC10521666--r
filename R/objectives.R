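# Training losses: reconstruction, Gaussian KL against the learned prior,
# the Gaussian-blurred edge mask, the edge-aware weighted reconstruction,
# and the weighted total.
#
# Reduction convention: per-frame mean over pixels, summed over predicted
# time steps (t = 2..T).  This keeps lambda and beta_kl scale-stable across
# image sizes.

as_frame_list <- function(x) if (is.list(x)) x else list(x)

#' Reconstruction loss (summed per-frame MSE)
#'
#' Mean squared error per frame (mean over pixels), summed over the predicted
#' time steps.
#'
#' @param preds Predicted frame, or list of predicted frames.
#' @param targets Ground-truth frame(s) of identical shapes.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(preds, targets) {
  preds <- as_frame_list(preds); targets <- as_frame_list(targets)
  if (length(preds) != length(targets))
    stop("preds and targets must contain the same number of frames")
  total <- 0
  for (i in seq_along(preds)) {
    if (!identical(dim(preds[[i]]), dim(targets[[i]])))
      stop("frame ", i, ": shape mismatch between prediction and target")
    total <- total + mean((preds[[i]] - targets[[i]])^2)
  }
  total
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' KL(posterior || prior) summed over latent dimensions, in nats:
#' sum_i 0.5 * (log s2_p - log s2_q + (s2_q + (mu_q - mu_p)^2) / s2_p - 1).
#'
#' @param posterior,prior [latent_distribution()] objects of equal dimension.
#' @return Non-negative scalar.
#' @export
gaussian_kl <- function(posterior, prior) {
  stopifnot(inherits(posterior, "latent_distribution"),
            inherits(prior, "latent_distribution"))
  if (length(posterior$mean) != length(prior$mean))
    stop("posterior and prior must have equal dimension")
  lq <- posterior$log_variance; lp <- prior$log_variance
  if (!all(is.finite(c(lq, lp, posterior$mean, prior$mean))))
    stop("distribution parameters must be finite")
  sum(0.5 * (lp - lq + (exp(lq) + (posterior$mean - prior$mean)^2) / exp(lp) - 1))
}

# batched KL on matrices of parameters (B x z); returns mean over batch of
# the per-item dimension-summed KL, plus gradients scaled by `weight`.
kl_batch <- function(mu_q, lv_q, mu_p, lv_p, weight = 1) {
  vq <- exp(lv_q); vp <- exp(lv_p)
  dmu <- mu_q - mu_p
  per <- 0.5 * (lv_p - lv_q + (vq + dmu^2) / vp - 1)
  B <- nrow(mu_q)
  w <- weight / B
  list(value = sum(per) / B,
       dmu_q = w * dmu / vp,
       dmu_p = -w * dmu / vp,
       dlv_q = w * 0.5 * (vq / vp - 1),
       dlv_p = w * 0.5 * (1 - (vq + dmu^2) / vp))
}

## Gaussian blur (separable, reflective boundary, kernel truncated at 4 sigma)

gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# n x n smoothing matrix with half-sample symmetric (reflective) boundary.
blur_matrix <- function(n, sigma) {
  kern <- gaussian_kernel_1d(sigma)
  r <- (length(kern) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pos <- i + seq(-r, r)
    # fold out-of-range indices back into [1, n] (edge-duplicating reflection)
    repeat {
      bad_lo <- pos < 1L; bad_hi <- pos > n
      if (!any(bad_lo | bad_hi)) break
      pos[bad_lo] <- 1L - pos[bad_lo]
      pos[bad_hi] <- 2L * n + 1L - pos[bad_hi]
    }
    for (j in seq_along(pos)) M[i, pos[j]] <- M[i, pos[j]] + kern[j]
  }
  M
}

.blur_mat_cache <- new.env(parent = emptyenv())
blur_matrix_cached <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  m <- .blur_mat_cache[[key]]
  if (is.null(m)) {
    m <- blur_matrix(n, sigma)
    .blur_mat_cache[[key]] <- m
  }
  m
}

# isotropic Gaussian blur of a matrix or 3D array (applied separably per axis)
gaussian_blur <- function(x, sigma) {
  d <- dim(x)
  if (length(d) == 2L) {
    return(blur_matrix_cached(d[1L], sigma) %*% x %*% t(blur_matrix_cached(d[2L], sigma)))
  }
  if (length(d) == 3L) {
    for (ax in 1:3) {
      M <- blur_matrix_cached(dim(x)[1L], sigma)
      xm <- x; dim(xm) <- c(dim(x)[1L], prod(dim(x)[-1L]))
      xm <- M %*% xm
      dim(xm) <- dim(x)
      x <- aperm(xm, c(2, 3, 1))
    }
    return(x)
  }
  stop("gaussian_blur supports 2D matrices and 3D arrays")
}

#' Build the Gaussian edge mask from the week-1 frame
#'
#' Convolves the first frame with an isotropic Gaussian (kernel truncated at
#' 4 sigma, reflective boundary) to obtain a soft attention mask over the
#' valid/boundary pixels, used by [edge_aware_loss()].
#'
#' @param x1 Week-1 frame (matrix or 3D array), values in \[0, 1\].
#' @param sigma Kernel standard deviation in pixels (> 0); default 5.
#' @return An `edge_mask` object (same shape as `x1`, values in \[0, 1\]).
#' @export
build_edge_mask <- function(x1, sigma = 5) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(!is.finite(x1))) stop("x1 must be finite")
  m <- pmin(pmax(gaussian_blur(x1, sigma), 0), 1)
  structure(m, class = c("edge_mask", class(m)))
}

#' Edge-aware weighted reconstruction loss
#'
#' Squared error weighted pixelwise by (1 + lambda * G(x1)), where G(x1) is
#' the Gaussian-blurred week-1 mask; per-frame pixel mean, summed over time
#' steps.  With `lambda_weight = 0` this equals [reconstruction_loss()].
#'
#' @param preds,targets Frame or list of frames, equal shapes.
#' @param mask An [build_edge_mask()] result (or any array in \[0, 1\] of
#'   frame shape).
#' @param lambda_weight Non-negative mask weight (default 1).
#' @param exponent 2 for squared error (default) or 1 for absolute error.
#' @return Non-negative scalar.
#' @export
edge_aware_loss <- function(preds, targets, mask, lambda_weight = 1,
                            exponent = 2) {
  if (lambda_weight < 0) stop("lambda_weight must be non-negative")
  stopifnot(exponent %in% c(1, 2))
  preds <- as_frame_list(preds); targets <- as_frame_list(targets)
  if (length(preds) != length(targets))
    stop("preds and targets must contain the same number of frames")
  w <- 1 + lambda_weight * unclass(mask)
  total <- 0
  for (i in seq_along(preds)) {
    if (!identical(dim(preds[[i]]), dim(targets[[i]])) ||
        !identical(dim(unclass(mask)), dim(preds[[i]])))
      stop("frame ", i, ": shape mismatch among prediction, target and mask")
    d <- preds[[i]] - targets[[i]]
    total <- total + mean(w * (if (exponent == 2) d * d else abs(d)))
  }
  total
}

#' Total training loss
#'
#' total = edge_aware + beta_kl * kl, with beta_kl defaulting to 0.0001.
#'
#' @param edge_aware Edge-aware reconstruction term.
#' @param kl KL divergence term.
#' @param beta_kl KL weight (default 1e-4).
#' @return A `tvae_loss` object with fields `edge_aware`, `kl`, `total`.
#' @export
total_loss <- function(edge_aware, kl, beta_kl = 1e-4) {
  stopifnot(is.finite(edge_aware), is.finite(kl))
  structure(list(edge_aware = edge_aware, kl = kl, beta_kl = beta_kl,
                 total = edge_aware + beta_kl * kl),
            class = "tvae_loss")
}

#' @export
print.tvae_loss <- function(x, ...) {
  cat(sprintf("total %.6g = edge_aware %.6g + %g * kl %.6g\n",
              x$total, x$edge_aware, x$beta_kl, x$kl))
  invisible(x)
}

## Batched loss + gradients used by the training loop ------------------------

# fw: result of fw_seq; targets: list over t of (B, sp, 1) arrays;
# wmask: (B, sp, 1) array of (1 + lambda * G(x1)) weights.
# Returns loss components and the full parameter gradient list.
loss_and_grads <- function(m, fw, targets, wmask, beta_kl, exponent = 2) {
  T_ <- fw$T_
  B <- fw$B
  npix <- prod(dim(targets[[2L]])[-1L])
  ea <- 0; kl <- 0
  dpreds <- vector("list", T_)
  dkl <- vector("list", T_)
  for (t in 2:T_) {
    d <- fw$preds[[t]] - targets[[t]]
    if (exponent == 2) {
      ea <- ea + sum(wmask * d * d) / (B * npix)
      dpreds[[t]] <- 2 * wmask * d / (B * npix)
    } else {
      ea <- ea + sum(wmask * abs(d)) / (B * npix)
      dpreds[[t]] <- wmask * sign(d) / (B * npix)
    }
    stp <- fw$steps[[t]]
    kb <- kl_batch(stp$po$mu, stp$po$lv, stp$pr$mu, stp$pr$lv, weight = beta_kl)
    kl <- kl + kb$value
    dkl[[t]] <- kb
  }
  grads <- bw_seq(m, fw, dpreds, dkl)
  list(edge_aware = ea, kl = kl, total = ea + beta_kl * kl, grads = grads)
}
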