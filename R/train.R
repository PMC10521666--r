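# Model fitting (teacher forcing, Adam, early stopping), generation-phase
# prediction, per-slice volume prediction, and uncertainty maps.

get_seq_frames <- function(s) {
  if (inherits(s, "volume_sequence")) s$volumes
  else if (inherits(s, "slice_sequence")) s$frames
  else if (is.list(s)) s
  else stop("expected a slice_sequence, volume_sequence or list of frames")
}

# stack a list of sequences into per-time-step batch arrays (B, spatial, 1)
stack_batch <- function(model, seqs) {
  frames1 <- get_seq_frames(seqs[[1L]])
  T_ <- length(frames1)
  sp <- model$cfg$input_spatial
  B <- length(seqs)
  xs <- vector("list", T_)
  for (t in seq_len(T_)) {
    arr <- array(0, c(B, sp, 1L))
    flat <- matrix(0, B, prod(sp))
    for (b in seq_len(B)) {
      f <- get_seq_frames(seqs[[b]])[[t]]
      if (!identical(as.integer(dim(f)), sp))
        stop("sequence ", b, " frame ", t, " has shape ",
             paste(dim(f), collapse = "x"), "; model expects ",
             paste(sp, collapse = "x"))
      flat[b, ] <- as.vector(f)
    }
    dim(flat) <- c(B, sp, 1L)
    xs[[t]] <- flat
  }
  xs
}

# (1 + lambda * G(x1)) weights for a batch, recomputed from each (possibly
# augmented) sequence's week-1 frame so mask and frames stay aligned
batch_edge_weights <- function(model, xs1, lambda_weight, mask_sigma) {
  d <- dim(xs1)
  B <- d[1L]
  sp <- d[2:(length(d) - 1L)]
  xm <- xs1
  dim(xm) <- c(B, prod(sp))
  om <- matrix(0, B, prod(sp))
  for (b in seq_len(B)) {
    x1 <- array(xm[b, ], sp)
    if (length(sp) == 2L) x1 <- as.matrix(x1)
    g <- unclass(build_edge_mask(x1, mask_sigma))
    om[b, ] <- 1 + lambda_weight * as.vector(g)
  }
  dim(om) <- d
  om
}

# loss of a forward pass without gradients (validation)
loss_only <- function(fw, targets, wmask, beta_kl, exponent = 2) {
  T_ <- fw$T_
  B <- fw$B
  npix <- prod(dim(targets[[2L]])[-1L])
  ea <- 0; kl <- 0
  for (t in 2:T_) {
    d <- fw$preds[[t]] - targets[[t]]
    ea <- ea + (if (exponent == 2) sum(wmask * d * d) else sum(wmask * abs(d))) / (B * npix)
    stp <- fw$steps[[t]]
    kl <- kl + kl_batch(stp$po$mu, stp$po$lv, stp$pr$mu, stp$pr$lv)$value
  }
  list(edge_aware = ea, kl = kl, total = ea + beta_kl * kl)
}

zero_eps <- function(B, z_dim, t_index) {
  eps <- list()
  for (t in t_index) eps[[t]] <- matrix(0, B, z_dim)
  eps
}

#' Fit a temporal variational autoencoder
#'
#' Trains the coupled prior-estimator / future-predictor / latent-inference
#' model on subject sequences with teacher forcing: at each step the
#' posterior is inferred from the ground-truth current frame, a latent is
#' sampled by reparameterization, and the predictor reconstructs the frame
#' from the encoded previous ground-truth frame, the latent and its LSTM
#' state.  The objective is the edge-aware reconstruction loss plus
#' `beta_kl` times the KL divergence between posterior and learned prior.
#' Optimization is Adam with early stopping on the validation total loss
#' (computed with posterior-mean latents so it is deterministic).
#'
#' @param train List of [slice_sequence()] (or [volume_sequence()] for
#'   `mode = "conv3d"`) objects of equal length T >= 2.
#' @param val Optional validation list; when `NULL`, `val_fraction` of the
#'   training subjects are held out (by subject).
#' @param image_size Frame side; inferred from the data when `NULL`.
#' @param mode `"conv2d"` or `"conv3d"`.
#' @param z_dim,g_dim,base_channels,lstm_hidden,n_skip_levels Architecture
#'   sizes passed to [tvae_model()].
#' @param lambda_weight Edge-mask weight in the loss (default 1).
#' @param mask_sigma Gaussian mask standard deviation in pixels (default 5).
#' @param beta_kl KL weight (default 1e-4).
#' @param edge_loss_exponent 2 (squared error, default) or 1.
#' @param batch_size Sequences per gradient step (default 48; use 4 for 3D).
#' @param max_epochs Maximum epochs (default 200).
#' @param beta_warmup,noise_warmup Warm-up horizons (epochs).  The KL weight
#'   ramps linearly from 0 to `beta_kl` over `beta_warmup` epochs, and the
#'   reparameterization noise from 0 to its full scale over `noise_warmup`
#'   epochs, so the latent route is established as a near-deterministic
#'   autoencoder before the variational pressures arrive (the usual guard
#'   against posterior collapse).  Both default to a quarter of
#'   `max_epochs`; set to 0 to disable.
#' @param patience Early-stopping patience in epochs (default 20).
#' @param learning_rate Adam learning rate (default 0.002).
#' @param adam_beta1 Adam first-moment decay (default 0.9).
#' @param grad_clip Global gradient-norm clip (default 10).
#' @param val_fraction Fraction of subjects held out when `val` is `NULL`.
#' @param augment Optional list with `crop_size`, `out_size`, `flip_prob`:
#'   per-sequence random crop + horizontal flip applied each epoch.
#' @param model Optionally a pre-built [tvae_model()] to continue training.
#' @param seed Integer seed controlling initialization, splits, shuffling,
#'   augmentation and latent draws; identical seeds give bit-identical fits.
#' @param verbose Print per-epoch losses.
#' @return An object of class `tvae` with the trained model, the per-epoch
#'   loss `history`, and the configuration; supports `print`, `summary`,
#'   `coef`, `predict`, `simulate`, `residuals` and `plot`.
#' @export
tvae <- function(train, val = NULL, image_size = NULL,
                 mode = c("conv2d", "conv3d"),
                 z_dim = 10, g_dim = 128, base_channels = 32,
                 lstm_hidden = 256, n_skip_levels = 1,
                 lambda_weight = 1, mask_sigma = 5,
                 beta_kl = 1e-4, edge_loss_exponent = 2,
                 batch_size = 48, max_epochs = 200, patience = 20,
                 beta_warmup = ceiling(max_epochs / 4),
                 noise_warmup = ceiling(max_epochs / 4),
                 learning_rate = 0.002, adam_beta1 = 0.9, grad_clip = 10,
                 val_fraction = 0.1, augment = NULL, model = NULL,
                 seed = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (!is.list(train) || length(train) < 1L) stop("empty training set")
  stopifnot(batch_size >= 1, learning_rate >= 0, patience >= 1)
  set.seed(seed)

  if (is.null(val)) {
    n <- length(train)
    n_val <- max(1L, round(val_fraction * n))
    if (n_val >= n) stop("training set too small to hold out validation subjects")
    vid <- sample.int(n, n_val)
    val <- train[vid]
    train <- train[-vid]
  }
  if (length(val) < 1L) stop("empty validation set")

  f1 <- get_seq_frames(train[[1L]])[[1L]]
  dd <- dim(f1)
  if (is.null(image_size)) image_size <- dd[length(dd)]
  depth <- if (mode == "conv3d") dd[1L] else 48
  if (is.null(model))
    model <- tvae_model(image_size = image_size, z_dim = z_dim, g_dim = g_dim,
                        base_channels = base_channels, lstm_hidden = lstm_hidden,
                        mode = mode, depth = depth, n_skip_levels = n_skip_levels,
                        seed = sample.int(.Machine$integer.max, 1L))
  T_ <- length(get_seq_frames(train[[1L]]))
  if (T_ < 2L) stop("sequences must contain at least 2 frames")

  maybe_augment <- function(s) {
    if (is.null(augment)) return(s)
    augment_sequence(s, crop_size = augment$crop_size %||% NULL,
                     out_size = augment$out_size %||% model$cfg$image_size,
                     flip_prob = augment$flip_prob %||% 0.5)
  }
  val_xs <- stack_batch(model, lapply(val, function(s)
    if (is.null(augment)) s else augment_sequence(s, crop_size = NULL,
      out_size = augment$out_size %||% model$cfg$image_size, flip_prob = 0)))
  val_w <- batch_edge_weights(model, val_xs[[1L]], lambda_weight, mask_sigma)
  val_eps <- zero_eps(length(val), model$cfg$z_dim, 2:T_)

  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(), train_total = numeric(),
                        train_edge_aware = numeric(), train_kl = numeric(),
                        val_total = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  nb <- length(train)

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(nb)
    beta_e <- if (beta_warmup > 0) beta_kl * min(1, (epoch - 1) / beta_warmup)
              else beta_kl
    noise_e <- if (noise_warmup > 0) min(1, (epoch - 1) / noise_warmup) else 1
    ep_tot <- ep_ea <- ep_kl <- 0; nbatches <- 0L
    for (start in seq(1L, nb, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, nb)]
      seqs <- lapply(train[idx], maybe_augment)
      xs <- stack_batch(model, seqs)
      wm <- batch_edge_weights(model, xs[[1L]], lambda_weight, mask_sigma)
      eps <- draw_eps_list(length(idx), model$cfg$z_dim, 2:T_)
      if (noise_e < 1) eps <- lapply(eps, function(e) if (is.null(e)) e else noise_e * e)
      fw <- fw_seq(model, xs, eps, "posterior")
      lg <- loss_and_grads(model, fw, xs, wm, beta_e, edge_loss_exponent)
      if (!is.finite(lg$total))
        stop("non-finite training loss at epoch ", epoch)
      grads <- clip_grads(lg$grads, grad_clip)
      if (learning_rate > 0) {
        up <- adam_step(model$params, grads, opt, learning_rate,
                        beta1 = adam_beta1)
        model$params <- up$params
        opt <- up$state
      }
      ep_tot <- ep_tot + lg$total; ep_ea <- ep_ea + lg$edge_aware
      ep_kl <- ep_kl + lg$kl; nbatches <- nbatches + 1L
    }
    vfw <- fw_seq(model, val_xs, val_eps, "posterior")
    vl <- loss_only(vfw, val_xs, val_w, beta_kl, edge_loss_exponent)
    if (!is.finite(vl$total)) stop("non-finite validation loss at epoch ", epoch)
    history[epoch, ] <- list(epoch, ep_tot / nbatches, ep_ea / nbatches,
                             ep_kl / nbatches, vl$total)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_tot / nbatches, vl$total))
    if (vl$total < best$val - 1e-12) {
      best <- list(val = vl$total, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$params <- best$params

  structure(list(model = model, history = history, best_epoch = best$epoch,
                 best_val = best$val,
                 config = list(lambda_weight = lambda_weight,
                               mask_sigma = mask_sigma, beta_kl = beta_kl,
                               edge_loss_exponent = edge_loss_exponent,
                               batch_size = batch_size, max_epochs = max_epochs,
                               beta_warmup = beta_warmup,
                               noise_warmup = noise_warmup,
                               patience = patience, learning_rate = learning_rate,
                               adam_beta1 = adam_beta1, grad_clip = grad_clip,
                               seed = seed, augment = augment),
                 call = cl),
            class = "tvae")
}

as_tvae_model <- function(object) {
  if (inherits(object, "tvae")) object$model
  else if (inherits(object, "tvae_model")) object
  else stop("expected a fitted 'tvae' object or a 'tvae_model'")
}

#' Predict the week-4 frame from three context frames
#'
#' Draws `n_samples` independent latent trajectories from the learned prior
#' (the inference model is not used) and generates one candidate next frame
#' per draw, all sharing the same context.
#'
#' @param object A fitted `tvae` or a `tvae_model`.
#' @param context List of exactly 3 context frames (or a [slice_sequence()]
#'   whose first 3 frames are used as context).
#' @param n_samples Number of candidate predictions (>= 1).
#' @param seed Optional seed for the prior draws.
#' @return List of `n_samples` predicted frames with values in (0, 1).
#' @export
predict_week4 <- function(object, context, n_samples = 1L, seed = NULL) {
  model <- as_tvae_model(object)
  frames <- if (inherits(context, "slice_sequence")) context$frames[1:3]
            else context
  if (length(frames) != 3L)
    stop("context must contain exactly 3 frames, got ", length(frames))
  stopifnot(n_samples >= 1)
  sp <- model$cfg$input_spatial
  B <- as.integer(n_samples)
  ctx <- lapply(frames, function(f) {
    if (!identical(as.integer(dim(f)), sp))
      stop("context frame shape ", paste(dim(f), collapse = "x"),
           " does not match model input ", paste(sp, collapse = "x"))
    arr <- array(rep(as.vector(f), each = B), c(B, sp, 1L))
    arr
  })
  eps <- with_seed(seed, draw_eps_list(B, model$cfg$z_dim, 2:4))
  outs <- gen_seq(model, ctx, 1L, eps)
  pred <- outs[[1L]]
  lapply(seq_len(B), function(b) {
    d <- dim(pred)
    ix <- c(list(b), lapply(d[-1L], seq_len))
    out <- array(do.call(`[`, c(list(pred), ix, list(drop = FALSE))), d[2:(length(d) - 1L)])
    if (length(dim(out)) == 2L) as.matrix(out) else out
  })
}

#' Predict a future volume slice-by-slice with a 2D model
#'
#' For each slice location d, predicts the next frame from the three context
#' slices at that location (single prior draw each) and stacks the
#' predictions into a volume.
#'
#' @param object A fitted conv2d `tvae` or `tvae_model`.
#' @param volumes List of 3 context volumes (D x H x W), equal D.
#' @param seed Optional seed.
#' @return Predicted D x H x W volume.
#' @export
predict_volume <- function(object, volumes, seed = NULL) {
  model <- as_tvae_model(object)
  if (model$cfg$mode != "conv2d")
    stop("predict_volume requires a conv2d-mode model")
  if (length(volumes) != 3L) stop("need exactly 3 context volumes")
  ds <- lapply(volumes, dim)
  if (length(unique(vapply(ds, function(d) d[1L], 0))) != 1L)
    stop("context volumes must share the slice count D")
  D <- ds[[1L]][1L]
  sp <- model$cfg$input_spatial
  # batch across slice locations: one generation pass for the whole volume
  ctx <- lapply(volumes, function(v) {
    arr <- array(0, c(D, sp, 1L))
    arr[, , , 1L] <- v
    arr
  })
  eps <- with_seed(seed, draw_eps_list(D, model$cfg$z_dim, 2:4))
  pred <- gen_seq(model, ctx, 1L, eps)[[1L]]
  array(pred, c(D, sp))
}

#' Per-pixel uncertainty map over sampled predictions
#'
#' For each pixel, the fraction of sampled predictions whose intensity
#' exceeds `nonzero_threshold` -- an empirical probability that the predicted
#' pixel is non-negligible.
#'
#' @param samples List of >= 2 predicted frames of equal shape.
#' @param nonzero_threshold Intensity threshold in \[0, 1) (default 0.05).
#' @return An `uncertainty_map` (array in \[0, 1\]) with attributes
#'   `n_samples` and `nonzero_threshold`.
#' @export
uncertainty_map <- function(samples, nonzero_threshold = 0.05) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need at least 2 samples")
  if (nonzero_threshold < 0 || nonzero_threshold >= 1)
    stop("nonzero_threshold must lie in [0, 1)")
  d <- dim(samples[[1L]])
  acc <- array(0, d)
  for (s in samples) {
    if (!identical(dim(s), d)) stop("samples must share a common shape")
    acc <- acc + (s > nonzero_threshold)
  }
  structure(acc / length(samples), class = c("uncertainty_map", "matrix"),
            n_samples = length(samples), nonzero_threshold = nonzero_threshold)
}

#' Score week-4 predictions on a test set
#'
#' For each test sequence, predicts the final frame from the first three
#' (one prior draw, seeded per item) and scores it against ground truth with
#' PSNR and SSIM.
#'
#' @param object A fitted `tvae` or `tvae_model`.
#' @param test_set List of [slice_sequence()] objects with >= 4 frames.
#' @param seed Integer seed making the report reproducible.
#' @return A `tvae_evaluation` data frame (subject, psnr, ssim) with
#'   aggregate attributes `mean` and `sd`.
#' @export
evaluate_testset <- function(object, test_set, seed = 1) {
  model <- as_tvae_model(object)
  if (length(test_set) < 1L) stop("empty test set")
  rows <- lapply(seq_along(test_set), function(i) {
    s <- test_set[[i]]
    fr <- get_seq_frames(s)
    if (length(fr) < 4L) stop("test sequences must contain at least 4 frames")
    pred <- predict_week4(model, fr[1:3], n_samples = 1L,
                          seed = mix_seed(seed, i))[[1L]]
    gt <- fr[[4L]]
    data.frame(subject_id = if (!is.null(s$subject_id)) s$subject_id else
                 paste0("item", i),
               psnr = psnr(pred, gt), ssim = ssim(pred, gt))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- c(psnr = mean(out$psnr), ssim = mean(out$ssim))
  attr(out, "sd") <- c(psnr = stats::sd(out$psnr), ssim = stats::sd(out$ssim))
  class(out) <- c("tvae_evaluation", "data.frame")
  out
}

#' @export
print.tvae_evaluation <- function(x, ...) {
  cat("Week-4 prediction quality over", nrow(x), "test sequences\n")
  m <- attr(x, "mean"); s <- attr(x, "sd")
  cat(sprintf("  PSNR %.2f dB (sd %.2f)   SSIM %.3f (sd %.3f)\n",
              m["psnr"], s["psnr"], m["ssim"], s["ssim"]))
  NextMethod()
}

## S3 methods for the fitted model -------------------------------------------

#' @export
print.tvae <- function(x, ...) {
  cat("Fitted temporal VAE\n")
  print(x$model)
  cat("  trained", nrow(x$history), "epochs; best validation loss",
      signif(x$best_val, 5), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @export
summary.tvae <- function(object, ...) {
  h <- object$history
  cat("Temporal VAE fit\n\n")
  print(object$model)
  cat("\nLoss (first / best-val / last epoch):\n")
  rows <- unique(c(1L, object$best_epoch, nrow(h)))
  print(h[rows, ], row.names = FALSE)
  cat("\nConfig: lambda", object$config$lambda_weight,
      " mask sigma", object$config$mask_sigma,
      " beta_kl", object$config$beta_kl,
      " lr", object$config$learning_rate, "\n")
  invisible(object)
}

#' @export
coef.tvae <- function(object, ...) object$model$params

#' Predict from a fitted temporal VAE
#'
#' @param object A fitted `tvae`.
#' @param newdata A [slice_sequence()] (first three frames form the context)
#'   or a list of them.
#' @param n_samples Candidate predictions per sequence.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return For one sequence, a list of predicted frames; for a list of
#'   sequences, a list of such lists.
#' @export
predict.tvae <- function(object, newdata, n_samples = 1L, seed = NULL, ...) {
  if (inherits(newdata, "slice_sequence") ||
      (is.list(newdata) && !is.null(dim(newdata[[1L]]))))
    return(predict_week4(object, newdata, n_samples, seed))
  lapply(seq_along(newdata), function(i)
    predict_week4(object, newdata[[i]], n_samples,
                  seed = if (is.null(seed)) NULL else mix_seed(seed, i)))
}

#' Simulate week-4 outcomes from a fitted temporal VAE
#'
#' @param object A fitted `tvae`.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param context Three context frames (or a [slice_sequence()]).
#' @param ... Unused.
#' @return List of `nsim` sampled predicted frames.
#' @export
simulate.tvae <- function(object, nsim = 1, seed = NULL, context, ...) {
  predict_week4(object, context, n_samples = nsim, seed = seed)
}

#' Prediction residuals on held-out sequences
#'
#' Ground-truth final frame minus the prior-mean prediction, per sequence.
#'
#' @param object A fitted `tvae`.
#' @param newdata A [slice_sequence()] with >= 4 frames, or a list of them.
#' @param ... Unused.
#' @return A residual matrix, or a list of them.
#' @export
residuals.tvae <- function(object, newdata, ...) {
  one <- function(s) {
    fr <- get_seq_frames(s)
    if (length(fr) < 4L) stop("need at least 4 frames to form residuals")
    pred <- forward_generate(object$model, fr[1:3], n_future = 1L,
                             sample = "mean")[[1L]]
    fr[[4L]] - pred
  }
  if (inherits(newdata, "slice_sequence")) one(newdata) else lapply(newdata, one)
}

#' Plot training history
#'
#' @param x A fitted `tvae`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tvae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "total loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Checkpoints store the weights, the full configuration and the training
#' history; loading restores bit-exact generation for a fixed seed.
#'
#' @param object A fitted `tvae` or `tvae_model`.
#' @param path Checkpoint file path.
#' @return `load_tvae` returns the restored object.
#' @export
save_tvae <- function(object, path) {
  saveRDS(list(object = object, package_version = as.character(utils::packageVersion("tvae"))),
          path)
  invisible(path)
}

#' @rdname save_tvae
#' @export
load_tvae <- function(path) readRDS(path)$object
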