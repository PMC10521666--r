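#' Latent Gaussian distribution
#'
#' Diagonal Gaussian over the latent vector, parameterized by a mean and a
#' log-variance (the networks emit log-variance for numerical safety).
#'
#' @param mean Numeric vector (or one-row matrix) of latent means.
#' @param log_variance Numeric vector of the same length; log of the
#'   per-dimension variance.  Must be finite.
#' @return An object of class `latent_distribution`.
#' @export
latent_distribution <- function(mean, log_variance) {
  mean <- drop(mean); log_variance <- drop(log_variance)
  if (length(mean) != length(log_variance))
    stop("mean and log_variance must have the same length")
  if (!all(is.finite(mean)) || !all(is.finite(log_variance)))
    stop("latent distribution parameters must be finite")
  structure(list(mean = as.numeric(mean), log_variance = as.numeric(log_variance)),
            class = "latent_distribution")
}

#' @export
print.latent_distribution <- function(x, ...) {
  cat("Diagonal Gaussian latent, dim", length(x$mean), "\n")
  cat("  mean sd:", signif(stats::sd(x$mean), 3),
      " mean var:", signif(mean(exp(x$log_variance)), 3), "\n")
  invisible(x)
}

## Model construction --------------------------------------------------------

#' Construct a temporal VAE model
#'
#' Builds the three coupled recurrent sub-models -- the prior estimator, the
#' future predictor and the training-only latent inference model -- around a
#' shared DCGAN-style strided convolutional encoder and a transposed
#' convolutional decoder with sigmoid output.  Skip connections link the
#' `n_skip_levels` highest-resolution encoder levels to the decoder; the
#' low-resolution bottleneck is skip-free so that the latent path carries
#' information.
#'
#' @param image_size Side length of (square) input frames; a power of two,
#'   at least 16.  Default 64.
#' @param z_dim Latent dimension (default 10).
#' @param g_dim Encoder output feature dimension (default 128).
#' @param base_channels Channels of the first convolution; doubled per level,
#'   capped at `8 * base_channels`.
#' @param lstm_hidden Hidden width of each of the three LSTMs (default 256).
#' @param mode `"conv2d"` for per-slice models, `"conv3d"` for volumes.
#' @param depth Number of slices per volume (conv3d mode only; default 48).
#' @param n_skip_levels Number of highest-resolution encoder levels wired to
#'   the decoder (default 1; the bottleneck stays skip-free so the latent
#'   path matters).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `tvae_model` holding the configuration and a
#'   named list of weight arrays.
#' @export
tvae_model <- function(image_size = 64, z_dim = 10, g_dim = 128,
                       base_channels = 32, lstm_hidden = 256,
                       mode = c("conv2d", "conv3d"), depth = 48,
                       n_skip_levels = 1, seed = 1) {
  mode <- match.arg(mode)
  if (image_size < 16 || bitwAnd(image_size, image_size - 1L) != 0)
    stop("image_size must be a power of two, at least 16")
  n_levels <- as.integer(round(log2(image_size / 4)))
  sp0 <- if (mode == "conv3d") c(depth, image_size, image_size)
         else c(image_size, image_size)
  spatial <- vector("list", n_levels + 1L)
  spatial[[1L]] <- as.integer(sp0)
  for (l in seq_len(n_levels)) {
    if (any(spatial[[l]] %% 2L != 0L))
      stop("spatial dimensions must stay even through all ", n_levels,
           " encoder levels; got ", paste(spatial[[l]], collapse = "x"),
           " at level ", l)
    spatial[[l + 1L]] <- conv_out_spatial(spatial[[l]], 4L, 2L, 1L)
  }
  channels <- pmin(base_channels * 2^(seq_len(n_levels) - 1L), 8L * base_channels)
  skip_levels <- seq_len(min(n_skip_levels, n_levels - 1L))
  flat_dim <- prod(spatial[[n_levels + 1L]]) * channels[n_levels]
  nd <- length(sp0)
  kk <- 4L^nd

  cfg <- list(mode = mode, image_size = image_size, depth = if (mode == "conv3d") depth else NULL,
              z_dim = z_dim, g_dim = g_dim, base_channels = base_channels,
              lstm_hidden = lstm_hidden, n_levels = n_levels, channels = channels,
              spatial = spatial, skip_levels = skip_levels, flat_dim = flat_dim,
              nd = nd, input_spatial = as.integer(sp0))

  params <- with_seed(seed, {
    p <- list()
    # scale-preserving initialization (no batch normalization in this
    # network): He for leaky-ReLU fan-in, Xavier-like for tanh/sigmoid heads
    cw <- function(n, m, fan_in) matrix(stats::rnorm(n * m, sd = sqrt(2 / fan_in)), n, m)
    cin <- 1L
    for (l in seq_len(n_levels)) {
      p[[paste0("enc.conv", l, ".W")]] <- cw(kk * cin, channels[l], kk * cin)
      p[[paste0("enc.conv", l, ".b")]] <- numeric(channels[l])
      cin <- channels[l]
    }
    p[["enc.fc.W"]] <- cw(flat_dim, g_dim, 2L * flat_dim)
    p[["enc.fc.b"]] <- numeric(g_dim)
    # layer normalization ahead of the bounded (tanh) heads keeps their
    # pre-activations in range; without it adaptive-step optimization drifts
    # them into saturation and the feature path dies
    p[["enc.ln.g"]] <- rep(1, g_dim)
    p[["enc.ln.b"]] <- numeric(g_dim)
    # the decoder consumes the predictor features with the latent draw
    # appended, giving the latent a direct path to the pixels
    p[["dec.fc.W"]] <- cw(g_dim + z_dim, flat_dim, g_dim + z_dim)
    p[["dec.fc.b"]] <- numeric(flat_dim)
    for (l in seq_len(n_levels)) {
      cout <- if (l == 1L) 1L else channels[l - 1L]
      # inputs per level: upsampled features, optionally the skip map, plus
      # the latent broadcast spatially as z_dim constant channels -- a short
      # path from the latent to every output resolution
      cin_d <- channels[l] + z_dim + if (l %in% skip_levels) channels[l] else 0L
      # each transposed-conv output receives (k/s)^nd = 2^nd taps per input
      # channel, so the effective fan-in is cin_d * 2^nd
      p[[paste0("dec.tconv", l, ".W")]] <- cw(kk * cout, cin_d, cin_d * 2L^nd)
      p[[paste0("dec.tconv", l, ".b")]] <- numeric(cout)
    }
    # log-variance bias starts at -6 (sd ~ 0.05): early latent draws stay
    # close to their mean, so the reconstruction path can pick up the signal
    # they carry before learning the spread.  The inference head outputs the
    # residual correction to the prior and starts at zero, so posterior and
    # prior coincide at initialization.
    hb <- c(numeric(z_dim), rep(-6, z_dim))
    for (nm in c("prior", "inf")) {
      lw <- lstm_init(g_dim, lstm_hidden)
      p[[paste0(nm, ".lstm.W")]] <- lw$W
      p[[paste0(nm, ".lstm.b")]] <- lw$b
      p[[paste0(nm, ".out.W")]] <- if (nm == "inf")
        matrix(0, g_dim + lstm_hidden, 2L * z_dim)
      else cw(g_dim + lstm_hidden, 2L * z_dim, 2L * (g_dim + lstm_hidden))
      p[[paste0(nm, ".out.b")]] <- hb
    }
    lw <- lstm_init(g_dim + z_dim, lstm_hidden)
    p[["pred.lstm.W"]] <- lw$W
    p[["pred.lstm.b"]] <- lw$b
    p[["pred.out.W"]] <- cw(lstm_hidden, g_dim, 2L * lstm_hidden)
    p[["pred.out.b"]] <- numeric(g_dim)
    p[["pred.ln.g"]] <- rep(1, g_dim)
    p[["pred.ln.b"]] <- numeric(g_dim)
    p
  })

  structure(list(cfg = cfg, params = params, phase = "train"),
            class = "tvae_model")
}

#' @export
print.tvae_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Temporal VAE model (", cfg$mode, ")\n", sep = "")
  cat("  input:", paste(cfg$input_spatial, collapse = "x"),
      " levels:", cfg$n_levels,
      " channels:", paste(cfg$channels, collapse = ","), "\n")
  cat("  z_dim:", cfg$z_dim, " g_dim:", cfg$g_dim,
      " lstm_hidden:", cfg$lstm_hidden, "\n")
  cat("  parameters:", format(sum(vapply(x$params, length, 0L)), big.mark = ","), "\n")
  invisible(x)
}

#' Set the model phase
#'
#' The latent inference model is only valid during training; in the
#' generation phase [inference_step()] refuses to run.
#'
#' @param model A `tvae_model`.
#' @param value `"train"` or `"generate"`.
#' @export
`model_phase<-` <- function(model, value) {
  stopifnot(value %in% c("train", "generate"))
  model$phase <- value
  model
}

#' Fresh recurrent state
#'
#' Zero-initialized hidden and cell states for the three LSTMs, to be used at
#' the start of a sequence.
#'
#' @param model A `tvae_model`.
#' @param batch Batch size.
#' @return An object of class `tvae_state`.
#' @export
tvae_state <- function(model, batch = 1L) {
  nh <- model$cfg$lstm_hidden
  z0 <- function() matrix(0, batch, nh)
  structure(list(prior = list(h = z0(), c = z0()),
                 inf = list(h = z0(), c = z0()),
                 pred = list(h = z0(), c = z0())),
            class = "tvae_state", batch = batch)
}

check_state <- function(state) {
  if (!inherits(state, "tvae_state"))
    stop("state must be created by tvae_state() (or returned by a *_step function)")
  state
}

## Internal batched passes ---------------------------------------------------

# frames enter internal code as arrays (B, spatial..., 1)
as_batch <- function(model, x) {
  sp <- model$cfg$input_spatial
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array")
  if (length(d) == length(sp) && all(d == sp)) {
    dim(x) <- c(1L, sp, 1L)
  } else if (length(d) == length(sp) + 1L && all(d[-1L] == sp)) {
    dim(x) <- c(d[1L], sp, 1L)
  } else if (!(length(d) == length(sp) + 2L && all(d[1L + seq_along(sp)] == sp)))
    stop("input shape ", paste(d, collapse = "x"),
         " does not match model input ", paste(sp, collapse = "x"))
  x
}

unbatch_frame <- function(x) {
  d <- dim(x)
  out <- array(x, d[2:(length(d) - 1L)])
  if (length(dim(out)) == 2L) out <- as.matrix(out)
  out
}

enc_forward <- function(m, x) {
  cfg <- m$cfg
  p <- m$params
  h <- x
  convs <- acts <- vector("list", cfg$n_levels)
  skips <- vector("list", cfg$n_levels)
  for (l in seq_len(cfg$n_levels)) {
    cv <- conv_fwd(h, p[[paste0("enc.conv", l, ".W")]],
                   p[[paste0("enc.conv", l, ".b")]], 4L, 2L, 1L)
    ac <- lrelu_fwd(cv$y)
    convs[[l]] <- cv$cache
    acts[[l]] <- ac
    if (l %in% cfg$skip_levels) skips[[l]] <- ac$y
    h <- ac$y
  }
  B <- dim(x)[1L]
  hm <- h
  dim(hm) <- c(B, cfg$flat_dim)
  fc <- linear_fwd(hm, p[["enc.fc.W"]], p[["enc.fc.b"]])
  ln <- ln_fwd(fc$y, p[["enc.ln.g"]], p[["enc.ln.b"]])
  f <- tanh(ln$y)
  list(f = f, skips = skips,
       cache = list(convs = convs, acts = acts, fc = fc, ln = ln$cache,
                    f = f, B = B))
}

enc_backward <- function(m, df, dskips, cache, genv) {
  cfg <- m$cfg
  p <- m$params
  dy <- tanh_bwd(df, cache$f)
  lnb <- ln_bwd(dy, cache$ln)
  acc_grad(genv, "enc.ln.g", lnb$dg); acc_grad(genv, "enc.ln.b", lnb$db)
  lb <- linear_bwd(lnb$dx, p[["enc.fc.W"]], cache$fc)
  acc_grad(genv, "enc.fc.W", lb$dW); acc_grad(genv, "enc.fc.b", lb$db)
  dh <- lb$dx
  dim(dh) <- c(cache$B, cfg$spatial[[cfg$n_levels + 1L]], cfg$channels[cfg$n_levels])
  for (l in rev(seq_len(cfg$n_levels))) {
    if (!is.null(dskips[[l]])) dh <- dh + dskips[[l]]
    da <- lrelu_bwd(dh, cache$acts[[l]])
    cb <- conv_bwd(da, p[[paste0("enc.conv", l, ".W")]], cache$convs[[l]])
    acc_grad(genv, paste0("enc.conv", l, ".W"), cb$dW)
    acc_grad(genv, paste0("enc.conv", l, ".b"), cb$db)
    dh <- cb$dx
  }
  invisible(dh)
}

# broadcast a (B x zd) latent matrix to (B, spatial, zd) constant channels
broadcast_latent <- function(z, sp) {
  B <- nrow(z); zd <- ncol(z); P <- prod(sp)
  out <- array(0, c(B, P, zd))
  for (c in seq_len(zd)) out[, , c] <- z[, c]
  dim(out) <- c(B, sp, zd)
  out
}

# sum the gradient of a broadcast latent back to (B x zd)
collapse_latent_grad <- function(dz_arr) {
  d <- dim(dz_arr)
  B <- d[1L]; zd <- d[length(d)]; P <- prod(d[-c(1L, length(d))])
  m <- aperm(array(dz_arr, c(B, P, zd)), c(2L, 1L, 3L))
  dim(m) <- c(P, B * zd)
  matrix(colSums(m), B, zd)
}

# decoder: dense projection of [features, latent] to the bottleneck, then
# transposed convolutions; at every level the latent is re-injected as
# spatially broadcast channels, and skip maps are concatenated where wired
dec_forward <- function(m, g, z, skips) {
  cfg <- m$cfg
  p <- m$params
  fc <- linear_fwd(cbind(g, z), p[["dec.fc.W"]], p[["dec.fc.b"]])
  a0 <- lrelu_fwd(fc$y)
  h <- a0$y
  B <- nrow(g)
  dim(h) <- c(B, cfg$spatial[[cfg$n_levels + 1L]], cfg$channels[cfg$n_levels])
  tcs <- acts <- vector("list", cfg$n_levels)
  concat_c <- integer(cfg$n_levels)
  for (l in rev(seq_len(cfg$n_levels))) {
    if (l %in% cfg$skip_levels) {
      concat_c[l] <- dim(h)[length(dim(h))]
      h <- concat_channels(h, skips[[l]])
    }
    h <- concat_channels(h, broadcast_latent(z, cfg$spatial[[l + 1L]]))
    tc <- tconv_fwd(h, p[[paste0("dec.tconv", l, ".W")]],
                    p[[paste0("dec.tconv", l, ".b")]], 4L, 2L, 1L)
    tcs[[l]] <- tc$cache
    if (l > 1L) {
      a <- lrelu_fwd(tc$y)
      acts[[l]] <- a
      h <- a$y
    } else {
      h <- sigmoid(tc$y)
      acts[[l]] <- h
    }
  }
  list(xhat = h, cache = list(fc = fc, a0 = a0, tcs = tcs, acts = acts,
                              concat_c = concat_c, B = B, zd = ncol(z)))
}

dec_backward <- function(m, dxhat, cache, genv) {
  cfg <- m$cfg
  p <- m$params
  dskips <- vector("list", cfg$n_levels)
  dz <- matrix(0, cache$B, cache$zd)
  dh <- NULL
  for (l in seq_len(cfg$n_levels)) {
    dy <- if (l == 1L) sigmoid_bwd(dxhat, cache$acts[[1L]])
          else lrelu_bwd(dh, cache$acts[[l]])
    tb <- tconv_bwd(dy, p[[paste0("dec.tconv", l, ".W")]], cache$tcs[[l]])
    acc_grad(genv, paste0("dec.tconv", l, ".W"), tb$dW)
    acc_grad(genv, paste0("dec.tconv", l, ".b"), tb$db)
    dh <- tb$dx
    nch <- dim(dh)[length(dim(dh))]
    spz <- split_channels(dh, nch - cache$zd)
    dh <- spz[[1L]]
    dz <- dz + collapse_latent_grad(spz[[2L]])
    if (l %in% cfg$skip_levels) {
      sp <- split_channels(dh, cache$concat_c[l])
      dh <- sp[[1L]]
      dskips[[l]] <- sp[[2L]]
    }
  }
  da0 <- dh
  dim(da0) <- c(cache$B, cfg$flat_dim)
  dfc <- lrelu_bwd(da0, cache$a0)
  lb <- linear_bwd(dfc, p[["dec.fc.W"]], cache$fc)
  acc_grad(genv, "dec.fc.W", lb$dW); acc_grad(genv, "dec.fc.b", lb$db)
  gd <- ncol(lb$dx) - cache$zd
  list(dg = lb$dx[, seq_len(gd), drop = FALSE],
       dz = dz + lb$dx[, -seq_len(gd), drop = FALSE],
       dskips = dskips)
}

acc_grad <- function(genv, nm, g) {
  cur <- genv$g[[nm]]
  genv$g[[nm]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# One step of a recurrent Gaussian head (prior / inference).  The (mu,
# logvar) output is a direct linear map of the current features and the
# previous hidden state -- the head takes (x_t or x_{t-1}, h_{t-1}) -- while
# the LSTM advances the recurrent state from the same features.
head_fwd <- function(m, which, f, st) {
  p <- m$params
  out <- linear_fwd(cbind(f, st$h), p[[paste0(which, ".out.W")]],
                    p[[paste0(which, ".out.b")]])
  lf <- lstm_fwd(f, st$h, st$c, p[[paste0(which, ".lstm.W")]],
                 p[[paste0(which, ".lstm.b")]])
  z <- m$cfg$z_dim
  list(mu = out$y[, seq_len(z), drop = FALSE],
       lv = out$y[, z + seq_len(z), drop = FALSE],
       state = list(h = lf$h, c = lf$c),
       cache = list(lstm = lf$cache, out = out, gdim = ncol(f)))
}

head_bwd <- function(m, which, dmu, dlv, dh_carry, dc_carry, cache, genv) {
  p <- m$params
  dy <- cbind(dmu, dlv)
  lb <- linear_bwd(dy, p[[paste0(which, ".out.W")]], cache$out)
  acc_grad(genv, paste0(which, ".out.W"), lb$dW)
  acc_grad(genv, paste0(which, ".out.b"), lb$db)
  lw <- lstm_bwd(dh_carry, dc_carry, p[[paste0(which, ".lstm.W")]], cache$lstm)
  acc_grad(genv, paste0(which, ".lstm.W"), lw$dW)
  acc_grad(genv, paste0(which, ".lstm.b"), lw$db)
  gd <- cache$gdim
  list(df = lw$dx + lb$dx[, seq_len(gd), drop = FALSE],
       dh = lw$dh + lb$dx[, -seq_len(gd), drop = FALSE],
       dc = lw$dc)
}

pred_fwd <- function(m, f, z, st) {
  p <- m$params
  x <- cbind(f, z)
  lf <- lstm_fwd(x, st$h, st$c, p[["pred.lstm.W"]], p[["pred.lstm.b"]])
  out <- linear_fwd(lf$h, p[["pred.out.W"]], p[["pred.out.b"]])
  ln <- ln_fwd(out$y, p[["pred.ln.g"]], p[["pred.ln.b"]])
  g <- tanh(ln$y)
  list(g = g, state = list(h = lf$h, c = lf$c),
       cache = list(lstm = lf$cache, out = out, ln = ln$cache, g = g,
                    gdim = ncol(f)))
}

pred_bwd <- function(m, dg, dh_carry, dc_carry, cache, genv) {
  p <- m$params
  dy <- tanh_bwd(dg, cache$g)
  lnb <- ln_bwd(dy, cache$ln)
  acc_grad(genv, "pred.ln.g", lnb$dg); acc_grad(genv, "pred.ln.b", lnb$db)
  lb <- linear_bwd(lnb$dx, p[["pred.out.W"]], cache$out)
  acc_grad(genv, "pred.out.W", lb$dW); acc_grad(genv, "pred.out.b", lb$db)
  lw <- lstm_bwd(lb$dx + dh_carry, dc_carry, p[["pred.lstm.W"]], cache$lstm)
  acc_grad(genv, "pred.lstm.W", lw$dW); acc_grad(genv, "pred.lstm.b", lw$db)
  gd <- cache$gdim
  list(df = lw$dx[, seq_len(gd), drop = FALSE],
       dz = lw$dx[, -seq_len(gd), drop = FALSE],
       dh = lw$dh, dc = lw$dc)
}

# Teacher-forced forward pass over a whole sequence.
# xs: list of T arrays (B, spatial, 1).  eps: list indexed by t (2..T) of
# B x z_dim standard-normal draws.  Returns predictions for t = 2..T and all
# per-step caches needed by bw_seq.
fw_seq <- function(m, xs, eps, latent_source = "posterior") {
  T_ <- length(xs)
  B <- dim(xs[[1L]])[1L]
  enc <- lapply(xs, function(x) enc_forward(m, x))
  st <- tvae_state(m, B)
  steps <- vector("list", T_)
  preds <- vector("list", T_)
  for (t in 2:T_) {
    pr <- head_fwd(m, "prior", enc[[t - 1L]]$f, st$prior)
    po <- head_fwd(m, "inf", enc[[t]]$f, st$inf)
    # residual posterior: the inference head models the correction to the
    # learned prior, so mu_q - mu_p is exactly the information in x_t beyond
    # the history and the KL penalizes only that correction
    po$mu <- pr$mu + po$mu
    st$prior <- pr$state; st$inf <- po$state
    use <- if (latent_source == "posterior") po else pr
    zt <- use$mu + exp(use$lv / 2) * eps[[t]]
    pd <- pred_fwd(m, enc[[t - 1L]]$f, zt, st$pred)
    st$pred <- pd$state
    de <- dec_forward(m, pd$g, zt, enc[[t - 1L]]$skips)
    preds[[t]] <- de$xhat
    steps[[t]] <- list(pr = pr, po = po, pd = pd, de = de, z = zt, eps = eps[[t]])
  }
  list(preds = preds, enc = enc, steps = steps, T_ = T_, B = B,
       latent_source = latent_source)
}

# Backward through fw_seq.  dpreds: list over t of gradients w.r.t. the
# predicted frames; dkl: list over t of lists (dmu_q, dlv_q, dmu_p, dlv_p)
# from the KL term (already weighted).  Returns the gradient list.
bw_seq <- function(m, fw, dpreds, dkl) {
  cfg <- m$cfg
  T_ <- fw$T_
  B <- fw$B
  nh <- cfg$lstm_hidden
  genv <- new.env(parent = emptyenv()); genv$g <- list()
  zero_h <- matrix(0, B, nh)
  car <- list(prior = list(h = zero_h, c = zero_h),
              inf = list(h = zero_h, c = zero_h),
              pred = list(h = zero_h, c = zero_h))
  dfacc <- vector("list", T_)
  dskipacc <- vector("list", T_)
  zmat0 <- matrix(0, B, cfg$z_dim)
  add_f <- function(t, d) dfacc[[t]] <<- if (is.null(dfacc[[t]])) d else dfacc[[t]] + d
  add_sk <- function(t, ds) {
    cur <- dskipacc[[t]]
    if (is.null(cur)) dskipacc[[t]] <<- ds
    else dskipacc[[t]] <<- mapply(function(a, b) {
      if (is.null(a)) b else if (is.null(b)) a else a + b
    }, cur, ds, SIMPLIFY = FALSE)
  }
  for (t in T_:2) {
    stp <- fw$steps[[t]]
    db <- dec_backward(m, dpreds[[t]], stp$de$cache, genv)
    add_sk(t - 1L, db$dskips)
    pb <- pred_bwd(m, db$dg, car$pred$h, car$pred$c, stp$pd$cache, genv)
    car$pred <- list(h = pb$dh, c = pb$dc)
    add_f(t - 1L, pb$df)
    dz <- pb$dz + db$dz
    kl <- if (is.null(dkl[[t]])) list(dmu_q = zmat0, dlv_q = zmat0,
                                      dmu_p = zmat0, dlv_p = zmat0) else dkl[[t]]
    use <- if (fw$latent_source == "posterior") stp$po else stp$pr
    dmu_use <- dz
    dlv_use <- dz * stp$eps * 0.5 * exp(use$lv / 2)
    if (fw$latent_source == "posterior") {
      dmu_q <- kl$dmu_q + dmu_use; dlv_q <- kl$dlv_q + dlv_use
      dmu_p <- kl$dmu_p; dlv_p <- kl$dlv_p
    } else {
      dmu_q <- kl$dmu_q; dlv_q <- kl$dlv_q
      dmu_p <- kl$dmu_p + dmu_use; dlv_p <- kl$dlv_p + dlv_use
    }
    ib <- head_bwd(m, "inf", dmu_q, dlv_q, car$inf$h, car$inf$c, stp$po$cache, genv)
    car$inf <- list(h = ib$dh, c = ib$dc)
    add_f(t, ib$df)
    # mu_q = mu_p + correction: gradients on the posterior mean also reach
    # the prior head (which therefore trains on reconstruction, not KL alone)
    dmu_p <- dmu_p + dmu_q
    pb2 <- head_bwd(m, "prior", dmu_p, dlv_p, car$prior$h, car$prior$c,
                    stp$pr$cache, genv)
    car$prior <- list(h = pb2$dh, c = pb2$dc)
    add_f(t - 1L, pb2$df)
  }
  empty_sk <- vector("list", cfg$n_levels)
  for (t in seq_len(T_)) {
    df <- dfacc[[t]]
    ds <- dskipacc[[t]]
    if (is.null(df) && is.null(ds)) next
    if (is.null(df)) df <- matrix(0, B, cfg$g_dim)
    if (is.null(ds)) ds <- empty_sk
    enc_backward(m, df, ds, fw$enc[[t]]$cache, genv)
  }
  genv$g
}

# Generation pass: warm the recurrent states on the context frames, then roll
# out future frames sampling latents from the learned prior.  Skip features
# are taken from the last context frame and frozen (generated content stays
# anchored to observed anatomy).
gen_seq <- function(m, ctx, n_future, eps, use_mean = FALSE) {
  k <- length(ctx)
  enc <- lapply(ctx, function(x) enc_forward(m, x))
  B <- dim(ctx[[1L]])[1L]
  st <- tvae_state(m, B)
  draw <- function(pr, e) if (use_mean) pr$mu else pr$mu + exp(pr$lv / 2) * e
  if (k >= 2L) for (t in 2:k) {
    pr <- head_fwd(m, "prior", enc[[t - 1L]]$f, st$prior)
    st$prior <- pr$state
    zt <- draw(pr, eps[[t]])
    pd <- pred_fwd(m, enc[[t - 1L]]$f, zt, st$pred)
    st$pred <- pd$state
  }
  skips <- enc[[k]]$skips
  f_prev <- enc[[k]]$f
  outs <- vector("list", n_future)
  for (j in seq_len(n_future)) {
    pr <- head_fwd(m, "prior", f_prev, st$prior)
    st$prior <- pr$state
    zt <- draw(pr, eps[[k + j]])
    pd <- pred_fwd(m, f_prev, zt, st$pred)
    st$pred <- pd$state
    de <- dec_forward(m, pd$g, zt, skips)
    outs[[j]] <- de$xhat
    if (j < n_future) f_prev <- enc_forward(m, de$xhat)$f
  }
  outs
}

draw_eps_list <- function(B, z_dim, t_index) {
  eps <- list()
  for (t in t_index) eps[[t]] <- matrix(stats::rnorm(B * z_dim), B)
  eps
}

## Exported functional operations -------------------------------------------

#' Encode a frame or volume
#'
#' Deterministic strided-convolution encoder shared by all three sub-models.
#'
#' @param model A `tvae_model`.
#' @param x A frame matrix (conv2d mode) or a depth x height x width volume
#'   array (conv3d mode) matching the configured input size.
#' @return A list with `features` (length `g_dim` vector) and `skips`
#'   (intermediate feature maps retained for decoder skip connections).
#' @export
encode <- function(model, x) {
  e <- enc_forward(model, as_batch(model, x))
  list(features = drop(e$f), skips = lapply(e$skips, function(s)
    if (is.null(s)) NULL else unbatch_multi(s)))
}

unbatch_multi <- function(x) {
  d <- dim(x)
  array(x, d[-1L])
}

rebatch_multi <- function(x) {
  array(x, c(1L, dim(x)))
}

#' Decode features back to a frame
#'
#' @param model A `tvae_model`.
#' @param features Feature vector of length `g_dim` (as produced by
#'   [encode()] or the predictor head; the latent slot is then taken as
#'   zero) or `g_dim + z_dim` (features with the latent draw appended).
#' @param skips Skip feature maps from [encode()].
#' @return A frame (or volume) of the encoder's input shape with all values
#'   strictly inside (0, 1).
#' @export
decode <- function(model, features, skips) {
  gd <- model$cfg$g_dim; zd <- model$cfg$z_dim
  if (length(features) == gd) features <- c(features, numeric(zd))
  if (length(features) != gd + zd)
    stop("features must have length g_dim = ", gd,
         " or g_dim + z_dim = ", gd + zd)
  g <- matrix(features[seq_len(gd)], 1L)
  z <- matrix(features[-seq_len(gd)], 1L)
  sk <- lapply(skips, function(s) if (is.null(s)) NULL else rebatch_multi(s))
  de <- dec_forward(model, g, z, sk)
  unbatch_frame(de$xhat)
}

#' One step of the prior estimator
#'
#' Computes the learned conditional prior over the next latent from the frame
#' at the previous time step and the prior LSTM's recurrent state.
#'
#' @param model A `tvae_model`.
#' @param x_prev Frame at time t-1.
#' @param state A `tvae_state` (from [tvae_state()] or a previous step).
#' @return List with `dist` (a [latent_distribution()]) and the advanced
#'   `state`.
#' @export
prior_step <- function(model, x_prev, state) {
  check_state(state)
  f <- enc_forward(model, as_batch(model, x_prev))$f
  h <- head_fwd(model, "prior", f, state$prior)
  state$prior <- h$state
  list(dist = latent_distribution(h$mu, h$lv), state = state)
}

#' One step of the latent inference model (training only)
#'
#' Computes the approximate posterior over the current latent from the
#' ground-truth current frame.  Refuses to run when the model phase is
#' `"generate"`, since ground truth is unavailable at generation time.
#'
#' @inheritParams prior_step
#' @param x_t Ground-truth frame at time t.
#' @param prior_mean Mean of the matching learned prior at this step.  The
#'   inference network parameterizes the posterior mean as a correction to
#'   the prior mean (residual parameterization), so the full posterior is
#'   `prior_mean + correction`; the default 0 returns the bare correction
#'   distribution.
#' @return List with `dist` and the advanced `state`.
#' @export
inference_step <- function(model, x_t, state, prior_mean = 0) {
  if (identical(model$phase, "generate"))
    stop("inference_step cannot be used in generation phase: ",
         "the posterior requires the ground-truth current frame")
  check_state(state)
  f <- enc_forward(model, as_batch(model, x_t))$f
  h <- head_fwd(model, "inf", f, state$inf)
  state$inf <- h$state
  list(dist = latent_distribution(drop(h$mu) + prior_mean, h$lv),
       state = state)
}

#' Sample a latent vector by reparameterization
#'
#' Draws z = mean + exp(log_variance / 2) * eps with eps standard normal.
#'
#' @param dist A [latent_distribution()].
#' @param seed Optional integer seed for a reproducible draw.
#' @return Numeric latent vector.
#' @export
sample_latent <- function(dist, seed = NULL) {
  stopifnot(inherits(dist, "latent_distribution"))
  eps <- with_seed(seed, stats::rnorm(length(dist$mean)))
  dist$mean + exp(dist$log_variance / 2) * eps
}

#' One step of the future predictor
#'
#' Concatenates the encoded previous frame with a latent draw, advances the
#' predictor LSTM and decodes (with skip connections) to the predicted frame.
#'
#' @inheritParams prior_step
#' @param z_t Latent vector of length `z_dim`.
#' @param skips Optional skip feature maps to use for decoding; defaults to
#'   those of `x_prev`.
#' @return List with `frame` (values in (0, 1)) and the advanced `state`.
#' @export
predictor_step <- function(model, x_prev, z_t, state, skips = NULL) {
  check_state(state)
  if (length(z_t) != model$cfg$z_dim)
    stop("z_t must have length z_dim = ", model$cfg$z_dim)
  e <- enc_forward(model, as_batch(model, x_prev))
  zmat <- matrix(z_t, 1L)
  pd <- pred_fwd(model, e$f, zmat, state$pred)
  state$pred <- pd$state
  sk <- if (is.null(skips)) e$skips
        else lapply(skips, function(s) if (is.null(s)) NULL else rebatch_multi(s))
  de <- dec_forward(model, pd$g, zmat, sk)
  list(frame = unbatch_frame(de$xhat), state = state)
}

#' Teacher-forced forward pass over a sequence
#'
#' Runs the full training-time pass: for each t = 2..T the posterior is
#' inferred from the ground-truth frame, the prior from the history, a latent
#' is sampled (from the posterior by default) and the predictor produces the
#' frame conditioned on the ground-truth previous frame.
#'
#' @param model A `tvae_model`.
#' @param seq A [slice_sequence()] or plain list of frames, length >= 2.
#' @param seed Optional seed for the latent draws.
#' @param latent_source `"posterior"` (training behaviour) or `"prior"`
#'   (mirrors the generation path; useful for consistency checks).
#' @return List with `predictions` (frames for t = 2..T), `priors`,
#'   `posteriors` (lists of [latent_distribution()]) and the `eps` draws used.
#' @export
forward_train <- function(model, seq, seed = NULL,
                          latent_source = c("posterior", "prior")) {
  latent_source <- match.arg(latent_source)
  frames <- if (inherits(seq, "slice_sequence")) seq$frames else seq
  if (length(frames) < 2L) stop("sequence must contain at least 2 frames")
  xs <- lapply(frames, function(f) as_batch(model, f))
  T_ <- length(xs)
  eps <- with_seed(seed, draw_eps_list(1L, model$cfg$z_dim, 2:T_))
  fw <- fw_seq(model, xs, eps, latent_source)
  list(predictions = lapply(fw$preds[2:T_], unbatch_frame),
       priors = lapply(2:T_, function(t)
         latent_distribution(fw$steps[[t]]$pr$mu, fw$steps[[t]]$pr$lv)),
       posteriors = lapply(2:T_, function(t)
         latent_distribution(fw$steps[[t]]$po$mu, fw$steps[[t]]$po$lv)),
       eps = eps)
}

#' Generate future frames from context
#'
#' Warms all recurrent states on the context frames, then rolls the model
#' forward sampling latents from the learned prior (the inference model is
#' not used).  The predictor is conditioned on the last context frame for the
#' first future step and on previously generated frames thereafter; skip
#' features are frozen from the last context frame.
#'
#' @param model A `tvae_model`.
#' @param context List of context frames x_1..x_k (k >= 1), or a
#'   [slice_sequence()].
#' @param n_future Number of frames to generate.
#' @param seed Optional seed for the prior draws.
#' @param sample `"random"` (default) draws latents; `"mean"` uses the prior
#'   mean (deterministic).
#' @return List of `n_future` generated frames.
#' @export
forward_generate <- function(model, context, n_future = 1L, seed = NULL,
                             sample = c("random", "mean")) {
  sample <- match.arg(sample)
  frames <- if (inherits(context, "slice_sequence")) context$frames else context
  if (length(frames) < 1L) stop("context must contain at least one frame")
  ctx <- lapply(frames, function(f) as_batch(model, f))
  k <- length(ctx)
  eps <- with_seed(seed, draw_eps_list(1L, model$cfg$z_dim, 2:(k + n_future)))
  outs <- gen_seq(model, ctx, n_future, eps, use_mean = (sample == "mean"))
  lapply(outs, unbatch_frame)
}
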