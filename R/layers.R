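# Low-level neural-network primitives on base R arrays.
#
# Feature maps are stored as arrays of dimension (B, spatial..., C) where B is
# the batch size, spatial is (H, W) for 2D or (D, H, W) for 3D, and C the
# channel count.  Convolutions are evaluated as matrix products through an
# im2col gather whose index table is cached per geometry; transposed
# convolutions are the exact adjoint (a scatter-add with the same table), so
# forward/backward pairs share code and the analytic gradients are exact.

.conv_geom_cache <- new.env(parent = emptyenv())

conv_out_spatial <- function(in_sp, k, s, p) (in_sp + 2L * p - k) %/% s + 1L

# im2col index table: idx[m, q] is the linear index (within one image laid out
# as (spatial..., C) column-major) of the input element that kernel column q
# reads when producing output position m.  Kernel columns are ordered
# (offset dim1 fastest, ..., channel slowest) to match the weight layout.
conv_geometry <- function(in_sp, cin, k, s, p) {
  key <- paste(c(in_sp, cin, k, s, p), collapse = "_")
  g <- .conv_geom_cache[[key]]
  if (!is.null(g)) return(g)
  nd <- length(in_sp)
  pad_sp <- in_sp + 2L * p
  out_sp <- conv_out_spatial(in_sp, k, s, p)
  if (any(out_sp < 1L))
    stop("convolution output would be empty for input ", paste(in_sp, collapse = "x"))
  no <- prod(out_sp)
  base <- as.matrix(do.call(expand.grid, lapply(out_sp, function(n) seq_len(n) - 1L))) * s
  koff <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), nd)))
  strides <- cumprod(c(1L, pad_sp[-nd]))
  plane <- prod(pad_sp)
  K <- nrow(koff) * cin
  idx <- matrix(0L, no, K)
  q <- 0L
  for (ch in seq_len(cin)) {
    ch_off <- (ch - 1L) * plane
    for (j in seq_len(nrow(koff))) {
      q <- q + 1L
      coord <- sweep(base, 2L, koff[j, ], "+")  # 1-based within padded image
      idx[, q] <- as.integer(1L + (coord - 1L) %*% strides + ch_off)
    }
  }
  g <- list(idx = idx, out_sp = out_sp, pad_sp = pad_sp, no = no, K = K,
            in_sp = in_sp, cin = cin, k = k, s = s, p = p)
  .conv_geom_cache[[key]] <- g
  g
}

pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  nd <- length(d) - 2L
  pd <- d
  pd[1L + seq_len(nd)] <- pd[1L + seq_len(nd)] + 2L * p
  xp <- array(0, pd)
  ix <- lapply(seq_along(d), function(i)
    if (i >= 2L && i <= nd + 1L) (p + 1L):(p + d[i]) else seq_len(d[i]))
  do.call(`[<-`, c(list(xp), ix, list(value = x)))
}

crop_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  nd <- length(d) - 2L
  ix <- lapply(seq_along(d), function(i)
    if (i >= 2L && i <= nd + 1L) (p + 1L):(d[i] - p) else seq_len(d[i]))
  do.call(`[`, c(list(x), ix, list(drop = FALSE)))
}

add_bias_cols <- function(Y, b) Y + rep(b, each = nrow(Y))

# Strided convolution.  W is a (k^nd * cin) x cout matrix whose rows follow
# the conv_geometry kernel-column order; b has length cout.
conv_fwd <- function(x, W, b, k, s, p) {
  d <- dim(x)
  B <- d[1L]
  nd <- length(d) - 2L
  sp <- d[1L + seq_len(nd)]
  cin <- d[length(d)]
  g <- conv_geometry(sp, cin, k, s, p)
  xp <- pad_spatial(x, p)
  dim(xp) <- c(B, prod(g$pad_sp) * cin)
  Xg <- xp[, as.vector(g$idx), drop = FALSE]
  dim(Xg) <- c(B * g$no, g$K)
  Y <- add_bias_cols(Xg %*% W, b)
  dim(Y) <- c(B, g$out_sp, ncol(W))
  list(y = Y, cache = list(Xg = Xg, g = g, B = B, cout = ncol(W)))
}

conv_bwd <- function(dy, W, cache) {
  g <- cache$g
  B <- cache$B
  dY <- dy
  dim(dY) <- c(B * g$no, cache$cout)
  dW <- crossprod(cache$Xg, dY)
  db <- colSums(dY)
  dXg <- dY %*% t(W)
  dxp <- matrix(0, B, prod(g$pad_sp) * g$cin)
  for (q in seq_len(g$K)) {
    cols <- g$idx[, q]
    dxp[, cols] <- dxp[, cols] + matrix(dXg[, q], B)
  }
  dim(dxp) <- c(B, g$pad_sp, g$cin)
  list(dx = crop_spatial(dxp, g$p), dW = dW, db = db)
}

tconv_out_spatial <- function(in_sp, k, s, p) (in_sp - 1L) * s - 2L * p + k

# Transposed convolution (adjoint of conv_fwd).  W is (k^nd * cout) x cin;
# geometry is that of the matching forward convolution out_sp -> in_sp.
tconv_fwd <- function(x, W, b, k, s, p) {
  d <- dim(x)
  B <- d[1L]
  nd <- length(d) - 2L
  in_sp <- d[1L + seq_len(nd)]
  cin <- d[length(d)]
  out_sp <- tconv_out_spatial(in_sp, k, s, p)
  cout <- nrow(W) %/% k^nd
  g <- conv_geometry(out_sp, cout, k, s, p)
  stopifnot(all(g$out_sp == in_sp))
  xmat <- x
  dim(xmat) <- c(B * prod(in_sp), cin)
  Ycol <- xmat %*% t(W)                         # (B*No_in) x (k^nd * cout)
  dyp <- matrix(0, B, prod(g$pad_sp) * cout)
  for (q in seq_len(g$K)) {
    cols <- g$idx[, q]
    dyp[, cols] <- dyp[, cols] + matrix(Ycol[, q], B)
  }
  dim(dyp) <- c(B, g$pad_sp, cout)
  y <- crop_spatial(dyp, p)
  y <- y + rep(b, each = B * prod(out_sp))
  list(y = y, cache = list(xmat = xmat, g = g, B = B, cin = cin,
                           cout = cout, out_sp = out_sp, in_sp = in_sp))
}

tconv_bwd <- function(dy, W, cache) {
  g <- cache$g
  B <- cache$B
  dym <- dy
  dim(dym) <- c(B * prod(cache$out_sp), cache$cout)
  db <- colSums(dym)
  dyp <- pad_spatial(dy, g$p)
  dim(dyp) <- c(B, prod(g$pad_sp) * cache$cout)
  Yg <- dyp[, as.vector(g$idx), drop = FALSE]
  dim(Yg) <- c(B * prod(cache$in_sp), g$K)
  dx <- Yg %*% W
  dim(dx) <- c(B, cache$in_sp, cache$cin)
  dW <- crossprod(Yg, cache$xmat)
  list(dx = dx, dW = dW, db = db)
}

# Channel concatenation/split for skip connections (last dimension).
concat_channels <- function(a, b) {
  da <- dim(a); db_ <- dim(b)
  stopifnot(all(da[-length(da)] == db_[-length(db_)]))
  n <- prod(da[-length(da)])
  am <- a; dim(am) <- c(n, da[length(da)])
  bm <- b; dim(bm) <- c(n, db_[length(db_)])
  out <- cbind(am, bm)
  dim(out) <- c(da[-length(da)], da[length(da)] + db_[length(db_)])
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  n <- prod(d[-length(d)])
  xm <- x; dim(xm) <- c(n, d[length(d)])
  a <- xm[, seq_len(c1), drop = FALSE]
  b <- xm[, -seq_len(c1), drop = FALSE]
  dim(a) <- c(d[-length(d)], c1)
  dim(b) <- c(d[-length(d)], d[length(d)] - c1)
  list(a, b)
}

## Activations ---------------------------------------------------------------

lrelu_fwd <- function(x, slope = 0.2) {
  m <- x > 0
  list(y = ifelse(m, x, slope * x), mask = m, slope = slope)
}
lrelu_bwd <- function(dy, act) dy * ifelse(act$mask, 1, act$slope)

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(dy, y) dy * y * (1 - y)
tanh_bwd <- function(dy, y) dy * (1 - y * y)

## Layer normalization (per sample over features) ----------------------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  s <- sqrt(v + eps)
  xh <- xc / s
  list(y = add_bias_cols(xh * rep(g, each = nrow(x)), b),
       cache = list(xh = xh, s = s, g = g))
}

ln_bwd <- function(dy, cache) {
  xh <- cache$xh
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dxh <- dy * rep(cache$g, each = nrow(dy))
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / cache$s
  list(dx = dx, dg = dg, db = db)
}

## Dense layer ---------------------------------------------------------------

linear_fwd <- function(x, W, b) list(y = add_bias_cols(x %*% W, b), x = x)
linear_bwd <- function(dy, W, cache)
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))

## LSTM cell -----------------------------------------------------------------

# Gate order in the weight matrix: input, forget, cell, output.
lstm_fwd <- function(x, h, c, W, b) {
  nh <- ncol(h)
  Z <- cbind(x, h)
  G <- add_bias_cols(Z %*% W, b)
  i <- sigmoid(G[, seq_len(nh), drop = FALSE])
  f <- sigmoid(G[, nh + seq_len(nh), drop = FALSE])
  g <- tanh(G[, 2L * nh + seq_len(nh), drop = FALSE])
  o <- sigmoid(G[, 3L * nh + seq_len(nh), drop = FALSE])
  c2 <- f * c + i * g
  tc2 <- tanh(c2)
  h2 <- o * tc2
  list(h = h2, c = c2,
       cache = list(Z = Z, i = i, f = f, g = g, o = o, c = c, tc2 = tc2,
                    nin = ncol(x), nh = nh))
}

lstm_bwd <- function(dh2, dc2, W, cache) {
  with(cache, {
    do_ <- dh2 * tc2
    dc <- dc2 + dh2 * o * (1 - tc2 * tc2)
    di <- dc * g
    df <- dc * c
    dg <- dc * i
    dc_prev <- dc * f
    dG <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g * g), do_ * o * (1 - o))
    dZ <- dG %*% t(W)
    list(dx = dZ[, seq_len(nin), drop = FALSE],
         dh = dZ[, nin + seq_len(nh), drop = FALSE],
         dc = dc_prev,
         dW = crossprod(Z, dG), db = colSums(dG))
  })
}

lstm_init <- function(nin, nh) {
  r <- 1 / sqrt(nh)
  W <- matrix(stats::runif((nin + nh) * 4L * nh, -r, r), nin + nh, 4L * nh)
  b <- numeric(4L * nh)
  b[nh + seq_len(nh)] <- 1  # forget-gate bias
  list(W = W, b = b)
}

## Parameter utilities & Adam ------------------------------------------------

zero_like_params <- function(params) lapply(params, function(p) array(0, dim(p) %||% length(p)))

`%||%` <- function(a, b) if (is.null(a)) b else a

grad_global_norm <- function(grads) sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))

clip_grads <- function(grads, max_norm) {
  n <- grad_global_norm(grads)
  if (is.finite(max_norm) && n > max_norm) grads <- lapply(grads, function(g) g * (max_norm / n))
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
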