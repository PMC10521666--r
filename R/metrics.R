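# Full-reference image-quality metrics.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`.  Identical inputs (zero MSE) return
#' `Inf` as a documented sentinel.
#'
#' @param pred,gt Frames (matrices or arrays) of equal shape.
#' @param data_range Dynamic range of the signal (1 for normalized frames).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, gt, data_range = 1) {
  if (!identical(dim(pred), dim(gt)))
    stop("psnr: shape mismatch between pred and gt")
  mse <- mean((pred - gt)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# valid-mode separable filtering with a 1D kernel along both axes
.valid_filter_matrix <- function(n, kern) {
  wlen <- length(kern)
  m <- n - wlen + 1L
  if (m < 1L) stop("frame smaller than the filter window")
  M <- matrix(0, m, n)
  for (i in seq_len(m)) M[i, i:(i + wlen - 1L)] <- kern
  M
}

#' Structural similarity index
#'
#' Mean local SSIM with the canonical construction: 11x11 Gaussian window of
#' standard deviation 1.5, stability constants K1 = 0.01 and K2 = 0.03,
#' population-weighted local moments, valid-mode windows.
#'
#' @param pred,gt Frames (matrices) of equal shape, at least 11x11.
#' @param data_range Dynamic range (default 1).
#' @return SSIM score in \[-1, 1\].
#' @export
ssim <- function(pred, gt, data_range = 1) {
  if (!identical(dim(pred), dim(gt)))
    stop("ssim: shape mismatch between pred and gt")
  if (any(dim(pred) < 11L))
    stop("ssim: frame smaller than the 11x11 window")
  kern <- stats::dnorm(seq(-5, 5), sd = 1.5)
  kern <- kern / sum(kern)
  Mr <- .valid_filter_matrix(nrow(pred), kern)
  Mc <- .valid_filter_matrix(ncol(pred), kern)
  F_ <- function(x) Mr %*% x %*% t(Mc)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- F_(pred); mu2 <- F_(gt)
  s11 <- F_(pred * pred) - mu1 * mu1
  s22 <- F_(gt * gt) - mu2 * mu2
  s12 <- F_(pred * gt) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1 * mu1 + mu2 * mu2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}
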