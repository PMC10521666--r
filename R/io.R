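# Image-stack I/O, normalization, resizing and training augmentations.
#
# Coordinate convention: frames are (row, col) matrices, row 1 at top;
# volumes are (slice, row, col) arrays, slices indexed from the first stack
# page.  All pixel values are gray levels; normalized frames live in [0, 1].

#' Ordered slice sequence for one subject
#'
#' @param frames List of T >= 2 frame matrices sharing dimensions.
#' @param subject_id Subject identifier.
#' @param slice_index Slice location within the volume (0-based, default 0).
#' @param week_labels Strictly increasing integer week labels.
#' @return A `slice_sequence` object.
#' @export
slice_sequence <- function(frames, subject_id = "subject",
                           slice_index = 0L,
                           week_labels = seq_along(frames)) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("frames must be a list of at least 2 frames")
  d1 <- dim(frames[[1L]])
  if (is.null(d1) || length(d1) != 2L) stop("frames must be matrices")
  for (f in frames) if (!identical(dim(f), d1))
    stop("all frames in a sequence must share dimensions")
  if (length(week_labels) != length(frames) || any(diff(week_labels) <= 0))
    stop("week_labels must be strictly increasing, one per frame")
  structure(list(frames = frames, subject_id = subject_id,
                 slice_index = as.integer(slice_index),
                 week_labels = as.integer(week_labels)),
            class = "slice_sequence")
}

#' @export
print.slice_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat("slice_sequence", x$subject_id, ":", length(x$frames), "frames of",
      d[1L], "x", d[2L], "(weeks", paste(x$week_labels, collapse = ","), ")\n")
  invisible(x)
}

#' Ordered volume sequence for one subject
#'
#' @param volumes List of T (slice, row, col) arrays sharing dimensions.
#' @param subject_id Subject identifier.
#' @param week_labels Strictly increasing integer week labels.
#' @return A `volume_sequence` object.
#' @export
volume_sequence <- function(volumes, subject_id = "subject",
                            week_labels = seq_along(volumes)) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("volumes must be a list of at least 2 volumes")
  d1 <- dim(volumes[[1L]])
  if (is.null(d1) || length(d1) != 3L) stop("volumes must be 3D arrays")
  for (v in volumes) if (!identical(dim(v), d1))
    stop("all volumes in a sequence must share dimensions")
  if (length(week_labels) != length(volumes) || any(diff(week_labels) <= 0))
    stop("week_labels must be strictly increasing, one per volume")
  structure(list(volumes = volumes, subject_id = subject_id,
                 week_labels = as.integer(week_labels)),
            class = "volume_sequence")
}

#' Read an image stack
#'
#' Reads a multi-page TIFF or a NIfTI (.nii / .nii.gz) file into a
#' (slice, row, col) volume array, preserving slice order and enforcing
#' single-channel grayscale data.
#'
#' @param path File path; the format is chosen from the extension.
#' @return Numeric array of dimension D x H x W.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d1 <- dim(pages[[1L]])
    if (length(d1) == 3L && d1[3L] > 1L)
      stop("TIFF: multi-channel (", d1[3L], " channels) input; ",
           "grayscale single-channel data required")
    for (p in pages) {
      dp <- dim(p)
      if (!identical(dp[1:2], d1[1:2]))
        stop("TIFF: inconsistent page sizes within the stack")
      if (length(dp) == 3L && dp[3L] > 1L)
        stop("TIFF: multi-channel page in stack; grayscale required")
    }
    vol <- array(0, c(length(pages), d1[1L], d1[2L]))
    for (i in seq_along(pages)) {
      p <- pages[[i]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      vol[i, , ] <- p
    }
    return(vol)
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop("NIfTI: expected a 3D single-channel volume, got ",
           length(dim(arr)), " dimensions")
    return(aperm(arr, c(3L, 1L, 2L)))
  }
  stop("unsupported stack format (need .tif/.tiff or .nii/.nii.gz): ", path)
}

#' Write an image stack
#'
#' Inverse of [read_stack()]: writes a (slice, row, col) volume as a
#' multi-page 32-bit TIFF or a NIfTI file.  NIfTI stores single-precision
#' floats, so a write/read round trip is bit-identical for data already at
#' single precision; TIFF stores 32-bit integer samples (the `tiff` package
#' does not write floats), so values in \[0, 1\] round-trip to within
#' `1 / 2^32`.
#'
#' @param vol Numeric D x H x W array.
#' @param path Output path (.tif/.tiff or .nii/.nii.gz).
#' @export
write_stack <- function(vol, path) {
  stopifnot(length(dim(vol)) == 3L)
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    pages <- lapply(seq_len(dim(vol)[1L]), function(i) vol[i, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    RNifti::writeNifti(RNifti::asNifti(aperm(vol, c(2L, 3L, 1L)), datatype = "float"),
                       path)
    return(invisible(path))
  }
  stop("unsupported stack format (need .tif/.tiff or .nii/.nii.gz): ", path)
}

#' Min-max normalize frames to \[0, 1\]
#'
#' Linear rescaling of a frame, or of a whole sequence sharing one intensity
#' range (the default for lists, so week-over-week intensity change within a
#' subject is preserved).  A constant input maps to all zeros.
#'
#' @param x A frame (matrix/array) or a list of frames.
#' @param lo,hi Optional range overrides; default is the observed min/max of
#'   the full input.
#' @return Same structure as `x`, values in \[0, 1\].
#' @export
normalize_frames <- function(x, lo = NULL, hi = NULL) {
  vals <- unlist(x, use.names = FALSE)
  if (any(!is.finite(vals))) stop("normalize_frames: input contains NaN/Inf")
  if (is.null(lo)) lo <- min(vals)
  if (is.null(hi)) hi <- max(vals)
  rescale <- function(f) {
    if (hi <= lo) return(f * 0)
    pmin(pmax((f - lo) / (hi - lo), 0), 1)
  }
  if (is.list(x)) lapply(x, rescale) else rescale(x)
}

#' Bilinear resize of a frame
#'
#' Separable bilinear interpolation to `target` x `target` pixels, using the
#' pixel-center alignment convention; the output is clipped to \[0, 1\] when
#' `clip = TRUE`.
#'
#' @param frame Frame matrix.
#' @param target Output side length (>= 1).
#' @param clip Clip output into \[0, 1\] (default TRUE).
#' @return `target` x `target` matrix.
#' @export
resize_frame <- function(frame, target, clip = TRUE) {
  stopifnot(target >= 1)
  Mr <- .bilinear_matrix(nrow(frame), target)
  Mc <- .bilinear_matrix(ncol(frame), target)
  out <- Mr %*% frame %*% t(Mc)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

.bilinear_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    src <- min(max(src, 1), n_in)
    lo <- floor(src)
    hi <- min(lo + 1, n_in)
    w <- src - lo
    M[i, lo] <- M[i, lo] + (1 - w)
    M[i, hi] <- M[i, hi] + w
  }
  M
}

#' Training augmentation of a sequence
#'
#' Draws one crop offset (uniform over valid positions) and one horizontal
#' flip decision per sequence and applies them identically to every frame,
#' preserving temporal correspondence; frames are then resized to `out_size`.
#'
#' @param seq A [slice_sequence()] whose frames are at least
#'   `crop_size` x `crop_size`.
#' @param crop_size Side of the random crop (default 96); `NULL` disables
#'   cropping.
#' @param out_size Side of the final resize (default 64); `NULL` disables
#'   resizing.
#' @param flip_prob Horizontal flip probability (default 0.5).
#' @param seed Optional seed for the augmentation draws.
#' @return The augmented `slice_sequence`; the draw actually applied is
#'   attached as attribute `"augmentation"`.
#' @export
augment_sequence <- function(seq, crop_size = 96, out_size = 64,
                             flip_prob = 0.5, seed = NULL) {
  stopifnot(inherits(seq, "slice_sequence"))
  d <- dim(seq$frames[[1L]])
  aug <- with_seed(seed, {
    off <- c(1L, 1L)
    if (!is.null(crop_size)) {
      if (any(d < crop_size))
        stop("frames (", d[1L], "x", d[2L], ") are smaller than crop_size ", crop_size)
      off <- c(sample.int(d[1L] - crop_size + 1L, 1L),
               sample.int(d[2L] - crop_size + 1L, 1L))
    }
    list(offset = off, flip = stats::runif(1) < flip_prob)
  })
  tf <- function(f) {
    if (!is.null(crop_size))
      f <- f[aug$offset[1L]:(aug$offset[1L] + crop_size - 1L),
             aug$offset[2L]:(aug$offset[2L] + crop_size - 1L), drop = FALSE]
    if (aug$flip) f <- f[, rev(seq_len(ncol(f))), drop = FALSE]
    if (!is.null(out_size) && !identical(dim(f), c(out_size, out_size)))
      f <- resize_frame(f, out_size)
    f
  }
  out <- seq
  out$frames <- lapply(seq$frames, tf)
  attr(out, "augmentation") <- aug
  out
}

#' Evaluation-time preprocessing
#'
#' The test-time path performs no crop and no flip: every frame is directly
#' resized to `out_size`.
#'
#' @param seq A [slice_sequence()].
#' @param out_size Final side length (default 64).
#' @return The resized `slice_sequence`.
#' @export
prepare_eval_sequence <- function(seq, out_size = 64) {
  stopifnot(inherits(seq, "slice_sequence"))
  out <- seq
  out$frames <- lapply(seq$frames, function(f)
    if (identical(dim(f), c(out_size, out_size))) f else resize_frame(f, out_size))
  out
}
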