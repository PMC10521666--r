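# Synthetic longitudinal osteolysis phantom.
#
# Each phantom frame is a transverse bone cross-section: near-zero soft-tissue
# background, a bright annular cortical ring, and a dim textured marrow
# interior.  A lesion, when present, is an angular perforation of the ring
# that appears at a stochastic onset week and widens monotonically -- the
# dynamics the temporal model is asked to learn.

mix_seed <- function(a, b) {
  x <- (as.numeric(a) %% 2147483647 + 2147483647) %% 2147483647
  x <- (x * 48271 + as.numeric(b) %% 2147483647 * 2654435 + 12345) %% 2147483647
  x <- (x * 69069 + 1) %% 2147483647
  as.integer(x) + 1L
}

#' Phantom generator parameters
#'
#' Geometry, intensity and lesion-dynamics parameters of the synthetic bone
#' cross-section simulator.  Cortical bone is bright and marrow dim, as in
#' attenuation-based CT; intensities are gray levels in \[0, 1\].
#'
#' @param image_size Pixels per side (default 64).
#' @param ring_center (row, col) center in pixels; defaults to the image
#'   center.
#' @param ring_outer_radius Outer cortical radius in pixels; default
#'   `0.38 * image_size`.
#' @param ring_thickness Cortical thickness in pixels; default
#'   `0.14 * image_size`.
#' @param cortical_intensity Gray level of cortical bone (default 0.85).
#' @param marrow_intensity_mean,marrow_intensity_sd Mean and spatial standard
#'   deviation of the textured marrow interior (defaults 0.15, 0.08).
#' @param marrow_ar1 Week-to-week AR(1) correlation of the marrow texture
#'   field in \[0, 1\]; 1 freezes the texture (fully deterministic interior),
#'   the default 0.6 leaves part of the interior unpredictable, emulating
#'   trabecular remodelling.
#' @param lesion_prevalence Probability that a subject develops a lesion
#'   (default 0.6).
#' @param lesion_onset_week Either a single onset week in {2, 3, 4} or a
#'   probability vector over weeks 2..4 (default uniform).
#' @param lesion_growth_rate Radians of angular width gained per week
#'   (default 0.5).
#' @param lesion_angle Fixed angular position of the lesion center in
#'   radians, or `NULL` (default) to draw it uniformly per subject.  Fixing
#'   it (together with a single onset week, prevalence 1 and frozen marrow
#'   texture) makes the phantom dynamics fully deterministic.
#' @param lesion_band `"random"` (default) draws a contiguous slice band the
#'   lesion occupies in volume phantoms; `"full"` lets it span every slice
#'   (used for fully deterministic dynamics).
#' @param noise_sd Additive Gaussian noise scale (default 0.03).
#' @param n_weeks Sequence length T (default 4, >= 2).
#' @param n_slices Slices per volume (default 48).
#' @return A validated `phantom_params` object.
#' @export
phantom_params <- function(image_size = 64,
                           ring_center = NULL,
                           ring_outer_radius = 0.38 * image_size,
                           ring_thickness = 0.14 * image_size,
                           cortical_intensity = 0.85,
                           marrow_intensity_mean = 0.15,
                           marrow_intensity_sd = 0.08,
                           marrow_ar1 = 0.6,
                           lesion_prevalence = 0.6,
                           lesion_onset_week = c(`2` = 1, `3` = 1, `4` = 1) / 3,
                           lesion_growth_rate = 0.5,
                           lesion_angle = NULL,
                           lesion_band = c("random", "full"),
                           noise_sd = 0.03,
                           n_weeks = 4,
                           n_slices = 48) {
  if (is.null(ring_center)) ring_center <- rep((image_size + 1) / 2, 2)
  if (!(ring_thickness > 0 && ring_thickness < ring_outer_radius &&
        ring_outer_radius < image_size / 2))
    stop("require 0 < ring_thickness < ring_outer_radius < image_size/2")
  ints <- c(cortical_intensity, marrow_intensity_mean, marrow_intensity_sd)
  if (any(ints < 0) || any(ints > 1))
    stop("intensity parameters must lie in [0, 1]")
  if (lesion_prevalence < 0 || lesion_prevalence > 1)
    stop("lesion_prevalence must lie in [0, 1]")
  if (marrow_ar1 < 0 || marrow_ar1 > 1)
    stop("marrow_ar1 must lie in [0, 1]")
  if (n_weeks < 2) stop("n_weeks must be at least 2")
  if (length(lesion_onset_week) == 1L) {
    if (!lesion_onset_week %in% 2:4) stop("lesion_onset_week must be in {2, 3, 4}")
  } else {
    if (length(lesion_onset_week) != 3L || any(lesion_onset_week < 0) ||
        sum(lesion_onset_week) <= 0)
      stop("lesion_onset_week distribution must be 3 non-negative weights over weeks 2..4")
  }
  structure(list(image_size = as.integer(image_size), ring_center = ring_center,
                 ring_outer_radius = ring_outer_radius,
                 ring_thickness = ring_thickness,
                 cortical_intensity = cortical_intensity,
                 marrow_intensity_mean = marrow_intensity_mean,
                 marrow_intensity_sd = marrow_intensity_sd,
                 marrow_ar1 = marrow_ar1,
                 lesion_prevalence = lesion_prevalence,
                 lesion_onset_week = lesion_onset_week,
                 lesion_growth_rate = lesion_growth_rate,
                 lesion_angle = lesion_angle,
                 lesion_band = match.arg(lesion_band),
                 noise_sd = noise_sd, n_weeks = as.integer(n_weeks),
                 n_slices = as.integer(n_slices)),
            class = "phantom_params")
}

#' Lesion ground-truth state
#'
#' @param present Logical: does the subject develop a lesion.
#' @param onset_week Integer onset week (NA when absent).
#' @param angular_position Lesion center angle in \[0, 2*pi).
#' @param angular_width_by_week Non-decreasing angular widths (radians), one
#'   per week, zero before onset.
#' @param slice_band Optional (lo, hi) contiguous slice range the lesion
#'   occupies in volume phantoms.
#' @return A validated `lesion_state` object.
#' @export
lesion_state <- function(present, onset_week = NA_integer_,
                         angular_position = 0,
                         angular_width_by_week = numeric(),
                         slice_band = NULL) {
  w <- angular_width_by_week
  if (length(w) && any(diff(w) < 0))
    stop("angular_width_by_week must be non-decreasing")
  if (present && !is.na(onset_week) && onset_week > 1 &&
      any(w[seq_len(onset_week - 1L)] != 0))
    stop("angular width must be 0 before onset_week")
  if (!present && length(w) && any(w != 0))
    stop("angular width must be 0 when no lesion is present")
  structure(list(present = isTRUE(present), onset_week = as.integer(onset_week),
                 angular_position = angular_position %% (2 * pi),
                 angular_width_by_week = w, slice_band = slice_band),
            class = "lesion_state")
}

draw_lesion_state <- function(params, seed, with_band = FALSE) {
  with_seed(seed, {
    present <- stats::runif(1) < params$lesion_prevalence
    nw <- params$n_weeks
    if (!present)
      return(lesion_state(FALSE, angular_width_by_week = numeric(nw)))
    onset <- if (length(params$lesion_onset_week) == 1L) {
      stats::runif(1)  # keep the rng stream aligned across onset modes
      as.integer(params$lesion_onset_week)
    } else {
      p <- params$lesion_onset_week / sum(params$lesion_onset_week)
      (2:4)[findInterval(stats::runif(1), cumsum(p), left.open = TRUE) + 1L]
    }
    pos <- stats::runif(1, 0, 2 * pi)
    if (!is.null(params$lesion_angle)) pos <- params$lesion_angle
    weeks <- seq_len(nw)
    widths <- pmin(pmax(weeks - onset + 1, 0) * params$lesion_growth_rate, 2 * pi)
    band <- NULL
    if (with_band) {
      if (identical(params$lesion_band, "full")) {
        band <- c(1L, params$n_slices)
      } else {
        half <- max(1L, params$n_slices %/% 6L)
        ctr <- sample.int(params$n_slices, 1L)
        band <- c(max(1L, ctr - half), min(params$n_slices, ctr + half))
      }
    }
    lesion_state(TRUE, onset, pos, widths, band)
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# marrow texture: low-amplitude smoothed random field evolving week to week
# as an AR(1) process -- trabecular remodelling makes the interior only
# partially predictable from earlier scans, so non-boundary regions carry
# genuine stochasticity (the regime where sampled predictions may vary).
# marrow_ar1 = 1 freezes the texture (fully deterministic interior).

marrow_field <- function(n, seed) {
  with_seed(seed, {
    f <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 2)
    f / stats::sd(f)
  })
}

marrow_texture <- function(params, seed, week) {
  n <- params$image_size
  rho <- params$marrow_ar1 %||% 0.6
  field <- marrow_field(n, mix_seed(seed, 501))
  if (week > 1 && rho < 1) for (w in 2:week) {
    innov <- marrow_field(n, mix_seed(seed, 500 + w))
    field <- rho * field + sqrt(1 - rho^2) * innov
  }
  clamp01(params$marrow_intensity_mean + params$marrow_intensity_sd * field)
}

#' Render one phantom frame
#'
#' Draws the cross-section at the given week: annular cortical ring, textured
#' marrow interior, near-zero background, and -- if the lesion is present and
#' the week has reached its onset -- an erased angular sector of the ring
#' whose width follows the lesion state.  The marrow texture evolves across
#' weeks as a smooth AR(1) random field and the additive noise is drawn per
#' week, both as deterministic functions of `(rng_seed, week)`, so repeated
#' calls are bit-identical while the annulus is time-invariant apart from
#' noise in lesion-free subjects.
#'
#' @param params [phantom_params()].
#' @param lesion [lesion_state()].
#' @param week Week index in 1..n_weeks.
#' @param rng_seed Integer seed.
#' @param slice_index Optional slice index (volume phantoms): tapers the ring
#'   radius along the metaphysis and restricts the lesion to its slice band.
#' @return An image_size x image_size frame with values in \[0, 1\].
#' @export
render_phantom_slice <- function(params, lesion, week, rng_seed,
                                 slice_index = NULL) {
  stopifnot(inherits(params, "phantom_params"), inherits(lesion, "lesion_state"))
  if (week < 1 || week > params$n_weeks)
    stop("week must lie in 1..", params$n_weeks)
  n <- params$image_size
  taper <- 1
  if (!is.null(slice_index)) {
    if (slice_index < 1 || slice_index > params$n_slices)
      stop("slice_index must lie in 1..", params$n_slices)
    taper <- 0.75 + 0.25 * (slice_index - 1) / max(1L, params$n_slices - 1L)
  }
  outer <- params$ring_outer_radius * taper
  inner <- outer - params$ring_thickness
  rr <- matrix(seq_len(n) - params$ring_center[1], n, n)
  cc <- matrix(seq_len(n) - params$ring_center[2], n, n, byrow = TRUE)
  r <- sqrt(rr * rr + cc * cc)
  cort_w <- clamp01(r - (inner - 1)) * clamp01(outer + 1 - r)
  marrow_w <- clamp01(inner - r)
  tex <- marrow_texture(params, rng_seed, week)

  sector <- 0
  in_band <- is.null(slice_index) || is.null(lesion$slice_band) ||
    (slice_index >= lesion$slice_band[1] && slice_index <= lesion$slice_band[2])
  if (lesion$present && !is.na(lesion$onset_week) && week >= lesion$onset_week &&
      in_band) {
    width <- lesion$angular_width_by_week[week]
    if (width > 0) {
      theta <- atan2(rr, cc) %% (2 * pi)
      adist <- abs((theta - lesion$angular_position + pi) %% (2 * pi) - pi)
      sector <- clamp01((width / 2 - adist) / 0.08)
    }
  }

  img <- cort_w * (1 - sector) * params$cortical_intensity +
    (cort_w * sector + marrow_w) * tex
  noise_seed <- mix_seed(rng_seed, 7919 + week)
  noise <- with_seed(noise_seed, matrix(stats::rnorm(n * n, sd = params$noise_sd), n, n))
  clamp01(img + noise)
}

#' Generate one phantom slice sequence
#'
#' Draws a lesion state (Bernoulli presence, onset and angular position from
#' the configured distributions) and renders `n_weeks` frames sharing that
#' state.  The returned sequence carries the ground-truth state in its
#' `lesion` field.
#'
#' @param params [phantom_params()].
#' @param subject_seed Integer seed; identical seeds give identical output.
#' @return A [slice_sequence()] with a `lesion` ground-truth field.
#' @export
generate_phantom_sequence <- function(params, subject_seed) {
  lesion <- draw_lesion_state(params, mix_seed(subject_seed, 1))
  rseed <- mix_seed(subject_seed, 2)
  frames <- lapply(seq_len(params$n_weeks), function(w)
    render_phantom_slice(params, lesion, w, rseed))
  seq <- slice_sequence(frames, subject_id = paste0("S", subject_seed),
                        week_labels = seq_len(params$n_weeks))
  seq$lesion <- lesion
  seq
}

#' Generate one phantom volume sequence
#'
#' A volume is `n_slices` rendered slices sharing one lesion state, with a
#' slice-dependent ring radius (tapered metaphysis) and the lesion restricted
#' to a contiguous slice band.
#'
#' @inheritParams generate_phantom_sequence
#' @return A [volume_sequence()] with a `lesion` ground-truth field.
#' @export
generate_phantom_volume_sequence <- function(params, subject_seed) {
  lesion <- draw_lesion_state(params, mix_seed(subject_seed, 1), with_band = TRUE)
  n <- params$image_size
  vols <- lapply(seq_len(params$n_weeks), function(w) {
    v <- array(0, c(params$n_slices, n, n))
    for (d in seq_len(params$n_slices))
      v[d, , ] <- render_phantom_slice(params, lesion, w,
                                       mix_seed(subject_seed, 100 + d),
                                       slice_index = d)
    v
  })
  seq <- volume_sequence(vols, subject_id = paste0("S", subject_seed),
                         week_labels = seq_len(params$n_weeks))
  seq$lesion <- lesion
  seq
}

#' Generate a subject-split phantom dataset
#'
#' Renders `n_subjects` independent phantom sequences and partitions the
#' subjects (never frames or slices) into train and test sets.  The split and
#' every sequence are deterministic functions of `master_seed`; each subject
#' is individually regenerable from its derived seed.
#'
#' @param params [phantom_params()].
#' @param n_subjects Number of subjects (>= 2).
#' @param train_fraction Proportion of subjects in the training split
#'   (default 0.8); the train size is `floor(train_fraction * n_subjects)`.
#' @param master_seed Integer seed controlling subject seeds and the split.
#' @param type `"slice"` (default) or `"volume"` sequences.
#' @param slices_per_subject For `type = "slice"`: number of slice locations
#'   sampled per subject (default 1).  Locations are evenly spread across the
#'   volume; all slices of one subject share its lesion state (restricted to
#'   the lesion's slice band) and stay in the same split.
#' @return List with `train` and `test` lists of sequences; the ground-truth
#'   table (subject, split, lesion state) is attached as attribute `"truth"`.
#' @export
generate_dataset <- function(params, n_subjects, train_fraction = 0.8,
                             master_seed = 1, type = c("slice", "volume"),
                             slices_per_subject = 1L) {
  type <- match.arg(type)
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n_train <- floor(train_fraction * n_subjects)
  if (n_train < 1 || n_train >= n_subjects)
    stop("n_subjects too small to populate both splits at this train_fraction")
  perm <- with_seed(master_seed, sample.int(n_subjects))
  train_ids <- sort(perm[seq_len(n_train)])
  seqs <- vector("list", n_subjects)
  lesions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%04d", i)
    sseed <- mix_seed(master_seed, 1000 + i)
    if (type == "volume") {
      s <- generate_phantom_volume_sequence(params, sseed)
      s$subject_id <- sid
      seqs[[i]] <- list(s)
      lesions[[i]] <- s$lesion
    } else if (slices_per_subject <= 1L) {
      s <- generate_phantom_sequence(params, sseed)
      s$subject_id <- sid
      seqs[[i]] <- list(s)
      lesions[[i]] <- s$lesion
    } else {
      lesion <- draw_lesion_state(params, mix_seed(sseed, 1), with_band = TRUE)
      locs <- unique(round(seq(1, params$n_slices,
                               length.out = slices_per_subject)))
      seqs[[i]] <- lapply(locs, function(d) {
        frames <- lapply(seq_len(params$n_weeks), function(w)
          render_phantom_slice(params, lesion, w, mix_seed(sseed, 100 + d),
                               slice_index = d))
        sq <- slice_sequence(frames, subject_id = sid, slice_index = d,
                             week_labels = seq_len(params$n_weeks))
        sq$lesion <- lesion
        sq
      })
      lesions[[i]] <- lesion
    }
  }
  truth <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    le <- lesions[[i]]
    data.frame(subject_id = sprintf("S%04d", i),
               split = if (i %in% train_ids) "train" else "test",
               present = le$present, onset_week = le$onset_week,
               angular_position = le$angular_position,
               t(stats::setNames(le$angular_width_by_week,
                                 paste0("width_w", seq_along(le$angular_width_by_week)))))
  }))
  out <- list(train = do.call(c, seqs[train_ids]),
              test = do.call(c, seqs[-train_ids]))
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}
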