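test_that("rendered frames respect geometry, range and sparsity", {
  p <- small_phantom()
  s <- generate_phantom_sequence(p, 42)
  masks <- phantom_masks(p)
  for (f in s$frames) {
    expect_true(all(f >= 0 & f <= 1))
    expect_lte(mean(f[masks$background]), p$noise_sd)
    expect_gt(mean(f[masks$annulus]), 0.6)
  }
})

test_that("rendering is deterministic and time-invariant without a lesion", {
  p <- small_phantom(lesion_prevalence = 0)
  le <- tvae:::draw_lesion_state(p, 5)
  expect_false(le$present)
  f1 <- render_phantom_slice(p, le, 1, rng_seed = 9)
  expect_identical(f1, render_phantom_slice(p, le, 1, rng_seed = 9))
  # annulus pixels identical across weeks up to additive noise
  masks <- phantom_masks(p)
  f3 <- render_phantom_slice(p, le, 3, rng_seed = 9)
  expect_lt(max(abs(f1[masks$annulus] - f3[masks$annulus])), 8 * p$noise_sd)
})

test_that("lesion width is zero before onset and erases the ring after", {
  p <- small_phantom(lesion_prevalence = 1, lesion_onset_week = 4,
                     lesion_angle = 0)
  le <- tvae:::draw_lesion_state(p, 3)
  expect_identical(le$angular_width_by_week[1:3], c(0, 0, 0))
  f3 <- render_phantom_slice(p, le, 3, rng_seed = 2)
  f4 <- render_phantom_slice(p, le, 4, rng_seed = 2)
  masks <- phantom_masks(p)
  th <- atan2(matrix(seq_len(32) - p$ring_center[1], 32, 32),
              t(matrix(seq_len(32) - p$ring_center[2], 32, 32))) %% (2 * pi)
  sec <- abs((th - le$angular_position + pi) %% (2 * pi) - pi) <
    le$angular_width_by_week[4] / 2
  expect_gt(mean(f3[masks$annulus & sec]), 0.6)  # intact before onset
  expect_lt(mean(f4[masks$annulus & sec]), 0.45) # perforated at onset
  expect_error(render_phantom_slice(p, le, 5, 1), "week")
})

test_that("growth recurrence matches the hand-computed width table", {
  p <- small_phantom(lesion_prevalence = 1, lesion_onset_week = 2,
                     lesion_growth_rate = 0.4)
  le <- tvae:::draw_lesion_state(p, 11)
  # onset week 2, rate 0.4: widths 0, 0.4, 0.8, 1.2
  expect_equal(le$angular_width_by_week, c(0, 0.4, 0.8, 1.2))
  expect_equal(le$angular_width_by_week[4],
               le$angular_width_by_week[2] + 2 * p$lesion_growth_rate)
})

test_that("lesion widths are non-decreasing across 1000 seeded subjects", {
  p <- small_phantom()
  for (i in 1:1000) {
    le <- tvae:::draw_lesion_state(p, i)
    expect_false(is.unsorted(le$angular_width_by_week))
    if (le$present && le$onset_week > 1)
      expect_true(all(le$angular_width_by_week[seq_len(le$onset_week - 1)] == 0))
  }
})

test_that("lesion prevalence matches its Bernoulli rate", {
  p <- small_phantom(lesion_prevalence = 0.6)
  hits <- vapply(1:10000, function(i) tvae:::draw_lesion_state(p, i)$present,
                 logical(1))
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(mean(hits) - 0.6), 3 * se)
  p0 <- small_phantom(lesion_prevalence = 0)
  expect_false(any(vapply(1:50, function(i)
    tvae:::draw_lesion_state(p0, i)$present, logical(1))))
})

test_that("sequences are reproducible and carry ground truth", {
  p <- small_phantom()
  a <- generate_phantom_sequence(p, 123)
  b <- generate_phantom_sequence(p, 123)
  expect_identical(a, b)
  expect_s3_class(a, "slice_sequence")
  expect_s3_class(a$lesion, "lesion_state")
  expect_length(a$frames, p$n_weeks)
})

test_that("dataset split partitions subjects and mirrors an 80:20 design", {
  p <- small_phantom()
  ds <- generate_dataset(p, 111, 0.8, master_seed = 5)
  expect_length(ds$train, 88)
  expect_length(ds$test, 23)
  ids_tr <- vapply(ds$train, function(s) s$subject_id, "")
  ids_te <- vapply(ds$test, function(s) s$subject_id, "")
  expect_length(intersect(ids_tr, ids_te), 0)
  expect_setequal(c(ids_tr, ids_te), sprintf("S%04d", 1:111))
  ds2 <- generate_dataset(p, 111, 0.8, master_seed = 5)
  expect_identical(attr(ds, "truth"), attr(ds2, "truth"))
  expect_identical(ds$train[[1]]$frames, ds2$train[[1]]$frames)
  expect_error(generate_dataset(p, 1, 0.8, 1), "at least 2")
  expect_error(generate_dataset(p, 3, 0.1, 1), "too small")
})

test_that("multi-slice subjects share lesion state and stay in one split", {
  p <- small_phantom(n_slices = 16)
  ds <- generate_dataset(p, 10, 0.8, master_seed = 3, slices_per_subject = 3)
  expect_length(ds$train, 8 * 3)
  ids_tr <- unique(vapply(ds$train, function(s) s$subject_id, ""))
  ids_te <- unique(vapply(ds$test, function(s) s$subject_id, ""))
  expect_length(intersect(ids_tr, ids_te), 0)
  by_subj <- split(ds$train, vapply(ds$train, function(s) s$subject_id, ""))
  for (grp in by_subj) {
    expect_length(unique(lapply(grp, function(s) s$lesion)), 1L)
    expect_gt(length(unique(vapply(grp, function(s) s$slice_index, 0L))), 1L)
  }
})

test_that("volume phantoms taper the ring and confine lesions to a band", {
  p <- small_phantom(n_slices = 8, lesion_prevalence = 1,
                     lesion_onset_week = 2)
  vs <- generate_phantom_volume_sequence(p, 77)
  expect_identical(dim(vs$volumes[[1]]), c(8L, 32L, 32L))
  expect_length(vs$volumes, p$n_weeks)
  expect_true(all(vs$lesion$slice_band >= 1 & vs$lesion$slice_band <= 8))
  # ring radius grows with slice index (tapered metaphysis): compare bright
  # areas of the first and last slice
  v1 <- vs$volumes[[1]]
  expect_lt(sum(v1[1, , ] > 0.5), sum(v1[8, , ] > 0.5))
})

test_that("invalid parameters are rejected", {
  expect_error(phantom_params(ring_thickness = 0), "ring_thickness")
  expect_error(phantom_params(ring_outer_radius = 40, image_size = 64),
               "ring")
  expect_error(phantom_params(cortical_intensity = 1.5), "intensity")
  expect_error(phantom_params(lesion_prevalence = 2), "prevalence")
  expect_error(phantom_params(n_weeks = 1), "n_weeks")
  expect_error(lesion_state(TRUE, 2L, 0, c(0.5, 0.4, 0.3, 0.2)),
               "non-decreasing")
  expect_error(lesion_state(TRUE, 3L, 0, c(0.1, 0.2, 0.3, 0.4)),
               "before onset")
})
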