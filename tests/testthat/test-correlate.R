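naive_ttc <- function(mat) {
  n_t <- nrow(mat)
  out <- matrix(0, n_t, n_t)
  for (a in seq_len(n_t)) {
    for (b in seq_len(n_t)) {
      out[a, b] <- mean(mat[a, ] * mat[b, ]) / (mean(mat[a, ]) * mean(mat[b, ]))
    }
  }
  out
}

frames_from_matrix <- function(mat, n) {
  # embed a (n_t x n_pix) intensity matrix into a 3D frame stack whose
  # first n_pix linear positions form the mask
  n_t <- nrow(mat)
  arr <- array(1, c(n_t, n, n))
  for (t in seq_len(n_t)) arr[t, , ][seq_len(ncol(mat))] <- mat[t, ]
  arr
}

test_that("the TTC agrees with a naive double-loop evaluation", {
  set.seed(7)
  n_t <- 10
  n_pix <- 50
  mat <- matrix(rexp(n_t * n_pix) + 0.1, n_t, n_pix)
  arr <- frames_from_matrix(mat, 12)
  ttc <- compute_ttc(arr, seq_len(n_pix), q_center = 5, dq = 1)
  expect_equal(ttc$values, naive_ttc(mat), tolerance = 1e-12)
  expect_identical(ttc$values, t(ttc$values))
  expect_equal(ttc$ring_intensity, rowMeans(mat))
})

test_that("degenerate TTC inputs are rejected or collapse to constants", {
  arr <- array(2, c(5, 8, 8))
  ttc <- compute_ttc(arr, 1:10)
  expect_true(all(abs(ttc$values - 1) < 1e-14))  # constant frames, flat mask
  # single-pixel mask: C is identically 1
  ttc1 <- compute_ttc(array(rexp(5 * 64) + 1, c(5, 8, 8)), 7L)
  expect_true(all(abs(ttc1$values - 1) < 1e-12))
  # a zero frame has zero mean intensity
  arr0 <- array(1, c(4, 8, 8)); arr0[2, , ] <- 0
  expect_error(compute_ttc(arr0, 1:5),
               class = "specklematch_degenerate_error")
  expect_error(compute_ttc(array(1, c(1, 8, 8)), 1:5),
               class = "specklematch_input_error")
})

test_that("fully coherent static speckle has diagonal contrast near 2", {
  # complex-Gaussian field => exponential intensity statistics =>
  # <I^2>/<I>^2 = 2; Monte-Carlo check over a 2000-pixel mask
  set.seed(11)
  n_pix <- 2000
  n_t <- 6
  amp <- complex(real = rnorm(n_pix), imaginary = rnorm(n_pix))
  mat <- matrix(rep(Mod(amp)^2, each = n_t), n_t, n_pix)
  ttc <- compute_ttc(frames_from_matrix(mat, 64), seq_len(n_pix))
  expect_equal(mean(diag(ttc$values)), 2, tolerance = 0.1)
})

test_that("cropping at the intensity peak keeps the right sub-matrix", {
  set.seed(3)
  n_t <- 30
  mat <- matrix(rexp(n_t * 40) + 0.5, n_t, 40)
  ttc <- compute_ttc(frames_from_matrix(mat, 10), 1:40)

  ri <- c(seq(1, 3, length.out = 10), seq(3, 0.5, length.out = 20))
  cropped <- crop_at_intensity_peak(ttc, ring_intensity = ri)
  expect_equal(cropped$crop_index, 10)
  expect_equal(dim(cropped$values), c(21, 21))
  expect_equal(cropped$values, ttc$values[10:30, 10:30])

  # peak at the first frame: identity crop
  same <- crop_at_intensity_peak(ttc, ring_intensity = rev(sort(ri)))
  expect_equal(same$values, ttc$values)
  expect_equal(same$crop_index, 1)

  # ties resolve to the earliest frame
  tied <- crop_at_intensity_peak(ttc, ring_intensity = rep(c(1, 2, 2), 10))
  expect_equal(tied$crop_index, 2)

  expect_error(crop_at_intensity_peak(ttc, ring_intensity = seq_len(n_t)),
               class = "specklematch_too_short_error")
  # the cap turns the error into a latest-allowed crop
  capped <- crop_at_intensity_peak(ttc, ring_intensity = seq_len(n_t),
                                   cap = TRUE)
  expect_equal(capped$crop_index, n_t - 8 + 1)
  # rel_tol crops at the plateau onset rather than the noisy argmax
  plateau <- c(seq(0.1, 1, length.out = 10), rep(1, 20)) +
    c(rep(0, 29), 0.001)
  early <- crop_at_intensity_peak(ttc, ring_intensity = plateau,
                                  rel_tol = 0.05)
  expect_lt(early$crop_index, which.max(plateau))
})

test_that("visibility normalization rescales contrast as defined", {
  s <- 20
  idx <- seq_len(s)
  base <- exp(-abs(outer(idx, idx, `-`)) / 6)
  ttc <- specklematch:::new_ttc_map(1 + 0.25 * base, idx, rep(1, s),
                                    q_center = 5, dq = 1, source = "fixture")
  out <- normalize_visibility(ttc)
  off <- mean(c(out$values[cbind(1:(s - 1), 2:s)],
                out$values[cbind(2:s, 1:(s - 1))]))
  expect_equal(off, 2, tolerance = 1e-12)
  expect_equal(out$beta, 0.25 * mean(base[cbind(1:(s - 1), 2:s)]),
               tolerance = 1e-12)

  # input whose off-diagonal contrast is already 1 passes unchanged
  beta1 <- mean(base[cbind(1:(s - 1), 2:s)])
  ttc1 <- specklematch:::new_ttc_map(1 + base / beta1, idx, rep(1, s),
                                     q_center = 5, dq = 1, source = "fixture")
  out1 <- normalize_visibility(ttc1)
  expect_equal(out1$values, ttc1$values, tolerance = 1e-12)
  expect_equal(out1$beta, 1, tolerance = 1e-12)

  flat <- specklematch:::new_ttc_map(matrix(1, s, s), idx, rep(1, s),
                                     q_center = 5, dq = 1, source = "fixture")
  expect_error(normalize_visibility(flat),
               class = "specklematch_no_contrast_error")
})

test_that("area-average downsampling preserves structure and symmetry", {
  s <- 20
  const <- specklematch:::new_ttc_map(matrix(3, 50, 50), 1:50, rep(1, 50),
                                      q_center = 5, dq = 1, source = "simulated")
  out <- rescale_ttc(const, s)
  expect_true(all(abs(out$values - 3) < 1e-12))
  expect_equal(out$s, s)

  # smooth input: two-stage and one-stage resampling agree
  idx <- seq_len(128)
  smooth <- 1 + exp(-abs(outer(idx, idx, `-`)) / 30) +
    0.3 * exp(-outer(idx, idx, `+`) / 200)
  ttc <- specklematch:::new_ttc_map(smooth, idx, rep(1, 128),
                                    q_center = 5, dq = 1, source = "simulated")
  two <- rescale_ttc(specklematch:::new_ttc_map(
    rescale_ttc(ttc, 64)$values, 1:64, rep(1, 64), 5, 1, "simulated"), 32)
  one <- rescale_ttc(ttc, 32)
  expect_equal(two$values, one$values, tolerance = 1e-6)

  # symmetric in, symmetric out
  expect_lt(max(abs(one$values - t(one$values))), 1e-9)
  expect_error(rescale_ttc(specklematch:::new_ttc_map(
    matrix(1, 4, 4), 1:4, rep(1, 4), 5, 1, "simulated"), 8),
    class = "specklematch_input_error")
})

test_that("crop and rescale commute with transposition", {
  set.seed(5)
  n_t <- 40
  mat <- matrix(rexp(n_t * 60) + 0.2, n_t, 60)
  ttc <- compute_ttc(frames_from_matrix(mat, 12), 1:60)
  ri <- c(seq(0, 1, length.out = 15), seq(1, 0.2, length.out = 25))
  out <- rescale_ttc(crop_at_intensity_peak(ttc, ring_intensity = ri), 16)
  expect_equal(out$values, t(out$values), tolerance = 1e-9)
})

test_that("slower dynamics at smaller q show as a broader diagonal band", {
  traj <- cached_small_traj()
  ramp <- ring_ramp(q_lo = 5, q_hi = 14)
  maps <- ttc_from_trajectory(traj, n_rings = 2, ramp = ramp)
  # decorrelation over 5 frames relative to the near-diagonal contrast,
  # late in the run (raw contrast is not comparable across rings: the
  # far tail has non-Gaussian speckle statistics)
  decay_ratio <- function(m, lag = 5) {
    v <- m$values
    n <- nrow(v)
    rows <- (n - 40):(n - lag)
    mean(v[cbind(rows, rows + lag)] - 1) / mean(v[cbind(rows, rows + 1)] - 1)
  }
  expect_gt(decay_ratio(maps[[1]]), decay_ratio(maps[[2]]))
})
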