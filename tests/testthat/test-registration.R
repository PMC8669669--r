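test_that("manual reference square passes through; undersized frames error", {
  f <- matrix(runif(300 * 400), 300, 400)
  expect_equal(select_reference_square(f, 64, "manual", corner = c(10, 20)),
               c(10L, 20L, 64L))
  expect_error(select_reference_square(f, 512), class = "cammesh_validation_error")
})

test_that("auto square selection matches an exhaustive contrast scan", {
  set.seed(7)
  f <- cammesh:::sep_convolve(matrix(rnorm(96 * 96), 96, 96),
                              cammesh:::gaussian_kernel_1d(2))
  f[30:60, 40:70] <- f[30:60, 40:70] + 3 * matrix(rnorm(31^2), 31)  # contrast pocket
  sq <- select_reference_square(f, 32, "auto", stride = 1)
  # brute-force oracle over every corner
  best <- -Inf
  for (r in 1:(96 - 32 + 1)) for (cc in 1:(96 - 32 + 1)) {
    v <- stats::var(as.vector(f[r:(r + 31), cc:(cc + 31)]))
    if (v > best) best <- v
  }
  got <- stats::var(as.vector(f[sq[1] + 1:32, sq[2] + 1:32]))
  expect_gte(got, 0.99 * best)
  expect_warning(select_reference_square(matrix(1, 64, 64), 32, "auto"),
                 "constant")
})

test_that("displacement estimation is exact for identity and known translations", {
  set.seed(1)
  world <- matrix(runif(100 * 100), 100, 100)
  f0 <- world[11:90, 11:90]
  est0 <- estimate_displacement(f0[31:60, 31:60], f0, pos = c(30, 30))
  expect_equal(est0$shift, c(0, 0))
  expect_equal(est0$peak_corr, 1, tolerance = 1e-9)
  ft <- world[11:90 - 3, 11:90 + 2]  # content translated by (+3, -2), no wrap
  est <- estimate_displacement(f0[31:60, 31:60], ft, pos = c(30, 30))
  expect_equal(est$shift, c(3, -2))
})

test_that("displacement matches an exhaustive normalized cross-correlation scan", {
  for (seed in 1:10) {
    set.seed(seed)
    world <- cammesh:::sep_convolve(matrix(rnorm(80 * 80), 80, 80),
                                    cammesh:::gaussian_kernel_1d(1.5))
    frame <- world[9:72, 9:72] + matrix(rnorm(64^2, 0, 0.05), 64)
    patch <- world[20:43, 20:43]  # 24x24 patch at pos (11, 11) in frame coords
    est <- estimate_displacement(patch, frame, pos = c(11, 11), max_shift_px = 5)
    # brute force over the full +/-5 grid with cor()
    best <- -Inf; bs <- NULL
    for (dr in -5:5) for (dc in -5:5) {
      r0 <- 11 + dr; c0 <- 11 + dc
      if (r0 < 0 || c0 < 0 || r0 + 24 > 64 || c0 + 24 > 64) next
      v <- stats::cor(as.vector(patch),
                      as.vector(frame[r0 + 1:24, c0 + 1:24]))
      if (v > best) { best <- v; bs <- c(dr, dc) }
    }
    expect_equal(est$shift, bs)
    expect_equal(est$peak_corr, best, tolerance = 1e-9)
  }
})

test_that("aligning identical frames is the identity", {
  f <- matrix(runif(64^2), 64, 64)
  st <- frame_stack(array(f, dim = c(64, 64, 4)))
  al <- align_stack(st, analysis_config(reference_square = c(16, 16, 32)))
  expect_equal(al$trace$d_row, rep(0, 4))
  expect_equal(al$aligned$frames, st$frames)
  expect_equal(al$valid_region, c(0, 64, 0, 64))
})

test_that("scripted drift is recovered exactly and aligning is idempotent", {
  drift <- rbind(c(0, 0), c(1, 0), c(2, 1), c(2, 2), c(1, 2), c(0, 1))
  ds <- make_drift_stack(11, n_frames = 6, drift = drift)
  cfg <- analysis_config(reference_square = c(16, 16, 32), max_shift_px = 4)
  al <- align_stack(ds$stack, cfg)
  expect_identical(cbind(al$trace$d_row, al$trace$d_col), ds$drift)
  # re-estimating on the aligned stack gives all-zero shifts
  al2 <- align_stack(al$aligned, analysis_config(reference_square = c(10, 10, 32),
                                                 max_shift_px = 4))
  expect_true(all(al2$trace$d_row == 0 & al2$trace$d_col == 0))
  # valid region excludes rows/cols not covered by every shifted frame:
  # drift reaches +2 in rows and +2 in cols, so 2 trailing lines are lost
  expect_equal(al$valid_region, c(0, 62, 0, 62))
})

test_that("drift beyond max_shift_px raises a registration error naming the frame", {
  drift <- rbind(c(0, 0), c(1, 1), c(8, 8), c(8, 8))
  ds <- make_drift_stack(13, n_frames = 4, max_drift = 8, drift = drift)
  err <- expect_error(
    align_stack(ds$stack, analysis_config(reference_square = c(20, 20, 32),
                                          max_shift_px = 3)),
    class = "cammesh_registration_error")
  expect_match(conditionMessage(err), "frame 2")
})
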