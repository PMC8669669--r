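test_that("SD and cumulative-change images match brute-force per-pixel formulas", {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  cum_abs <- function(x) sum(abs(diff(x)))
  for (seed in 1:50) {
    set.seed(seed)
    d <- c(sample(3:6, 2, TRUE), sample(2:8, 1))
    f <- array(runif(prod(d), 0, 255), dim = d)
    st <- frame_stack(f)
    expect_lt(max(abs(sd_image(st)$values - apply(f, c(1, 2), pop_sd))), 1e-9)
    expect_lt(max(abs(cumulative_change_image(st)$values - apply(f, c(1, 2), cum_abs))), 1e-9)
  }
})

test_that("the witness pair separates SD from perfusion", {
  # same amplitude, different frequency: equal SD, unequal cumulative change
  a <- frame_stack(array(rep(c(0, 0, 10, 10), each = 1), dim = c(1, 1, 4)))
  b <- frame_stack(array(rep(c(0, 10, 0, 10), each = 1), dim = c(1, 1, 4)))
  expect_equal(sd_image(a)$values[1, 1], 5)
  expect_equal(sd_image(b)$values[1, 1], 5)
  expect_equal(cumulative_change_image(a)$values[1, 1], 10)
  expect_equal(cumulative_change_image(b)$values[1, 1], 30)
})

test_that("SD is permutation-invariant; cumulative change is not", {
  set.seed(5)
  f <- array(runif(6 * 6 * 8, 0, 50), dim = c(6, 6, 8))
  perm <- sample(8)
  st <- frame_stack(f); stp <- frame_stack(f[, , perm])
  expect_equal(sd_image(st)$values, sd_image(stp)$values)
  expect_false(isTRUE(all.equal(cumulative_change_image(st)$values,
                                cumulative_change_image(stp)$values)))
})

test_that("repeating an oscillation doubles the raw cumulative change", {
  one <- frame_stack(array(c(0, 10, 0, 10), dim = c(1, 1, 4)))
  two <- frame_stack(array(c(0, 10, 0, 10, 0, 10, 0, 10), dim = c(1, 1, 8)))
  expect_equal(cumulative_change_image(two)$values[1, 1],
               2 * cumulative_change_image(one)$values[1, 1] + 10)
  # (the extra 10 is the single transition joining the two repeats)
})

test_that("constant stacks yield all-zero projections", {
  st <- frame_stack(array(7, dim = c(4, 4, 5)))
  expect_true(all(sd_image(st)$values == 0))
  expect_true(all(cumulative_change_image(st)$values == 0))
})

test_that("normalization scales the maximum to 1, preserves zero, and is idempotent", {
  img <- projection_image(matrix(c(0, 1, 2, 5), 2, 2), "vessel_sd", "raw")
  n1 <- normalize_to_dynamic_range(img)
  expect_equal(max(n1$values), 1)
  expect_equal(n1$values, img$values / 5)
  expect_equal(normalize_to_dynamic_range(n1)$values, n1$values)
  zero <- projection_image(matrix(0, 2, 2), "vessel_sd", "raw")
  expect_warning(nz <- normalize_to_dynamic_range(zero), "all-zero")
  expect_true(all(nz$values == 0))
  bad <- projection_image(matrix(c(1, NA, 1, 1), 2, 2), "vessel_sd", "raw")
  expect_error(normalize_to_dynamic_range(bad), class = "cammesh_validation_error")
})

test_that("pseudocolor maps endpoints to LUT extremes with monotone luminance", {
  lut <- cammesh:::perfusion_lut()
  ramp <- projection_image(matrix(seq(0, 1, length.out = 256), 16, 16),
                           "perfusion_cumchange", "unit")
  rgb <- pseudocolor(ramp)
  expect_equal(rgb[1, 1, ], unname(lut[1, ]))
  expect_equal(rgb[16, 16, ], unname(lut[256, ]))
  # photometric (linear-light) luminance rises along the LUT, up to the
  # 8-bit quantization of the stored colors (1/255 per channel)
  lin <- ifelse(lut <= 0.04045, lut / 12.92, ((lut + 0.055) / 1.055)^2.4)
  Y <- 0.2126 * lin[, 1] + 0.7152 * lin[, 2] + 0.0722 * lin[, 3]
  expect_true(all(diff(Y) > -1 / 255))
  expect_gt(Y[256], Y[1] + 0.5)
  expect_gt(stats::cor(seq_len(256), Y, method = "spearman"), 0.999)
  # identical normalized values -> identical RGB, regardless of raw maxima
  a <- normalize_to_dynamic_range(projection_image(matrix(c(1, 2, 3, 4), 2, 2),
                                                   "perfusion_cumchange", "raw"))
  b <- normalize_to_dynamic_range(projection_image(matrix(c(10, 20, 30, 40), 2, 2),
                                                   "perfusion_cumchange", "raw"))
  expect_identical(pseudocolor(a), pseudocolor(b))
  raw <- projection_image(matrix(1:4, 2, 2), "perfusion_cumchange", "raw")
  expect_error(pseudocolor(raw), class = "cammesh_validation_error")
})
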