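test_that("Gaussian enhancement preserves constants, mass, and the kernel center", {
  expect_equal(enhance(matrix(3.5, 9, 9), 1.2), matrix(3.5, 9, 9))
  # unit impulse: center value equals the 2-D kernel center weight; mass kept
  k <- cammesh:::gaussian_kernel_1d(1)
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  e <- enhance(img, 1)
  expect_equal(e[11, 11], max(k)^2)
  expect_lt(abs(sum(e) - 1), 1e-6)
  set.seed(2)
  interior <- matrix(0, 31, 31)
  interior[8:24, 8:24] <- runif(17^2)
  expect_lt(abs(sum(enhance(interior, 1.5)) - sum(interior)), 1e-6)
  expect_error(enhance(img, 0), class = "cammesh_validation_error")
})

test_that("double threshold separates bimodal images and rescues dim lines", {
  b <- matrix(10, 20, 20); b[5:10, 5:10] <- 200
  expect_identical(double_threshold(b, 5, -0.02, 1), b == 200)
  # dim thin line (60) on background 50 next to a bright blob (200):
  img <- matrix(50, 120, 120)
  img[60, 10:110] <- 60
  img[20:40, 20:40] <- 200
  line_px <- cbind(60, 10:110)
  union_mask <- double_threshold(img, 51, -0.02, 5)
  global_mask <- double_threshold(img, 51, -0.02, 5, use_local = FALSE)
  expect_gte(mean(union_mask[line_px]), 0.95)
  expect_lt(mean(global_mask[line_px]), 0.5)
  expect_true(all(union_mask[global_mask]))   # union superset of global-only
  expect_warning(flat <- double_threshold(matrix(4, 10, 10), 5, -0.02, 1), "flat")
  expect_false(any(flat))
})

test_that("union mask is a pixelwise superset of the global-only mask", {
  for (seed in 1:10) {
    set.seed(seed)
    img <- cammesh:::sep_convolve(matrix(runif(48^2), 48, 48),
                                  cammesh:::gaussian_kernel_1d(1))
    u <- double_threshold(img, 11, -0.01, 3)
    g <- double_threshold(img, 11, -0.01, 3, use_local = FALSE)
    expect_true(all(u[g]))
  }
})

test_that("skeletonization thins a bar to its medial row and keeps topology on a ring", {
  bar <- matrix(FALSE, 9, 21); bar[4:6, ] <- TRUE
  sk <- skeletonize_mask(bar)
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 5))   # middle row only
  expect_equal(sum(sk), 21)
  expect_equal(attr(flood_label(sk, 8), "n"), 1)
  ring <- ring_mask()
  skr <- skeletonize_mask(ring)
  expect_equal(euler_oracle(skr), 0)          # one component, one hole
  expect_equal(euler_oracle(skr), euler_oracle(ring))
  expect_false(any(skeletonize_mask(matrix(FALSE, 5, 5))))
})

test_that("thinning preserves component count and Euler number on 200 random masks", {
  for (seed in 1:200) {
    m <- if (seed %% 10 == 0) ring_mask(15, 1 + seed %% 3, 5 + seed %% 2)
         else random_blob_mask(seed)
    sk <- skeletonize_mask(m)
    expect_true(all(!(sk & !m)))                               # skeleton inside mask
    expect_identical(attr(flood_label(sk, 8), "n"), attr(flood_label(m, 8), "n"))
    expect_identical(euler_oracle(sk), euler_oracle(m))
    # the package's own Euler bookkeeping agrees with the independent oracle
    expect_identical(euler_number(m), euler_oracle(m))
  }
})

test_that("tissue islands are enclosed holes, cleaned and area-filtered", {
  m <- matrix(FALSE, 20, 20)
  m[4:16, 4:16] <- TRUE; m[6:14, 6:14] <- FALSE   # ring around a 9x9 hole
  isl <- extract_tissue_islands(m, morph_radius_px = 1, min_island_area_px = 10)
  expect_equal(attr(isl, "n"), 1L)
  expect_gte(sum(isl > 0), 49)                    # >= (9x9 minus opening loss)
  expect_true(all(!(isl > 0 & m)))                # disjoint from vessels
  expect_equal(attr(extract_tissue_islands(matrix(TRUE, 8, 8), 1, 1), "n"), 0L)
  expect_equal(attr(extract_tissue_islands(matrix(FALSE, 8, 8), 1, 1), "n"), 0L)
  # area filter: raising the minimum above the hole size drops it
  expect_equal(attr(extract_tissue_islands(m, 1, 60), "n"), 1L)
  expect_equal(attr(extract_tissue_islands(m, 1, 200), "n"), 0L)
})

test_that("morphometry of an analytic 3-px vessel matches geometry", {
  m <- matrix(FALSE, 100, 100); m[49:51, ] <- TRUE
  seg <- network_segmentation(m)
  rec <- measure_network(seg)
  expect_equal(rec$area_fraction, 0.03)
  expect_lt(abs(rec$diam_mean_px - 3), 0.5)
  expect_lt(rec$diam_cv, 0.1)
  expect_equal(rec$n_islands, 0L)
  expect_true(is.na(rec$island_area_cv))
  # all outputs non-negative; area fraction bounded
  nums <- unlist(rec[vapply(rec, is.numeric, logical(1))])
  expect_true(all(nums[!is.na(nums)] >= 0))
  expect_lte(rec$area_fraction, 1)
  empty <- network_segmentation(matrix(FALSE, 10, 10))
  expect_warning(rec0 <- measure_network(empty), "empty skeleton")
  expect_equal(rec0$diam_mean_px, 0)
})

test_that("network_segmentation enforces its structural invariants", {
  m <- ring_mask()
  expect_error(network_segmentation(m, skeleton = m | TRUE),
               class = "cammesh_validation_error")
  bad_isl <- matrix(0L, nrow(m), ncol(m)); bad_isl[which(m)[1]] <- 1L
  expect_error(network_segmentation(m, islands = bad_isl),
               class = "cammesh_validation_error")
})
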