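test_that("quad area: unit square, orientation and cyclic invariance", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(quad_area(landmark_quad(sq)), 1)
  expect_equal(quad_area(landmark_quad(sq[4:1, ])), 1)          # reversed
  expect_equal(quad_area(landmark_quad(sq[c(3, 4, 1, 2), ])), 1) # rotated
  expect_equal(quad_area(landmark_quad(sq * 10), pixel_size_um = 2), 400)
  # bow-tie ordering is rejected with a reorder hint
  expect_error(landmark_quad(sq[c(1, 3, 2, 4), ]), "reorder")
})

test_that("random convex quads match a two-triangle oracle", {
  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  for (seed in 1:25) {
    set.seed(seed)
    ang <- sort(runif(4, 0, 2 * pi))
    r <- runif(1, 5, 20)
    p <- cbind(50 + r * sin(ang), 50 + r * cos(ang))  # on a circle: convex
    q <- landmark_quad(p)
    oracle <- tri_area(p[1, ], p[2, ], p[3, ]) + tri_area(p[1, ], p[3, ], p[4, ])
    expect_equal(quad_area(q), oracle, tolerance = 1e-9)
  }
})

test_that("relative-area traces start at 1 and track scaling exactly", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  same <- lapply(c(0, 5, 10), function(tp) landmark_quad(sq, timepoint_h = tp))
  tr <- area_series(same)
  expect_identical(tr$rel_area, rep(1, 3))
  scaled <- list(landmark_quad(sq, 0), landmark_quad(sq * 1.1, 7))
  tr2 <- area_series(scaled)
  expect_equal(tr2$rel_area[2], 1.21, tolerance = 1e-9)
  expect_error(area_series(scaled[1]), class = "cammesh_validation_error")
})

test_that("scripted linear areal growth is recovered by a fitted slope", {
  # 5%/interval areal growth over 5 timepoints
  sq <- rbind(c(10, 10), c(10, 110), c(110, 110), c(110, 10))
  quads <- lapply(0:4, function(t)
    landmark_quad((sq - 60) * sqrt(1 + 0.05 * t) + 60, timepoint_h = t))
  tr <- area_series(quads)
  slope <- stats::coef(stats::lm(rel_area ~ timepoint_h, tr))[2]
  expect_lt(abs(slope - 0.05), 0.005 * 0.05 + 1e-9)
})

test_that("capillary density is consistent with whole-ROI morphometry and additive", {
  p1 <- phase1_fixture()
  seg <- p1$res$segmentation
  d <- dim(seg$vessel_mask)
  full <- landmark_quad(rbind(c(-0.5, -0.5), c(-0.5, d[2] - 0.5),
                              c(d[1] - 0.5, d[2] - 0.5), c(d[1] - 0.5, -0.5)))
  dens <- capillary_density(seg, full)
  rec <- p1$res$morphometry
  expect_lt(abs(dens$skel_len_density - rec$skel_len_density),
            0.01 * rec$skel_len_density)
  expect_lt(abs(dens$area_fraction - rec$area_fraction),
            0.01 * rec$area_fraction)
  # two quads tiling a region: area-weighted densities match the whole
  mid <- (d[1] - 1) / 2
  qa <- landmark_quad(rbind(c(0, 0), c(0, d[2] - 1), c(mid, d[2] - 1), c(mid, 0)))
  qb <- landmark_quad(rbind(c(mid, 0), c(mid, d[2] - 1),
                            c(d[1] - 1, d[2] - 1), c(d[1] - 1, 0)))
  qall <- landmark_quad(rbind(c(0, 0), c(0, d[2] - 1),
                              c(d[1] - 1, d[2] - 1), c(d[1] - 1, 0)))
  da <- capillary_density(seg, qa); db <- capillary_density(seg, qb)
  dall <- capillary_density(seg, qall)
  pooled <- (da$skel_len_density * da$n_px + db$skel_len_density * db$n_px) /
    (da$n_px + db$n_px)
  expect_lt(abs(pooled - dall$skel_len_density), 0.01 * max(dall$skel_len_density, 1e-9))
  expect_equal(da$n_px + db$n_px, dall$n_px)
  # degenerate and invalid quads
  empty_seg <- network_segmentation(matrix(FALSE, 40, 40))
  q <- landmark_quad(rbind(c(5, 5), c(5, 30), c(30, 30), c(30, 5)))
  expect_equal(capillary_density(empty_seg, q)$skel_len_density, 0)
  far <- landmark_quad(rbind(c(5, 5), c(5, 90), c(30, 90), c(30, 5)))
  expect_error(capillary_density(empty_seg, far), class = "cammesh_validation_error")
})
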