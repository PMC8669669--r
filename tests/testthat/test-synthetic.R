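test_that("scene generation is deterministic and validates geometry", {
  s1 <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 9)
  s2 <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 9)
  expect_identical(s1, s2)
  s3 <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 10)
  expect_false(identical(s1$segments, s3$segments))
  expect_error(generate_mesh_scene(c(128, 128), mean_island_diameter_px = 60),
               class = "cammesh_validation_error")
  expect_error(generate_mesh_scene(c(256, 256), mean_island_diameter_px = 2),
               class = "cammesh_validation_error")
})

test_that("phase presets order island statistics as the remodeling sequence does", {
  for (seed in 1:3) {
    ss <- do.call(rbind, lapply(c("I", "II", "III", "IV"), function(ph)
      scene_summary(generate_mesh_scene(c(256, 256), phase_preset = ph, seed = seed))))
    expect_lt(ss$island_area_cv[1], ss$island_area_cv[4])  # I more even than IV
    expect_lt(ss$diam_cv[1], ss$diam_cv[2])                # pathway widens in II
    expect_equal(ss$n_islands_in_band[4], 0)               # IV: channel cleared
    expect_lte(ss$n_islands_in_band[3], 2)                 # III: residual pillars
    expect_gt(ss$n_islands_in_band[2], ss$n_islands_in_band[3])
  }
})

test_that("null renders are static and dark-particle renders obey the absorbance contract", {
  scene <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 4)
  null <- render_video(scene, render_params(
    n_frames = 4, rbc_density_per_px = 0, tissue_flicker_sd = 0,
    sensor_noise_sd = 0, static_texture_sd = 0, seed = 1))
  f <- null$stack$frames
  expect_true(all(f[, , 1] == f[, , 2]) && all(f[, , 1] == f[, , 4]))
  expect_true(all(sd_image(null$stack)$values == 0))
  # with particles: vessels darker on average, fluctuating more, than tissue
  rv <- render_video(scene, render_params(n_frames = 30, seed = 2))
  tm <- rv$truth$vessel_mask
  mean_img <- rowMeans(rv$stack$frames, dims = 2)
  sd_img <- sd_image(rv$stack)$values
  expect_lt(mean(mean_img[tm]), mean(mean_img[!tm]))
  expect_gt(mean(sd_img[tm]), mean(sd_img[!tm]))
})

test_that("renders are bit-identical under a fixed seed with seed-independent truth", {
  scene <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 4)
  r1 <- render_video(scene, render_params(n_frames = 6, seed = 5))
  r2 <- render_video(scene, render_params(n_frames = 6, seed = 5))
  r3 <- render_video(scene, render_params(n_frames = 6, seed = 6))
  expect_identical(r1$stack$frames, r2$stack$frames)
  expect_false(identical(r1$stack$frames, r3$stack$frames))
  expect_identical(r1$truth$vessel_mask, r3$truth$vessel_mask)
  expect_identical(r1$truth$islands, r3$truth$islands)
})

test_that("drift beyond the scene margin is rejected", {
  scene <- generate_mesh_scene(c(256, 256), phase_preset = "I", seed = 4)
  drift <- matrix(0L, 4, 2); drift[3, ] <- c(scene$margin + 1L, 0L)
  expect_error(render_video(scene, render_params(n_frames = 4, drift_script = drift)),
               class = "cammesh_validation_error")
})

test_that("truth islands lie outside the rendered lumen", {
  for (ph in c("I", "III")) {
    scene <- generate_mesh_scene(c(256, 256), phase_preset = ph, seed = 8)
    rv <- render_video(scene, render_params(n_frames = 2, seed = 1))
    expect_false(any(rv$truth$vessel_mask & rv$truth$islands > 0))
  }
})

test_that("recovery scoring behaves at its fixed points and for random masks", {
  p1 <- phase1_fixture()
  truth <- p1$rv$truth
  perfect <- network_segmentation(truth$vessel_mask, islands = truth$islands,
                                  check = FALSE)
  tm <- truth_metrics(truth, perfect)
  expect_equal(tm$dice, 1)
  expect_equal(tm$island_count_error, 0L)
  expect_true(all(tm$island_jaccard == 1))
  allfalse <- network_segmentation(matrix(FALSE, 256, 256), check = FALSE)
  expect_equal(truth_metrics(truth, allfalse)$dice, 0)
  # a random mask at the truth's foreground fraction has expected Dice ~ p
  p <- mean(truth$vessel_mask)
  set.seed(1)
  dices <- replicate(100, {
    rnd <- matrix(runif(256^2) < p, 256, 256)
    seg <- network_segmentation(rnd, skeleton = matrix(FALSE, 256, 256),
                                islands = matrix(0L, 256, 256), check = FALSE)
    truth_metrics(truth, seg)$dice
  })
  expect_lt(abs(mean(dices) - p), 0.02)
})
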