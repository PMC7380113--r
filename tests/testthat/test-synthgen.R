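test_that("caliper ground truth obeys the PPC conversion rules", {
  g10 <- generate_caliper(caliper_spec("10", 59, 5), image_height = 300,
                          noise_level = 0, seed = 0)
  expect_equal(g10$truth$ppc, 59)
  g5 <- generate_caliper(caliper_spec("5", 30, 6), image_height = 260,
                         noise_level = 0, seed = 0)
  expect_equal(g5$truth$ppc, 60)
  expect_equal(diff(g10$truth$tick_y), rep(59, 4))
})

test_that("caliper spec invariants are enforced", {
  expect_error(caliper_spec("5", 30, 5, big_tick_len = 5, small_tick_len = 4),
               class = "lv_validation_error")
  expect_error(caliper_spec("10", 3, 5), class = "lv_validation_error")
  expect_error(caliper_spec("10", 30, 2), class = "lv_validation_error")
  # spec that does not fit the canvas
  expect_error(generate_caliper(caliper_spec("10", 60, 10), image_height = 100),
               class = "lv_dimension_error")
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- caliper_spec("10", 40, 5)
  a <- generate_caliper(sp, 220, noise_level = 0.4, seed = 7)
  b <- generate_caliper(sp, 220, noise_level = 0.4, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_caliper(sp, 220, noise_level = 0.4, seed = 8)
  expect_false(identical(a$image, c$image))

  s1 <- compose_scene(sp, list(width_mm = 9), noise_level = 0.3, seed = 5)
  s2 <- compose_scene(sp, list(width_mm = 9), noise_level = 0.3, seed = 5)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(generate_caliper(caliper_spec("10", 40, 5), 220,
                             noise_level = 0.5, seed = 99))
  expect_identical(runif(1), before)
})

test_that("LV blob rasterisation hits the requested physical width", {
  # 10 mm at 60 px/cm = one centimeter of pixels: 60-row minor axis
  b <- generate_lv_blob(10, 60, 2, 0, center = c(100.5, 100.5),
                        canvas = c(240, 240))
  expect_equal(sum(b$mask[, 101]), 60)      # central column
  expect_equal(max(colSums(b$mask)), 60)
  # fractional request: 7 mm at 65 px/cm = 45.5 px, extent within 1 px
  b2 <- generate_lv_blob(7, 65, 2, 0, center = c(80.5, 80.5),
                         canvas = c(200, 200))
  expect_lte(abs(max(colSums(b2$mask)) - 45.5), 1)
  # circle: mask invariant to rotation up to rasterisation
  c0 <- generate_lv_blob(8, 50, 1, 0, center = c(60.5, 60.5),
                         canvas = c(140, 140))
  c1 <- generate_lv_blob(8, 50, 1, 37, center = c(60.5, 60.5),
                         canvas = c(140, 140))
  expect_lt(sum(abs(c0$mask - c1$mask)) / sum(c0$mask), 0.02)
  expect_error(generate_lv_blob(50, 80, 2, 0, center = c(50, 50),
                                canvas = c(100, 100)),
               class = "lv_dimension_error")
})

test_that("scene ground truth is self-consistent and recoverable", {
  sp <- caliper_spec("5", 30, 6, column_x = 30)
  scene <- compose_scene(sp, list(width_mm = 9.5, theta_deg = 40),
                         noise_level = 0, seed = 2)
  tr <- scene$truth
  expect_equal(tr$true_width_px / tr$true_ppc * 10, tr$true_width_mm)
  expect_equal(tr$true_ppc, 60)
  # noiseless caliper crop thresholded at 127 shows exactly n_ticks blobs
  cal <- crop(scene$image, tr$caliper_box)
  expect_equal(max(label_components((cal > 127) * 1L)), 6L)
  # noiseless recovery of the calibration from the caliper crop
  est <- estimate_ppc(cal)
  expect_equal(est$ppc, tr$true_ppc)
  expect_equal(est$caliper_type, tr$caliper_type)
})

test_that("overlapping LV and caliper layouts are rejected", {
  sp <- caliper_spec("10", 40, 5, column_x = 30)
  expect_error(
    compose_scene(sp, list(width_mm = 10, center = c(40, 200))),
    class = "lv_layout_error")
})

test_that("scene files round-trip losslessly through disk", {
  sp <- caliper_spec("10", 45, 5, column_x = 25)
  scene <- compose_scene(sp, list(width_mm = 11, theta_deg = 15),
                         noise_level = 0.2, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_scene(scene, dir)
  expect_identical(read_gray(paths[["image"]]), scene$image)
  expect_identical(read_mask(paths[["mask"]]), scene$truth$lv_mask)
  tr <- read_scene_truth(paths[["truth"]])
  expect_equal(tr$ppc, scene$truth$true_ppc)
  expect_equal(tr$lv$width_mm, scene$truth$true_width_mm)
  expect_equal(unlist(tr$caliper$tick_y), scene$truth$tick_y)
  # identical seed -> byte-identical sidecar
  paths2 <- write_scene(compose_scene(sp, list(width_mm = 11, theta_deg = 15),
                                      noise_level = 0.2, seed = 11),
                        dir, "again")
  expect_identical(readLines(paths[["truth"]], warn = FALSE),
                   readLines(paths2[["truth"]], warn = FALSE))
})

test_that("distractor blobs are off by default and optional", {
  sp <- caliper_spec("10", 40, 5, column_x = 25)
  plain <- compose_scene(sp, list(width_mm = 8), seed = 1)
  busy <- compose_scene(sp, list(width_mm = 8), seed = 1, n_distractors = 2)
  expect_gt(sum(busy$image > 127), sum(plain$image > 127))
  expect_identical(plain$truth$lv_mask, busy$truth$lv_mask)
})
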