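# bar-grid mask: 2-px-high bars of width `len` whose top-left corners sit at
# the given 0-based (x, y) positions — the shape family the ruler emits
bars_mask <- function(nr, nc, ys, x0 = 20, len = 9, h = 2) {
  m <- matrix(0L, nr, nc)
  for (y in ys) m[(y + 1):(y + h), (x0 + 1):(x0 + len)] <- 1L
  m
}

test_that("background filtering suppresses flats and specks, keeps ticks", {
  expect_equal(sum(preprocess_caliper(matrix(128L, 40, 40))), 0)
  speck <- matrix(10L, 40, 40); speck[20, 20] <- 255L
  expect_equal(sum(preprocess_caliper(speck)), 0)
  # large smooth bright blob: zero Laplacian interior, opening eats the rim
  blob <- generate_lv_blob(10, 50, 1.5, 0, c(40.5, 40.5), c(90, 90))$image
  expect_lt(sum(preprocess_caliper(blob)) / sum(blob > 0), 0.2)
  # a noiseless ruler crop keeps exactly one component per tick
  for (type in c("10", "5")) {
    g <- generate_caliper(caliper_spec(type, 40, 7), 300, 0, seed = 1)
    m <- preprocess_caliper(g$image)
    expect_equal(max(label_components(m)), 7L)
  }
})

test_that("contours are 8-connected outer boundaries in raster order", {
  expect_length(find_contours(matrix(0L, 10, 10)), 0L)
  sq <- matrix(0L, 10, 10); sq[4:6, 4:6] <- 1L
  cts <- find_contours(sq)
  expect_length(cts, 1L)
  expect_equal(cts[[1]]$n_points, 8L)     # 3x3 block minus its centre
  expect_equal(cts[[1]]$ref_point, c(3L, 3L))
  # diagonal touch joins into one component
  diag2 <- matrix(0L, 10, 10); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_length(find_contours(diag2), 1L)
  # two disjoint squares sorted by row then column
  two <- matrix(0L, 20, 20); two[12:14, 2:4] <- 1L; two[2:4, 8:10] <- 1L
  refs <- lapply(find_contours(two), `[[`, "ref_point")
  expect_equal(refs, list(c(7L, 1L), c(1L, 11L)))
})

test_that("large-contour filtering uses the strict boundary-point cutoff", {
  m <- matrix(0L, 40, 80)
  m[5, 2:32] <- 1L          # 1x31 bar: 31 boundary points -> removed
  m[20, 2:31] <- 1L         # 1x30 bar: 30 points -> kept
  kept <- filter_large(find_contours(m), 30)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$n_points, 30L)
  expect_length(filter_large(list(), 30), 0L)
})

test_that("ruler axis voting picks the column crossed by most contours", {
  m <- bars_mask(300, 80, ys = c(10, 69, 128, 187, 246), x0 = 36, len = 9)
  m[5, 5] <- 1L; m[290, 70] <- 1L       # stray specks off the ruler line
  vote <- ruler_axis_vote(find_contours(m))
  expect_length(vote$contours, 5L)
  expect_true(vote$axis_coord >= 36 && vote$axis_coord < 45)
  # tie between two columns breaks toward the smaller coordinate
  tie <- matrix(0L, 100, 60)
  for (y in c(10, 40, 70)) { tie[y, 10] <- 1L; tie[y, 50] <- 1L }
  expect_equal(ruler_axis_vote(find_contours(tie))$axis_coord, 9L)
  expect_error(ruler_axis_vote(list()), class = "lv_extraction_error")
})

test_that("modal adjacent spacing handles exact, noisy and tied gaps", {
  cts <- find_contours(bars_mask(260, 60, c(10, 69, 128, 187)))
  expect_equal(adjacent_spacing_mode(cts), 59L)
  # gaps 29, 29, 28, 29 -> mode 29
  cts2 <- find_contours(bars_mask(180, 60, c(10, 39, 68, 96, 125)))
  expect_equal(adjacent_spacing_mode(cts2), 29L)
  # tie 10, 10, 20, 20 -> smaller distance wins (harmonic guard)
  cts3 <- find_contours(bars_mask(120, 60, c(5, 15, 25, 45, 65), h = 2))
  expect_equal(adjacent_spacing_mode(cts3), 10L)
  expect_error(adjacent_spacing_mode(cts3[1:2]),
               class = "lv_extraction_error")
})

test_that("tick chaining drops strays and tolerates small gap jitter", {
  m <- bars_mask(220, 60, c(10, 69, 128))
  m[76, 22] <- 1L                        # stray speck on the ruler line
  cts <- find_contours(m)
  ticks <- select_scale_ticks(cts, 59L, tolerance_px = 2L)
  expect_length(ticks, 3L)
  # gap of 61 is within 59 +/- 2: all four ticks kept
  cts2 <- find_contours(bars_mask(260, 60, c(10, 69, 128, 189)))
  expect_length(select_scale_ticks(cts2, 59L, 2L), 4L)
  # output independent of input contour ordering
  for (perm in list(c(3, 1, 4, 2), c(4, 3, 2, 1))) {
    shuffled <- select_scale_ticks(cts2[perm], 59L, 2L)
    expect_equal(lapply(shuffled, function(t) t$contour$ref_point),
                 lapply(select_scale_ticks(cts2, 59L, 2L),
                        function(t) t$contour$ref_point))
  }
  expect_error(select_scale_ticks(cts[1:2], 59L),
               class = "lv_extraction_error")
})

test_that("caliper type follows the big-small-big / uniform size rules", {
  tick <- function(s) list(size_score = s)
  expect_equal(classify_caliper(lapply(c(9, 4, 9, 4, 9), tick)), "5")
  expect_equal(classify_caliper(lapply(c(8, 8, 8, 8), tick)), "10")
  expect_error(classify_caliper(lapply(c(9, 9, 4, 4), tick)),
               class = "lv_classification_error")
  # mild size jitter is still a 10-caliper, not an alternating pattern
  expect_equal(classify_caliper(lapply(c(8, 9, 8, 9), tick)), "10")
})

test_that("the PPC conversion doubles for the 5-mm ruler", {
  expect_equal(compute_ppc(59, "10")$ppc, 59)
  expect_equal(compute_ppc(30, "5")$ppc, 60)
  expect_equal(compute_ppc(1, "10")$ppc, 1)
  expect_error(compute_ppc(0, "10"), class = "lv_validation_error")
})

test_that("end-to-end estimation recovers noiseless fixtures exactly", {
  g <- generate_caliper(caliper_spec("10", 59, 5), 320, 0, seed = 0)
  est <- estimate_ppc(g$image)
  expect_equal(est$caliper_type, "10")
  expect_equal(est$spacing_px, 59L)
  expect_equal(est$ppc, 59)
  g5 <- generate_caliper(caliper_spec("5", 30, 6), 260, 0, seed = 0)
  est5 <- estimate_ppc(g5$image)
  expect_equal(est5$caliper_type, "5")
  expect_equal(est5$ppc, 60)
  expect_error(estimate_ppc(matrix(15L, 60, 60)),
               class = "lv_extraction_error")
})

test_that("estimation is invariant to translating the crop", {
  g <- generate_caliper(caliper_spec("5", 36, 5, column_x = 18), 240, 0, 0)
  base <- estimate_ppc(g$image)
  shifted <- matrix(15L, 260, 90)
  shifted[13:252, 9:72] <- g$image
  est <- estimate_ppc(shifted)
  expect_equal(est$spacing_px, base$spacing_px)
  expect_equal(est$caliper_type, base$caliper_type)
})

test_that("exact recovery holds across a spacing x tick-count sample", {
  for (type in c("10", "5")) for (s in c(20, 35, 50, 65, 80))
    for (k in c(3, 7, 12)) {
      g <- generate_caliper(caliper_spec(type, s, k),
                            image_height = (k - 1) * s + 20,
                            noise_level = 0, seed = 1)
      est <- estimate_ppc(g$image)
      expect_equal(est$spacing_px, as.integer(s))
      expect_equal(est$caliper_type, type)
    }
})

test_that("a horizontal ruler is supported via the axis switch", {
  g <- generate_caliper(caliper_spec("10", 40, 5), 240, 0, seed = 0)
  est <- estimate_ppc(t(g$image), ppc_config(ruler_axis = "horizontal"))
  expect_equal(est$spacing_px, 40L)
  expect_equal(est$caliper_type, "10")
})
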